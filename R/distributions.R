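# Per-cell concentration distribution fitting and sampling.
#
# Candidate families are right-skewed non-negative laws (lognormal, gamma,
# Weibull) plus a normal truncated at zero; lognormal/gamma/Weibull are fitted
# by fitdistrplus::fitdist, the truncated normal by direct ML since no
# installed fitter supports it.

FIT_FAMILIES <- c("lognormal", "gamma", "weibull", "tnorm")

# density / cdf / quantile of a normal truncated to [0, Inf), computed in
# survival form: ML fits can land in the far-left-tail (exponential-like)
# regime where 1 - pnorm(0, m, s) underflows
dtnorm0 <- function(x, mean, sd) {
  lz <- stats::pnorm(0, mean, sd, lower.tail = FALSE, log.p = TRUE)
  ifelse(x < 0, 0, exp(stats::dnorm(x, mean, sd, log = TRUE) - lz))
}
ptnorm0 <- function(q, mean, sd) {
  s0 <- stats::pnorm(0, mean, sd, lower.tail = FALSE)
  sq <- stats::pnorm(q, mean, sd, lower.tail = FALSE)
  ifelse(q < 0, 0, 1 - sq / s0)
}
qtnorm0 <- function(p, mean, sd) {
  s0 <- stats::pnorm(0, mean, sd, lower.tail = FALSE)
  stats::qnorm(s0 * (1 - p), mean, sd, lower.tail = FALSE)
}

fit_tnorm0 <- function(x) {
  nll <- function(par) {
    m <- par[1]; s <- exp(par[2])
    -sum(stats::dnorm(x, m, s, log = TRUE)) +
      length(x) * stats::pnorm(0, m, s, lower.tail = FALSE, log.p = TRUE)
  }
  start <- c(mean(x), log(stats::sd(x)))
  opt <- stats::optim(start, nll, method = "Nelder-Mead")
  list(params = c(mean = opt$par[1], sd = exp(opt$par[2])),
       loglik = -opt$value, k = 2L)
}

new_fitted_dist <- function(family, params, loglik = NA_real_, n = NA_integer_,
                            aic = NA_real_, ks_stat = NA_real_,
                            fit_score = NA_real_, criterion = NA_character_) {
  structure(list(family = family, params = params, loglik = loglik, n = n,
                 aic = aic, ks_stat = ks_stat, fit_score = fit_score,
                 criterion = criterion),
            class = "fitted_dist")
}

#' @export
print.fitted_dist <- function(x, ...) {
  cat("fitted_dist:", x$family, "(",
      paste(names(x$params), signif(x$params, 4), sep = "=", collapse = ", "),
      ")\n")
  if (!is.na(x$fit_score)) {
    cat("  n =", x$n, " ", x$criterion, "=", signif(x$fit_score, 6), "\n")
  }
  invisible(x)
}

#' Fit the best concentration distribution to one grid cell's data
#'
#' Fits each candidate family by maximum likelihood and returns the family
#' minimising the selection criterion (AIC by default; a Kolmogorov–Smirnov
#' statistic on the fitted CDF can be selected instead). A zero-variance cell
#' cannot support a continuous fit and falls back, with a warning, to a point
#' mass at the observed value.
#'
#' @param x Numeric vector of (corrected) 1-minute concentrations, all >= 0.
#' @param families Subset of `c("lognormal", "gamma", "weibull", "tnorm")`.
#' @param criterion `"AIC"` or `"KS"`.
#' @return A `fitted_dist` object: family, named parameter vector, log
#'   likelihood, AIC, KS statistic and the selected criterion value. Samples
#'   drawn from any fitted family are non-negative by construction.
#' @export
fit_cell_distribution <- function(x, families = FIT_FAMILIES,
                                  criterion = c("AIC", "KS")) {
  criterion <- match.arg(criterion)
  families <- match.arg(families, FIT_FAMILIES, several.ok = TRUE)
  x <- as.numeric(x)
  if (length(x) < 2) stop("need at least 2 observations to fit", call. = FALSE)
  if (any(x < 0)) stop("concentrations must be non-negative", call. = FALSE)
  if (stats::sd(x) == 0) {
    warning("degenerate (zero-variance) cell: falling back to a point mass at ",
            x[1], call. = FALSE)
    return(new_fitted_dist("point", c(value = x[1]), n = length(x)))
  }
  # lognormal/gamma need strictly positive data
  if (any(x == 0)) families <- setdiff(families, c("lognormal", "gamma"))
  cand <- list()
  for (fam in families) {
    fit <- tryCatch(fit_one_family(x, fam), error = function(e) NULL)
    if (!is.null(fit)) cand[[fam]] <- fit
  }
  if (!length(cand)) stop("no candidate family could be fitted", call. = FALSE)
  score <- vapply(cand, function(f) {
    if (criterion == "AIC") f$aic else f$ks_stat
  }, numeric(1))
  best <- cand[[which.min(score)]]
  best$fit_score <- unname(min(score))
  best$criterion <- criterion
  best
}

fit_one_family <- function(x, family) {
  if (family == "tnorm") {
    f <- fit_tnorm0(x)
    params <- f$params; loglik <- f$loglik; k <- f$k
  } else {
    dist <- switch(family, lognormal = "lnorm", gamma = "gamma",
                   weibull = "weibull")
    f <- suppressWarnings(fitdistrplus::fitdist(x, dist, method = "mle"))
    params <- f$estimate; loglik <- f$loglik; k <- length(f$estimate)
  }
  aic <- 2 * k - 2 * loglik
  pfun <- cdf_fun(family, params)
  ks <- suppressWarnings(stats::ks.test(x, pfun)$statistic)
  new_fitted_dist(family, params, loglik = loglik, n = length(x),
                  aic = aic, ks_stat = unname(ks))
}

cdf_fun <- function(family, p) {
  switch(family,
         lognormal = function(q) stats::plnorm(q, p[["meanlog"]], p[["sdlog"]]),
         gamma     = function(q) stats::pgamma(q, p[["shape"]], p[["rate"]]),
         weibull   = function(q) stats::pweibull(q, p[["shape"]], p[["scale"]]),
         tnorm     = function(q) ptnorm0(q, p[["mean"]], p[["sd"]]),
         stop("no cdf for family ", family))
}

#' Draw random samples from a fitted cell distribution
#'
#' All families are supported on `[0, Inf)` so draws are non-negative with
#' probability 1; the truncated normal is sampled by inverse-CDF so no
#' rejection loop perturbs the RNG stream.
#'
#' @param fit A `fitted_dist` object.
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
sample_fitted <- function(fit, n) {
  p <- fit$params
  switch(fit$family,
         point     = rep(unname(p[["value"]]), n),
         lognormal = stats::rlnorm(n, p[["meanlog"]], p[["sdlog"]]),
         gamma     = stats::rgamma(n, p[["shape"]], p[["rate"]]),
         weibull   = stats::rweibull(n, p[["shape"]], p[["scale"]]),
         tnorm     = qtnorm0(stats::runif(n), p[["mean"]], p[["sd"]]),
         stop("cannot sample from family ", fit$family))
}

#' Analytic mean of a fitted cell distribution
#'
#' Closed-form expectation of each supported family; used by the simulation
#' engine's convergence checks (the Monte-Carlo population mean converges to
#' the time-weighted average of these, not of the raw cell means).
#'
#' @param x A `fitted_dist` object.
#' @param ... Unused.
#' @return The distribution mean (µg/m³).
#' @export
mean.fitted_dist <- function(x, ...) {
  p <- x$params
  switch(x$family,
         point     = unname(p[["value"]]),
         lognormal = exp(p[["meanlog"]] + p[["sdlog"]]^2 / 2),
         gamma     = unname(p[["shape"]] / p[["rate"]]),
         weibull   = unname(p[["scale"]] * gamma(1 + 1 / p[["shape"]])),
         tnorm     = {
           m <- p[["mean"]]; s <- p[["sd"]]; a <- -m / s
           # Mills-ratio form, stable deep in the left tail
           m + s * exp(stats::dnorm(a, log = TRUE) -
                         stats::pnorm(a, lower.tail = FALSE, log.p = TRUE))
         },
         stop("no mean for family ", x$family))
}
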