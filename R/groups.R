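#' Label the top fraction of the exposure distribution
#'
#' Splits a population into a high-exposure group — the `ceil(fraction * N)`
#' subjects with the highest exposure — and a low-exposure group (everyone
#' else). Ties at the cut are broken deterministically by input order
#' (stable sort on decreasing exposure), so the labelling is seed-free and
#' reproducible.
#'
#' @param exposures Data frame with `subject_id` and `exposure` columns (as
#'   from [compute_exposures()]), or a named numeric vector.
#' @param fraction Fraction in (0, 1); default 0.05 (top 5%).
#' @return A `group_labeling`: `$labels` (`subject_id, exposure, group`),
#'   `$threshold` (minimum exposure in the high group), `$n_high`, `$n_low`.
#' @export
#' @examples
#' e <- data.frame(subject_id = paste0("s", 1:100), exposure = 1:100)
#' label_top_fraction(e, 0.05)$n_high  # 5
label_top_fraction <- function(exposures, fraction = 0.05) {
  if (!is.data.frame(exposures)) {
    exposures <- data.frame(subject_id = names(exposures),
                            exposure = as.numeric(exposures),
                            stringsAsFactors = FALSE)
  }
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      fraction <= 0 || fraction >= 1) {
    stop("fraction must lie strictly in (0, 1)", call. = FALSE)
  }
  N <- nrow(exposures)
  n_high <- as.integer(ceiling(fraction * N))
  if (N < n_high + 1) stop("too few subjects for fraction ", fraction, call. = FALSE)
  ord <- order(-exposures$exposure)  # stable: ties keep input order
  group <- rep("low", N)
  group[ord[seq_len(n_high)]] <- "high"
  labels <- data.frame(subject_id = exposures$subject_id,
                       exposure = exposures$exposure,
                       group = factor(group, levels = c("low", "high")),
                       stringsAsFactors = FALSE)
  structure(list(labels = labels,
                 threshold = min(exposures$exposure[group == "high"]),
                 fraction = fraction,
                 n_high = n_high,
                 n_low = N - n_high),
            class = "group_labeling")
}

#' @export
print.group_labeling <- function(x, ...) {
  cat("group_labeling: high", x$n_high, "/ low", x$n_low,
      sprintf("(top %.1f%%, threshold %.4g ug/m3)\n",
              100 * x$fraction, x$threshold))
  invisible(x)
}

#' Fisher's exact test of independence
#'
#' Two-sided exact p-value for an r x c contingency table under fixed
#' margins, using the probability-ordering convention (the p-value sums the
#' probabilities of all tables no more probable than the observed one). For
#' tables too large to enumerate, a seeded Monte-Carlo p-value is returned
#' with its binomial standard error.
#'
#' @param table Matrix of non-negative counts with no all-zero row or column.
#' @param simulate Force Monte-Carlo estimation.
#' @param B Number of Monte-Carlo replicates.
#' @param seed Seed for the Monte-Carlo path.
#' @return A list: `p_value`, `method` (`"exact"` or `"monte_carlo"`), and
#'   `se` (`NA` for the exact path).
#' @export
fisher_exact <- function(table, simulate = FALSE, B = 1e5, seed = 1) {
  table <- as.matrix(table)
  if (any(table < 0) || any(table != floor(table))) {
    stop("table must contain non-negative integer counts", call. = FALSE)
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("degenerate table: all-zero row or column", call. = FALSE)
  }
  if (!simulate) {
    res <- tryCatch(stats::fisher.test(table), error = function(e) NULL)
    if (!is.null(res)) {
      return(list(p_value = res$p.value, method = "exact", se = NA_real_))
    }
  }
  set.seed(seed)
  res <- stats::fisher.test(table, simulate.p.value = TRUE, B = B)
  p <- res$p.value
  list(p_value = p, method = "monte_carlo", se = sqrt(p * (1 - p) / B))
}

#' Univariate screening of covariates against the exposure grouping
#'
#' For each covariate, tests association with the high/low grouping:
#' categorical (factor, character or logical) variables with Fisher's exact
#' test on the level-by-group contingency table, continuous variables with
#' Welch's two-sample t-test. Levels listed in `na_levels` (and `NA`s) are
#' treated as missing and excluded variable-wise — e.g. `not_applicable` for
#' industry/job among non-working respondents. Variables with
#' `p < alpha_in` (strict) are selected for the multivariate model.
#'
#' @param labeling A `group_labeling`.
#' @param covariates Data frame, one row per subject in `labeling` order.
#' @param alpha_in Selection threshold on the p-value (default 0.1).
#' @param na_levels Factor levels treated as missing.
#' @return A list: `rows` (data frame `variable, test, statistic, p_value,
#'   n_used`) and `selected` (character vector of variables with
#'   `p < alpha_in`).
#' @export
univariate_screen <- function(labeling, covariates, alpha_in = 0.1,
                              na_levels = "not_applicable") {
  stopifnot(inherits(labeling, "group_labeling"))
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != nrow(labeling$labels)) {
    stop("covariates must have one row per labelled subject", call. = FALSE)
  }
  grp <- labeling$labels$group
  rows <- lapply(names(covariates), function(v) {
    x <- covariates[[v]]
    if (is.character(x) || is.logical(x)) x <- factor(x)
    if (is.factor(x)) {
      keep <- !is.na(x) & !(as.character(x) %in% na_levels)
      tab <- table(droplevels(x[keep]), grp[keep])
      tab <- tab[rowSums(tab) > 0, , drop = FALSE]
      if (nrow(tab) < 2 || any(colSums(tab) == 0)) {
        return(data.frame(variable = v, test = "fisher_exact",
                          statistic = NA_real_, p_value = NA_real_,
                          n_used = sum(keep), stringsAsFactors = FALSE))
      }
      ft <- fisher_exact(tab)
      data.frame(variable = v, test = "fisher_exact", statistic = NA_real_,
                 p_value = ft$p_value, n_used = sum(keep),
                 stringsAsFactors = FALSE)
    } else {
      keep <- !is.na(x)
      tt <- stats::t.test(x[keep] ~ grp[keep])  # Welch by default
      data.frame(variable = v, test = "welch_t",
                 statistic = unname(tt$statistic), p_value = tt$p.value,
                 n_used = sum(keep), stringsAsFactors = FALSE)
    }
  })
  rows <- do.call(rbind, rows)
  selected <- rows$variable[!is.na(rows$p_value) & rows$p_value < alpha_in]
  list(rows = rows, selected = selected)
}

# per-column VIFs of a design matrix (intercept excluded) via auxiliary
# regressions of each column on all the others
design_vifs <- function(mm) {
  p <- ncol(mm)
  vifs <- numeric(p)
  for (j in seq_len(p)) {
    others <- cbind(1, mm[, -j, drop = FALSE])
    fit <- stats::lm.fit(others, mm[, j])
    ssr <- sum(fit$residuals^2)
    sst <- sum((mm[, j] - mean(mm[, j]))^2)
    r2 <- if (sst == 0) 1 else 1 - ssr / sst
    vifs[j] <- if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  stats::setNames(vifs, colnames(mm))
}

#' Collinearity screening by variance inflation factors
#'
#' Computes a VIF for every design-matrix term (dummy level or continuous
#' column) of the selected covariates via auxiliary regressions
#' (`VIF = 1/(1 - R^2)`). Exactly collinear terms are resolved first (the
#' later-ordered duplicate is dropped with a warning); then the variable
#' whose worst term exceeds `vif_threshold` is dropped, highest first,
#' until all remaining terms are below the threshold.
#'
#' @param covariates Data frame of covariates.
#' @param selected Character vector of variable names to screen.
#' @param vif_threshold Drop threshold (default 10).
#' @return A list: `vifs` (data frame `term, variable, vif` for the retained
#'   set), `retained` and `dropped` variable name vectors.
#' @export
check_collinearity <- function(covariates, selected, vif_threshold = 10) {
  if (!length(selected)) stop("selected variable set is empty", call. = FALSE)
  covariates <- as.data.frame(covariates)[selected]
  covariates[] <- lapply(covariates, function(x) {
    if (is.character(x) || is.logical(x)) factor(x) else x
  })
  dropped <- character(0)
  current <- selected
  repeat {
    mm <- stats::model.matrix(~., data = covariates[current])[, -1, drop = FALSE]
    assign_var <- current[attr(stats::model.matrix(~., covariates[current]),
                               "assign")[-1]]
    # exact collinearity: drop the later-ordered aliased term's variable
    qrm <- qr(cbind(1, mm))
    if (qrm$rank < ncol(mm) + 1) {
      aliased_col <- qrm$pivot[(qrm$rank + 1):(ncol(mm) + 1)] - 1
      aliased_col <- aliased_col[aliased_col > 0]
      v <- assign_var[max(aliased_col)]
      warning("exactly collinear term in variable '", v,
              "': dropped", call. = FALSE)
      dropped <- c(dropped, v)
      current <- setdiff(current, v)
      if (!length(current)) break
      next
    }
    vifs <- design_vifs(mm)
    worst <- max(vifs)
    if (!is.finite(worst) || worst > vif_threshold) {
      v <- assign_var[which.max(vifs)]
      dropped <- c(dropped, v)
      current <- setdiff(current, v)
      if (!length(current)) break
      next
    }
    break
  }
  vif_df <- if (length(current)) {
    mm <- stats::model.matrix(~., data = covariates[current])[, -1, drop = FALSE]
    assign_var <- current[attr(stats::model.matrix(~., covariates[current]),
                               "assign")[-1]]
    data.frame(term = colnames(mm), variable = assign_var,
               vif = unname(design_vifs(mm)), stringsAsFactors = FALSE)
  } else {
    data.frame(term = character(0), variable = character(0),
               vif = numeric(0), stringsAsFactors = FALSE)
  }
  list(vifs = vif_df, retained = current, dropped = dropped)
}

#' Odds ratio with Wald confidence interval from a logistic coefficient
#'
#' `OR = exp(beta)`; 95% CI bounds `exp(beta +/- 1.96 * se)`.
#'
#' @param coef Log-odds coefficient(s).
#' @param se Standard error(s).
#' @param z Normal multiplier (1.96 for 95%).
#' @return Data frame with `or, ci_low, ci_high`.
#' @export
#' @examples
#' or_ci(0.356, 0.147)$or  # 1.428 to 3 decimals
or_ci <- function(coef, se, z = 1.96) {
  data.frame(or = exp(coef),
             ci_low = exp(coef - z * se),
             ci_high = exp(coef + z * se))
}

#' Multivariate logistic regression of high-exposure group membership
#'
#' Maximum-likelihood logistic fit of high vs low group on the given terms,
#' with dummy coding against specified reference levels, per-variable
#' likelihood-ratio p-values from drop-one refits, and Wald odds-ratio
#' confidence intervals.
#'
#' @param labeling A `group_labeling`.
#' @param covariates Data frame, one row per labelled subject.
#' @param terms Character vector of covariate names to fit.
#' @param references Optional named list/vector mapping a categorical
#'   variable to its reference level.
#' @param na_levels Factor levels treated as missing; rows carrying one in a
#'   fitted term are dropped (complete-case fit).
#' @return A `logistic_model`: `$terms` (data frame `variable, level,
#'   coefficient, se, or, ci_low, ci_high`), `$lrt` (per-variable LRT
#'   p-values), `$fit` (the underlying `glm`), `$n`, `$n_events`.
#' @export
fit_logistic <- function(labeling, covariates, terms,
                         references = NULL, na_levels = "not_applicable") {
  stopifnot(inherits(labeling, "group_labeling"))
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != nrow(labeling$labels)) {
    stop("covariates must have one row per labelled subject", call. = FALSE)
  }
  dat <- covariates[terms]
  dat[] <- lapply(dat, function(x) {
    if (is.character(x) || is.logical(x)) x <- factor(x)
    if (is.factor(x)) {
      x[as.character(x) %in% na_levels] <- NA
      droplevels(x)
    } else x
  })
  for (v in names(references)) {
    if (v %in% names(dat) && is.factor(dat[[v]])) {
      dat[[v]] <- stats::relevel(dat[[v]], ref = references[[v]])
    }
  }
  dat$.high <- labeling$labels$group == "high"
  cc <- stats::complete.cases(dat)
  dat <- dat[cc, ]
  n_events <- sum(dat$.high)
  n_par <- ncol(stats::model.matrix(~., dat[terms])) # incl. intercept
  if (n_events / n_par < 10) {
    warning(sprintf("only %.1f events per parameter (%d events, %d parameters)",
                    n_events / n_par, n_events, n_par), call. = FALSE)
  }
  fit <- stats::glm(.high ~ ., data = dat, family = stats::binomial())
  if (!fit$converged) {
    stop("logistic fit did not converge after ", fit$iter, " iterations",
         call. = FALSE)
  }
  mu <- fit$fitted.values
  separated <- any(mu > 1 - 1e-8 | mu < 1e-8)
  if (separated) {
    warning("possible complete separation: fitted probabilities of 0 or 1",
            call. = FALSE)
  }
  sm <- summary(fit)$coefficients
  keep <- rownames(sm) != "(Intercept)"
  # map each coefficient back to its source variable and level
  asn <- attr(stats::model.matrix(fit), "assign")[keep]
  vars <- terms[asn]
  lev <- rownames(sm)[keep]
  lev <- mapply(function(nm, v) sub(paste0("^", v), "", nm), lev, vars)
  co <- sm[keep, "Estimate"]
  se <- sm[keep, "Std. Error"]
  oc <- or_ci(co, se)
  term_df <- data.frame(variable = vars,
                        level = ifelse(nzchar(lev), lev, NA_character_),
                        coefficient = unname(co), se = unname(se),
                        or = oc$or, ci_low = oc$ci_low, ci_high = oc$ci_high,
                        stringsAsFactors = FALSE)
  rownames(term_df) <- NULL
  lrt <- stats::drop1(fit, test = "LRT")
  lrt_df <- data.frame(variable = rownames(lrt)[-1],
                       lrt_p = lrt$`Pr(>Chi)`[-1],
                       stringsAsFactors = FALSE)
  structure(list(terms = term_df, lrt = lrt_df, fit = fit,
                 references = references, n = nrow(dat),
                 n_events = n_events, separated = separated),
            class = "logistic_model")
}

#' @export
print.logistic_model <- function(x, ...) {
  cat("logistic_model of high-exposure group membership:", x$n, "subjects,",
      x$n_events, "events\n")
  df <- x$terms
  df[c("coefficient", "se", "or", "ci_low", "ci_high")] <-
    lapply(df[c("coefficient", "se", "or", "ci_low", "ci_high")],
           round_half_up, digits = 3)
  print(df, row.names = FALSE)
  cat("likelihood-ratio p-values:\n")
  print(x$lrt, row.names = FALSE)
  invisible(x)
}

#' Characterize the high-exposure group end to end
#'
#' Convenience wrapper chaining [univariate_screen()],
#' [check_collinearity()] and [fit_logistic()]: screen every covariate at
#' `alpha_in`, prune collinear variables by VIF, fit the multivariate
#' logistic model on what remains. Screening-then-single-fit is used rather
#' than iterative add/drop elimination, so screened-in but individually
#' non-significant variables stay in the final model.
#'
#' @param labeling A `group_labeling`.
#' @param covariates Data frame of covariates.
#' @param alpha_in Univariate selection threshold (default 0.1).
#' @param vif_threshold VIF drop threshold (default 10).
#' @param references Reference levels for [fit_logistic()].
#' @return A `group_report`: `$labeling`, `$univariate`, `$collinearity`,
#'   `$model`.
#' @export
group_report <- function(labeling, covariates, alpha_in = 0.1,
                         vif_threshold = 10, references = NULL) {
  uni <- univariate_screen(labeling, covariates, alpha_in)
  if (!length(uni$selected)) {
    return(structure(list(labeling = labeling, univariate = uni,
                          collinearity = NULL, model = NULL),
                     class = "group_report"))
  }
  col <- check_collinearity(covariates, uni$selected, vif_threshold)
  model <- if (length(col$retained)) {
    fit_logistic(labeling, covariates, col$retained, references)
  }
  structure(list(labeling = labeling, univariate = uni,
                 collinearity = col, model = model),
            class = "group_report")
}

#' @export
print.group_report <- function(x, ...) {
  print(x$labeling)
  cat("univariate screen (p <", x$univariate$selected_alpha %||% 0.1, "):",
      paste(x$univariate$selected, collapse = ", "), "\n")
  if (!is.null(x$model)) print(x$model)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
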