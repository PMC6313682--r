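test_that("top-fraction labelling sizes follow the ceiling rule", {
  set.seed(51)
  e <- data.frame(subject_id = sprintf("s%04d", 1:8072),
                  exposure = rlnorm(8072, log(26), 0.1))
  lab <- label_top_fraction(e, 0.05)
  expect_equal(lab$n_high, 404L)
  expect_equal(lab$n_low, 7668L)
  expect_equal(sum(lab$labels$group == "high"), 404L)
  expect_equal(label_top_fraction(e[1:100, ], 0.05)$n_high, 5L)
  expect_equal(label_top_fraction(e[1:60, ], 0.05)$n_high, 3L)
  # threshold is the minimum exposure inside the high group
  expect_equal(lab$threshold,
               min(lab$labels$exposure[lab$labels$group == "high"]))
  expect_error(label_top_fraction(e, 0), "fraction")
  expect_error(label_top_fraction(e, 1), "fraction")
})

test_that("labelling is monotone in the fraction and deterministic on ties", {
  set.seed(52)
  e <- data.frame(subject_id = sprintf("s%03d", 1:200),
                  exposure = sample(rep(1:50, 4)))
  l1 <- label_top_fraction(e, 0.03)
  l2 <- label_top_fraction(e, 0.05)
  high1 <- e$subject_id[l1$labels$group == "high"]
  high2 <- e$subject_id[l2$labels$group == "high"]
  expect_true(all(high1 %in% high2))  # lowering fraction never promotes
  # ties at the cut resolve by input order: first-seen tied subject wins
  e3 <- data.frame(subject_id = c("a", "b", "c", "d"),
                   exposure = c(5, 9, 9, 1))
  l3 <- label_top_fraction(e3, 0.25)
  expect_equal(as.character(l3$labels$group), c("low", "high", "low", "low"))
  expect_identical(label_top_fraction(e, 0.05)$labels, l2$labels)
})

test_that("Fisher's exact test matches hypergeometric enumeration", {
  t1 <- matrix(c(3, 1, 1, 3), 2)
  expect_equal(fisher_exact(t1)$p_value, fisher_oracle_2x2(t1))
  t2 <- matrix(c(5, 0, 0, 5), 2)
  expect_equal(fisher_exact(t2)$p_value, 2 / 252, tolerance = 1e-12)
  # proportional rows: perfect independence
  t3 <- matrix(c(10, 20, 5, 10), 2)
  expect_equal(fisher_exact(t3)$p_value, 1)
  expect_error(fisher_exact(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "degenerate")
  # exhaustive agreement over all tables with margins <= 8
  for (r1 in 1:8) for (c1 in 1:8) {
    n <- 8
    for (a in max(0, r1 + c1 - n):min(r1, c1)) {
      tab <- matrix(c(a, r1 - a, c1 - a, n - r1 - c1 + a), 2)
      if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
      expect_equal(fisher_exact(tab)$p_value, fisher_oracle_2x2(tab),
                   tolerance = 1e-12)
    }
  }
})

test_that("Monte-Carlo Fisher path reports a standard error and agrees", {
  tab <- matrix(c(12, 5, 7, 14, 8, 10), 2)
  exact <- fisher_exact(tab)
  mc <- fisher_exact(tab, simulate = TRUE, B = 2e4, seed = 3)
  expect_equal(mc$method, "monte_carlo")
  expect_true(is.finite(mc$se))
  expect_lt(abs(mc$p_value - exact$p_value), 4 * mc$se + 1e-4)
})

test_that("univariate screening picks tests by type and selects strictly", {
  set.seed(53)
  n <- 400
  y <- rep(c(TRUE, FALSE), c(40, 360))
  cov <- data.frame(
    job = ifelse(runif(n) < plogis(-1 + 1.5 * y), "non_office", "office"),
    hours = rnorm(n, 40 + 6 * y, 10),
    noise = rnorm(n),
    industry = sample(c("tertiary", "primary_secondary", "not_applicable"),
                      n, TRUE))
  lab <- labeling_from_outcome(y)
  scr <- univariate_screen(lab, cov, alpha_in = 0.1)
  expect_equal(scr$rows$test,
               c("fisher_exact", "welch_t", "welch_t", "fisher_exact"))
  expect_true(all(c("job", "hours") %in% scr$selected))
  # not_applicable rows are excluded variable-wise
  expect_equal(scr$rows$n_used[scr$rows$variable == "industry"],
               sum(cov$industry != "not_applicable"))
  # boundary semantics: strict inequality at alpha_in
  p_noise <- scr$rows$p_value[scr$rows$variable == "noise"]
  at <- univariate_screen(lab, cov, alpha_in = p_noise)
  above <- univariate_screen(lab, cov, alpha_in = p_noise + 1e-9)
  expect_false("noise" %in% at$selected)
  expect_true("noise" %in% above$selected)
})

test_that("screening has power against a built-in effect and holds its size", {
  set.seed(54)
  hits_effect <- 0; hits_noise <- 0; reps <- 60
  for (i in 1:reps) {
    n <- 2000
    job <- sample(c("office", "non_office"), n, TRUE)
    # odds ratio ~2.2 built into group membership
    y <- runif(n) < plogis(-3 + log(2.2) * (job == "non_office"))
    if (sum(y) < 5) next
    cov <- data.frame(job = job, noise = rnorm(n))
    scr <- univariate_screen(labeling_from_outcome(y), cov, alpha_in = 0.1)
    hits_effect <- hits_effect + ("job" %in% scr$selected)
    hits_noise <- hits_noise + ("noise" %in% scr$selected)
  }
  expect_gte(hits_effect / reps, 0.9)
  # type-I rate of the noise covariate ~ 10%, generous binomial envelope
  expect_lte(hits_noise / reps, 0.25)
})

test_that("VIFs match the 1/(1-R^2) oracle and prune collinear variables", {
  set.seed(55)
  n <- 300
  x1 <- rnorm(n); x2 <- x1 + rnorm(n, sd = 0.1); x3 <- rnorm(n)
  cov <- data.frame(x1 = x1, x2 = x2, x3 = x3)
  res <- check_collinearity(cov, c("x1", "x2", "x3"), vif_threshold = 1e6)
  # direct auxiliary-regression oracle
  r2 <- summary(lm(x2 ~ x1 + x3))$r.squared
  expect_equal(res$vifs$vif[res$vifs$term == "x2"], 1 / (1 - r2),
               tolerance = 1e-8)
  # near-orthogonal covariate has VIF close to 1
  expect_lt(res$vifs$vif[res$vifs$term == "x3"], 1.05)
  # agreement with car's VIF on the same design
  v_car <- car::vif(lm(rnorm(n) ~ x1 + x2 + x3))
  expect_equal(res$vifs$vif, unname(v_car[res$vifs$term]), tolerance = 1e-6)
  # with a meaningful threshold the worse-collinear pair loses a member
  res2 <- check_collinearity(cov, c("x1", "x2", "x3"), vif_threshold = 10)
  expect_true(length(res2$dropped) >= 1)
  expect_true("x3" %in% res2$retained)
  # exact duplicate: later-ordered copy dropped with a warning
  cov$dup <- cov$x1
  expect_warning(res3 <- check_collinearity(cov, c("x1", "x3", "dup"), 10),
                 "collinear")
  expect_equal(res3$dropped, "dup")
  expect_error(check_collinearity(cov, character(0)), "empty")
})

test_that("odds ratios are exp(coefficient) with Wald intervals", {
  o <- or_ci(0.356, 0.147)
  expect_equal(round_half_up(o$or, 3), 1.428)
  expect_equal(o$ci_low, exp(0.356 - 1.96 * 0.147))
  expect_equal(o$ci_high, exp(0.356 + 1.96 * 0.147))
  expect_equal(or_ci(0, 0.2)$or, 1)
})

test_that("logistic fit recovers generating coefficients and is consistent", {
  set.seed(56)
  n <- 8000
  job <- sample(c("office", "non_office"), n, TRUE)
  hours <- pmax(0, rnorm(n, 40, 15))
  eta <- -5 + 0.8 * (job == "non_office") + 0.028 * hours
  y <- runif(n) < plogis(eta)
  cov <- data.frame(job = job, hours = hours)
  fit <- fit_logistic(labeling_from_outcome(y), cov, c("job", "hours"),
                      references = list(job = "office"))
  td <- fit$terms
  # internal consistency: or = exp(coef), ci brackets it
  expect_equal(td$or, exp(td$coefficient))
  expect_true(all(td$ci_low <= td$or & td$or <= td$ci_high))
  b_job <- td[td$variable == "job", ]
  b_hr <- td[td$variable == "hours", ]
  expect_lt(abs(b_job$coefficient - 0.8), 2 * b_job$se)
  expect_lt(abs(b_hr$coefficient - 0.028), 2 * b_hr$se)
  expect_equal(b_job$level, "non_office")
  # row-permutation invariance of the fit
  perm <- sample(n)
  fit2 <- fit_logistic(labeling_from_outcome(y[perm]), cov[perm, ],
                       c("job", "hours"), references = list(job = "office"))
  expect_equal(fit2$terms$coefficient, td$coefficient, tolerance = 1e-8)
})

test_that("LRT p-values approach Wald p-values at large n", {
  set.seed(57)
  n <- 1e5
  x <- rnorm(n)
  y <- runif(n) < plogis(-3 + 0.1 * x)
  fit <- fit_logistic(labeling_from_outcome(y), data.frame(x = x), "x")
  p_wald <- 2 * pnorm(-abs(fit$terms$coefficient / fit$terms$se))
  p_lrt <- fit$lrt$lrt_p[fit$lrt$variable == "x"]
  expect_lt(abs(p_lrt - p_wald), 0.01)
})

test_that("separation and sparse events are detected and reported", {
  y <- rep(c(TRUE, FALSE), c(12, 38))
  sep <- data.frame(z = as.numeric(y) + 0.001 * seq_along(y))
  w <- capture_warnings(
    fit <- fit_logistic(labeling_from_outcome(y), sep, "z"))
  expect_true(any(grepl("separation", w)))
  expect_true(any(grepl("events per parameter", w)))
  expect_true(fit$separated)
})

test_that("the chained group report runs on a synthetic population", {
  pop <- generate_population(population_spec(n_subjects = 1500, seed = 58))
  g <- fit_grid_distributions(
    build_grid(generate_campaign(campaign_spec(seed = 58)), 5),
    families = "lognormal")
  ex <- compute_exposures(pop, g)
  lab <- label_top_fraction(ex, 0.05)
  cov <- pop$covariates
  cov$day_type <- as.character(pop$day_type)
  rep <- suppressWarnings(
    group_report(lab, cov,
                 references = list(day_type = "weekday", sex = "male",
                                   job = "office")))
  expect_s3_class(rep, "group_report")
  expect_true(nrow(rep$univariate$rows) == ncol(cov))
  expect_false(is.null(rep$model))
  # working characteristics drive exposure by construction
  expect_true("working_hours" %in% rep$model$lrt$variable ||
                "job" %in% rep$model$lrt$variable)
})
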