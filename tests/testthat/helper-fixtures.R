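# Shared fixtures and independent oracles, all built in code.

# records giving every (non-skipped) cell exactly n_obs observations at the
# value of mean_mat[slot, me]; skip is a data.frame(slot, me) of cell indices
records_from_means <- function(mean_mat, n_obs = 5, skip = NULL) {
  slot <- rep(rep(1:144, each = 3), each = n_obs)
  me <- rep(rep(1:3, times = 144), each = n_obs)
  rep_i <- rep(seq_len(n_obs) - 1L, times = 432)
  keep <- rep(TRUE, length(slot))
  if (!is.null(skip)) {
    drop_key <- paste(skip$slot, skip$me)
    keep <- !(paste(slot, me) %in% drop_key)
  }
  data.frame(date = "d1",
             minute_of_day = (10L * (slot - 1L) + rep_i %% 10L)[keep],
             pm25 = mean_mat[cbind(slot, me)][keep],
             microenv = ME_LEVELS[me][keep],
             run_id = "r1",
             stringsAsFactors = FALSE)
}

# grid with every cell at a constant value (all cells degenerate)
constant_grid <- function(value = 20, n_obs = 5, skip = NULL) {
  build_grid(records_from_means(matrix(value, 144, 3), n_obs, skip),
             min_obs_per_cell = n_obs)
}

# brute-force minute-level exposure oracle: walk all 1440 minutes, look up
# the slot/microenvironment cell, average over the minutes whose cell is
# available
oracle_exposure <- function(slots, grid) {
  M <- pmexposure:::grid_means(grid)
  A <- pmexposure:::grid_available(grid)
  vals <- numeric(0)
  for (minute in 0:1439) {
    t <- minute %/% 10 + 1
    m <- slots[t]
    if (A[t, m]) vals <- c(vals, M[t, m])
  }
  mean(vals)
}

# explicit sum-of-squares one-way ANOVA oracle
anova_oracle <- function(groups) {
  k <- length(groups)
  N <- sum(lengths(groups))
  gm <- mean(unlist(groups))
  ssb <- sum(lengths(groups) * (vapply(groups, mean, 0) - gm)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  f <- (ssb / (k - 1)) / (ssw / (N - k))
  list(f = f, p = stats::pf(f, k - 1, N - k, lower.tail = FALSE))
}

# exact two-sided Fisher p for a 2x2 table by full hypergeometric
# enumeration under fixed margins (probability-ordering convention)
fisher_oracle_2x2 <- function(tab) {
  m <- sum(tab[1, ]); n2 <- sum(tab[2, ]); k <- sum(tab[, 1])
  a <- max(0, k - n2):min(k, m)
  probs <- stats::dhyper(a, m, n2, k)
  pobs <- stats::dhyper(tab[1, 1], m, n2, k)
  sum(probs[probs <= pobs * (1 + 1e-7)])
}

# diary slot row with given slot counts laid out contiguously
slots_with_counts <- function(n_res, n_trans, n_other) {
  stopifnot(n_res + n_trans + n_other == 144)
  c(rep(1L, n_res), rep(2L, n_trans), rep(3L, n_other))
}

# group labelling built directly from a binary outcome, for testing the
# logistic fit in isolation from the exposure path
labeling_from_outcome <- function(y) {
  structure(list(labels = data.frame(
    subject_id = sprintf("s%05d", seq_along(y)),
    exposure = NA_real_,
    group = factor(ifelse(y, "high", "low"), levels = c("low", "high")),
    stringsAsFactors = FALSE),
    threshold = NA_real_, fraction = mean(y),
    n_high = sum(y), n_low = sum(!y)),
    class = "group_labeling")
}
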