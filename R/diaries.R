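#' Construct a diary set
#'
#' A diary set holds one 144-slot time–activity diary per person-day: for
#' each 10-minute slot, the microenvironment the subject occupied, plus the
#' day type and (optionally) a demographic covariate table keyed by subject.
#'
#' @param subject_id Character or integer vector of subject identifiers.
#' @param day_type Character vector, one of [DAY_TYPES] per subject.
#' @param slots Integer matrix `n x 144` of microenvironment codes (1–3), or
#'   a character matrix of labels from [ME_LEVELS].
#' @param covariates Optional data frame of demographic covariates, one row
#'   per subject, in the same order.
#' @return A `diary_set` object.
#' @export
diary_set <- function(subject_id, day_type, slots, covariates = NULL) {
  n <- length(subject_id)
  if (anyDuplicated(subject_id)) stop("duplicate subject_id", call. = FALSE)
  if (length(day_type) != n) stop("day_type length mismatch", call. = FALSE)
  if (!all(day_type %in% DAY_TYPES)) {
    stop("day_type must be one of ", paste(DAY_TYPES, collapse = ", "),
         call. = FALSE)
  }
  if (is.character(slots)) {
    slots <- matrix(me_code(slots), nrow = nrow(slots), ncol = ncol(slots))
  }
  slots <- as.matrix(slots)
  storage.mode(slots) <- "integer"
  if (nrow(slots) != n || ncol(slots) != N_SLOTS) {
    stop("slots must be an n x 144 matrix", call. = FALSE)
  }
  if (any(is.na(slots)) || any(slots < 1L | slots > 3L)) {
    stop("slot codes must be microenvironment codes 1..3", call. = FALSE)
  }
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != n) stop("covariates row count mismatch", call. = FALSE)
  }
  structure(list(subject_id = as.character(subject_id),
                 day_type = factor(day_type, levels = DAY_TYPES),
                 slots = slots,
                 covariates = covariates),
            class = "diary_set")
}

#' @export
print.diary_set <- function(x, ...) {
  cat("diary_set:", length(x$subject_id), "person-days\n")
  print(table(x$day_type))
  if (!is.null(x$covariates)) {
    cat("  covariates:", paste(names(x$covariates), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
length.diary_set <- function(x) length(x$subject_id)

#' Read time–activity diaries from a wide CSV
#'
#' Expects columns `subject_id, day_type, s001 ... s144` where the slot
#' columns carry microenvironment labels ([ME_LEVELS]). Codes outside the
#' three-category scheme are rejected at read time; seven-category survey
#' codes must be mapped first (see [map_seven_category()]).
#'
#' @param path Path to the diary CSV.
#' @param covariates_path Optional path to a companion `covariates.csv` keyed
#'   by `subject_id`.
#' @return A `diary_set`.
#' @export
read_diaries <- function(path, covariates_path = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  slot_cols <- sprintf("s%03d", seq_len(N_SLOTS))
  need <- c("subject_id", "day_type", slot_cols)
  if (!all(need %in% names(df))) {
    stop("diaries.csv must have columns subject_id, day_type, s001..s144",
         call. = FALSE)
  }
  slots <- as.matrix(df[slot_cols])
  codes <- matrix(me_code(as.vector(slots)), nrow = nrow(df))
  cov <- NULL
  if (!is.null(covariates_path)) {
    cov <- utils::read.csv(covariates_path, stringsAsFactors = FALSE)
    if (!"subject_id" %in% names(cov)) {
      stop("covariates.csv must have a subject_id column", call. = FALSE)
    }
    m <- match(as.character(df$subject_id), as.character(cov$subject_id))
    if (anyNA(m)) {
      stop("covariates missing for subject(s): ",
           paste(utils::head(df$subject_id[is.na(m)], 5), collapse = ", "),
           call. = FALSE)
    }
    cov <- cov[m, setdiff(names(cov), "subject_id"), drop = FALSE]
    rownames(cov) <- NULL
  }
  diary_set(df$subject_id, df$day_type, codes, cov)
}

#' Write a diary set to the wide CSV schema
#'
#' @param diaries A `diary_set`.
#' @param path Output diary CSV path.
#' @param covariates_path Optional output path for the covariate table.
#' @return `path`, invisibly.
#' @export
write_diaries <- function(diaries, path, covariates_path = NULL) {
  stopifnot(inherits(diaries, "diary_set"))
  lab <- matrix(ME_LEVELS[diaries$slots], nrow = length(diaries))
  colnames(lab) <- sprintf("s%03d", seq_len(N_SLOTS))
  df <- data.frame(subject_id = diaries$subject_id,
                   day_type = as.character(diaries$day_type),
                   lab, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  if (!is.null(covariates_path) && !is.null(diaries$covariates)) {
    cov <- cbind(subject_id = diaries$subject_id, diaries$covariates)
    utils::write.csv(cov, covariates_path, row.names = FALSE)
  }
  invisible(path)
}

#' Daily time budget of each diary
#'
#' Hours spent in each microenvironment: slot counts divided by 6. The three
#' components of every row sum to exactly 24 h and are multiples of 1/6 h
#' (one 10-minute slot).
#'
#' @param diaries A `diary_set`.
#' @return Data frame with `subject_id, day_type, hours_residential,
#'   hours_transport, hours_other`.
#' @export
time_budgets <- function(diaries) {
  stopifnot(inherits(diaries, "diary_set"))
  s <- diaries$slots
  data.frame(subject_id = diaries$subject_id,
             day_type = as.character(diaries$day_type),
             hours_residential = rowSums(s == 1L) / 6,
             hours_transport = rowSums(s == 2L) / 6,
             hours_other = rowSums(s == 3L) / 6,
             stringsAsFactors = FALSE)
}

#' Compare time budgets across day types (one-way ANOVA + Scheffé)
#'
#' Classical equal-variance one-way ANOVA of one time-budget component
#' across the three day types, followed by Scheffé's simultaneous pairwise
#' post-hoc comparisons (each pairwise contrast's F statistic referred to
#' `(k-1) F(k-1, N-k)`, which controls the family-wise error over all
#' contrasts and is never less conservative than the unadjusted test).
#'
#' @param diaries A `diary_set`.
#' @param component One of `"residential"`, `"transport"`, `"other"`.
#' @return A list: `f`, `df`, `p_value`, `group_means`, and `scheffe`, a data
#'   frame of pairwise differences with adjusted p-values.
#' @export
compare_budgets_by_daytype <- function(diaries,
                                       component = c("residential",
                                                     "transport", "other")) {
  component <- match.arg(component)
  b <- time_budgets(diaries)
  y <- b[[paste0("hours_", component)]]
  g <- factor(b$day_type, levels = DAY_TYPES)
  cnt <- table(g)
  if (any(cnt < 2)) {
    stop("need at least 2 diaries per day type; counts: ",
         paste(names(cnt), cnt, sep = "=", collapse = ", "), call. = FALSE)
  }
  fit <- stats::aov(y ~ g)
  tab <- summary(fit)[[1]]
  fstat <- tab$`F value`[1]
  p <- tab$`Pr(>F)`[1]
  k <- nlevels(g)
  N <- length(y)
  mse <- tab$`Mean Sq`[2]
  means <- tapply(y, g, mean)
  pairs <- utils::combn(levels(g), 2)
  scheffe <- data.frame(
    group1 = pairs[1, ], group2 = pairs[2, ],
    diff = NA_real_, f_scheffe = NA_real_, p_adj = NA_real_,
    stringsAsFactors = FALSE)
  for (i in seq_len(ncol(pairs))) {
    g1 <- pairs[1, i]; g2 <- pairs[2, i]
    d <- means[[g1]] - means[[g2]]
    se2 <- mse * (1 / cnt[[g1]] + 1 / cnt[[g2]])
    fs <- d^2 / (se2 * (k - 1))
    scheffe$diff[i] <- d
    scheffe$f_scheffe[i] <- fs
    scheffe$p_adj[i] <- stats::pf(fs, k - 1, N - k, lower.tail = FALSE)
  }
  list(component = component, f = fstat, df = c(k - 1, N - k), p_value = p,
       group_means = means, scheffe = scheffe)
}
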