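#' Read 1-minute PM2.5 measurement records
#'
#' Reads a measurement campaign CSV with columns
#' `date, minute_of_day, pm25_ugm3, microenv, run_id`. Rows with a negative
#' concentration, an unknown microenvironment code or an out-of-range minute
#' are rejected with line-numbered errors: instrument output is non-negative,
#' so a negative value signals a parse or logging error and is never clipped.
#'
#' @param path Path to the CSV file.
#' @return A `data.frame` with columns `date` (character), `minute_of_day`
#'   (integer 0–1439), `pm25` (non-negative numeric, µg/m³), `microenv`
#'   (character, one of [ME_LEVELS]) and `run_id` (character).
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) stop("measurement file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("date", "minute_of_day", "pm25_ugm3", "microenv", "run_id")
  if (!all(need %in% names(df))) {
    stop("measurements.csv must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) == 0) stop("measurement file is empty: ", path, call. = FALSE)
  # line numbers: header is line 1
  line <- seq_len(nrow(df)) + 1L
  bad_pm <- !is.finite(df$pm25_ugm3) | df$pm25_ugm3 < 0
  bad_min <- !is.finite(df$minute_of_day) | df$minute_of_day < 0 |
    df$minute_of_day > 1439 | df$minute_of_day != floor(df$minute_of_day)
  bad_me <- !(df$microenv %in% ME_LEVELS)
  bad <- bad_pm | bad_min | bad_me
  if (any(bad)) {
    why <- ifelse(bad_pm, "negative or non-numeric pm25_ugm3",
                  ifelse(bad_min, "minute_of_day outside [0, 1439]",
                         "unknown microenv code"))
    msgs <- paste0("line ", line[bad], ": ", why[bad])
    stop("invalid measurement rows:\n  ",
         paste(utils::head(msgs, 10), collapse = "\n  "),
         if (sum(bad) > 10) paste0("\n  ... and ", sum(bad) - 10, " more"),
         call. = FALSE)
  }
  data.frame(date = as.character(df$date),
             minute_of_day = as.integer(df$minute_of_day),
             pm25 = as.numeric(df$pm25_ugm3),
             microenv = df$microenv,
             run_id = as.character(df$run_id),
             stringsAsFactors = FALSE)
}

#' Read gravimetric correction factors
#'
#' Reads `correction_factors.csv` with columns `run_id, factor`; all factors
#' must be positive.
#'
#' @param path Path to the CSV file.
#' @return A named numeric vector of factors, names being run identifiers.
#' @export
read_correction_factors <- function(path) {
  if (!file.exists(path)) stop("correction-factor file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("run_id", "factor") %in% names(df))) {
    stop("correction_factors.csv must have columns run_id, factor", call. = FALSE)
  }
  if (any(!is.finite(df$factor) | df$factor <= 0)) {
    stop("correction factors must be positive", call. = FALSE)
  }
  stats::setNames(as.numeric(df$factor), as.character(df$run_id))
}

#' Apply gravimetric correction factors to measurement records
#'
#' Multiplies each 1-minute concentration by the correction factor of its
#' measurement run. Optical particle counters are calibrated against
#' co-located filter gravimetry; the resulting run-level multiplier (around
#' 1.1 for the campaigns this model was built for) is applied here. A single
#' unnamed factor is accepted as a global multiplier.
#'
#' @param records Measurement records as returned by [read_measurements()].
#' @param factors Named numeric vector (or list) mapping `run_id` to a
#'   positive factor, or a single unnamed number applied to all runs.
#' @return The records with `pm25` scaled; row count and order unchanged.
#' @export
#' @examples
#' rec <- data.frame(date = "d1", minute_of_day = 0L, pm25 = 20,
#'                   microenv = "other", run_id = "r1")
#' apply_correction(rec, c(r1 = 1.1))$pm25  # 22
apply_correction <- function(records, factors) {
  factors <- unlist(factors)
  if (any(!is.finite(factors) | factors <= 0)) {
    stop("correction factors must be positive", call. = FALSE)
  }
  if (length(factors) == 1 && is.null(names(factors))) {
    records$pm25 <- records$pm25 * as.numeric(factors)
    return(records)
  }
  missing <- setdiff(unique(records$run_id), names(factors))
  if (length(missing)) {
    stop("no correction factor for run(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  records$pm25 <- records$pm25 * as.numeric(factors[records$run_id])
  records
}
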