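#' Build the 144-slot by 3-microenvironment concentration grid
#'
#' Pools all (corrected) 1-minute records into one diurnal grid: each record
#' lands in the 10-minute slot containing its minute of day, within its
#' microenvironment. Multi-day campaigns are pooled into a single 24-h grid
#' (no date stratification). The grid always has 432 cells; cells with fewer
#' than `min_obs_per_cell` observations are flagged unavailable and are later
#' excluded from a diary's exposure denominator rather than imputed.
#'
#' @param records Measurement records (see [read_measurements()]), already
#'   corrected via [apply_correction()] if correction factors apply.
#' @param min_obs_per_cell Minimum observation count for a cell to be usable.
#' @return A `slot_grid` object: `$cells` is a 432-row data frame
#'   (`slot, microenv, n_obs, mean, sd, available`), `$cell_data` keeps the
#'   member observations for distribution fitting, `$fits` holds
#'   `fitted_dist` objects once [fit_grid_distributions()] has run.
#' @export
build_grid <- function(records, min_obs_per_cell = 5) {
  if (is.null(records) || nrow(records) == 0) {
    stop("records must be non-empty", call. = FALSE)
  }
  if (any(records$pm25 < 0)) stop("negative concentrations in records", call. = FALSE)
  slot <- slot_of_minute(records$minute_of_day)
  me <- me_code(records$microenv)
  idx <- cell_index(slot, me)
  cell_data <- split(records$pm25, factor(idx, levels = seq_len(N_CELLS)))
  n_obs <- lengths(cell_data)
  mu <- vapply(cell_data, function(v) if (length(v)) mean(v) else NA_real_,
               numeric(1))
  sdv <- vapply(cell_data, function(v) if (length(v) > 1) stats::sd(v) else
    if (length(v) == 1) 0 else NA_real_, numeric(1))
  cells <- data.frame(
    slot = rep(seq_len(N_SLOTS), each = 3L),
    microenv = rep(ME_LEVELS, times = N_SLOTS),
    n_obs = as.integer(n_obs),
    mean = unname(mu),
    sd = unname(sdv),
    available = unname(n_obs >= min_obs_per_cell),
    stringsAsFactors = FALSE
  )
  structure(list(cells = cells,
                 cell_data = unname(cell_data),
                 fits = vector("list", N_CELLS),
                 min_obs_per_cell = min_obs_per_cell),
            class = "slot_grid")
}

#' @export
print.slot_grid <- function(x, ...) {
  cat("slot_grid: 144 slots x 3 microenvironments (432 cells)\n")
  cat("  available cells:", sum(x$cells$available), "of", nrow(x$cells), "\n")
  cat("  observations:", sum(x$cells$n_obs), "\n")
  fitted <- sum(!vapply(x$fits, is.null, logical(1)))
  if (fitted) cat("  fitted cells:", fitted, "\n")
  invisible(x)
}

# 144 x 3 matrix of cell means (NA where no data)
grid_means <- function(grid) {
  matrix(grid$cells$mean, nrow = N_SLOTS, ncol = 3L, byrow = TRUE,
         dimnames = list(NULL, ME_LEVELS))
}

# 144 x 3 logical availability matrix
grid_available <- function(grid) {
  matrix(grid$cells$available, nrow = N_SLOTS, ncol = 3L, byrow = TRUE,
         dimnames = list(NULL, ME_LEVELS))
}

#' Fit concentration distributions to every available grid cell
#'
#' Runs [fit_cell_distribution()] on each available cell and stores the
#' result in the grid. Unavailable cells are left unfitted (they are excluded
#' from exposure calculations anyway).
#'
#' @param grid A `slot_grid` from [build_grid()].
#' @param families,criterion Passed to [fit_cell_distribution()].
#' @return The grid with `$fits` populated and per-cell family recorded in
#'   `$cells$family`.
#' @export
fit_grid_distributions <- function(grid, families = FIT_FAMILIES,
                                   criterion = c("AIC", "KS")) {
  criterion <- match.arg(criterion)
  stopifnot(inherits(grid, "slot_grid"))
  if (is.null(grid$cell_data)) {
    stop("grid carries no raw cell data (was it read from a file?); ",
         "rebuild it from records before fitting", call. = FALSE)
  }
  fam <- rep(NA_character_, N_CELLS)
  for (k in seq_len(N_CELLS)) {
    if (!grid$cells$available[k]) next
    fit <- withCallingHandlers(
      fit_cell_distribution(grid$cell_data[[k]], families, criterion),
      warning = function(w) invokeRestart("muffleWarning"))
    grid$fits[[k]] <- fit
    fam[k] <- fit$family
  }
  grid$cells$family <- fam
  grid$criterion <- criterion
  grid
}

#' Write a fitted grid to a CSV summary file
#'
#' One row per cell: `slot, microenv, n_obs, mean, sd, available, family,
#' params_json`. The file is sufficient to drive both exposure paths (cell
#' means for the deterministic path, fitted parameters for the simulation
#' path); raw per-cell observations are not persisted.
#'
#' @param grid A `slot_grid`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_grid <- function(grid, path) {
  stopifnot(inherits(grid, "slot_grid"))
  df <- grid$cells
  df$family <- vapply(grid$fits, function(f) if (is.null(f)) NA_character_ else
    f$family, character(1))
  df$params_json <- vapply(grid$fits, function(f) {
    if (is.null(f)) NA_character_ else
      as.character(jsonlite::toJSON(as.list(f$params), auto_unbox = TRUE,
                                    digits = NA))
  }, character(1))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a grid summary file written by [write_grid()]
#'
#' @param path Path to the grid CSV.
#' @return A `slot_grid` (without raw cell data; refitting requires the
#'   original records).
#' @export
read_grid <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("slot", "microenv", "n_obs", "mean", "sd", "available")
  if (!all(need %in% names(df)) || nrow(df) != N_CELLS) {
    stop("not a grid summary file: ", path, call. = FALSE)
  }
  ord <- order(df$slot, me_code(df$microenv))
  df <- df[ord, ]
  fits <- vector("list", N_CELLS)
  if ("params_json" %in% names(df)) {
    for (k in seq_len(N_CELLS)) {
      if (!is.na(df$family[k]) && nzchar(df$family[k]) &&
          !is.na(df$params_json[k])) {
        pl <- jsonlite::fromJSON(df$params_json[k])
        fits[[k]] <- new_fitted_dist(df$family[k], unlist(pl),
                                     n = df$n_obs[k])
      }
    }
  }
  cells <- df[c("slot", "microenv", "n_obs", "mean", "sd", "available")]
  if ("family" %in% names(df)) cells$family <- df$family
  rownames(cells) <- NULL
  structure(list(cells = cells, cell_data = NULL, fits = fits,
                 min_obs_per_cell = NA),
            class = "slot_grid")
}
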