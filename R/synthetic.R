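# Synthetic measurement campaigns and diary populations.
#
# The generators emulate the statistical structure the model assumes — a
# diurnal lognormal concentration field per microenvironment, block-structured
# daily schedules whose time budgets vary by day type, and a demographic
# covariate table with controllable schedule-tilting effect sizes — so every
# pipeline stage can be exercised without any external data.

default_hourly_means <- function() {
  residential <- rep(22.8, 24)
  residential[13] <- 45      # lunch-time cooking bump (12:00-12:59)
  transportation <- rep(24.2, 24)
  other <- rep(27.8, 24)
  other[19:23] <- 61.2       # evening elevation 18:00-22:59 (restaurants, bars)
  cbind(residential_indoor = residential,
        transportation = transportation,
        other = other)
}

default_blanked_cells <- function() {
  # 23 transportation cells with no measurements, 02:10-06:00 (covers the
  # early-morning 04:00-05:59 window that forces reduced denominators)
  data.frame(slot = 14:36, microenv = "transportation",
             stringsAsFactors = FALSE)
}

#' Specification of a synthetic measurement campaign
#'
#' Defaults emulate a summer weekday urban campaign: overall means of about
#' 23.7 (residential indoor, with a lunch-time bump), 24.2 (transportation)
#' and 34.7 µg/m³ ("other", elevated 18:00–22:59), right-skewed lognormal
#' minute-to-minute noise with GSDs back-computed from SD/mean ratios of
#' roughly 1.0, 0.94 and 1.8, per-slot observation counts of 229/37/150
#' minutes (about 59,900 minutes in total), and 23 blanked early-morning
#' transportation cells.
#'
#' @param hourly_means 24 x 3 matrix of hourly mean concentrations (µg/m³),
#'   columns in [ME_LEVELS] order.
#' @param gsd Length-3 geometric standard deviations (>= 1) per
#'   microenvironment; `gsd = 1` gives noise-free cells.
#' @param minutes_per_cell Length-3 observation counts per cell per
#'   microenvironment.
#' @param blanked_cells Data frame `slot, microenv` of cells to leave empty.
#' @param seed Integer seed.
#' @return A `campaign_spec` list.
#' @export
campaign_spec <- function(hourly_means = default_hourly_means(),
                          gsd = c(2.3, 2.2, 3.3),
                          minutes_per_cell = c(229, 37, 150),
                          blanked_cells = default_blanked_cells(),
                          seed = 1) {
  hourly_means <- as.matrix(hourly_means)
  if (!all(dim(hourly_means) == c(24, 3)) || any(hourly_means <= 0)) {
    stop("hourly_means must be a positive 24 x 3 matrix", call. = FALSE)
  }
  if (length(gsd) != 3 || any(gsd < 1)) {
    stop("gsd must be 3 values >= 1", call. = FALSE)
  }
  if (length(minutes_per_cell) != 3 || any(minutes_per_cell < 0)) {
    stop("minutes_per_cell must be 3 non-negative counts", call. = FALSE)
  }
  if (!is.null(blanked_cells) && nrow(blanked_cells)) {
    if (any(blanked_cells$slot < 1 | blanked_cells$slot > N_SLOTS) ||
        !all(blanked_cells$microenv %in% ME_LEVELS)) {
      stop("blanked_cells must reference cells of the 144 x 3 grid",
           call. = FALSE)
    }
  }
  structure(list(hourly_means = hourly_means,
                 gsd = as.numeric(gsd),
                 minutes_per_cell = as.numeric(minutes_per_cell),
                 blanked_cells = blanked_cells,
                 seed = as.integer(seed)),
            class = "campaign_spec")
}

#' Generate a synthetic 1-minute measurement campaign
#'
#' Per non-blanked cell, draws `minutes_per_cell` lognormal 1-minute
#' concentrations whose arithmetic mean matches the cell's diurnal profile
#' value and whose GSD is the microenvironment's; minutes cycle through the
#' slot and days/runs advance every 10 observations. Byte-reproducible for a
#' given spec.
#'
#' @param spec A [campaign_spec()].
#' @return A measurement record data frame in the [read_measurements()]
#'   schema (columns `date, minute_of_day, pm25, microenv, run_id`).
#' @export
generate_campaign <- function(spec) {
  stopifnot(inherits(spec, "campaign_spec"))
  set.seed(spec$seed)
  blank_idx <- integer(0)
  if (!is.null(spec$blanked_cells) && nrow(spec$blanked_cells)) {
    blank_idx <- cell_index(spec$blanked_cells$slot,
                            me_code(spec$blanked_cells$microenv))
  }
  out <- vector("list", N_CELLS)
  for (m in 1:3) {
    n <- spec$minutes_per_cell[m]
    if (n == 0) next
    sdlog <- log(spec$gsd[m])
    for (slot in seq_len(N_SLOTS)) {
      k <- cell_index(slot, m)
      if (k %in% blank_idx) next
      hour <- (slot - 1L) %/% 6L + 1L
      mu <- spec$hourly_means[hour, m]
      meanlog <- log(mu) - sdlog^2 / 2    # arithmetic mean = mu
      vals <- if (sdlog == 0) rep(mu, n) else stats::rlnorm(n, meanlog, sdlog)
      minute <- rep(10L * (slot - 1L) + 0:9, length.out = n)
      day <- rep(seq_len(ceiling(n / 10)), each = 10)[seq_len(n)]
      out[[k]] <- data.frame(date = sprintf("day%02d", day),
                             minute_of_day = minute,
                             pm25 = vals,
                             microenv = ME_LEVELS[m],
                             run_id = sprintf("run%02d", day),
                             stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(out[!vapply(out, is.null, logical(1))],
                   list(make.row.names = FALSE)))
}

default_budget_targets <- function() {
  list(weekday  = list(mean = c(13.95, 2.03, 8.01), sd = c(4.77, 1.68, 4.28)),
       saturday = list(mean = c(15.02, 2.02, 6.96), sd = c(5.09, 1.72, 4.46)),
       sunday   = list(mean = c(17.01, 1.76, 5.23), sd = c(5.40, 1.86, 4.46)))
}

#' Specification of a synthetic diary population
#'
#' Defaults emulate a large urban time-use survey: day-type mix of about
#' 60/20/20% weekday/Saturday/Sunday, day-type-specific time-budget targets
#' (e.g. 13.95/2.03/8.01 h residential/transport/other on weekdays, up to
#' 17.01 h residential on Sundays), demographic marginals typical of such a
#' survey, and schedule-tilting effect sizes (log-odds of high-exposure
#' membership per covariate) through which working characteristics push
#' subjects into the higher-concentration "other" microenvironment.
#'
#' @param n_subjects Number of person-days to generate.
#' @param day_type_weights Named proportions over [DAY_TYPES] (normalised).
#' @param budget_targets Per-day-type list of `mean` and `sd` triples
#'   (residential, transport, other hours); each mean triple must sum to
#'   24 h within 0.25 h or the spec is rejected as infeasible.
#' @param effect_sizes Named numeric: `tertiary`, `non_office` (indicator
#'   log-odds) and `working_hours` (log-odds per weekly hour). Zero effects
#'   give a null population.
#' @param tilt_hours_per_logodds Hours of "other" time added per unit of a
#'   subject's centred linear predictor (centring keeps day-type budget
#'   means on target).
#' @param early_transit_prob Probability a commuting subject departs in the
#'   04:00–05:59 window (where default campaigns have no transportation
#'   data, triggering the reduced-denominator rule downstream).
#' @param seed Integer seed.
#' @return A `population_spec` list.
#' @export
population_spec <- function(n_subjects = 8072,
                            day_type_weights = c(weekday = 4849,
                                                 saturday = 1608,
                                                 sunday = 1618),
                            budget_targets = default_budget_targets(),
                            effect_sizes = c(tertiary = 1.0,
                                             non_office = 0.8,
                                             working_hours = 0.028),
                            tilt_hours_per_logodds = 0.6,
                            early_transit_prob = 0.05,
                            seed = 1) {
  if (n_subjects < 1) stop("n_subjects must be positive", call. = FALSE)
  if (!all(DAY_TYPES %in% names(day_type_weights))) {
    stop("day_type_weights must name all of ",
         paste(DAY_TYPES, collapse = ", "), call. = FALSE)
  }
  w <- day_type_weights[DAY_TYPES]
  if (any(w < 0) || sum(w) <= 0) stop("invalid day_type_weights", call. = FALSE)
  w <- w / sum(w)
  for (dt in DAY_TYPES) {
    tg <- budget_targets[[dt]]
    if (is.null(tg) || length(tg$mean) != 3 || length(tg$sd) != 3 ||
        any(tg$mean < 0) || any(tg$sd < 0)) {
      stop("budget_targets must give mean and sd triples per day type",
           call. = FALSE)
    }
    if (abs(sum(tg$mean) - 24) > 0.25) {
      stop("infeasible budget targets for ", dt, ": means sum to ",
           round(sum(tg$mean), 2), " h, expected 24 h", call. = FALSE)
    }
  }
  es <- c(tertiary = 0, non_office = 0, working_hours = 0)
  es[names(effect_sizes)] <- effect_sizes
  structure(list(n_subjects = as.integer(n_subjects),
                 day_type_weights = w,
                 budget_targets = budget_targets,
                 effect_sizes = es,
                 tilt_hours_per_logodds = tilt_hours_per_logodds,
                 early_transit_prob = early_transit_prob,
                 seed = as.integer(seed)),
            class = "population_spec")
}

# one day's slot sequence from slot counts: home - commute - "other" block -
# commute - home, optionally departing in the early-morning window
build_schedule <- function(n_t, n_o, start_slot, early = FALSE) {
  slots <- rep(1L, N_SLOTS)
  if (n_t + n_o == 0) return(slots)
  n_o <- min(n_o, N_SLOTS - n_t - 1L)
  out <- ceiling(n_t / 2)
  back <- n_t - out
  start <- if (early && out > 0) 26L else start_slot
  start <- max(2L, min(start, N_SLOTS - (n_t + n_o) + 1L))
  pos <- start
  if (out > 0) { slots[pos:(pos + out - 1L)] <- 2L; pos <- pos + out }
  if (n_o > 0) { slots[pos:(pos + n_o - 1L)] <- 3L; pos <- pos + n_o }
  if (back > 0) slots[pos:(pos + back - 1L)] <- 2L
  slots
}

#' Generate a synthetic diary population with covariates
#'
#' Samples day types by weight, draws per-subject time budgets around the
#' day-type targets (component draws clipped at zero and renormalised to
#' 24 h), tilts schedules by the centred covariate linear predictor (extra
#' "other" hours for high-linear-predictor subjects, taken from residential
#' time), and lays each day out as home–commute–activity–commute–home
#' blocks, reproducing morning/evening transit bands. Demographic covariates
#' are sampled from urban-survey-like marginals; industry, job type and
#' working hours are generated jointly with an employment indicator
#' (non-working respondents get `not_applicable` and zero hours).
#'
#' @param spec A [population_spec()].
#' @return A `diary_set` with covariates; the generating truth (per-subject
#'   linear predictor and tilt hours) is attached as `attr(x, "truth")` for
#'   recovery testing.
#' @export
generate_population <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  set.seed(spec$seed)
  n <- spec$n_subjects
  day_type <- sample(DAY_TYPES, n, replace = TRUE,
                     prob = spec$day_type_weights)
  # demographic covariates (marginals typical of an urban time-use survey)
  sex <- sample(c("male", "female"), n, TRUE, prob = c(0.469, 0.531))
  age <- pmin(93, pmax(10, round(stats::rnorm(n, 38, 18))))
  marital <- sample(c("married", "unmarried"), n, TRUE, prob = c(0.555, 0.445))
  education <- sample(c("middle_school_or_below", "college_or_below",
                        "university_or_above"), n, TRUE,
                      prob = c(0.277, 0.365, 0.358))
  employed <- stats::runif(n) < 0.549
  industry <- rep("not_applicable", n)
  industry[employed] <- sample(c("primary_secondary", "tertiary", "other"),
                               sum(employed), TRUE,
                               prob = c(0.173, 0.549, 0.278))
  job <- rep("not_applicable", n)
  job[employed] <- sample(c("office", "non_office"), sum(employed), TRUE,
                          prob = c(0.457, 0.543))
  working_hours <- numeric(n)
  working_hours[employed] <- pmin(120, pmax(1, round(stats::rnorm(
    sum(employed), 48, 18))))
  income_band <- sample(c("lt_2000", "ge_2000"), n, TRUE,
                        prob = c(0.851, 0.149))
  house_size <- round(pmin(340, pmax(10, stats::rlnorm(n, log(66), 0.45))), 1)
  owns_house <- stats::runif(n) < 0.521
  owns_car <- stats::runif(n) < 0.613
  covariates <- data.frame(sex = sex, age = age, marital = marital,
                           education = education, industry = industry,
                           job = job, working_hours = working_hours,
                           income_band = income_band,
                           house_size = house_size,
                           owns_house = owns_house, owns_car = owns_car,
                           stringsAsFactors = FALSE)
  es <- spec$effect_sizes
  eta <- es[["tertiary"]] * (industry == "tertiary") +
    es[["non_office"]] * (job == "non_office") +
    es[["working_hours"]] * working_hours
  tilt <- spec$tilt_hours_per_logodds * (eta - mean(eta))
  # time budgets: component-wise normal draws, clipped, renormalised to 24 h
  r <- t_h <- o <- numeric(n)
  for (dt in DAY_TYPES) {
    i <- which(day_type == dt)
    if (!length(i)) next
    tg <- spec$budget_targets[[dt]]
    r[i] <- pmax(0, stats::rnorm(length(i), tg$mean[1], tg$sd[1]))
    t_h[i] <- pmax(0, stats::rnorm(length(i), tg$mean[2], tg$sd[2]))
    o[i] <- pmax(0, stats::rnorm(length(i), tg$mean[3], tg$sd[3]))
  }
  tot <- r + t_h + o
  r <- 24 * r / tot; t_h <- 24 * t_h / tot; o <- 24 * o / tot
  # schedule tilt: high-linear-predictor subjects trade residential time for
  # "other" time (centred, so day-type budget means stay on target)
  shift <- pmin(pmax(tilt, -o + 0.5), r - 5)
  r <- r - shift
  o <- o + shift
  n_t <- pmin(24L, as.integer(round(t_h * 6)))
  n_o <- pmax(0L, as.integer(round(o * 6)))
  n_o <- pmin(n_o, N_SLOTS - n_t - 6L)   # keep at least 1 h at home
  start_slot <- 43L + sample(0:12, n, replace = TRUE)
  early <- stats::runif(n) < spec$early_transit_prob
  slots <- matrix(1L, n, N_SLOTS)
  for (i in seq_len(n)) {
    slots[i, ] <- build_schedule(n_t[i], n_o[i], start_slot[i], early[i])
  }
  diaries <- diary_set(sprintf("subj%05d", seq_len(n)), day_type, slots,
                       covariates)
  attr(diaries, "truth") <- list(spec = spec, eta = eta, tilt_hours = tilt,
                                 employed = employed, early_transit = early)
  diaries
}
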