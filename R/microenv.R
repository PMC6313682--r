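#' Microenvironment codes
#'
#' The three microenvironment categories used throughout the package:
#' `residential_indoor`, `transportation` and `other`. Every measurement
#' record and every diary slot carries exactly one of these codes.
#'
#' @format Character vector of length 3.
#' @export
ME_LEVELS <- c("residential_indoor", "transportation", "other")

#' Day-type codes
#'
#' Day-of-week categories for diaries: `weekday`, `saturday`, `sunday`.
#'
#' @format Character vector of length 3.
#' @export
DAY_TYPES <- c("weekday", "saturday", "sunday")

# number of 10-min slots per day and cells per grid
N_SLOTS <- 144L
N_CELLS <- 432L

#' Convert a minute of the day to its 10-minute slot index
#'
#' Slots are 1-based: slot `t` covers minutes `[10(t-1), 10t)` (half-open),
#' so minutes 0, 5 and 9 all fall in slot 1 and minute 1439 in slot 144.
#'
#' @param minute Integer vector, minutes since midnight in `[0, 1439]`.
#' @return Integer vector of slot indices in `1:144`.
#' @export
#' @examples
#' slot_of_minute(c(0, 5, 9, 10, 1439))
slot_of_minute <- function(minute) {
  if (any(minute < 0 | minute > 1439)) {
    stop("minute_of_day must lie in [0, 1439]", call. = FALSE)
  }
  as.integer(minute %/% 10L + 1L)
}

# linear cell index for (slot, microenv index), 1..432
cell_index <- function(slot, me_idx) {
  (slot - 1L) * 3L + me_idx
}

# integer code 1..3 for a microenvironment label, with validation
me_code <- function(x) {
  idx <- match(x, ME_LEVELS)
  if (anyNA(idx)) {
    bad <- unique(x[is.na(idx)])
    stop("unknown microenvironment code(s): ", paste(bad, collapse = ", "),
         "; expected one of ", paste(ME_LEVELS, collapse = ", "),
         call. = FALSE)
  }
  as.integer(idx)
}

#' Round half away from zero
#'
#' Decimal rounding with ties going up (0.05 -> 0.1), the convention used in
#' the package's report tables; base [round()] rounds ties to even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Day type of a calendar date
#'
#' Maps Monday–Friday to `weekday`, Saturday to `saturday` and Sunday to
#' `sunday`.
#'
#' @param date A `Date` vector (or something coercible via [as.Date()]).
#' @return Character vector of day-type codes.
#' @export
day_type_of_date <- function(date) {
  wd <- as.POSIXlt(as.Date(date))$wday  # 0 = Sunday
  out <- rep("weekday", length(wd))
  out[wd == 6] <- "saturday"
  out[wd == 0] <- "sunday"
  out
}

#' Map seven-category activity-survey location codes to the three-category scheme
#'
#' Later waves of national time-use surveys record seven location categories.
#' This maps them onto the three microenvironments used here: own home to
#' `residential_indoor`; walk, private and public transportation to
#' `transportation`; workplace/school, restaurant and other to `other`.
#'
#' @param x Character vector of seven-category codes (`own_home`,
#'   `workplace_school`, `restaurant`, `other`, `walk`,
#'   `private_transportation`, `public_transportation`).
#' @return Character vector of three-category microenvironment codes.
#' @export
map_seven_category <- function(x) {
  map <- c(own_home = "residential_indoor",
           walk = "transportation",
           private_transportation = "transportation",
           public_transportation = "transportation",
           workplace_school = "other",
           restaurant = "other",
           other = "other")
  out <- map[x]
  if (anyNA(out)) {
    stop("unknown seven-category code(s): ",
         paste(unique(x[is.na(out)]), collapse = ", "), call. = FALSE)
  }
  unname(out)
}
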