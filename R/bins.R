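#' The eight-bin longitudinal observation schedule
#'
#' The observation window spans the 7.5 years before the time of prediction,
#' split into eight contiguous half-open bins whose widths grow roughly
#' logarithmically with distance from the prediction date: two periods of
#' three months, two of six months, two of one year and two of two years.
#' Bin 0 is the most recent (ending at the time of prediction) and bin 7 the
#' most distant. The same schedule is used for every study design so that
#' models trained on one cohort can score another.
#'
#' @param time_of_prediction A `Date` (scalar) ending the observation window.
#' @return A tibble with columns `bin` (0-7), `start`, `end` (half-open
#'   `[start, end)`) and `width_months`.
#' @examples
#' make_time_bins(as.Date("2017-01-01"))
#' @export
make_time_bins <- function(time_of_prediction) {
  stopifnot(inherits(time_of_prediction, "Date"), length(time_of_prediction) == 1)
  cum <- bin_cum_months()
  bounds <- add_with_rollback(time_of_prediction, lubridate::period(months = -cum))
  tibble(
    bin = 0:7,
    start = bounds[2:9],
    end = bounds[1:8],
    width_months = diff(cum)
  )
}

# widths in months, most recent bin first
bin_widths_months <- function() c(3L, 3L, 6L, 6L, 12L, 12L, 24L, 24L)

bin_cum_months <- function() cumsum(c(0L, bin_widths_months()))

#' Assign events to time bins relative to a per-row prediction date
#'
#' Vectorised over (date, time_of_prediction) pairs. Bins are half-open
#' `[start, end)`, so an event falling exactly on a boundary belongs to the
#' later (more recent) bin, and an event dated exactly at the time of
#' prediction falls outside the window.
#'
#' @param date Event dates (`Date`).
#' @param time_of_prediction Prediction dates (`Date`), recycled against `date`.
#' @return Integer bin index 0-7, or `NA` for events outside the 7.5-year
#'   window. Events dated after the time of prediction raise a leakage error.
#' @export
assign_bin <- function(date, time_of_prediction) {
  n <- max(length(date), length(time_of_prediction))
  date <- rep_len(date, n)
  top <- rep_len(time_of_prediction, n)
  if (any(date > top)) {
    abort("event dated after the time of prediction: predictor leakage",
          class = "riskpipe_leakage_error")
  }
  cum <- bin_cum_months()
  # boundaries depend only on the prediction date: compute them once per
  # unique date, then count how many of the 9 boundaries (top - cum months)
  # lie strictly after the event; c boundaries after => bin c - 1 (9 = too old)
  ut <- unique(top)
  b_mat <- vapply(cum, function(m) {
    as.numeric(add_with_rollback(ut, lubridate::period(months = -m)))
  }, numeric(length(ut)))
  b_mat <- matrix(b_mat, nrow = length(ut))
  idx <- match(top, ut)
  dnum <- as.numeric(date)
  cnt <- integer(n)
  for (k in seq_along(cum)) {
    cnt <- cnt + (dnum < b_mat[idx, k])
  }
  bin <- cnt - 1L
  bin[bin < 0L | bin > 7L] <- NA_integer_
  bin
}

# day-based bin boundaries used by the synthetic generator's ground-truth
# hazard (91/183/365/730-day approximations of the calendar-month schedule)
bin_bounds_days <- function() cumsum(c(0L, 91L, 91L, 183L, 183L, 365L, 365L, 730L, 730L))

assign_bin_days <- function(days_before) {
  # days_before = time_of_prediction - event date, in days (> 0 inside window)
  b <- findInterval(days_before, bin_bounds_days(), left.open = TRUE)
  b[days_before <= 0 | b > 8L] <- NA_integer_
  b - 1L
}
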