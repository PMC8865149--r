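# Per-minute accelerometer activity scoring.

#' Score per-minute activity from accelerometer samples
#'
#' A minute is *observed* if at least `min_samples` samples fall in it, and
#' *active* if the standard deviation of the acceleration magnitude
#' `sqrt(x^2 + y^2 + z^2)` over the minute's samples exceeds
#' `sd_threshold_g`. Magnitude-SD scoring is orientation-invariant and
#' platform-neutral: at rest the magnitude sits near 1 g with little
#' variation regardless of how the phone is held.
#'
#' @param samples data.frame `timestamp` (UTC epoch ms), `x`, `y`, `z` (g),
#'   time-sorted.
#' @param tz subject timezone for day/minute binning.
#' @param sd_threshold_g activity threshold on the magnitude SD (g).
#' @param min_samples minimum samples per observed minute.
#' @return data.frame with one row per observed minute: `date`,
#'   `minute_of_day` (0-1439), `n_samples`, `active`.
#' @export
minute_activity <- function(samples, tz = "UTC", sd_threshold_g = 0.1,
                            min_samples = 5) {
  if (nrow(samples) == 0)
    return(data.frame(date = as.Date(character(0)),
                      minute_of_day = integer(0), n_samples = integer(0),
                      active = logical(0)))
  if (is.unsorted(samples$timestamp)) stop("samples must be time-sorted")
  mag <- sqrt(samples$x^2 + samples$y^2 + samples$z^2)
  date <- local_date(samples$timestamp, tz)
  mod <- floor(local_seconds(samples$timestamp, tz) / 60)
  key <- as.numeric(date) * 1440 + mod
  agg <- rowsum(cbind(1, mag, mag^2), key)
  ukey <- as.numeric(rownames(agg))
  n <- agg[, 1]; s1 <- agg[, 2]; s2 <- agg[, 3]
  keep <- n >= min_samples
  var_m <- pmax(s2 / n - (s1 / n)^2, 0) # population variance per minute
  out <- data.frame(
    date = as.Date(ukey[keep] %/% 1440, origin = "1970-01-01"),
    minute_of_day = as.integer(ukey[keep] %% 1440),
    n_samples = as.integer(n[keep]),
    active = sqrt(var_m[keep]) > sd_threshold_g)
  out <- out[order(out$date, out$minute_of_day), ]
  rownames(out) <- NULL
  out
}

#' Hourly activity curve
#'
#' For each hour of the day, the proportion of *observed* minutes of the
#' requested day type that were active, pooled over all days (a ratio
#' estimator: weighting by observation rather than averaging per-day curves
#' avoids overweighting time intervals during which data tended to be
#' collected). Hours with no observed minutes are `NA`.
#'
#' @param minutes output of [minute_activity()].
#' @param type `"weekday"` or `"weekend"` (or `NULL` for all days).
#' @return data.frame `hour` (0-23), `activity` in `[0,1]` or `NA`,
#'   `observed_minutes`.
#' @export
hourly_activity_curve <- function(minutes, type = NULL) {
  if (!is.null(type)) minutes <- minutes[day_type(minutes$date) == type, ,
                                         drop = FALSE]
  hour <- minutes$minute_of_day %/% 60
  obs <- tabulate(hour + 1, nbins = 24)
  act <- vapply(0:23, function(h) sum(minutes$active[hour == h]), numeric(1))
  data.frame(hour = 0:23,
             activity = ifelse(obs > 0, act / obs, NA_real_),
             observed_minutes = obs)
}

#' Daily activity level and missing minutes
#'
#' @param minutes [minute_activity()] rows (any days); summarized per day.
#' @return data.frame per local day: `date`, `day_type`, `activity_level`
#'   (active/observed minutes; `NA` when nothing observed), and
#'   `accel_missing_minutes` (`1440 -` observed minutes).
#' @export
daily_activity <- function(minutes) {
  if (nrow(minutes) == 0)
    return(data.frame(date = as.Date(character(0)), day_type = character(0),
                      activity_level = numeric(0),
                      accel_missing_minutes = numeric(0)))
  obs <- tapply(minutes$active, minutes$date, length)
  act <- tapply(minutes$active, minutes$date, sum)
  dates <- as.Date(names(obs))
  data.frame(date = dates, day_type = day_type(dates),
             activity_level = as.numeric(act / obs),
             accel_missing_minutes = 1440 - as.numeric(obs),
             row.names = NULL)
}
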