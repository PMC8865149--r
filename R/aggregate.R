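# Per-visit weekly feature vectors, completeness accounting, and
# communication-log summaries.

#' Canonical names of the 32 weekly passive summary statistics
#'
#' For each of the 15 daily feature families (14 GPS-based plus the
#' accelerometer activity level), a weekday mean and a weekend mean over the
#' 7 days preceding a visit (30 values), plus the GPS and accelerometer
#' missing-minute totals over the window (2 values): 32 in all, fixed order.
#'
#' @return Character vector of length 32.
#' @export
passive_feature_names <- function() {
  c(paste0("weekday_", FEATURE_FAMILIES),
    paste0("weekend_", FEATURE_FAMILIES),
    "gps_missing_minutes", "accel_missing_minutes")
}

#' Weekly passive feature vector for one visit
#'
#' Aggregates daily summaries over the 7 local days *strictly preceding* the
#' visit date (the visit day itself is excluded): per-family means computed
#' separately over weekday and weekend days that have a value, and
#' missing-minute totals summed over all 7 days. Days with no value
#' contribute nothing to the means (never zeros) — absence is encoded solely
#' by the missing-minute features; days entirely absent from the daily
#' tables contribute their full expected minutes to those totals.
#'
#' @param daily_gps per-day mobility table from [mobility_daily()] (one
#'   subject).
#' @param daily_accel per-day activity table from [daily_activity()] (one
#'   subject).
#' @param visit_date the visit `Date`.
#' @param gps_expected_min expected observable GPS minutes per day under the
#'   duty cycle (240 for 2 min on / 10 min off).
#' @return One-row data.frame with the 32 named statistics, in
#'   [passive_feature_names()] order.
#' @export
weekly_feature_vector <- function(daily_gps, daily_accel, visit_date,
                                  gps_expected_min = 240) {
  visit_date <- as.Date(visit_date)
  window <- seq(visit_date - 7, visit_date - 1, by = "day")
  wtypes <- day_type(window)
  g <- daily_gps[daily_gps$date %in% window, , drop = FALSE]
  a <- daily_accel[daily_accel$date %in% window, , drop = FALSE]
  daily <- merge(g, a[, c("date", "activity_level", "accel_missing_minutes")],
                 by = "date", all = TRUE)
  daily$day_type <- day_type(daily$date)

  out <- stats::setNames(as.list(rep(NA_real_, 32)), passive_feature_names())
  for (type in c("weekday", "weekend")) {
    rows <- daily[daily$day_type == type, , drop = FALSE]
    for (f in FEATURE_FAMILIES) {
      v <- rows[[f]]
      v <- v[!is.na(v)]
      if (length(v)) out[[paste0(type, "_", f)]] <- mean(v)
    }
  }
  # missing-minute totals over all 7 window days; absent days are fully missing
  gm <- daily$gps_missing_minutes[match(window, daily$date)]
  gm[is.na(gm)] <- gps_expected_min
  am <- daily$accel_missing_minutes[match(window, daily$date)]
  am[is.na(am)] <- 1440
  out$gps_missing_minutes <- sum(gm)
  out$accel_missing_minutes <- sum(am)
  as.data.frame(out)
}

#' Attach the closest preceding PHQ-8 to each visit
#'
#' For each visit, the completed survey of that subject with the latest
#' completion time at or before the visit time; `NA` if none. The completion
#' timestamp (not delivery) is used — the score exists only once completed.
#'
#' @param visits visit data.frame (`subject`, `visit_index`, `date`,
#'   `madrs`).
#' @param surveys survey data.frame (`subject`, `delivered`, `completed`,
#'   `total`).
#' @param tz timezone; the visit is anchored at `visit_hour` local.
#' @param visit_hour hour of day of the clinic assessment.
#' @return `visits` with a `phq8` column added.
#' @export
attach_phq <- function(visits, surveys, tz = "UTC", visit_hour = 12) {
  visits$phq8 <- NA_real_
  vt <- midnight_ms(as.Date(visits$date), tz) + visit_hour * 3600 * 1000
  done <- surveys[!is.na(surveys$completed), , drop = FALSE]
  for (i in seq_len(nrow(visits))) {
    s <- done[done$subject == visits$subject[i] & done$completed <= vt[i], ,
              drop = FALSE]
    if (nrow(s)) visits$phq8[i] <- s$total[which.max(s$completed)]
  }
  visits
}

#' Sensor completeness proportions
#'
#' Minutes with at least one sample divided by the number of expected
#' minutes over the study window. For the accelerometer (scheduled to reach
#' every minute) the denominator is every minute of the window; for GPS it
#' is the window scaled by the duty-cycle on-fraction (1/6 under 2 min on /
#' 10 min off).
#'
#' @param gps,accel sensor streams for one subject.
#' @param window_start,window_end first and last local `Date` of the window
#'   (the full days between the baseline and last visit).
#' @param gps_on_s,gps_off_s GPS duty cycle.
#' @param tz timezone.
#' @return Named numeric: `accel`, `gps` proportions in `[0, 1]`.
#' @export
sensor_completeness <- function(gps, accel, window_start, window_end,
                                gps_on_s = 120, gps_off_s = 600, tz = "UTC") {
  t0 <- midnight_ms(as.Date(window_start), tz)
  t1 <- midnight_ms(as.Date(window_end) + 1, tz)
  total_min <- (t1 - t0) / 60000
  stopifnot(total_min > 0)
  obs_minutes <- function(ts) {
    ts <- ts[ts >= t0 & ts < t1]
    length(unique(floor((ts - t0) / 60000)))
  }
  c(accel = min(obs_minutes(accel$timestamp) / total_min, 1),
    gps = min(obs_minutes(gps$timestamp) /
                (total_min * gps_on_s / (gps_on_s + gps_off_s)), 1))
}

#' Weekly survey completion rates with late-completion reassignment
#'
#' A completion is credited to the latest survey already delivered at the
#' completion time: a participant completing Survey t after Survey t+1 was
#' sent counts as not having completed Survey t but as having completed
#' Survey t+1. The weeks histogram counts, per subject, survey weeks with at
#' least one credited completion (multiple completions in one week count
#' once).
#'
#' @param surveys survey table with one row per delivered survey (`subject`,
#'   `delivered`, `completed`).
#' @return List: `rates` (data.frame `survey`, `completion_rate`),
#'   `weeks_completed` (named integer per subject).
#' @export
survey_completion_rates <- function(surveys) {
  subjects <- unique(surveys$subject)
  deliveries <- sort(unique(surveys$delivered))
  K <- length(deliveries)
  credited <- matrix(FALSE, length(subjects), K,
                     dimnames = list(subjects, NULL))
  for (si in seq_along(subjects)) {
    s <- surveys[surveys$subject == subjects[si], , drop = FALSE]
    comp <- s$completed[!is.na(s$completed)]
    for (cts in comp) {
      k <- findInterval(cts, deliveries) # latest survey delivered by then
      if (k >= 1) credited[si, k] <- TRUE
    }
  }
  list(rates = data.frame(survey = seq_len(K),
                          completion_rate = colMeans(credited)),
       weeks_completed = rowSums(credited))
}

#' Communication-log summaries over a study window
#'
#' Counts per subject the outgoing calls and unique numbers dialed within
#' the window (weeks 2-7 of follow-up by default, i.e. study days 7-48),
#' then summarizes by group (healthy control versus any psychiatric
#' diagnosis): empirical CDFs, medians and IQRs.
#'
#' @param calls call-log table (`subject`, `timestamp`, `direction`,
#'   `hashed_number`).
#' @param demographics demographics table (defines the HC group via
#'   `diagnosis == hc_label`); only Android subjects contribute.
#' @param start_date study day 0.
#' @param window_days integer range of study days included (default weeks
#'   2-7).
#' @param hc_label diagnosis label of the healthy-control group.
#' @param tz timezone.
#' @return List: `per_subject` data.frame (`subject`, `group`,
#'   `outgoing_calls`, `unique_numbers`), `summary` data.frame of group
#'   medians/IQRs, `ecdf` named list of ECDF functions.
#' @export
comm_log_stats <- function(calls, demographics, start_date,
                           window_days = c(7, 48), hc_label = "HC",
                           tz = "UTC") {
  android <- demographics$subject[demographics$os == "Android"]
  t0 <- midnight_ms(as.Date(start_date) + window_days[1], tz)
  t1 <- midnight_ms(as.Date(start_date) + window_days[2] + 1, tz)
  w <- calls[calls$subject %in% android & calls$timestamp >= t0 &
               calls$timestamp < t1 & calls$direction == "outgoing", ,
             drop = FALSE]
  per <- data.frame(subject = android)
  per$outgoing_calls <- vapply(android, function(s)
    sum(w$subject == s), numeric(1))
  per$unique_numbers <- vapply(android, function(s)
    length(unique(w$hashed_number[w$subject == s])), numeric(1))
  grp <- demographics$diagnosis[match(android, demographics$subject)]
  per$group <- ifelse(grp == hc_label, "HC", "non-HC")
  summ <- do.call(rbind, lapply(split(per, per$group), function(g) {
    data.frame(group = g$group[1], n = nrow(g),
               median_calls = stats::median(g$outgoing_calls),
               iqr_calls_lo = stats::quantile(g$outgoing_calls, 0.25),
               iqr_calls_hi = stats::quantile(g$outgoing_calls, 0.75),
               median_numbers = stats::median(g$unique_numbers),
               iqr_numbers_lo = stats::quantile(g$unique_numbers, 0.25),
               iqr_numbers_hi = stats::quantile(g$unique_numbers, 0.75))
  }))
  rownames(summ) <- NULL
  ecdfs <- lapply(split(per$outgoing_calls, per$group), stats::ecdf)
  list(per_subject = per, summary = summ, ecdf = ecdfs)
}
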