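# End-to-end assembly: sensors -> daily tables -> analysis-ready table.

#' Extract daily passive features for every subject of a cohort
#'
#' Runs the GPS mobility chain ([mobility_daily()]) and the accelerometer
#' activity chain ([minute_activity()], [daily_activity()]) for each subject.
#'
#' @param cohort a `"cohort"` object (or any list with `demographics`, `gps`,
#'   `accel` in the same layout).
#' @param cfg a [mobility_config()]; its duty-cycle fields should match the
#'   data's schedule.
#' @param sd_threshold_g,min_samples accelerometer scoring parameters.
#' @return List of class `"passive_features"`: `daily_gps`, `daily_accel`
#'   (row-bound per-subject daily tables), and `minutes` (per-subject minute
#'   activity, kept for hourly curves).
#' @export
extract_features <- function(cohort, cfg = mobility_config(),
                             sd_threshold_g = 0.1, min_samples = 5) {
  demog <- cohort$demographics
  gps_rows <- list(); accel_rows <- list(); minutes <- list()
  for (i in seq_len(nrow(demog))) {
    sid <- demog$subject[i]
    tz <- demog$timezone[i]
    gps_rows[[sid]] <- mobility_daily(cohort$gps[[sid]], cfg, tz, sid)
    mins <- minute_activity(cohort$accel[[sid]], tz, sd_threshold_g,
                            min_samples)
    minutes[[sid]] <- mins
    da <- daily_activity(mins)
    if (nrow(da)) da <- cbind(subject = sid, da)
    accel_rows[[sid]] <- da
  }
  structure(list(
    daily_gps = do.call(rbind, c(gps_rows, make.row.names = FALSE)),
    daily_accel = do.call(rbind,
                          c(accel_rows[vapply(accel_rows, nrow, 1L) > 0],
                            make.row.names = FALSE)),
    minutes = minutes), class = "passive_features")
}

#' Build the analysis-ready visit table
#'
#' One row per follow-up visit (visit index 1-4): the MADRS outcome, the
#' baseline MADRS score, demographics, the closest preceding PHQ-8 total,
#' and the 32 weekly passive summary statistics from the 7 days preceding
#' the visit.
#'
#' @param cohort a `"cohort"` object.
#' @param features a `"passive_features"` object from [extract_features()].
#' @param cfg the [mobility_config()] used for extraction (for the
#'   expected-minute denominator).
#' @return data.frame with columns `subject`, `visit_index`, `date`,
#'   `madrs`, `baseline_madrs`, `age`, `sex`, `diagnosis`, `phq8`, and the
#'   32 passive features.
#' @export
analysis_table <- function(cohort, features, cfg = mobility_config()) {
  visits <- cohort$visits
  visits$date <- as.Date(visits$date)
  demog <- cohort$demographics
  visits <- attach_phq(visits, cohort$surveys,
                       tz = demog$timezone[1])
  baseline <- visits[visits$visit_index == 0, c("subject", "madrs")]
  fup <- visits[visits$visit_index >= 1, , drop = FALSE]
  exp_min <- gps_expected_minutes(cfg)
  rows <- vector("list", nrow(fup))
  for (i in seq_len(nrow(fup))) {
    sid <- fup$subject[i]
    wfv <- weekly_feature_vector(
      features$daily_gps[features$daily_gps$subject == sid, , drop = FALSE],
      features$daily_accel[features$daily_accel$subject == sid, ,
                           drop = FALSE],
      fup$date[i], gps_expected_min = exp_min)
    di <- match(sid, demog$subject)
    rows[[i]] <- cbind(
      data.frame(subject = sid, visit_index = fup$visit_index[i],
                 date = fup$date[i], madrs = fup$madrs[i],
                 baseline_madrs = baseline$madrs[match(sid, baseline$subject)],
                 age = demog$age[di], sex = demog$sex[di],
                 diagnosis = demog$diagnosis[di], phq8 = fup$phq8[i]),
      wfv)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Study-wide completeness report
#'
#' Per-subject accelerometer and GPS completeness over the full study days
#' (day after baseline to day before the last scheduled visit), per-survey
#' completion rates under the late-completion reassignment rule, and the
#' per-subject count of weeks with at least one completed PHQ-8.
#'
#' @param cohort a `"cohort"` object.
#' @return List: `sensors` (data.frame subject/accel/gps proportions),
#'   `surveys` (see [survey_completion_rates()]).
#' @export
completeness_report <- function(cohort) {
  cfg <- cohort$config
  demog <- cohort$demographics
  visits <- cohort$visits
  visits$date <- as.Date(visits$date)
  rows <- lapply(demog$subject, function(sid) {
    vd <- visits$date[visits$subject == sid]
    if (length(vd) < 2) return(NULL)
    pr <- sensor_completeness(cohort$gps[[sid]], cohort$accel[[sid]],
                              min(vd) + 1, max(vd) - 1,
                              cfg$gps_on_s, cfg$gps_off_s,
                              demog$timezone[demog$subject == sid])
    data.frame(subject = sid, accel = pr[["accel"]], gps = pr[["gps"]])
  })
  list(sensors = do.call(rbind, rows),
       surveys = survey_completion_rates(cohort$surveys))
}
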