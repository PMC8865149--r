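# Configuration for the synthetic cohort simulator.

#' Simulation configuration
#'
#' Builds and validates the configuration for [simulate_cohort()]. Defaults
#' emulate an 8-week transdiagnostic outpatient study: four diagnostic groups
#' (healthy controls, major depressive disorder, bipolar disorder,
#' schizophrenia/schizoaffective), biweekly clinician-rated MADRS visits,
#' weekly phone-based PHQ-8 surveys delivered on Saturdays, GPS duty-cycled
#' 2 min on / 10 min off and accelerometer 10 s on / 10 s off, with
#' phone-outage block missingness shared across sensors.
#'
#' Group baseline MADRS anchors default to the observed group means (SDs):
#' HC 0.7 (1.2), MDD 20.0 (12.7), BP 9.7 (10.6), SCZ 6.2 (5.4). Because MADRS
#' is floor-censored at 0, the simulator solves for latent normal parameters
#' whose censored moments match these observed values (see
#' [censored_normal_params()]); a plain normal would bias the healthy-control
#' mean upward.
#'
#' Severity couples to behaviour through log-linear coefficients: negative
#' `beta_trips` / `beta_away` / `beta_activity` make more-depressed days have
#' fewer excursions, shorter time away from home, and less accelerometer
#' activity.
#'
#' @param n_per_group named integer vector of subjects per diagnostic group.
#' @param study_weeks length of follow-up in weeks.
#' @param visit_interval_days days between clinic visits.
#' @param start_date local calendar date of the baseline visit (a Monday by
#'   default so that weekday/weekend structure is balanced).
#' @param tz IANA timezone applied to all subjects.
#' @param gps_on_s,gps_off_s GPS duty cycle in seconds.
#' @param accel_on_s,accel_off_s accelerometer duty cycle in seconds.
#' @param gps_sample_s spacing of GPS fixes within an on-cycle, seconds.
#' @param accel_sample_s spacing of accelerometer samples within an on-cycle,
#'   seconds.
#' @param outage_prob daily probability that a phone outage starts.
#' @param outage_mean_h mean outage duration, hours (exponential).
#' @param baseline_means,baseline_sds observed-scale group baseline MADRS
#'   moments, in group order.
#' @param ar_phi day-to-day AR(1) autocorrelation of latent severity.
#' @param sigma_within_max cap on the within-subject stationary SD of the
#'   latent severity walk (MADRS points).
#' @param rater_sd SD of MADRS rater noise (points).
#' @param beta_trips,beta_away,beta_activity severity coupling coefficients
#'   (per MADRS point, log scale) for excursion rate, away-pause duration and
#'   activity level.
#' @param trip_rate mean number of excursions per day at severity 0.
#' @param n_anchor_range integer range of away anchors per subject.
#' @param anchor_dist_range range of anchor distances from home, meters.
#' @param speed_mps typical travel speed, m/s (log-normal median).
#' @param away_pause_s typical pause duration at an away anchor, seconds
#'   (log-normal median).
#' @param gps_noise_m SD of planar GPS position noise, meters.
#' @param activity_profile 24 hourly baseline probabilities that a minute is
#'   active (severity 0).
#' @param accel_rest_sd,accel_active_sd per-axis accelerometer noise SD (g)
#'   for stationary and active minutes.
#' @param phq_slope,phq_intercept,phq_sd linear map from latent severity to
#'   PHQ-8 total plus noise.
#' @param survey_p_first,survey_p_last completion probability of the first and
#'   last weekly survey (linear in between).
#' @param survey_late_prob probability a completed survey is completed late.
#' @param dropout_frac fraction of subjects truncated after the first
#'   follow-up visit.
#' @param call_rate_hc,call_rate_other mean calls per day for healthy controls
#'   and for the clinical groups.
#' @param contact_pool_size number of distinct counterparts per subject.
#' @param seed root seed for all simulation substreams.
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_per_group = c(HC = 11, MDD = 10, BP = 10, SCZ = 10),
                       study_weeks = 8,
                       visit_interval_days = 14,
                       start_date = as.Date("2023-01-02"),
                       tz = "UTC",
                       gps_on_s = 120, gps_off_s = 600,
                       accel_on_s = 10, accel_off_s = 10,
                       gps_sample_s = 10,
                       accel_sample_s = 5,
                       outage_prob = 0.15,
                       outage_mean_h = 6,
                       baseline_means = c(HC = 0.7, MDD = 20.0, BP = 9.7, SCZ = 6.2),
                       baseline_sds = c(HC = 1.2, MDD = 12.7, BP = 10.6, SCZ = 5.4),
                       ar_phi = 0.95,
                       sigma_within_max = 2,
                       rater_sd = 1,
                       beta_trips = -0.02,
                       beta_away = -0.012,
                       beta_activity = -0.015,
                       trip_rate = 4,
                       n_anchor_range = c(2L, 4L),
                       anchor_dist_range = c(500, 5000),
                       speed_mps = 8,
                       away_pause_s = 5400,
                       gps_noise_m = 3,
                       activity_profile = default_activity_profile(),
                       accel_rest_sd = 0.02,
                       accel_active_sd = 0.35,
                       phq_slope = 0.4, phq_intercept = 0, phq_sd = 2,
                       survey_p_first = 0.95, survey_p_last = 0.80,
                       survey_late_prob = 0.1,
                       dropout_frac = 3 / 41,
                       call_rate_hc = 1.3,
                       call_rate_other = 2.9,
                       contact_pool_size = 30,
                       seed = 1L) {
  cfg <- as.list(environment())
  cfg$start_date <- as.Date(start_date)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  chk <- function(ok, field, msg) {
    if (!all(ok)) stop(sprintf("invalid sim_config field '%s': %s", field, msg),
                       call. = FALSE)
  }
  chk(length(cfg$n_per_group) >= 1 && all(cfg$n_per_group >= 0) &&
        !is.null(names(cfg$n_per_group)),
      "n_per_group", "must be a named vector of nonnegative group sizes")
  for (f in c("study_weeks", "visit_interval_days", "gps_on_s", "accel_on_s",
              "gps_sample_s", "accel_sample_s", "outage_mean_h", "trip_rate",
              "speed_mps", "away_pause_s"))
    chk(cfg[[f]] > 0, f, "must be positive")
  for (f in c("gps_off_s", "accel_off_s", "gps_noise_m", "rater_sd", "phq_sd"))
    chk(cfg[[f]] >= 0, f, "must be nonnegative")
  for (f in c("outage_prob", "survey_p_first", "survey_p_last",
              "survey_late_prob", "dropout_frac"))
    chk(cfg[[f]] >= 0 && cfg[[f]] <= 1, f, "must be a probability in [0,1]")
  chk(abs(cfg$ar_phi) < 1, "ar_phi", "must lie in (-1, 1)")
  chk(length(cfg$activity_profile) == 24 &&
        all(cfg$activity_profile >= 0 & cfg$activity_profile <= 1),
      "activity_profile", "must be 24 probabilities")
  chk(length(cfg$baseline_means) == length(cfg$n_per_group) &&
        length(cfg$baseline_sds) == length(cfg$n_per_group),
      "baseline_means", "must match the number of groups")
  chk(all(cfg$baseline_sds > 0), "baseline_sds", "must be positive")
  chk(cfg$n_anchor_range[1] >= 0 && diff(cfg$n_anchor_range) >= 0,
      "n_anchor_range", "must be a nondecreasing nonnegative range")
  cfg
}

#' Default diurnal activity profile
#'
#' Hourly baseline probabilities that a minute is "active" for a subject at
#' severity 0: near-zero overnight, rising from 7 a.m., peaking between
#' 9 a.m. and 1 p.m., declining over the evening.
#'
#' @return Numeric vector of 24 probabilities.
#' @export
default_activity_profile <- function() {
  c(rep(0.02, 6),            # 00-05
    0.05, 0.15,              # 06, 07
    0.25,                    # 08
    rep(0.35, 5),            # 09-13
    rep(0.25, 4),            # 14-17
    0.20, 0.15, 0.10,        # 18-20
    0.05, 0.03, 0.02)        # 21-23
}

#' Latent normal parameters matching floor-censored moments
#'
#' Finds `(mu, sigma)` of a normal random variable `X` such that
#' `Y = max(X, 0)` has the requested mean and SD. Used to anchor group
#' baseline severity so simulated cohorts reproduce observed (censored-scale)
#' group MADRS moments at any sample size.
#'
#' @param mean,sd target moments of the censored variable.
#' @return Named vector `c(mu, sigma)`.
#' @export
censored_normal_params <- function(mean, sd) {
  mean <- unname(mean); sd <- unname(sd)
  stopifnot(mean >= 0, sd > 0)
  cens_moments <- function(mu, s) {
    a <- mu / s
    m1 <- mu * pnorm(a) + s * dnorm(a)
    m2 <- (mu^2 + s^2) * pnorm(a) + mu * s * dnorm(a)
    c(m1, sqrt(pmax(m2 - m1^2, 1e-12)))
  }
  obj <- function(p) {
    m <- cens_moments(p[1], exp(p[2]))
    (m[1] - mean)^2 + (m[2] - sd)^2
  }
  fit <- optim(c(mean, log(sd)), obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-14))
  c(mu = fit$par[1], sigma = exp(fit$par[2]))
}

# Per-group latent severity parameters: subject-anchor SD (between) and
# AR(1) stationary SD (within), after removing rater noise from the observed
# baseline SD.
group_severity_params <- function(cfg) {
  g <- names(cfg$n_per_group)
  out <- lapply(seq_along(g), function(i) {
    cp <- censored_normal_params(cfg$baseline_means[i], cfg$baseline_sds[i])
    lat_var <- max(cp[["sigma"]]^2 - cfg$rater_sd^2, 0.04)
    s_w <- min(cfg$sigma_within_max, 0.5 * sqrt(lat_var))
    s_b <- sqrt(max(lat_var - s_w^2, 1e-4))
    list(group = g[i], mu = cp[["mu"]], sigma_between = s_b, sigma_within = s_w)
  })
  names(out) <- g
  out
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  groups: %s (n = %s)\n",
              paste(names(x$n_per_group), collapse = "/"),
              paste(x$n_per_group, collapse = "/")))
  cat(sprintf("  study: %d weeks from %s, visits every %d days\n",
              x$study_weeks, format(x$start_date), x$visit_interval_days))
  cat(sprintf("  GPS duty cycle %ds on / %ds off; accel %ds on / %ds off\n",
              x$gps_on_s, x$gps_off_s, x$accel_on_s, x$accel_off_s))
  cat(sprintf("  outages: p = %.2f/day, mean %.1f h; seed %d\n",
              x$outage_prob, x$outage_mean_h, x$seed))
  invisible(x)
}
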