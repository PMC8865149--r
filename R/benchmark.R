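# Study-level validation experiments: imputation benchmarking and
# mixed-model parameter-recovery data.

default_traj_params <- function() {
  list(trip_rate = 4, beta_trips = -0.02, beta_away = -0.012,
       speed_mps = 8, away_pause_s = 5400)
}

#' Benchmark resampling against linear gap imputation
#'
#' Simulates a subject's ground-truth days, observes them through the GPS
#' duty cycle with position noise, removes an additional contiguous block of
#' each day (fraction drawn uniformly from `removal`, emulating outages),
#' reconstructs the trace with each imputation method, and measures the mean
#' absolute error of the daily mobility features against ground truth. Each
#' feature's error is normalized by the mean magnitude of its true values
#' across days, then averaged over features and days.
#'
#' @param n_days number of simulated days.
#' @param removal range of the per-day removed fraction of the day.
#' @param seed seed for the whole experiment.
#' @param severity latent severity of the simulated subject.
#' @param gps_noise_m GPS position noise SD, meters.
#' @param cfg a [mobility_config()] for the feature chain.
#' @return List: `nmae` named vector (resampling, linear), `ratio`
#'   (linear / resampling, > 1 means resampling wins), `per_feature`
#'   data.frame of per-feature normalized MAEs.
#' @export
imputation_benchmark <- function(n_days = 100, removal = c(0.3, 0.7),
                                 seed = 1, severity = 10, gps_noise_m = 3,
                                 cfg = mobility_config(seed = seed)) {
  par <- default_traj_params()
  anchors <- with_seed(derive_seed(seed, "bench-anchors"), {
    r <- runif(3, 800, 4000); th <- runif(3, 0, 2 * pi)
    cbind(r * cos(th), r * sin(th))
  })
  dates <- as.Date("2023-01-02") + seq_len(n_days) - 1
  grid <- local({
    t <- seq(0, SEC_PER_DAY - 1, by = 10)
    t[t %% (cfg$gps_on_s + cfg$gps_off_s) < cfg$gps_on_s]
  })

  truth_days <- vector("list", n_days)
  obs <- vector("list", n_days)
  for (d in seq_len(n_days)) {
    segs <- simulate_day_trajectory(c(0, 0), anchors, severity, par,
                                    derive_seed(seed, "bench-day", d))
    day0 <- as.numeric(dates[d]) * SEC_PER_DAY
    abs_segs <- segs
    abs_segs$t0 <- segs$t0 + day0
    abs_segs$t1 <- segs$t1 + day0
    abs_segs$provenance <- "observed"
    truth_days[[d]] <- abs_segs
    keep <- with_seed(derive_seed(seed, "bench-rm", d), {
      f <- runif(1, removal[1], removal[2])
      start <- runif(1, 0, SEC_PER_DAY * (1 - f))
      !(grid >= start & grid < start + f * SEC_PER_DAY)
    })
    t_obs <- grid[keep]
    pos <- sample_path(segs, t_obs)
    noise <- with_seed(derive_seed(seed, "bench-noise", d),
                       matrix(rnorm(2 * length(t_obs), 0, gps_noise_m),
                              ncol = 2))
    obs[[d]] <- data.frame(timestamp = (day0 + t_obs) * 1000,
                           x = pos[, 1] + noise[, 1],
                           y = pos[, 2] + noise[, 2])
  }

  truth_tab <- features_from_segments(do.call(rbind, truth_days), dates, cfg)
  err <- list()
  for (method in c("resampling", "linear")) {
    mcfg <- cfg
    mcfg$impute_method <- method
    segs <- segment_flights_pauses(do.call(rbind, obs), mcfg)
    segs <- impute_gaps(segs, mcfg)
    tab <- features_from_segments(segs, dates, mcfg)
    err[[method]] <- abs(as.matrix(tab[, GPS_FEATURES]) -
                           as.matrix(truth_tab[, GPS_FEATURES]))
  }
  scale <- colMeans(abs(as.matrix(truth_tab[, GPS_FEATURES])), na.rm = TRUE)
  usable <- scale > 1e-9
  nmae <- vapply(err, function(e)
    mean(sweep(e[, usable, drop = FALSE], 2, scale[usable], "/"),
         na.rm = TRUE), numeric(1))
  per_feature <- data.frame(
    feature = GPS_FEATURES[usable],
    resampling = colMeans(err$resampling[, usable, drop = FALSE],
                          na.rm = TRUE) / scale[usable],
    linear = colMeans(err$linear[, usable, drop = FALSE],
                      na.rm = TRUE) / scale[usable])
  list(nmae = nmae, ratio = unname(nmae["linear"] / nmae["resampling"]),
       per_feature = per_feature)
}

# Daily feature table straight from a complete multi-day segment sequence
# (no raw stream: home/locations/routines computed from the segments).
features_from_segments <- function(segments, dates, cfg, tz = "UTC") {
  segments <- split_segments_by_day(segments, tz)
  home <- detect_home(segments, cfg, tz)
  p_all <- pause_table(segments)
  locations <- if (nrow(p_all) > 0) significant_locations(p_all, cfg) else NULL
  rows <- vector("list", length(dates))
  bins <- vector("list", length(dates))
  for (i in seq_along(dates)) {
    d0 <- midnight_ms(dates[i], tz) / 1000
    ds <- segments[segments$t0 >= d0 - 1e-6 &
                     segments$t1 <= d0 + SEC_PER_DAY + 1e-6, , drop = FALSE]
    rows[[i]] <- daily_mobility_features(ds, home, locations, cfg)
    bins[[i]] <- routine_bins(ds, d0, cfg)
  }
  out <- do.call(rbind, rows)
  rout <- routine_features(bins, day_type(dates), cfg)
  out$circadian_routine <- rout$circadian_routine
  out$weekend_weekday_routine <- rout$weekend_weekday_routine
  cbind(data.frame(date = dates, day_type = day_type(dates)), out)
}

#' Simulate visit rows from a known linear mixed model
#'
#' Generates an analysis-table-shaped dataset directly from the random
#' intercept model `madrs = beta0 + beta_phq * phq8 + beta_base *
#' baseline_madrs + b_i + e`, with `b_i ~ N(0, sigma_b^2)` and
#' `e ~ N(0, sigma_e^2)`. Used for parameter-recovery and cross-validation
#' calibration experiments where the generating coefficients must be known
#' exactly.
#'
#' @param n_subjects,n_visits design size.
#' @param beta `c(intercept, phq8, baseline_madrs)`.
#' @param sigma_b,sigma_e random-intercept and residual SDs.
#' @param seed integer seed.
#' @return data.frame with `subject`, `visit_index`, `phq8`,
#'   `baseline_madrs`, `madrs`.
#' @export
simulate_visit_rows <- function(n_subjects = 40, n_visits = 4,
                                beta = c(2, 1.5, 0.6), sigma_b = 3,
                                sigma_e = 4, seed = 1) {
  with_seed(seed, {
    subj <- sprintf("T%02d", seq_len(n_subjects))
    b <- rnorm(n_subjects, 0, sigma_b)
    do.call(rbind, lapply(seq_len(n_subjects), function(i) {
      phq <- runif(n_visits, 0, 24)
      base <- runif(1, 0, 40)
      data.frame(subject = subj[i], visit_index = seq_len(n_visits),
                 phq8 = phq, baseline_madrs = base,
                 madrs = beta[1] + beta[2] * phq + beta[3] * base + b[i] +
                   rnorm(n_visits, 0, sigma_e))
    }))
  })
}
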