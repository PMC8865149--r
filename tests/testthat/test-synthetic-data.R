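# The cohort simulator: schedules, determinism, severity anchoring,
# duty-cycling, outages, and assessment generation.

test_that("visit schedule follows the study design", {
  cfg <- sim_config(n_per_group = c(HC = 1, MDD = 1, BP = 1, SCZ = 1),
                    study_weeks = 8, dropout_frac = 0, outage_prob = 0,
                    seed = 3)
  coh <- simulate_cohort(cfg)
  expect_equal(nrow(coh$demographics), 4)
  for (sid in coh$demographics$subject) {
    v <- coh$visits[coh$visits$subject == sid, ]
    expect_equal(v$visit_index, 0:4)
    expect_equal(as.numeric(diff(as.Date(v$date))), rep(14, 4))
  }
})

test_that("identical config gives identical cohorts", {
  cfg <- sim_config(n_per_group = c(MDD = 2), baseline_means = c(MDD = 20),
                    baseline_sds = c(MDD = 12.7), study_weeks = 1, seed = 11)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$visits, b$visits)
  expect_identical(a$surveys, b$surveys)
  expect_identical(a$truth, b$truth)
  expect_identical(a$gps, b$gps)
  expect_identical(a$accel, b$accel)
})

test_that("dropout truncates subjects after the first follow-up", {
  cfg <- sim_config(n_per_group = c(MDD = 10), baseline_means = c(MDD = 20),
                    baseline_sds = c(MDD = 12.7), study_weeks = 4,
                    dropout_frac = 0.2, outage_prob = 0, seed = 5)
  coh <- simulate_cohort(cfg)
  n_visits <- table(coh$visits$subject)
  expect_equal(sum(n_visits == 2), 2) # 20% of 10 kept only baseline + FU1
  dropped <- names(n_visits)[n_visits == 2]
  expect_true(all(coh$truth$date[coh$truth$subject %in% dropped] <=
                    cfg$start_date + 14))
})

test_that("simulated group baseline MADRS matches the cohort anchors", {
  # group-mean baseline within 2 Monte-Carlo SEs of the target means
  coh <- simulate_cohort(sim_config(dropout_frac = 0, seed = 19))
  base <- coh$visits[coh$visits$visit_index == 0, ]
  base$group <- coh$demographics$diagnosis[match(base$subject,
                                                 coh$demographics$subject)]
  targets <- c(HC = 0.7, MDD = 20.0, BP = 9.7, SCZ = 6.2)
  for (g in names(targets)) {
    x <- base$madrs[base$group == g]
    se <- max(sd(x) / sqrt(length(x)), 0.3)
    expect_lt(abs(mean(x) - targets[[g]]), 2 * se + 0.4)
  }
})

test_that("severity couples to movement with the configured sign", {
  par <- list(trip_rate = 4, beta_trips = 0, beta_away = 0, speed_mps = 8,
              away_pause_s = 5400)
  anchors <- cbind(c(1000, -2000), c(500, 1500))
  # zero coupling: identical path regardless of severity (same substream)
  s1 <- simulate_day_trajectory(c(0, 0), anchors, 5, par, seed = 21)
  s2 <- simulate_day_trajectory(c(0, 0), anchors, 40, par, seed = 21)
  expect_identical(s1, s2)

  # negative distance coupling: less travel when more depressed
  par$beta_trips <- -0.02; par$beta_away <- -0.012
  d5 <- d40 <- numeric(200)
  for (r in 1:200) {
    d5[r] <- truth_from_segments(
      simulate_day_trajectory(c(0, 0), anchors, 5, par, seed = 1000 + r),
      c(0, 0))$distance_m
    d40[r] <- truth_from_segments(
      simulate_day_trajectory(c(0, 0), anchors, 40, par, seed = 1000 + r),
      c(0, 0))$distance_m
  }
  expect_lt(mean(d40), mean(d5))
})

test_that("severity-distance correlation is negative across the cohort", {
  coh <- small_cohort()
  expect_gte(nrow(coh$truth), 100)
  expect_lt(cor(coh$truth$severity, coh$truth$distance_m), 0)
  expect_gt(cor(coh$truth$severity, coh$truth$home_time_min), 0)
})

test_that("zero away-anchors keeps the path at home all day", {
  par <- list(trip_rate = 4, beta_trips = 0, beta_away = 0, speed_mps = 8,
              away_pause_s = 5400)
  segs <- simulate_day_trajectory(c(0, 0), matrix(numeric(0), ncol = 2), 10,
                                  par, seed = 2)
  expect_true(all(segs$kind == "pause"))
  expect_true(all(segs$x0 == 0 & segs$y0 == 0))
  expect_equal(truth_from_segments(segs, c(0, 0))$home_time_min, 1440)
})

test_that("duty cycle retains exactly the on-cycle samples", {
  day <- uniform_gps_day()
  kept <- apply_duty_cycle(day, 120, 600)
  expect_equal(nrow(kept) / nrow(day), 1 / 6)
  sec <- (kept$timestamp / 1000) %% 86400
  expect_true(all(sec %% 720 < 120))

  expect_identical(apply_duty_cycle(day, 120, 0), day)

  one_min <- day[1:60, ]
  kept10 <- apply_duty_cycle(one_min, 10, 10)
  expect_equal(nrow(kept10), 30)

  shuffled <- day[sample(nrow(day)), ]
  expect_error(apply_duty_cycle(shuffled, 120, 600), "sorted")
})

test_that("outage windows remove samples and respect their probability", {
  day <- uniform_gps_day()
  expect_identical(apply_outages(day, draw_outages(as.Date("2023-01-02"), 0,
                                                   6, seed = 1)), day)
  full <- data.frame(start_ms = min(day$timestamp),
                     end_ms = max(day$timestamp) + 1000)
  expect_equal(nrow(apply_outages(day, full)), 0)

  dates <- as.Date("2023-01-01") + 0:999
  out <- draw_outages(dates, 0.3, 6, seed = 9)
  # each sampled window corresponds to one day's draw
  p_hat <- nrow(out) / 1000
  ci <- qbinom(c(0.005, 0.995), 1000, 0.3) / 1000
  expect_gte(p_hat, ci[1])
  expect_lte(p_hat, ci[2])
})

test_that("accelerometer days reflect the planted activity structure", {
  cfg <- sim_config(n_per_group = c(HC = 1), baseline_means = c(HC = 0.7),
                    baseline_sds = c(HC = 1.2), accel_sample_s = 1, seed = 1)

  rest <- cfg; rest$activity_profile <- rep(0, 24)
  d <- simulate_accel_day(as.Date("2023-01-02"), 0, rest, seed = 4)
  mins <- minute_activity(d$samples)
  expect_true(all(!mins$active))

  busy <- cfg; busy$activity_profile <- rep(1, 24); busy$beta_activity <- 0
  d <- simulate_accel_day(as.Date("2023-01-02"), 0, busy, seed = 4)
  curve <- hourly_activity_curve(minute_activity(d$samples))
  expect_equal(curve$activity, rep(1, 24))

  peaked <- cfg
  peaked$activity_profile <- c(rep(0.02, 9), rep(0.9, 5), rep(0.02, 10))
  d <- simulate_accel_day(as.Date("2023-01-02"), 0, peaked, seed = 4)
  curve <- hourly_activity_curve(minute_activity(d$samples))
  expect_true((which.max(curve$activity) - 1) %in% 9:13)
})

test_that("assessments map severity through the stated score models", {
  cfg <- sim_config(n_per_group = c(MDD = 1), baseline_means = c(MDD = 20),
                    baseline_sds = c(MDD = 12.7), study_weeks = 2,
                    phq_sd = 0, rater_sd = 0, survey_p_first = 1,
                    survey_p_last = 1, survey_late_prob = 0, seed = 6)
  latent <- data.frame(subject = "S001", day = 0:14, severity = 30,
                       last_day = 14)
  a <- simulate_assessments(latent, cfg, seed = 8)
  expect_equal(a$surveys$total, rep(round(0.4 * 30), nrow(a$surveys)))
  expect_equal(rowSums(a$surveys[, paste0("q", 1:8)]), a$surveys$total,
               ignore_attr = TRUE)
  expect_true(all(a$surveys[, paste0("q", 1:8)] >= 0 &
                    a$surveys[, paste0("q", 1:8)] <= 3))

  # clipping: an out-of-scale severity can never produce MADRS > 60
  latent$severity <- 70
  a <- simulate_assessments(latent, cfg, seed = 8)
  expect_true(all(a$visits$madrs == 60))
})

test_that("first-survey completion rate matches its configured probability", {
  cfg <- sim_config(n_per_group = c(HC = 60), baseline_means = c(HC = 0.7),
                    baseline_sds = c(HC = 1.2), study_weeks = 2,
                    survey_p_first = 0.95, survey_p_last = 0.95,
                    survey_late_prob = 0, dropout_frac = 0, seed = 13)
  latent <- do.call(rbind, lapply(sprintf("S%03d", 1:60), function(s)
    data.frame(subject = s, day = 0:14, severity = 1, last_day = 14)))
  a <- simulate_assessments(latent, cfg, seed = 14)
  first <- a$surveys[a$surveys$delivered == min(a$surveys$delivered), ]
  rate <- mean(!is.na(first$completed))
  expect_lt(abs(rate - 0.95), 2 * sqrt(0.95 * 0.05 / 60) + 0.02)
})

test_that("simulator ground truth agrees with features on the dense path", {
  par <- list(trip_rate = 4, beta_trips = -0.02, beta_away = -0.012,
              speed_mps = 8, away_pause_s = 5400)
  anchors <- cbind(c(1500, -2500, 800), c(-700, 1200, 2600))
  cfgm <- mobility_config(seed = 3)
  for (seed in c(31, 32, 33)) {
    segs <- simulate_day_trajectory(c(0, 0), anchors, 12, par, seed = seed)
    truth <- truth_from_segments(segs, c(0, 0))
    t_s <- seq(0, 86399)
    pos <- sample_path(segs, t_s)
    stream <- planar_stream(t_s, pos[, 1], pos[, 2])
    day_segs <- segment_flights_pauses(stream, cfgm)
    locs <- significant_locations(pause_table(day_segs), cfgm)
    f <- daily_mobility_features(day_segs, c(0, 0), locs, cfgm)
    expect_lt(abs(f$distance_m - truth$distance_m) /
                max(truth$distance_m, 1), 0.01)
    expect_lt(abs(f$home_time_min - truth$home_time_min) /
                truth$home_time_min, 0.01)
    expect_lt(abs(f$radius_gyration_m - truth$radius_gyration_m) /
                max(truth$radius_gyration_m, 1), 0.01)
    expect_lt(abs(f$max_diameter_m - truth$max_diameter_m) /
                max(truth$max_diameter_m, 1), 0.01)
  }
})

test_that("invalid configurations are rejected with the field name", {
  expect_error(sim_config(outage_prob = 1.5), "outage_prob")
  expect_error(sim_config(gps_on_s = 0), "gps_on_s")
  expect_error(sim_config(n_per_group = c(-1)), "n_per_group")
  expect_error(sim_config(ar_phi = 1.2), "ar_phi")
})
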