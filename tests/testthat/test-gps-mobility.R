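# Projection, flight/pause segmentation, home and significant-location
# detection, and the daily mobility features.

test_that("planar projection matches spherical geometry and inverts exactly", {
  pts <- data.frame(timestamp = c(0, 1000),
                    latitude = c(42.360, 42.361), longitude = c(-71.06, -71.06),
                    accuracy = 5)
  pl <- project_to_plane(pts)
  d <- sqrt(diff(pl$x)^2 + diff(pl$y)^2)
  expect_lt(abs(d - 111.2), 0.5)
  # independent spherical oracle
  d_hav <- geosphere::distHaversine(c(-71.06, 42.360), c(-71.06, 42.361))
  expect_lt(abs(d - d_hav), 0.5)

  same <- data.frame(timestamp = c(0, 1000), latitude = 42.36,
                     longitude = -71.06, accuracy = 5)
  pls <- project_to_plane(same)
  expect_equal(sqrt(diff(pls$x)^2 + diff(pls$y)^2), 0)

  back <- plane_to_geo(pl, attr(pl, "origin"))
  expect_equal(back$latitude, pts$latitude, tolerance = 1e-9)
  expect_equal(back$longitude, pts$longitude, tolerance = 1e-9)

  expect_error(project_to_plane(pts[0, ]), "empty")
})

test_that("pauses collapse and flights connect retained points", {
  cfg <- mobility_config(pause_radius_m = 10, min_pause_s = 30)
  # 10 min of points jittered within 5 m -> one pause
  t <- seq(0, 600, by = 10)
  jit <- withr::with_seed(1, cbind(runif(length(t), -3, 3),
                                   runif(length(t), -3, 3)))
  segs <- segment_flights_pauses(planar_stream(t, jit[, 1], jit[, 2]), cfg)
  expect_equal(sum(segs$kind == "pause"), 1)
  expect_equal(segs$t1[1] - segs$t0[1], 600)
  expect_lt(sqrt(segs$x0[1]^2 + segs$y0[1]^2), 5)

  # two consecutive fixes 100 m apart -> a single flight of length 100 m
  segs <- segment_flights_pauses(planar_stream(c(0, 10), c(0, 100), c(0, 0)),
                                 cfg)
  expect_equal(sum(segs$kind == "flight"), 1)
  fl <- segs[segs$kind == "flight", ]
  expect_equal(sqrt((fl$x1 - fl$x0)^2 + (fl$y1 - fl$y0)^2), 100)
})

test_that("a constructed day of planted pauses and flights is recovered", {
  cfg <- mobility_config()
  anchors <- rbind(c(0, 0), c(800, 0), c(800, 600))
  # pause 2 h at each anchor, 10-min flights between, sampled at 10 s
  t <- c(); x <- c(); y <- c()
  t0 <- 0
  for (i in 1:3) {
    tp <- seq(t0, t0 + 7200, by = 10)
    t <- c(t, tp); x <- c(x, rep(anchors[i, 1], length(tp)))
    y <- c(y, rep(anchors[i, 2], length(tp)))
    t0 <- t0 + 7200
    if (i < 3) {
      tf <- seq(t0 + 10, t0 + 600 - 10, by = 10)
      u <- (tf - t0) / 600
      t <- c(t, tf)
      x <- c(x, anchors[i, 1] + u * (anchors[i + 1, 1] - anchors[i, 1]))
      y <- c(y, anchors[i, 2] + u * (anchors[i + 1, 2] - anchors[i, 2]))
      t0 <- t0 + 600
    }
  }
  segs <- segment_flights_pauses(planar_stream(t, x, y), cfg)
  pauses <- segs[segs$kind == "pause" & segs$t1 - segs$t0 > 3600, ]
  expect_equal(nrow(pauses), 3)
  for (i in 1:3) {
    d <- sqrt((pauses$x0 - anchors[i, 1])^2 + (pauses$y0 - anchors[i, 2])^2)
    expect_lt(min(d), cfg$pause_radius_m)
  }
})

test_that("gap imputation is endpoint-exact and degenerate-safe", {
  cfg <- mobility_config(seed = 5)
  # observed day with a 2 h gap in the middle
  t <- c(seq(0, 10000, by = 10), seq(17200, 30000, by = 10))
  x <- ifelse(t < 15000, 0, 500)
  segs <- segment_flights_pauses(planar_stream(t, x, rep(0, length(t))), cfg)
  expect_true(any(segs$kind == "gap"))
  done <- impute_gaps(segs, cfg)
  expect_false(any(done$kind == "gap"))
  imp <- done[done$provenance == "imputed", ]
  expect_gt(nrow(imp), 0)
  # endpoints exact, sequence contiguous
  expect_equal(imp$x0[1], 0); expect_equal(imp$x1[nrow(imp)], 500)
  expect_true(all(abs(done$t0[-1] - done$t1[-nrow(done)]) < 1e-6))
  # positions chain within the imputed block
  if (nrow(imp) > 1) {
    expect_equal(imp$x0[-1], imp$x1[-nrow(imp)])
    expect_equal(imp$y0[-1], imp$y1[-nrow(imp)])
  }

  # gap bounded by the same position with only pause donors -> a pause there
  t2 <- c(seq(0, 5000, by = 10), seq(50000, 55000, by = 10))
  segs2 <- segment_flights_pauses(planar_stream(t2, rep(0, length(t2)),
                                                rep(0, length(t2))), cfg)
  done2 <- impute_gaps(segs2, cfg)
  filled <- done2[done2$provenance == "imputed", ]
  expect_true(all(filled$kind == "pause"))
  expect_true(all(filled$x0 == 0 & filled$y0 == 0))

  # no donors at all -> linear with a warning
  lone <- segs2[segs2$kind == "gap", ]
  expect_warning(lin <- impute_gaps(lone, cfg), "linear")
  expect_equal(lin$kind, "flight")
})

test_that("home detection finds the dominant nighttime location", {
  cfg <- mobility_config()
  # stationary subject
  t <- seq(0, 86399, by = 60)
  segs <- segment_flights_pauses(planar_stream(t, rep(5, length(t)),
                                               rep(-3, length(t))), cfg)
  home <- detect_home(segs, cfg)
  expect_lt(sqrt((home[["x"]] - 5)^2 + (home[["y"]] + 3)^2), 1)

  # 9 nights at A, 1 night at B -> home = A
  A <- c(0, 0); B <- c(5000, 0)
  days <- lapply(0:9, function(d) {
    at <- if (d < 9) A else B
    tt <- d * 86400 + seq(22 * 3600, 23 * 3600, by = 60)
    planar_stream(tt, rep(at[1], length(tt)), rep(at[2], length(tt)))
  })
  segs <- segment_flights_pauses(do.call(rbind, days), cfg)
  home <- detect_home(segs, cfg)
  expect_lt(sqrt(sum((c(home[["x"]], home[["y"]]) - A)^2)), 50)

  # daytime-only data -> no home
  td <- seq(10 * 3600, 12 * 3600, by = 60)
  segs <- segment_flights_pauses(planar_stream(td, rep(0, length(td)),
                                               rep(0, length(td))), cfg)
  expect_null(detect_home(segs, cfg))
})

test_that("significant-location clustering grows k to cover the pauses", {
  cfg <- mobility_config(sig_radius_m = 200, k_max = 10, seed = 2)
  one <- data.frame(x = rnorm(20, 0, 20), y = rnorm(20, 0, 20),
                    w = rep(600, 20))
  sl <- significant_locations(one, cfg)
  expect_equal(nrow(sl$centroids), 1)

  two <- data.frame(x = c(rnorm(10, 0, 30), rnorm(10, 2000, 30)),
                    y = rnorm(20, 0, 30), w = rep(600, 20))
  sl <- significant_locations(two, cfg)
  expect_equal(nrow(sl$centroids), 2)
  d_a <- min(sqrt(rowSums(sweep(sl$centroids, 2, c(0, 0))^2)))
  d_b <- min(sqrt((sl$centroids[, 1] - 2000)^2 + sl$centroids[, 2]^2))
  expect_lt(d_a, 100); expect_lt(d_b, 100)

  capped <- significant_locations(two, mobility_config(k_max = 1, seed = 2))
  expect_equal(nrow(capped$centroids), 1)
  expect_false(capped$within_radius)
})

test_that("daily features satisfy their closed forms", {
  cfg <- mobility_config()
  home <- c(0, 0)
  # stationary day at home
  still <- data.frame(kind = "pause", t0 = 0, t1 = 86400, x0 = 0, y0 = 0,
                      x1 = 0, y1 = 0, provenance = "observed")
  locs <- significant_locations(pause_table(still), cfg)
  f <- daily_mobility_features(still, home, locs, cfg)
  expect_equal(f$distance_m, 0)
  expect_equal(f$radius_gyration_m, 0)
  expect_equal(f$max_diameter_m, 0)
  expect_equal(f$home_time_min, 1440)
  expect_equal(f$location_entropy, 0)
  expect_equal(f$pause_prob, 1.0)

  # half the day at home, half at 1000 m, instantaneous connecting flights
  half <- data.frame(
    kind = c("pause", "flight", "pause", "flight"),
    t0 = c(0, 43200, 43200, 86400), t1 = c(43200, 43200, 86400, 86400),
    x0 = c(0, 0, 1000, 1000), y0 = 0, x1 = c(0, 1000, 1000, 0), y1 = 0,
    provenance = "observed")
  half <- half[half$t1 > half$t0 | half$kind == "flight", ]
  locs <- significant_locations(pause_table(half), cfg)
  f <- daily_mobility_features(half, home, locs, cfg)
  expect_equal(f$distance_m, 2000)
  expect_equal(f$max_home_dist_m, 1000)
  expect_equal(f$radius_gyration_m, 500)
  expect_equal(f$location_entropy, log(2), tolerance = 1e-10)
  expect_equal(f$n_sig_locations, 2)

  # single-flight day: mean length L, SD 0
  one_fl <- data.frame(kind = c("pause", "flight", "pause"),
                       t0 = c(0, 40000, 41000), t1 = c(40000, 41000, 86400),
                       x0 = c(0, 0, 300), y0 = 0, x1 = c(0, 300, 300), y1 = 0,
                       provenance = "observed")
  f <- daily_mobility_features(one_fl, home, NULL, cfg)
  expect_equal(f$mean_flight_len_m, 300)
  expect_equal(f$sd_flight_len_m, 0)
})

test_that("distances are translation-invariant and RoG rotation-invariant", {
  cfg <- mobility_config()
  par <- list(trip_rate = 4, beta_trips = 0, beta_away = 0, speed_mps = 8,
              away_pause_s = 5400)
  segs <- simulate_day_trajectory(c(0, 0), cbind(c(1200, -900), c(300, 1700)),
                                  10, par, seed = 77)
  locs <- significant_locations(pause_table(segs), cfg)
  f0 <- daily_mobility_features(segs, c(0, 0), locs, cfg)

  shift <- segs
  shift[, c("x0", "x1")] <- shift[, c("x0", "x1")] + 5000
  shift[, c("y0", "y1")] <- shift[, c("y0", "y1")] - 2000
  f1 <- daily_mobility_features(shift, c(5000, -2000), NULL, cfg)
  for (nm in c("distance_m", "max_diameter_m", "max_home_dist_m",
               "radius_gyration_m", "home_time_min"))
    expect_equal(f1[[nm]], f0[[nm]], tolerance = 1e-9)

  th <- 0.73
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  rot <- segs
  p0 <- as.matrix(segs[, c("x0", "y0")]) %*% t(R)
  p1 <- as.matrix(segs[, c("x1", "y1")]) %*% t(R)
  rot$x0 <- p0[, 1]; rot$y0 <- p0[, 2]; rot$x1 <- p1[, 1]; rot$y1 <- p1[, 2]
  f2 <- daily_mobility_features(rot, c(0, 0), NULL, cfg)
  expect_equal(f2$radius_gyration_m, f0$radius_gyration_m, tolerance = 1e-9)
  expect_equal(f2$distance_m, f0$distance_m, tolerance = 1e-9)
})

test_that("entropy is bounded by the log cluster count", {
  cfg <- mobility_config(seed = 8)
  for (s in 1:5) {
    par <- list(trip_rate = 5, beta_trips = 0, beta_away = 0, speed_mps = 8,
                away_pause_s = 3600)
    segs <- simulate_day_trajectory(c(0, 0),
                                    cbind(c(1500, -2500, 900),
                                          c(-700, 1300, 2200)),
                                    5, par, seed = 100 + s)
    locs <- significant_locations(pause_table(segs), cfg)
    f <- daily_mobility_features(segs, c(0, 0), locs, cfg)
    expect_gte(f$location_entropy, 0)
    expect_lte(f$location_entropy, log(max(f$n_sig_locations, 1)) + 1e-12)
  }
})

test_that("routine similarity counts co-located bins", {
  cfg <- mobility_config()
  day <- function(xs) {
    data.frame(kind = "pause", t0 = seq(0, 84600, by = 1800),
               t1 = seq(1800, 86400, by = 1800),
               x0 = xs, y0 = 0, x1 = xs, y1 = 0, provenance = "observed")
  }
  a <- routine_bins(day(rep(0, 48)), 0, cfg)
  expect_equal(routine_similarity(a, a, cfg$routine_threshold_m), 1.0)
  b <- routine_bins(day(rep(5000, 48)), 0, cfg)
  expect_equal(routine_similarity(a, b, cfg$routine_threshold_m), 0.0)
  c2 <- routine_bins(day(c(rep(0, 24), rep(5000, 24))), 0, cfg)
  expect_equal(routine_similarity(a, c2, cfg$routine_threshold_m), 0.5)
  # no co-observed bins
  empty <- matrix(NA_real_, 48, 2)
  expect_true(is.na(routine_similarity(a, empty, 500)))
})

test_that("feature error shrinks as the observed fraction grows", {
  light <- imputation_benchmark(n_days = 12, removal = c(0.02, 0.05),
                                seed = 31)
  heavy <- imputation_benchmark(n_days = 12, removal = c(0.45, 0.65),
                                seed = 31)
  expect_lt(light$nmae[["resampling"]], heavy$nmae[["resampling"]])
})
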