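# Daily GPS mobility statistics.

# population SD (single observation -> 0, not NA)
sd_pop <- function(x) if (length(x) == 0) NA_real_ else
  sqrt(mean((x - mean(x))^2))

#' Daily mobility features from a complete day of segments
#'
#' Computes the GPS-based daily summary statistics from a (post-imputation)
#' contiguous segment sequence for one local day: distance traveled (sum of
#' flight lengths), maximum diameter (largest pairwise distance between
#' segment endpoints), maximum distance from home, time-weighted radius of
#' gyration (closed-form line integrals, no discretization), minutes at home
#' (within `home_radius_m`), flight length/duration moments (population SD,
#' so a single-flight day has SD 0), probability of pause (pause time over
#' the 1440-min day), number of significant locations visited, and
#' significant-location entropy (natural log over the day's pause-time shares
#' across clusters). The two routine features are filled in later by
#' [routine_features()] because they compare days with each other.
#'
#' @param segments one local day's segments (observed + imputed).
#' @param home planar home coordinates or `NULL` (home-dependent features
#'   become `NA`).
#' @param locations a `"sig_locations"` object for the subject, or `NULL`.
#' @param cfg a [mobility_config()].
#' @return One-row data.frame of the daily features (routines `NA`).
#' @export
daily_mobility_features <- function(segments, home, locations,
                                    cfg = mobility_config()) {
  out <- as.list(rep(NA_real_, length(GPS_FEATURES)))
  names(out) <- GPS_FEATURES
  if (nrow(segments) == 0 || sum(segments$t1 - segments$t0) == 0)
    return(as.data.frame(out))
  dur <- segments$t1 - segments$t0
  total <- sum(dur)
  fl <- segments[segments$kind == "flight", , drop = FALSE]
  flen <- sqrt((fl$x1 - fl$x0)^2 + (fl$y1 - fl$y0)^2)
  fdur <- fl$t1 - fl$t0
  out$distance_m <- sum(flen)
  out$mean_flight_len_m <- if (nrow(fl)) mean(flen) else 0
  out$sd_flight_len_m <- if (nrow(fl)) sd_pop(flen) else 0
  out$mean_flight_dur_s <- if (nrow(fl)) mean(fdur) else 0
  out$sd_flight_dur_s <- if (nrow(fl)) sd_pop(fdur) else 0
  out$pause_prob <- sum(dur[segments$kind == "pause"]) / total

  pts <- unique(rbind(as.matrix(segments[, c("x0", "y0")]),
                      as.matrix(segments[, c("x1", "y1")])))
  out$max_diameter_m <- if (nrow(pts) > 1) max(dist(pts)) else 0

  # time-weighted radius of gyration (exact line integrals)
  mx <- sum(dur * (segments$x0 + segments$x1) / 2) / total
  my <- sum(dur * (segments$y0 + segments$y1) / 2) / total
  ax <- segments$x0 - mx; ay <- segments$y0 - my
  vx <- segments$x1 - segments$x0; vy <- segments$y1 - segments$y0
  m2 <- sum(dur * (ax^2 + ay^2 + ax * vx + ay * vy + (vx^2 + vy^2) / 3)) / total
  out$radius_gyration_m <- sqrt(max(m2, 0))

  if (!is.null(home)) {
    out$max_home_dist_m <- max(sqrt((pts[, 1] - home[[1]])^2 +
                                      (pts[, 2] - home[[2]])^2))
    home_s <- sum(vapply(seq_len(nrow(segments)), function(i)
      segment_time_within(segments[i, ], c(home[[1]], home[[2]]),
                          cfg$home_radius_m), numeric(1)))
    out$home_time_min <- home_s / 60
  }

  p <- pause_table(segments)
  if (!is.null(locations) && nrow(p) > 0) {
    cen <- locations$centroids
    d2 <- outer(p$x^2 + p$y^2, rep(1, nrow(cen))) -
      2 * cbind(p$x, p$y) %*% t(cen) +
      outer(rep(1, nrow(p)), rowSums(cen^2))
    assign <- max.col(-d2, ties.method = "first")
    tshare <- tapply(p$w, assign, sum)
    out$n_sig_locations <- length(tshare)
    q <- tshare / sum(tshare)
    out$location_entropy <- -sum(q * log(q))
  } else if (nrow(p) == 0) {
    out$n_sig_locations <- 0
    out$location_entropy <- 0
  }
  as.data.frame(out)
}

#' Half-hour representative positions for the routine features
#'
#' Bins a day's trajectory into `1440 / routine_bin_min` time bins; each
#' bin's representative position is the time-weighted mean position of the
#' segments overlapping it.
#'
#' @param segments one local day's segments.
#' @param day_start epoch second of the day's local midnight.
#' @param cfg a [mobility_config()].
#' @return Matrix `n_bins x 2` (NA rows where the day has no coverage).
#' @export
routine_bins <- function(segments, day_start, cfg = mobility_config()) {
  nb <- as.integer(1440 / cfg$routine_bin_min)
  width <- cfg$routine_bin_min * 60
  out <- matrix(NA_real_, nb, 2)
  if (nrow(segments) == 0) return(out)
  for (b in seq_len(nb)) {
    lo <- day_start + (b - 1) * width; hi <- lo + width
    o_lo <- pmax(segments$t0, lo); o_hi <- pmin(segments$t1, hi)
    w <- pmax(o_hi - o_lo, 0)
    if (sum(w) == 0) next
    # mean position of each segment over its overlap window
    dt <- segments$t1 - segments$t0
    u0 <- ifelse(dt > 0, (o_lo - segments$t0) / dt, 0)
    u1 <- ifelse(dt > 0, (o_hi - segments$t0) / dt, 0)
    um <- (u0 + u1) / 2
    px <- segments$x0 + um * (segments$x1 - segments$x0)
    py <- segments$y0 + um * (segments$y1 - segments$y0)
    out[b, ] <- c(sum(px * w), sum(py * w)) / sum(w)
  }
  out
}

#' Similarity of two days' location patterns
#'
#' Fraction of co-observed time bins whose representative positions lie
#' within `threshold_m` of each other; `NA` if the days share no observed
#' bins.
#'
#' @param bins_a,bins_b matrices from [routine_bins()].
#' @param threshold_m match threshold in meters.
#' @return A fraction in `[0, 1]`, or `NA`.
#' @export
routine_similarity <- function(bins_a, bins_b, threshold_m = 500) {
  ok <- stats::complete.cases(bins_a) & stats::complete.cases(bins_b)
  if (!any(ok)) return(NA_real_)
  d <- sqrt(rowSums((bins_a[ok, , drop = FALSE] -
                       bins_b[ok, , drop = FALSE])^2))
  mean(d <= threshold_m)
}

#' Day-level routine features across a subject's days
#'
#' Circadian routine of a day is its mean [routine_similarity()] to all the
#' subject's other days; weekend-weekday routine is its mean similarity to
#' days of the opposite type.
#'
#' @param bins_list list of [routine_bins()] matrices, one per day.
#' @param types character vector of day types ("weekday"/"weekend").
#' @param cfg a [mobility_config()].
#' @return data.frame with `circadian_routine` and
#'   `weekend_weekday_routine` per day.
#' @export
routine_features <- function(bins_list, types, cfg = mobility_config()) {
  n <- length(bins_list)
  sim <- matrix(NA_real_, n, n)
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      s <- routine_similarity(bins_list[[i]], bins_list[[j]],
                              cfg$routine_threshold_m)
      sim[i, j] <- sim[j, i] <- s
    }
  }
  circ <- vapply(seq_len(n), function(i)
    mean(sim[i, -i], na.rm = TRUE), numeric(1))
  wwk <- vapply(seq_len(n), function(i) {
    opp <- which(types != types[i])
    if (length(opp) == 0) return(NA_real_)
    mean(sim[i, opp], na.rm = TRUE)
  }, numeric(1))
  data.frame(circadian_routine = ifelse(is.nan(circ), NA, circ),
             weekend_weekday_routine = ifelse(is.nan(wwk), NA, wwk))
}

# Minutes of the local day with at least one raw GPS fix, and the number of
# minutes the duty-cycle schedule makes observable.
gps_observed_minutes <- function(ts_ms, day_start_s) {
  mins <- unique(floor((ts_ms / 1000 - day_start_s) / 60))
  mins <- mins[mins >= 0 & mins < 1440]
  length(mins)
}

gps_expected_minutes <- function(cfg) {
  period <- cfg$gps_on_s + cfg$gps_off_s
  secs <- seq(0, SEC_PER_DAY - 1)
  on <- secs %% period < cfg$gps_on_s
  length(unique(secs[on] %/% 60))
}

#' Daily mobility table for one subject
#'
#' The full GPS chain: quality filter (accuracy above `accuracy_max_m`
#' dropped), planar projection, flight/pause segmentation, home detection,
#' gap imputation, subject-level significant-location clustering, daily
#' features, and cross-day routine features. Daily features use the imputed
#' (complete) trajectory except the missing-minutes count, which counts raw
#' observation only.
#'
#' @param gps GeoPoint data.frame (`timestamp`, `latitude`, `longitude`,
#'   `accuracy`).
#' @param cfg a [mobility_config()].
#' @param tz subject timezone.
#' @param subject subject id carried into the output.
#' @return data.frame, one row per local day: `subject`, `date`, `day_type`,
#'   the 14 mobility features and `gps_missing_minutes`.
#' @export
mobility_daily <- function(gps, cfg = mobility_config(), tz = "UTC",
                           subject = NA_character_) {
  gps <- gps[is.finite(gps$accuracy) & gps$accuracy <= cfg$accuracy_max_m, ,
             drop = FALSE]
  if (nrow(gps) == 0)
    return(empty_mobility_table(subject))
  planar <- project_to_plane(gps)
  segs <- segment_flights_pauses(planar, cfg)
  home <- detect_home(segs, cfg, tz)
  segs <- impute_gaps(segs, cfg, tz)
  segs <- split_segments_by_day(segs, tz)

  p_all <- pause_table(segs)
  locations <- if (nrow(p_all) > 0) significant_locations(p_all, cfg) else NULL

  dates <- sort(unique(local_date(segs$t0 * 1000 + 1, tz)))
  day_rows <- vector("list", length(dates))
  bins_list <- vector("list", length(dates))
  exp_min <- gps_expected_minutes(cfg)
  for (i in seq_along(dates)) {
    d0 <- midnight_ms(dates[i], tz) / 1000
    d1 <- d0 + SEC_PER_DAY
    ds <- segs[segs$t0 >= d0 - 1e-6 & segs$t1 <= d1 + 1e-6, , drop = FALSE]
    obs_min <- gps_observed_minutes(
      gps$timestamp[gps$timestamp >= d0 * 1000 & gps$timestamp < d1 * 1000],
      d0)
    if (obs_min == 0) {
      # entirely unobserved day: features undefined, not imputed-through
      feats <- as.data.frame(as.list(rep(NA_real_, length(GPS_FEATURES))))
      names(feats) <- GPS_FEATURES
      feats$gps_missing_minutes <- exp_min
      bins_list[[i]] <- matrix(NA_real_,
                               as.integer(1440 / cfg$routine_bin_min), 2)
    } else {
      feats <- daily_mobility_features(ds, home, locations, cfg)
      feats$gps_missing_minutes <- max(exp_min - obs_min, 0)
      bins_list[[i]] <- routine_bins(ds, d0, cfg)
    }
    day_rows[[i]] <- feats
  }
  out <- do.call(rbind, day_rows)
  types <- day_type(dates)
  rout <- routine_features(bins_list, types, cfg)
  out$circadian_routine <- rout$circadian_routine
  out$weekend_weekday_routine <- rout$weekend_weekday_routine
  cbind(data.frame(subject = subject, date = dates, day_type = types), out)
}

empty_mobility_table <- function(subject) {
  out <- as.data.frame(as.list(rep(NA_real_, length(GPS_FEATURES))))
  names(out) <- GPS_FEATURES
  cbind(data.frame(subject = subject, date = as.Date(character(0)),
                   day_type = character(0))[0, ], out[0, ],
        gps_missing_minutes = numeric(0))
}
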