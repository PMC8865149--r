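# Ground-truth daily movement model: alternating pauses (home + away anchors)
# and straight-line flights, with severity-coupled excursion behaviour.

#' Simulate one day's ground-truth movement path
#'
#' Produces a continuous-time planar trajectory for one local day as an
#' alternating sequence of pauses and straight-line flights. The subject
#' starts and ends the day at home; during a daytime window they make a
#' random number of excursions to away anchors. Depression severity couples
#' log-linearly to behaviour: the excursion count rate is multiplied by
#' `exp(beta_trips * severity)` and away-pause durations by
#' `exp(beta_away * severity)`, so with negative coefficients expected
#' distance traveled decreases and expected home time increases monotonically
#' in severity. With coupling coefficients of zero the path is independent of
#' severity (identical under the same seed).
#'
#' @param home length-2 numeric, planar home coordinates (meters).
#' @param anchors matrix with columns x, y of away-anchor coordinates; zero
#'   rows give a day spent entirely at home.
#' @param severity latent severity on the MADRS scale `[0, 60]`.
#' @param params list with elements `trip_rate`, `beta_trips`, `beta_away`,
#'   `speed_mps`, `away_pause_s` (see [sim_config()]).
#' @param seed integer seed for this day's substream.
#' @return A data.frame of contiguous segments covering `[0, 86400)` seconds
#'   with columns `kind` ("pause"/"flight"), `t0`, `t1` (seconds from local
#'   midnight), `x0`, `y0`, `x1`, `y1`.
#' @export
simulate_day_trajectory <- function(home, anchors, severity, params, seed) {
  stopifnot(severity >= 0, severity <= 60)
  anchors <- matrix(as.numeric(anchors), ncol = 2)
  with_seed(seed, {
    kinds <- character(0)
    rows <- list()
    add <- function(kind, t0, t1, p0, p1) {
      if (t1 > t0) {
        kinds[[length(kinds) + 1]] <<- kind
        rows[[length(rows) + 1]] <<- c(t0, t1, p0[1], p0[2], p1[1], p1[2])
      }
    }
    rate <- params$trip_rate * exp(params$beta_trips * severity)
    n_trips <- if (nrow(anchors) == 0) 0L else rpois(1, rate)
    win <- c(8, 20) * 3600
    starts <- sort(runif(n_trips, win[1], win[2]))
    t <- 0
    pos <- home
    for (s in starts) {
      t_start <- max(s, t)
      j <- sample.int(nrow(anchors), 1)
      a <- anchors[j, ]
      d <- sqrt(sum((a - home)^2))
      speed <- rlnorm(1, log(params$speed_mps), 0.3)
      travel <- d / speed
      stay <- rlnorm(1, log(params$away_pause_s), 0.5) *
        exp(params$beta_away * severity)
      if (t_start + 2 * travel + stay > 23 * 3600) next
      add("pause", t, t_start, home, home)
      add("flight", t_start, t_start + travel, home, a)
      add("pause", t_start + travel, t_start + travel + stay, a, a)
      add("flight", t_start + travel + stay, t_start + 2 * travel + stay, a, home)
      t <- t_start + 2 * travel + stay
    }
    add("pause", t, SEC_PER_DAY, home, home)
    m <- do.call(rbind, rows)
    data.frame(kind = kinds, t0 = m[, 1], t1 = m[, 2],
               x0 = m[, 3], y0 = m[, 4], x1 = m[, 5], y1 = m[, 6])
  })
}

#' Sample positions along a segment path
#'
#' Linearly interpolates a contiguous pause/flight segment sequence at
#' arbitrary times, yielding the exact ground-truth position.
#'
#' @param segments segment data.frame as from [simulate_day_trajectory()].
#' @param times_s numeric vector of times (same clock as the segments).
#' @return Matrix with columns x, y.
#' @export
sample_path <- function(segments, times_s) {
  i <- findInterval(times_s, segments$t0, rightmost.closed = FALSE)
  i <- clip(i, 1L, nrow(segments))
  dt <- segments$t1[i] - segments$t0[i]
  u <- ifelse(dt > 0, (times_s - segments$t0[i]) / dt, 0)
  u <- clip(u, 0, 1)
  cbind(x = segments$x0[i] + u * (segments$x1[i] - segments$x0[i]),
        y = segments$y0[i] + u * (segments$y1[i] - segments$y0[i]))
}

# Exact time within `radius` of point `p` for one segment (analytic:
# quadratic in the interpolation parameter).
segment_time_within <- function(seg, p, radius) {
  d <- seg$t1 - seg$t0
  a <- c(seg$x0 - p[1], seg$y0 - p[2])
  v <- c(seg$x1 - seg$x0, seg$y1 - seg$y0)
  vv <- sum(v^2)
  if (vv < 1e-12) return(if (sum(a^2) <= radius^2) d else 0)
  # |a + u v|^2 <= r^2  on u in [0,1]
  A <- vv; B <- 2 * sum(a * v); C <- sum(a^2) - radius^2
  disc <- B^2 - 4 * A * C
  if (disc <= 0) return(if (C <= 0) d else 0)
  r1 <- (-B - sqrt(disc)) / (2 * A); r2 <- (-B + sqrt(disc)) / (2 * A)
  lo <- max(min(r1, r2), 0); hi <- min(max(r1, r2), 1)
  max(hi - lo, 0) * d
}

#' Exact daily mobility truth from a segment path
#'
#' Computes reference values of the main daily mobility statistics directly
#' from the continuous segment representation (closed-form time integrals, no
#' sampling): distance traveled, time at home, radius of gyration, maximum
#' diameter, maximum distance from home, and pause-time fraction. These serve
#' as ground truth against which the observation-based feature extractor is
#' validated.
#'
#' @param segments segment data.frame covering one day.
#' @param home planar home coordinates.
#' @param home_radius_m radius defining "at home", meters.
#' @return Named list of truth metrics.
#' @export
truth_from_segments <- function(segments, home, home_radius_m = 200) {
  fl <- segments[segments$kind == "flight", , drop = FALSE]
  dist_m <- if (nrow(fl)) sum(sqrt((fl$x1 - fl$x0)^2 + (fl$y1 - fl$y0)^2)) else 0
  dur <- segments$t1 - segments$t0
  total <- sum(dur)
  # time-weighted centroid: pauses at centroid, flights contribute midpoint
  mx <- sum(dur * (segments$x0 + segments$x1) / 2) / total
  my <- sum(dur * (segments$y0 + segments$y1) / 2) / total
  # exact second moment about (mx,my): for p(u)=a+uv on [0,1],
  # integral |p-c|^2 du = |a-c|^2 + (a-c).v + |v|^2/3
  ax <- segments$x0 - mx; ay <- segments$y0 - my
  vx <- segments$x1 - segments$x0; vy <- segments$y1 - segments$y0
  m2 <- sum(dur * (ax^2 + ay^2 + ax * vx + ay * vy + (vx^2 + vy^2) / 3)) / total
  home_s <- sum(vapply(seq_len(nrow(segments)), function(i)
    segment_time_within(segments[i, ], home, home_radius_m), numeric(1)))
  pts <- unique(rbind(as.matrix(segments[, c("x0", "y0")]),
                      as.matrix(segments[, c("x1", "y1")])))
  dd <- as.matrix(dist(pts))
  hd <- sqrt((pts[, 1] - home[1])^2 + (pts[, 2] - home[2])^2)
  list(distance_m = dist_m,
       home_time_min = home_s / 60,
       radius_gyration_m = sqrt(max(m2, 0)),
       max_diameter_m = max(dd),
       max_home_dist_m = max(hd),
       pause_fraction = sum(dur[segments$kind == "pause"]) / total)
}
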