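# Flight/pause decomposition of duty-cycled GPS traces.

#' Mobility feature-extraction configuration
#'
#' Thresholds for the GPS processing chain. The trace decomposition and
#' feature definitions follow the flight/pause mobility-features literature;
#' all values are deliberately config-exposed.
#'
#' @param pause_radius_m maximum net displacement of a pause, meters.
#' @param min_pause_s minimum pause duration, seconds.
#' @param home_radius_m radius defining "at home", meters.
#' @param sig_radius_m assignment radius for significant-location clustering,
#'   meters.
#' @param k_max maximum number of significant-location clusters.
#' @param routine_threshold_m bin-position match threshold for the routine
#'   similarity, meters.
#' @param routine_bin_min width of the routine time bins, minutes.
#' @param accuracy_max_m GPS fixes with reported accuracy above this are
#'   discarded before segmentation.
#' @param gps_on_s,gps_off_s the GPS duty cycle (used for the expected-minute
#'   denominator of the missing-data count and the default gap threshold).
#' @param gap_threshold_s point spacings larger than this mark an unobserved
#'   interval; default one full duty cycle (`gps_on_s + gps_off_s`), so the
#'   regular off-cycle spacing is bridged by segmentation but a missed
#'   on-cycle opens a gap.
#' @param impute_method `"resampling"` or `"linear"` (see [impute_gaps()]).
#' @param donor_decay_h time-of-day decay scale for donor weights, hours.
#' @param seed seed for imputation and clustering.
#' @return A list of class `"mobility_config"`.
#' @export
mobility_config <- function(pause_radius_m = 10, min_pause_s = 30,
                            home_radius_m = 200, sig_radius_m = 200,
                            k_max = 10, routine_threshold_m = 500,
                            routine_bin_min = 30, accuracy_max_m = 250,
                            gps_on_s = 120, gps_off_s = 600,
                            gap_threshold_s = gps_on_s + gps_off_s,
                            impute_method = c("resampling", "linear"),
                            donor_decay_h = 3, seed = 1L) {
  cfg <- as.list(environment())
  cfg$impute_method <- match.arg(impute_method)
  stopifnot(cfg$pause_radius_m > 0, cfg$min_pause_s > 0, cfg$k_max >= 1,
            cfg$gap_threshold_s > 0)
  class(cfg) <- "mobility_config"
  cfg
}

#' Decompose a planar GPS trace into flights, pauses, and gaps
#'
#' Within observed stretches, runs of consecutive points staying within
#' `pause_radius_m` of their running centroid for at least `min_pause_s`
#' collapse to a pause at the centroid; remaining motion becomes
#' straight-line flights between successive retained points. Point spacings
#' larger than `gap_threshold_s` (a missed on-cycle or outage) are marked as
#' unobserved gaps with known endpoint positions. The regular off-cycle
#' spacing of the duty cycle is below the threshold and is bridged as normal
#' motion.
#'
#' @param planar data.frame with `timestamp` (UTC epoch ms), `x`, `y`
#'   (meters), time-sorted.
#' @param cfg a [mobility_config()].
#' @return A data.frame of contiguous segments: `kind`
#'   ("pause"/"flight"/"gap"), `t0`, `t1` (epoch seconds), `x0`, `y0`, `x1`,
#'   `y1`, `provenance` ("observed"; gaps carry their bounding positions).
#' @export
segment_flights_pauses <- function(planar, cfg = mobility_config()) {
  n <- nrow(planar)
  empty <- data.frame(kind = character(0), t0 = numeric(0), t1 = numeric(0),
                      x0 = numeric(0), y0 = numeric(0), x1 = numeric(0),
                      y1 = numeric(0), provenance = character(0))
  if (n == 0) return(empty)
  ts <- planar$timestamp / 1000
  if (is.unsorted(ts)) stop("planar stream must be time-sorted")
  x <- planar$x; y <- planar$y
  rad <- cfg$pause_radius_m
  gap_s <- cfg$gap_threshold_s

  # retained items: matrix rows (t0, t1, x, y); pauses have t1 > t0
  it0 <- numeric(n); it1 <- numeric(n); ix <- numeric(n); iy <- numeric(n)
  m <- 0L
  i <- 1L
  while (i <= n) {
    j <- i
    cx <- x[i]; cy <- y[i]; cnt <- 1
    while (j < n && ts[j + 1] - ts[j] <= gap_s) {
      dx <- x[j + 1] - cx; dy <- y[j + 1] - cy
      if (dx * dx + dy * dy >= rad * rad) break
      cx <- (cx * cnt + x[j + 1]) / (cnt + 1)
      cy <- (cy * cnt + y[j + 1]) / (cnt + 1)
      cnt <- cnt + 1
      j <- j + 1L
    }
    m <- m + 1L
    if (j > i && ts[j] - ts[i] >= cfg$min_pause_s) {
      it0[m] <- ts[i]; it1[m] <- ts[j]; ix[m] <- cx; iy[m] <- cy
      i <- j + 1L
    } else {
      it0[m] <- ts[i]; it1[m] <- ts[i]; ix[m] <- x[i]; iy[m] <- y[i]
      i <- i + 1L
    }
  }
  it0 <- it0[seq_len(m)]; it1 <- it1[seq_len(m)]
  ix <- ix[seq_len(m)]; iy <- iy[seq_len(m)]

  # assemble contiguous segments: retained pauses plus connectors
  km <- character(2L * m); rowm <- matrix(0, 2L * m, 6)
  k <- 0L
  push <- function(kind, r) {
    k <<- k + 1L
    km[k] <<- kind
    rowm[k, ] <<- r
  }
  for (q in seq_len(m)) {
    if (q > 1) {
      # connector from previous retained end to this start
      jump <- it0[q] - it1[q - 1]
      if (jump > 0) {
        kind <- if (jump > gap_s) "gap" else "flight"
        push(kind, c(it1[q - 1], it0[q], ix[q - 1], iy[q - 1], ix[q], iy[q]))
      }
    }
    if (it1[q] > it0[q])
      push("pause", c(it0[q], it1[q], ix[q], iy[q], ix[q], iy[q]))
  }
  if (k == 0L) {
    # single instantaneous point: degenerate zero-length pause
    push("pause", c(it0[1], it1[1], ix[1], iy[1], ix[1], iy[1]))
  }
  out <- data.frame(kind = km[seq_len(k)],
                    t0 = rowm[seq_len(k), 1], t1 = rowm[seq_len(k), 2],
                    x0 = rowm[seq_len(k), 3], y0 = rowm[seq_len(k), 4],
                    x1 = rowm[seq_len(k), 5], y1 = rowm[seq_len(k), 6],
                    provenance = "observed")
  out
}

# Split a contiguous segment sequence at local-midnight boundaries so that
# every segment lies within one local day. Positions at the cut are linear
# interpolations.
split_segments_by_day <- function(segments, tz = "UTC") {
  if (nrow(segments) == 0) return(segments)
  d0 <- local_date(segments$t0[1] * 1000, tz)
  d1 <- local_date(max(segments$t1) * 1000 - 1, tz)
  cuts <- midnight_ms(seq(d0 + 1, d1 + 1, by = "day"), tz) / 1000
  cuts <- cuts[cuts > min(segments$t0) & cuts < max(segments$t1)]
  for (cut in cuts) {
    hit <- which(segments$t0 < cut & segments$t1 > cut)
    for (h in hit) {
      s <- segments[h, ]
      u <- (cut - s$t0) / (s$t1 - s$t0)
      mx <- s$x0 + u * (s$x1 - s$x0); my <- s$y0 + u * (s$y1 - s$y0)
      left <- s; left$t1 <- cut; left$x1 <- mx; left$y1 <- my
      right <- s; right$t0 <- cut; right$x0 <- mx; right$y0 <- my
      segments <- rbind(segments[seq_len(h - 1), , drop = FALSE], left, right,
                        segments[-seq_len(h), , drop = FALSE])
    }
  }
  segments[order(segments$t0), , drop = FALSE]
}
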