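# Significant-location clustering and home detection.

#' Cluster pauses into significant locations
#'
#' Time-weighted k-means (Lloyd's algorithm, farthest-point initialization,
#' deterministic given the seed) on pause centroids, with k grown from 1
#' until every pause lies within `sig_radius_m` of its assigned centroid or
#' `k_max` is reached. Pause durations act as weights so that brief GPS
#' excursions do not spawn spurious places.
#'
#' @param pauses data.frame with `x`, `y` (pause centroids, meters) and `w`
#'   (pause durations, seconds).
#' @param cfg a [mobility_config()] (`sig_radius_m`, `k_max`, `seed`).
#' @return List of class `"sig_locations"`: `centroids` (k x 2 matrix),
#'   `assignment` (per pause), `within_radius` (logical, did the growth stop
#'   before `k_max`).
#' @export
significant_locations <- function(pauses, cfg = mobility_config()) {
  stopifnot(nrow(pauses) >= 1)
  pts <- cbind(pauses$x, pauses$y)
  w <- pauses$w
  for (k in seq_len(cfg$k_max)) {
    fit <- weighted_kmeans(pts, w, k, seed = derive_seed(cfg$seed, "kmeans", k))
    d <- sqrt(rowSums((pts - fit$centroids[fit$assignment, , drop = FALSE])^2))
    if (max(d) <= cfg$sig_radius_m || k == cfg$k_max) {
      return(structure(list(centroids = fit$centroids,
                            assignment = fit$assignment,
                            within_radius = max(d) <= cfg$sig_radius_m),
                       class = "sig_locations"))
    }
  }
}

# Weighted Lloyd iteration. Initialization: weighted mean, then repeatedly
# the point farthest from its nearest centroid (deterministic; the seed only
# breaks exact ties).
weighted_kmeans <- function(pts, w, k, seed = 1L, iter_max = 50) {
  n <- nrow(pts)
  k <- min(k, n)
  cen <- matrix(0, k, 2)
  cen[1, ] <- colSums(pts * w) / sum(w)
  if (k > 1) {
    for (j in 2:k) {
      d <- nearest_dist(pts, cen[seq_len(j - 1), , drop = FALSE])
      far <- which(d == max(d))
      pick <- if (length(far) == 1) far else
        with_seed(seed, sample(far, 1))
      cen[j, ] <- pts[pick, ]
    }
  }
  assign <- rep(1L, n)
  for (it in seq_len(iter_max)) {
    d2 <- outer(rowSums(pts^2), rep(1, k)) - 2 * pts %*% t(cen) +
      outer(rep(1, n), rowSums(cen^2))
    new_assign <- max.col(-d2, ties.method = "first")
    for (j in seq_len(k)) {
      sel <- new_assign == j
      if (any(sel)) cen[j, ] <- colSums(pts[sel, , drop = FALSE] * w[sel]) /
          sum(w[sel])
    }
    if (all(new_assign == assign) && it > 1) break
    assign <- new_assign
  }
  list(centroids = cen, assignment = assign)
}

nearest_dist <- function(pts, cen) {
  d2 <- outer(rowSums(pts^2), rep(1, nrow(cen))) - 2 * pts %*% t(cen) +
    outer(rep(1, nrow(pts)), rowSums(cen^2))
  sqrt(pmax(apply(d2, 1, min), 0))
}

# Extract pause rows (centroid + duration) from a segment sequence.
pause_table <- function(segments, include_imputed = TRUE) {
  sel <- segments$kind == "pause" & segments$t1 > segments$t0
  if (!include_imputed) sel <- sel & segments$provenance == "observed"
  p <- segments[sel, , drop = FALSE]
  data.frame(t0 = p$t0, t1 = p$t1, x = p$x0, y = p$y0, w = p$t1 - p$t0)
}

#' Detect a subject's home location
#'
#' Home is the centroid of the pause cluster carrying the greatest total
#' pause time during local night hours (21:00-06:00) across the whole
#' follow-up.
#'
#' @param segments the subject's full segment sequence (epoch-second times).
#' @param cfg a [mobility_config()].
#' @param tz subject timezone.
#' @return Planar `c(x, y)` of home, or `NULL` if the subject has no
#'   nighttime pauses (home-dependent features are then undefined).
#' @export
detect_home <- function(segments, cfg = mobility_config(), tz = "UTC") {
  p <- pause_table(segments, include_imputed = FALSE)
  if (nrow(p) == 0) return(NULL)
  # night overlap of each pause: seconds inside [21:00, 24:00) or [00:00, 06:00)
  night_w <- vapply(seq_len(nrow(p)), function(i)
    night_overlap(p$t0[i], p$t1[i], tz), numeric(1))
  p <- p[night_w > 0, , drop = FALSE]
  night_w <- night_w[night_w > 0]
  if (nrow(p) == 0) return(NULL)
  p$w <- night_w
  sl <- significant_locations(p, cfg)
  tot <- tapply(p$w, sl$assignment, sum)
  best <- as.integer(names(tot)[which.max(tot)])
  sel <- sl$assignment == best
  c(x = sum(p$x[sel] * p$w[sel]) / sum(p$w[sel]),
    y = sum(p$y[sel] * p$w[sel]) / sum(p$w[sel]))
}

# Seconds of [t0,t1] (epoch seconds) falling in local 21:00-06:00.
night_overlap <- function(t0, t1, tz = "UTC") {
  if (t1 <= t0) return(0)
  d0 <- local_date(t0 * 1000, tz)
  d1 <- local_date(t1 * 1000, tz)
  tot <- 0
  for (d in seq(d0 - 1, d1, by = "day")) {
    mid <- midnight_ms(as.Date(d, origin = "1970-01-01"), tz) / 1000
    for (win in list(c(21, 24) * 3600, c(0, 6) * 3600)) {
      lo <- max(t0, mid + win[1]); hi <- min(t1, mid + win[2])
      tot <- tot + max(hi - lo, 0)
    }
  }
  tot
}
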