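# Imputation of unobserved GPS intervals.

#' Fill unobserved gaps in a segment sequence
#'
#' Two methods. `"linear"` replaces each gap by a single straight-line flight
#' between its known endpoints. `"resampling"` (the default, and the method
#' of record) fills each gap by drawing the subject's own observed flights
#' and pauses as donors — weighted by exponential decay in time-of-day
#' distance (scale `donor_decay_h` hours) with a 2x bonus for donors from the
#' same day type — orienting drawn flights toward the gap's known endpoint
#' (with angular noise, never overshooting), and rescaling the final segment
#' to land exactly on it. Resampling preserves realistic movement statistics
#' inside gaps (pauses remain pauses, travel keeps its speed distribution)
#' where straight-line interpolation systematically understates both distance
#' and time at rest.
#'
#' Every imputed subsequence begins and ends exactly at the observed gap
#' endpoint positions. If no observed donors exist the method falls back to
#' linear with a warning.
#'
#' @param segments segment data.frame from [segment_flights_pauses()]
#'   (possibly containing `"gap"` rows).
#' @param cfg a [mobility_config()]; `cfg$impute_method` selects the method.
#' @param tz timezone for day-type donor bonuses.
#' @return The segment sequence with every gap replaced by imputed
#'   flights/pauses flagged `provenance = "imputed"`.
#' @export
impute_gaps <- function(segments, cfg = mobility_config(), tz = "UTC") {
  gi <- which(segments$kind == "gap")
  if (length(gi) == 0) return(segments)
  obs <- segments[segments$kind %in% c("flight", "pause") &
                    segments$provenance == "observed" &
                    segments$t1 > segments$t0, , drop = FALSE]
  method <- cfg$impute_method
  if (method == "resampling" && nrow(obs) == 0) {
    warning("no observed donor segments; falling back to linear imputation")
    method <- "linear"
  }
  don <- NULL
  if (method == "resampling") {
    don <- list(
      kind = obs$kind,
      dur = obs$t1 - obs$t0,
      len = sqrt((obs$x1 - obs$x0)^2 + (obs$y1 - obs$y0)^2),
      tod = local_seconds((obs$t0 + obs$t1) / 2 * 1000, tz),
      dtype = day_type(local_date((obs$t0 + obs$t1) / 2 * 1000, tz)))
  }
  pieces <- vector("list", 2 * length(gi) + 1)
  prev_end <- 0L
  pk <- 0L
  for (g in gi) {
    pk <- pk + 1L
    idx <- if (g > prev_end + 1) seq(prev_end + 1, g - 1) else integer(0)
    pieces[[pk]] <- segments[idx, , drop = FALSE]
    gap <- segments[g, ]
    fill <- if (method == "linear") linear_fill(gap) else
      resample_fill(gap, don, cfg, tz)
    pk <- pk + 1L
    pieces[[pk]] <- fill
    prev_end <- g
  }
  pk <- pk + 1L
  pieces[[pk]] <- segments[setdiff(seq_len(nrow(segments)),
                                   seq_len(prev_end)), , drop = FALSE]
  out <- do.call(rbind, pieces[seq_len(pk)])
  rownames(out) <- NULL
  out
}

linear_fill <- function(gap) {
  data.frame(kind = "flight", t0 = gap$t0, t1 = gap$t1,
             x0 = gap$x0, y0 = gap$y0, x1 = gap$x1, y1 = gap$y1,
             provenance = "imputed")
}

resample_fill <- function(gap, don, cfg, tz) {
  D <- gap$t1 - gap$t0
  if (D <= 0) return(NULL)
  target <- c(gap$x1, gap$y1)
  tod_gap <- local_seconds((gap$t0 + gap$t1) / 2 * 1000, tz)
  dt <- abs(don$tod - tod_gap)
  dt <- pmin(dt, SEC_PER_DAY - dt) / 3600        # circular time-of-day, hours
  w <- exp(-dt / cfg$donor_decay_h) *
    ifelse(don$dtype == day_type(local_date(gap$t0 * 1000, tz)), 2, 1)
  w <- w / sum(w)
  seed <- derive_seed(cfg$seed, "impute", format(round(gap$t0)))
  with_seed(seed, {
    t <- gap$t0
    p <- c(gap$x0, gap$y0)
    kinds <- character(0); rows <- list()
    while (t < gap$t1 - 1e-9) {
      i <- sample.int(length(w), 1, prob = w)
      dur <- min(don$dur[i], gap$t1 - t)
      if (don$kind[i] == "pause") {
        kinds <- c(kinds, "pause")
        rows[[length(rows) + 1]] <- c(t, t + dur, p[1], p[2], p[1], p[2])
      } else {
        len <- don$len[i] * dur / don$dur[i]
        to_target <- target - p
        d_t <- sqrt(sum(to_target^2))
        if (d_t > 1e-9) {
          len <- min(len, d_t)              # never overshoot the endpoint
          ang <- atan2(to_target[2], to_target[1]) + rnorm(1, 0, 20 * pi / 180)
        } else {
          ang <- runif(1, 0, 2 * pi)
        }
        q <- p + len * c(cos(ang), sin(ang))
        kinds <- c(kinds, "flight")
        rows[[length(rows) + 1]] <- c(t, t + dur, p[1], p[2], q[1], q[2])
        p <- q
      }
      t <- t + dur
    }
    m <- do.call(rbind, rows)
    # close the gap exactly: the final segment lands on the known endpoint
    last <- length(kinds)
    if (m[last, 5] != target[1] || m[last, 6] != target[2]) {
      m[last, 5] <- target[1]; m[last, 6] <- target[2]
      if (kinds[last] == "pause" &&
          (m[last, 3] != target[1] || m[last, 4] != target[2]))
        kinds[last] <- "flight"
    }
    data.frame(kind = kinds, t0 = m[, 1], t1 = m[, 2], x0 = m[, 3],
               y0 = m[, 4], x1 = m[, 5], y1 = m[, 6], provenance = "imputed")
  })
}
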