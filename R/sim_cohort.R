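# Synthetic cohort generator: latent severity trajectories, clinical
# assessments, ground-truth movement/activity, and duty-cycled, gap-ridden
# sensor observations with known generating parameters.

#' Restrict a timestamped stream to sensor on-cycles
#'
#' Retains exactly the samples whose local-time offset falls inside an
#' on-cycle of the schedule: sample at local second `t` is kept iff
#' `t mod (on + off) < on`, with the cycle phase anchored at local midnight.
#'
#' @param stream data.frame with a `timestamp` column (UTC epoch ms),
#'   time-sorted.
#' @param on_s,off_s on/off durations in seconds; `off_s = 0` returns the
#'   stream unchanged.
#' @param tz IANA timezone anchoring the phase.
#' @return The retained rows of `stream`.
#' @export
apply_duty_cycle <- function(stream, on_s, off_s, tz = "UTC") {
  stopifnot(on_s > 0, off_s >= 0)
  if (nrow(stream) == 0) return(stream)
  if (is.unsorted(stream$timestamp)) stop("stream must be time-sorted")
  if (off_s == 0) return(stream)
  sec <- local_seconds(stream$timestamp, tz)
  stream[sec %% (on_s + off_s) < on_s, , drop = FALSE]
}

#' Sample phone-outage windows
#'
#' Each study day independently starts an outage with probability
#' `outage_prob`; the outage begins at a uniform time of day and lasts an
#' exponential duration with mean `outage_mean_h` hours (it may run past
#' midnight). Outages model the phone being off: they are shared across all
#' sensors of a subject.
#'
#' @param dates vector of `Date`s covered by the stream.
#' @param outage_prob,outage_mean_h outage model parameters.
#' @param tz timezone.
#' @param seed integer seed.
#' @return data.frame with columns `start_ms`, `end_ms` (possibly 0 rows).
#' @export
draw_outages <- function(dates, outage_prob, outage_mean_h, tz = "UTC", seed = 1L) {
  with_seed(seed, {
    hit <- runif(length(dates)) < outage_prob
    if (!any(hit)) {
      return(data.frame(start_ms = numeric(0), end_ms = numeric(0)))
    }
    d <- dates[hit]
    start <- midnight_ms(d, tz) + runif(length(d), 0, SEC_PER_DAY) * 1000
    dur <- rexp(length(d), rate = 1 / (outage_mean_h * 3600)) * 1000
    data.frame(start_ms = start, end_ms = start + dur)
  })
}

#' Remove samples falling inside outage windows
#'
#' @param stream data.frame with a `timestamp` column (UTC epoch ms).
#' @param outages data.frame with `start_ms`, `end_ms` columns, as from
#'   [draw_outages()].
#' @return The stream with all samples in `[start, end)` of any outage
#'   removed.
#' @export
apply_outages <- function(stream, outages) {
  if (nrow(stream) == 0 || nrow(outages) == 0) return(stream)
  drop <- rep(FALSE, nrow(stream))
  for (i in seq_len(nrow(outages)))
    drop <- drop | (stream$timestamp >= outages$start_ms[i] &
                      stream$timestamp < outages$end_ms[i])
  stream[!drop, , drop = FALSE]
}

#' Simulate one day of triaxial accelerometer data
#'
#' Generates samples on the accelerometer on-cycle grid for one local day.
#' At rest the signal is gravity (0, 0, 1 g) plus small per-axis noise;
#' during active minutes a high-variance oscillation is added, so the
#' per-minute SD of the acceleration magnitude separates active from
#' stationary minutes. Which minutes are active follows a 24-bin diurnal
#' profile whose level is scaled down by `exp(beta_activity * severity)`.
#'
#' @param date local `Date`.
#' @param severity latent severity on the MADRS scale.
#' @param cfg a [sim_config()].
#' @param seed integer seed.
#' @return List with `samples` (data.frame `timestamp`, `x`, `y`, `z`) and
#'   `active_minutes` (logical 1440, the ground-truth schedule).
#' @export
simulate_accel_day <- function(date, severity, cfg, seed) {
  with_seed(seed, {
    p_act <- clip(cfg$activity_profile * exp(cfg$beta_activity * severity), 0, 1)
    active <- runif(1440) < rep(p_act, each = 60)
    period <- cfg$accel_on_s + cfg$accel_off_s
    t <- seq(0, SEC_PER_DAY - 1, by = cfg$accel_sample_s)
    t <- t[t %% period < cfg$accel_on_s]
    sd_i <- ifelse(active[t %/% 60 + 1], cfg$accel_active_sd, cfg$accel_rest_sd)
    n <- length(t)
    samples <- data.frame(
      timestamp = midnight_ms(date, cfg$tz) + t * 1000,
      x = rnorm(n, 0, sd_i), y = rnorm(n, 0, sd_i), z = rnorm(n, 1, sd_i))
    list(samples = samples, active_minutes = active)
  })
}

#' Simulate MADRS visits and weekly PHQ-8 surveys from latent severity
#'
#' Visit MADRS scores are `clip(round(severity + rater noise), 0, 60)`.
#' PHQ-8 totals are `clip(round(a * severity + b + noise), 0, 24)`, allocated
#' to 8 item scores in `[0, 3]` by largest remainder. Surveys are delivered
#' on Saturdays at 10:00 local; each is completed with a probability that
#' declines linearly from `survey_p_first` to `survey_p_last`, and completed
#' surveys are occasionally late by 1-5 days.
#'
#' @param latent data.frame with columns `subject`, `day`, `severity`,
#'   `last_day` (last study day the subject contributes).
#' @param cfg a [sim_config()].
#' @param seed integer seed.
#' @return List with `visits` and `surveys` data.frames in the canonical
#'   column layouts (see [read_visits()], [read_surveys()]).
#' @export
simulate_assessments <- function(latent, cfg, seed) {
  study_days <- cfg$study_weeks * 7
  visit_days <- seq(0, study_days, by = cfg$visit_interval_days)
  all_days <- 0:study_days
  sat_days <- all_days[as.POSIXlt(cfg$start_date + all_days)$wday == 6]
  n_sur <- length(sat_days)
  p_complete <- if (n_sur == 1) cfg$survey_p_first else
    seq(cfg$survey_p_first, cfg$survey_p_last, length.out = n_sur)

  visits <- list(); surveys <- list()
  for (sid in unique(latent$subject)) {
    li <- latent[latent$subject == sid, ]
    sev <- li$severity[order(li$day)]
    last_day <- li$last_day[1]
    s_visit <- derive_seed(seed, sid, "visits")
    s_surv <- derive_seed(seed, sid, "surveys")
    vd <- visit_days[visit_days <= last_day]
    visits[[sid]] <- with_seed(s_visit, data.frame(
      subject = sid,
      visit_index = seq_along(vd) - 1L,
      date = format(cfg$start_date + vd),
      madrs = as.integer(clip(round(sev[vd + 1] + rnorm(length(vd), 0, cfg$rater_sd)),
                              0, 60))))
    surveys[[sid]] <- with_seed(s_surv, {
      rows <- list()
      for (k in seq_along(sat_days)) {
        d <- sat_days[k]
        if (d > last_day) next
        delivered <- midnight_ms(cfg$start_date + d, cfg$tz) + 10 * 3600 * 1000
        done <- runif(1) < p_complete[k]
        if (done) {
          delay <- if (runif(1) < cfg$survey_late_prob) sample(1:5, 1) else 0
          comp_day <- min(d + delay, study_days)
          completed <- midnight_ms(cfg$start_date + comp_day, cfg$tz) +
            (10 + runif(1, 0, 8)) * 3600 * 1000
          total <- as.integer(clip(round(cfg$phq_slope * sev[comp_day + 1] +
                                           cfg$phq_intercept +
                                           rnorm(1, 0, cfg$phq_sd)), 0, 24))
          items <- phq_items(total)
        } else {
          completed <- NA_real_
          total <- NA_integer_
          items <- rep(NA_integer_, 8)
        }
        rows[[k]] <- data.frame(
          subject = sid, delivered = delivered, completed = completed,
          instrument = "PHQ8",
          q1 = items[1], q2 = items[2], q3 = items[3], q4 = items[4],
          q5 = items[5], q6 = items[6], q7 = items[7], q8 = items[8],
          total = total)
      }
      do.call(rbind, rows)
    })
  }
  list(visits = do.call(rbind, c(visits, make.row.names = FALSE)),
       surveys = do.call(rbind, c(surveys, make.row.names = FALSE)))
}

# Largest-remainder allocation of a PHQ-8 total to 8 items in [0,3].
phq_items <- function(total) {
  base <- total %/% 8L
  rem <- total %% 8L
  items <- rep(base, 8L)
  if (rem > 0) items[seq_len(rem)] <- items[seq_len(rem)] + 1L
  as.integer(items)
}

#' Simulate a full synthetic cohort
#'
#' Generates a complete study dataset with known parameters: demographics,
#' subject-level latent severity trajectories (AR(1) around a subject anchor
#' drawn from the group baseline distribution), biweekly MADRS visits and
#' weekly PHQ-8 surveys, duty-cycled GPS and accelerometer streams with
#' shared phone-outage gaps, Android call logs, and exact per-day ground
#' truth for the mobility and activity metrics. Deterministic given the
#' config (including its seed).
#'
#' @param config a [sim_config()].
#' @return An object of class `"cohort"`: a list with elements
#'   `demographics`, `visits`, `surveys`, `calls`, `gps`, `accel` (the last
#'   three named lists of per-subject data.frames for the sensors), `truth`
#'   (per subject-day ground-truth metrics incl. latent severity), `outages`,
#'   `home` (per-subject true home lon/lat and planar origin), and `config`.
#' @export
simulate_cohort <- function(config) {
  cfg <- validate_sim_config(config)
  sev_par <- group_severity_params(cfg)
  study_days <- cfg$study_weeks * 7
  groups <- rep(names(cfg$n_per_group), cfg$n_per_group)
  n <- length(groups)
  if (n == 0) stop("invalid sim_config field 'n_per_group': no subjects")
  ids <- sprintf("S%03d", seq_len(n))
  seed <- cfg$seed

  demog <- with_seed(derive_seed(seed, "demographics"), data.frame(
    subject = ids,
    age = as.integer(clip(round(rnorm(n, 43, 12)), 18, 75)),
    sex = sample(c("F", "M"), n, replace = TRUE, prob = c(0.63, 0.37)),
    diagnosis = groups,
    timezone = cfg$tz,
    os = sample(c("Android", "iOS"), n, replace = TRUE, prob = c(0.46, 0.54))))

  n_drop <- round(cfg$dropout_frac * n)
  dropouts <- with_seed(derive_seed(seed, "dropout"),
                        sample(ids, n_drop))
  last_day <- ifelse(ids %in% dropouts, cfg$visit_interval_days, study_days)
  names(last_day) <- ids

  # latent severity paths
  latent <- list()
  for (i in seq_len(n)) {
    sp <- sev_par[[groups[i]]]
    latent[[i]] <- with_seed(derive_seed(seed, ids[i], "severity"), {
      anchor <- rnorm(1, sp$mu, sp$sigma_between)
      x <- numeric(study_days + 1)
      x[1] <- anchor + rnorm(1, 0, sp$sigma_within)
      innov_sd <- sp$sigma_within * sqrt(1 - cfg$ar_phi^2)
      for (d in seq_len(study_days))
        x[d + 1] <- anchor + cfg$ar_phi * (x[d] - anchor) + rnorm(1, 0, innov_sd)
      data.frame(subject = ids[i], day = 0:study_days,
                 severity = clip(x, 0, 60), last_day = unname(last_day[i]))
    })
  }
  latent <- do.call(rbind, c(latent, make.row.names = FALSE))

  assess <- simulate_assessments(latent, cfg, derive_seed(seed, "assessments"))

  # per-subject geography
  home <- with_seed(derive_seed(seed, "geography"), data.frame(
    subject = ids,
    lat0 = 42.36 + runif(n, -0.5, 0.5),
    lon0 = -71.06 + runif(n, -0.5, 0.5)))

  gps_grid <- local({
    p <- cfg$gps_on_s + cfg$gps_off_s
    t <- seq(0, SEC_PER_DAY - 1, by = cfg$gps_sample_s)
    t[t %% p < cfg$gps_on_s]
  })

  traj_par <- cfg[c("trip_rate", "beta_trips", "beta_away", "speed_mps",
                    "away_pause_s")]
  gps <- list(); accel <- list(); calls <- list(); truth <- list()
  outages_all <- list()
  for (i in seq_len(n)) {
    sid <- ids[i]
    days <- 0:last_day[i]
    dates <- cfg$start_date + days
    sev_i <- latent$severity[latent$subject == sid]

    anchors <- with_seed(derive_seed(seed, sid, "anchors"), {
      k <- if (cfg$n_anchor_range[2] == 0) 0L else
        sample(seq(cfg$n_anchor_range[1], cfg$n_anchor_range[2]), 1)
      if (k == 0) matrix(numeric(0), ncol = 2) else {
        r <- runif(k, cfg$anchor_dist_range[1], cfg$anchor_dist_range[2])
        th <- runif(k, 0, 2 * pi)
        cbind(r * cos(th), r * sin(th))
      }
    })

    day_gps <- vector("list", length(days))
    day_accel <- vector("list", length(days))
    day_truth <- vector("list", length(days))
    for (j in seq_along(days)) {
      d <- days[j]
      segs <- simulate_day_trajectory(c(0, 0), anchors, sev_i[d + 1], traj_par,
                                      derive_seed(seed, sid, "traj", d))
      pos <- sample_path(segs, gps_grid)
      noisy <- with_seed(derive_seed(seed, sid, "gpsnoise", d), {
        m <- length(gps_grid)
        cbind(pos[, 1] + rnorm(m, 0, cfg$gps_noise_m),
              pos[, 2] + rnorm(m, 0, cfg$gps_noise_m),
              rlnorm(m, log(15), 0.4))
      })
      day_gps[[j]] <- cbind(midnight_ms(dates[j], cfg$tz) + gps_grid * 1000,
                            noisy)
      acc <- simulate_accel_day(dates[j], sev_i[d + 1], cfg,
                                derive_seed(seed, sid, "accel", d))
      day_accel[[j]] <- as.matrix(acc$samples)
      tr <- truth_from_segments(segs, c(0, 0))
      day_truth[[j]] <- data.frame(
        subject = sid, date = dates[j],
        day_type = day_type(dates[j]),
        severity = sev_i[d + 1],
        distance_m = tr$distance_m, home_time_min = tr$home_time_min,
        radius_gyration_m = tr$radius_gyration_m,
        max_diameter_m = tr$max_diameter_m,
        max_home_dist_m = tr$max_home_dist_m,
        pause_fraction = tr$pause_fraction,
        active_fraction = mean(acc$active_minutes))
    }

    gm <- do.call(rbind, day_gps)
    # planar -> geographic about the subject's home
    lat <- home$lat0[i] + (gm[, 3] / EARTH_R) * 180 / pi
    lon <- home$lon0[i] + gm[, 2] /
      (EARTH_R * cos(home$lat0[i] * pi / 180)) * 180 / pi
    gps_df <- data.frame(timestamp = gm[, 1], latitude = lat, longitude = lon,
                         accuracy = gm[, 4])
    am <- do.call(rbind, day_accel)
    accel_df <- data.frame(timestamp = am[, 1], x = am[, 2], y = am[, 3],
                           z = am[, 4])

    out_i <- draw_outages(dates, cfg$outage_prob, cfg$outage_mean_h, cfg$tz,
                          derive_seed(seed, sid, "outages"))
    gps[[sid]] <- apply_outages(gps_df, out_i)
    accel[[sid]] <- apply_outages(accel_df, out_i)
    if (nrow(out_i)) out_i$subject <- sid
    outages_all[[sid]] <- out_i
    truth[[sid]] <- do.call(rbind, day_truth)

    rate <- if (groups[i] == names(cfg$n_per_group)[1]) cfg$call_rate_hc else
      cfg$call_rate_other
    calls[[sid]] <- with_seed(derive_seed(seed, sid, "calls"), {
      cnt <- rpois(length(days), rate)
      tot <- sum(cnt)
      if (tot == 0) NULL else {
        day_rep <- rep(dates, cnt)
        w <- 1 / seq_len(cfg$contact_pool_size)
        who <- sample.int(cfg$contact_pool_size, tot, replace = TRUE,
                          prob = w / sum(w))
        data.frame(
          subject = sid,
          timestamp = midnight_ms(day_rep, cfg$tz) +
            runif(tot, 7 * 3600, 23 * 3600) * 1000,
          direction = sample(c("outgoing", "incoming", "missed"), tot,
                             replace = TRUE, prob = c(0.45, 0.45, 0.10)),
          hashed_number = sprintf("h%04x%04x", i, who))
      }
    })
    if (!is.null(calls[[sid]]))
      calls[[sid]] <- calls[[sid]][order(calls[[sid]]$timestamp), ]
  }

  structure(list(
    demographics = demog,
    visits = assess$visits,
    surveys = assess$surveys,
    calls = do.call(rbind, c(calls[!vapply(calls, is.null, logical(1))],
                             make.row.names = FALSE)),
    gps = gps,
    accel = accel,
    truth = do.call(rbind, c(truth, make.row.names = FALSE)),
    outages = do.call(rbind, c(outages_all, make.row.names = FALSE)),
    home = home,
    config = cfg), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d subjects (%s), %d visits, %d survey rows\n",
              nrow(x$demographics),
              paste(sprintf("%s=%d", names(table(x$demographics$diagnosis)),
                            table(x$demographics$diagnosis)), collapse = ", "),
              nrow(x$visits), nrow(x$surveys)))
  cat(sprintf("  GPS rows: %s; accel rows: %s; truth days: %d\n",
              format(sum(vapply(x$gps, nrow, 1L)), big.mark = ","),
              format(sum(vapply(x$accel, nrow, 1L)), big.mark = ","),
              nrow(x$truth)))
  invisible(x)
}
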