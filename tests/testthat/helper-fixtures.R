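# Shared fixtures, built once per test run.

.fixtures <- new.env()

# Small but complete cohort: 4 groups x 2 subjects, 3 weeks.
small_cohort <- function() {
  if (is.null(.fixtures$cohort)) {
    cfg <- sim_config(n_per_group = c(HC = 2, MDD = 2, BP = 2, SCZ = 2),
                      baseline_means = c(HC = 0.7, MDD = 20, BP = 9.7,
                                         SCZ = 6.2),
                      baseline_sds = c(HC = 1.2, MDD = 12.7, BP = 10.6,
                                       SCZ = 5.4),
                      study_weeks = 4, outage_prob = 0.1, dropout_frac = 0,
                      seed = 42)
    .fixtures$cohort <- simulate_cohort(cfg)
  }
  .fixtures$cohort
}

small_features <- function() {
  if (is.null(.fixtures$features))
    .fixtures$features <- extract_features(small_cohort(),
                                           mobility_config(seed = 42))
  .fixtures$features
}

small_table <- function() {
  if (is.null(.fixtures$table))
    .fixtures$table <- analysis_table(small_cohort(), small_features(),
                                      mobility_config(seed = 42))
  .fixtures$table
}

# Uniform 1 Hz GPS day at a fixed position (lat/lon degrees), for duty-cycle
# and completeness arithmetic.
uniform_gps_day <- function(date = as.Date("2023-01-02"), lat = 42.36,
                            lon = -71.06) {
  ts <- as.numeric(date) * 86400000 + seq(0, 86399) * 1000
  data.frame(timestamp = ts, latitude = lat, longitude = lon, accuracy = 10)
}

# Planar stream straight from x/y coordinates (already projected).
planar_stream <- function(t_s, x, y, day = as.Date("2023-01-02")) {
  data.frame(timestamp = (as.numeric(day) * 86400 + t_s) * 1000, x = x, y = y)
}

# Analysis-like table drawn from a known linear mixed model:
# madrs = beta0 + beta[phq8]*phq8 + beta[baseline]*baseline + b_i + e.
lmm_toy <- function(n_subjects = 40, n_visits = 4, beta = c(2, 1.5, 0.6),
                    sigma_b = 3, sigma_e = 4, seed = 1) {
  withr::with_seed(seed, {
    subj <- sprintf("T%02d", seq_len(n_subjects))
    b <- rnorm(n_subjects, 0, sigma_b)
    rows <- do.call(rbind, lapply(seq_len(n_subjects), function(i) {
      phq <- runif(n_visits, 0, 24)
      base <- runif(1, 0, 40)
      data.frame(subject = subj[i], visit_index = seq_len(n_visits),
                 phq8 = phq, baseline_madrs = base,
                 madrs = beta[1] + beta[2] * phq + beta[3] * base + b[i] +
                   rnorm(n_visits, 0, sigma_e))
    }))
    rows
  })
}
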