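# Package-wide constants (collated first).

MS_PER_DAY <- 86400000
SEC_PER_DAY <- 86400
EARTH_R <- 6371000

# The 14 GPS-based daily mobility features.
GPS_FEATURES <- c("n_sig_locations", "home_time_min", "distance_m",
                  "max_diameter_m", "max_home_dist_m", "radius_gyration_m",
                  "mean_flight_len_m", "sd_flight_len_m",
                  "mean_flight_dur_s", "sd_flight_dur_s", "pause_prob",
                  "location_entropy", "circadian_routine",
                  "weekend_weekday_routine")

# Daily feature families aggregated weekly by day type (14 GPS + activity).
FEATURE_FAMILIES <- c(GPS_FEATURES, "activity_level")
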