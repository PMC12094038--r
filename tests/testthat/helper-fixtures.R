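# fixture builders shared across test files; everything is generated in code

t0_utc <- as.POSIXct("2022-06-01 00:00:00", tz = "UTC")

# a single-cow trace on a 5-min grid; `values` recycled over the grid
make_trace <- function(values, n_days = 14, step_min = 5, cow_id = "c1",
                       start = t0_utc) {
  n <- n_days * 1440 / step_min
  data.frame(cow_id = cow_id,
             timestamp = start + seq(0, by = step_min * 60, length.out = n),
             temp_c = rep_len(values, n), stringsAsFactors = FALSE)
}

# visit log from start minutes / durations (minutes) for one cow
make_visits <- function(start_min, dur_min, intake, cow_id = "c1",
                        start = t0_utc) {
  data.frame(cow_id = cow_id,
             visit_start = start + start_min * 60,
             visit_end = start + (start_min + dur_min) * 60,
             intake_kg = intake, stringsAsFactors = FALSE)
}

# constant-THI weather for one station over a date span
make_weather <- function(t_mean, rh, from, to, station = "st1") {
  dates <- seq(as.Date(from), as.Date(to), by = "1 day")
  data.frame(station = station, date = dates,
             t_mean_c = rep_len(t_mean, length(dates)),
             rh_pct = rep_len(rh, length(dates)), stringsAsFactors = FALSE)
}

# efficiency records with exactly controlled covariates
make_records <- function(n, n_cohorts = 4, seed = 1, noise_sd = 0,
                         b = c(0.37, 0.10, 0.30), cohort_means = NULL) {
  set.seed(seed)
  cohort <- rep_len(paste0("coh", seq_len(n_cohorts)), n)
  if (is.null(cohort_means))
    cohort_means <- stats::setNames(rnorm(n_cohorts, 0, 1.5),
                                    paste0("coh", seq_len(n_cohorts)))
  milke <- rnorm(n, 31.4, 5.4)
  mbw <- rnorm(n, 131.7, 12.5)
  dbw <- rnorm(n, 4, 6)
  dmi <- cohort_means[cohort] + b[1] * milke + b[2] * mbw + b[3] * dbw +
    rnorm(n, 0, noise_sd)
  data.frame(cow_id = sprintf("c%04d", seq_len(n)), dmi = as.numeric(dmi),
             milke = milke, mbw = mbw, dbw = dbw,
             dim_class = dim_class(round(runif(n, 60, 195))),
             lact_class = lact_class(sample(1:5, n, replace = TRUE)),
             cohort = cohort,
             station = "st1", stringsAsFactors = FALSE)
}
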