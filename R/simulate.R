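# Synthetic herd generator. Emits the full input schema of the pipeline
# (5-min temperature traces, feeder-visit logs, daily DMI, weekly milk
# composition, sparse BW, station weather, cow metadata) with known ground
# truth, so every downstream stage is testable without external data.

#' Configuration for the synthetic herd generator
#'
#' Defaults encode a mid-lactation research-herd setting: 5-min vaginal
#' temperature sampling over a 14-d trial, a cow-mean temperature of
#' 38.7 degC with 0.11 degC between-cow SD, within-day structure (circadian
#' sinusoid, day-level shifts, sensor noise, 0.0625 degC quantization), a
#' two-component log10-minute inter-visit interval mixture, and a
#' post-prandial temperature dip sized so the measured post-meal change sits
#' near -0.27 degC. DMI is built from cohort, DIM-class and lactation-class
#' effects, the energy sinks (MilkE, metabolic BW, BW change) with
#' coefficients `rfi_true_coefs`, and an injected association
#' `dmi_temp_slope` with the cow's realized mean temperature.
#'
#' @param n_cows,n_stations,n_cohorts herd structure; cohorts are balanced
#'   (sizes differ by at most 1) and assigned round-robin to stations
#' @param trial_days trial length in days
#' @param sampling_interval minutes between temperature records; must divide
#'   1440
#' @param temp_baseline_mean,temp_baseline_sd_between_cows cow-mean
#'   temperature distribution, degC
#' @param circadian_amplitude,circadian_phase_hours 24-h sinusoid, degC /
#'   clock hours of the acrophase
#' @param day_effect_sd SD of day-level whole-day temperature shifts, degC
#' @param residual_sd record-level Gaussian sensor/physiology noise, degC
#' @param quantization_step logger precision, degC
#' @param meal_interval_mixture c(w1, mu1, sigma1, mu2, sigma2) on log10
#'   minutes; component 1 is the short within-meal component
#' @param postmeal_dip_depth,postmeal_dip_halflife exponential post-meal
#'   temperature dip: depth (degC, at meal end) and half-life (minutes); a
#'   negative depth turns the dip into a rise
#' @param dmi_temp_slope injected trial-level association, kg/d per degC of
#'   cow mean temperature
#' @param dmi_temp_slope_daily injected day-level association, kg/d per degC
#'   of daily mean temperature deviation from the cow's mean
#' @param rfi_true_coefs c(b1, b2, b3) for MilkE, metabolic BW and BW change
#' @param dmi_resid_sd SD of the cow-level DMI residual (the true RFI), kg/d
#' @param dmi_daily_sd SD of day-level DMI noise, kg/d
#' @param bw_schedule "daily", "weekly", or "endpoints" (3-d clusters at
#'   start, middle and end of trial)
#' @param bw_meas_sd BW scale measurement noise, kg
#' @param missing_day_prob probability a cow-day of temperature records is
#'   lost (whole-day dropout)
#' @param seed master seed; per-cow substreams are derived from it so a
#'   cow's data do not depend on herd size
#' @return object of class `sim_config`
#' @export
sim_config <- function(n_cows = 300, n_stations = 2, n_cohorts = 12,
                       trial_days = 14, sampling_interval = 5,
                       temp_baseline_mean = 38.7,
                       temp_baseline_sd_between_cows = 0.11,
                       circadian_amplitude = 0.12,
                       circadian_phase_hours = 16,
                       day_effect_sd = 0.087,
                       residual_sd = 0.12,
                       quantization_step = 0.0625,
                       meal_interval_mixture = c(w1 = 0.55, mu1 = 0.55,
                                                 sigma1 = 0.32, mu2 = 2.35,
                                                 sigma2 = 0.30),
                       postmeal_dip_depth = 0.38,
                       postmeal_dip_halflife = 40,
                       dmi_temp_slope = -2.5,
                       dmi_temp_slope_daily = -2.3,
                       rfi_true_coefs = c(b1 = 0.37, b2 = 0.10, b3 = 0.30),
                       dmi_resid_sd = 1.0, dmi_daily_sd = 1.5,
                       bw_schedule = c("endpoints", "weekly", "daily"),
                       bw_meas_sd = 5, missing_day_prob = 0.05,
                       seed = 1) {
  cfg <- list(n_cows = as.integer(n_cows), n_stations = as.integer(n_stations),
              n_cohorts = as.integer(n_cohorts),
              trial_days = as.integer(trial_days),
              sampling_interval = as.integer(sampling_interval),
              temp_baseline_mean = temp_baseline_mean,
              temp_baseline_sd_between_cows = temp_baseline_sd_between_cows,
              circadian_amplitude = circadian_amplitude,
              circadian_phase_hours = circadian_phase_hours,
              day_effect_sd = day_effect_sd, residual_sd = residual_sd,
              quantization_step = quantization_step,
              meal_interval_mixture = stats::setNames(
                as.numeric(meal_interval_mixture),
                c("w1", "mu1", "sigma1", "mu2", "sigma2")),
              postmeal_dip_depth = postmeal_dip_depth,
              postmeal_dip_halflife = postmeal_dip_halflife,
              dmi_temp_slope = dmi_temp_slope,
              dmi_temp_slope_daily = dmi_temp_slope_daily,
              rfi_true_coefs = stats::setNames(as.numeric(rfi_true_coefs),
                                               c("b1", "b2", "b3")),
              dmi_resid_sd = dmi_resid_sd, dmi_daily_sd = dmi_daily_sd,
              bw_schedule = match.arg(bw_schedule),
              bw_meas_sd = bw_meas_sd,
              missing_day_prob = missing_day_prob,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  mx <- cfg$meal_interval_mixture
  ok <- cfg$n_cows >= 1L && cfg$trial_days >= 1L && cfg$n_stations >= 1L &&
    cfg$n_cohorts >= 1L && cfg$sampling_interval >= 1L &&
    1440L %% cfg$sampling_interval == 0L &&
    cfg$quantization_step > 0 &&
    mx["w1"] > 0 && mx["w1"] < 1 && mx["mu1"] < mx["mu2"] &&
    mx["sigma1"] > 0 && mx["sigma2"] > 0 &&
    cfg$temp_baseline_sd_between_cows >= 0 && cfg$residual_sd >= 0 &&
    cfg$day_effect_sd >= 0 && cfg$circadian_amplitude >= 0 &&
    cfg$postmeal_dip_halflife > 0 &&
    cfg$missing_day_prob >= 0 && cfg$missing_day_prob < 1 &&
    cfg$dmi_resid_sd >= 0 && cfg$dmi_daily_sd >= 0 && cfg$bw_meas_sd >= 0
  if (!isTRUE(ok)) stop_param("invalid simulation configuration")
  invisible(cfg)
}

#' Analytic true meal criterion of a configuration
#'
#' The intersection of the two weighted interval-mixture component densities
#' on the log10-minute scale, exponentiated to minutes. This is the
#' ground-truth value the estimated criterion should recover.
#'
#' @param config a [sim_config()] (or a bare 5-number mixture vector)
#' @return minutes
#' @export
true_meal_criterion <- function(config) {
  mx <- if (inherits(config, "sim_config")) config$meal_interval_mixture
        else stats::setNames(as.numeric(config),
                             c("w1", "mu1", "sigma1", "mu2", "sigma2"))
  10^mixture_intersection(mx["w1"], mx["mu1"], mx["sigma1"],
                          1 - mx["w1"], mx["mu2"], mx["sigma2"])
}

#' Draw inter-visit intervals from a log10-scale Gaussian mixture
#'
#' @param mixture c(w1, mu1, sigma1, mu2, sigma2) on log10 minutes; w1 = 1
#'   collapses to the single short component
#' @param n number of intervals, >= 1
#' @param seed integer seed
#' @return n positive interval lengths in minutes
#' @export
simulate_visit_intervals <- function(mixture, n, seed = 1) {
  mx <- stats::setNames(as.numeric(mixture),
                        c("w1", "mu1", "sigma1", "mu2", "sigma2"))
  if (any(!is.finite(mx)) || mx["w1"] <= 0 || mx["w1"] > 1 ||
      mx["sigma1"] <= 0 || mx["sigma2"] <= 0 ||
      (mx["w1"] < 1 && mx["mu1"] >= mx["mu2"]))
    stop_param("invalid mixture parameters")
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop_param("n must be >= 1")
  n <- as.integer(n)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  comp1 <- stats::runif(n) < mx["w1"]
  x <- ifelse(comp1, stats::rnorm(n, mx["mu1"], mx["sigma1"]),
              stats::rnorm(n, mx["mu2"], mx["sigma2"]))
  10^x
}

# deterministic components of a trace on a minute grid (no noise, no
# quantization): circadian sinusoid plus summed post-meal dips
trace_signal <- function(tmin, baseline, day_effects, meal_end_min, config) {
  day_idx <- pmin(floor(tmin / 1440) + 1L, length(day_effects))
  hour <- (tmin %% 1440) / 60
  vals <- baseline + day_effects[day_idx] +
    config$circadian_amplitude *
    sin(2 * pi * (hour - config$circadian_phase_hours) / 24 + pi / 2)
  if (length(meal_end_min) && config$postmeal_dip_depth != 0) {
    h <- config$postmeal_dip_halflife
    horizon <- 15 * h
    for (me in meal_end_min) {
      i0 <- findInterval(me, tmin)        # dip starts AT the meal end
      if (i0 == 0L || tmin[i0] < me) i0 <- i0 + 1L
      if (i0 > length(tmin)) next
      i1 <- min(findInterval(me + horizon, tmin), length(tmin))
      if (i1 < i0) next
      dt <- tmin[i0:i1] - me
      vals[i0:i1] <- vals[i0:i1] - config$postmeal_dip_depth * 2^(-dt / h)
    }
  }
  vals
}

#' Simulate one cow's 5-min temperature trace
#'
#' Trace = cow baseline + day-level shifts + circadian sinusoid (peak at
#' `circadian_phase_hours`) + one exponential-decay dip per meal (depth
#' `postmeal_dip_depth` at the meal end, half-life `postmeal_dip_halflife`)
#' + Gaussian noise, quantized to `quantization_step`.
#'
#' @param baseline cow latent mean temperature, degC
#' @param meal_end_min meal end times in minutes since trial start (may be
#'   empty)
#' @param config a [sim_config()]
#' @param seed integer seed for the record noise and day effects
#' @param cow_id identifier stored in the output
#' @param trial_start POSIXct of trial day 1, 00:00
#' @return data.frame (cow_id, timestamp, temp_c)
#' @export
simulate_temperature_trace <- function(baseline, meal_end_min, config,
                                       seed = 1, cow_id = "cow",
                                       trial_start = as.POSIXct(
                                         "2022-06-01 00:00:00", tz = "UTC")) {
  validate_sim_config(config)
  if (length(meal_end_min) &&
      any(meal_end_min < 0 | meal_end_min > config$trial_days * 1440))
    stop_param("meals must fall within the trial window")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  tmin <- seq(0, config$trial_days * 1440 - config$sampling_interval,
              by = config$sampling_interval)
  day_effects <- stats::rnorm(config$trial_days, 0, config$day_effect_sd)
  vals <- trace_signal(tmin, baseline, day_effects, meal_end_min, config)
  vals <- vals + stats::rnorm(length(tmin), 0, config$residual_sd)
  data.frame(cow_id = cow_id, timestamp = trial_start + tmin * 60,
             temp_c = quantize(vals, config$quantization_step),
             stringsAsFactors = FALSE)
}

# visit process for one cow over the whole trial: durations lognormal,
# gaps drawn from the interval mixture; returns start/end minutes and raw
# intake weights (rescaled to daily DMI later). Uses the active RNG stream.
sim_visits_minutes <- function(config) {
  mx <- config$meal_interval_mixture
  total <- config$trial_days * 1440
  # expected visit cycle length (lognormal component means on log10 scale)
  l10 <- log(10)
  m_int <- mx["w1"] * exp(mx["mu1"] * l10 + (mx["sigma1"] * l10)^2 / 2) +
    (1 - mx["w1"]) * exp(mx["mu2"] * l10 + (mx["sigma2"] * l10)^2 / 2)
  n_draw <- max(50L, ceiling(2 * total / (m_int + 4)) + 50L)
  dur <- pmin(pmax(stats::rlnorm(n_draw, log(4), 0.5), 0.5), 30)
  comp1 <- stats::runif(n_draw) < mx["w1"]
  gap <- 10^ifelse(comp1, stats::rnorm(n_draw, mx["mu1"], mx["sigma1"]),
                   stats::rnorm(n_draw, mx["mu2"], mx["sigma2"]))
  t0 <- stats::runif(1, 5 * 60, 8 * 60)
  starts <- t0 + cumsum(c(0, dur[-n_draw] + gap[-n_draw]))
  keep <- starts + dur <= total
  starts <- starts[keep]; dur <- dur[keep]
  raw <- dur * 0.09 * stats::rlnorm(length(dur), 0, 0.3)
  data.frame(start_min = starts, end_min = starts + dur, raw_intake = raw)
}

#' Generate a complete synthetic herd dataset
#'
#' Produces every input table the pipeline consumes, plus a `truth` element
#' holding the generating values. The covariates that enter the
#' DMI-generating model (MilkE, metabolic BW, BW change) are the realized
#' trait values computed from the generated measurement tables with the
#' package's own trait functions, so `rfi_true_coefs` are recoverable by
#' [compute_rfi()] irrespective of the BW measurement schedule and noise.
#' With `traces = FALSE` the 5-min traces and visit logs are skipped and the
#' injected temperature associations act on the latent cow means and
#' day-level shifts (reported in `cows$mean_temp` and the `daily_temp`
#' table); this mode exists for replicate-heavy calibration studies.
#'
#' @param config a [sim_config()]
#' @param traces generate 5-min temperature traces and visit logs
#'   (default TRUE)
#' @return object of class `synthetic_herd`: list with temps, visits,
#'   dmi_daily, milk_weekly, bw, weather, cows, daily_temp (traces = FALSE
#'   only), truth, config
#' @export
simulate_herd <- function(config = sim_config(), traces = TRUE) {
  validate_sim_config(config)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))

  n <- config$n_cows
  trial_start <- as.POSIXct("2022-06-01 00:00:00", tz = "UTC")
  date1 <- as.Date("2022-06-01")
  cohort <- rep_len(seq_len(config$n_cohorts), n)
  station <- (cohort - 1L) %% config$n_stations + 1L
  cow_id <- sprintf("cow%04d", seq_len(n))

  # herd-level structure from the master seed
  set.seed(config$seed)
  cohort_eff <- stats::rnorm(config$n_cohorts, -1.0, 1.5)
  dim_eff <- seq(0, 1.2, length.out = 9)
  lact_eff <- c(0, 1.8, 2.4, 2.7)
  pad <- 5L
  wdates <- seq(date1 - pad, date1 + config$trial_days - 1L + pad, by = "1 day")
  st_mean_t <- seq(16, 24, length.out = config$n_stations)
  weather <- do.call(rbind, lapply(seq_len(config$n_stations), function(s) {
    nd <- length(wdates)
    tt <- numeric(nd); rh <- numeric(nd)
    tt[1] <- st_mean_t[s] + stats::rnorm(1, 0, 2)
    rh[1] <- 65 + stats::rnorm(1, 0, 8)
    for (d in 2:nd) {
      tt[d] <- st_mean_t[s] + 0.7 * (tt[d - 1] - st_mean_t[s]) +
        stats::rnorm(1, 0, 2)
      rh[d] <- 65 + 0.7 * (rh[d - 1] - 65) + stats::rnorm(1, 0, 8)
    }
    data.frame(station = paste0("st", s), date = wdates,
               t_mean_c = round(tt, 2),
               rh_pct = round(pmin(pmax(rh, 20), 100), 1))
  }))

  mx <- config$meal_interval_mixture
  crit_true <- true_meal_criterion(config)
  b <- config$rfi_true_coefs
  T_ <- config$trial_days
  n_weeks <- ceiling(T_ / 7)
  mid <- max(2L, ceiling(T_ / 2))
  bw_days <- switch(config$bw_schedule,
    daily = seq_len(T_),
    weekly = unique(c(seq(1L, T_, by = 7L), T_)),
    endpoints = sort(unique(pmin(pmax(c(1:3, (mid - 1):(mid + 1),
                                        (T_ - 2):T_), 1L), T_))))
  n_bw <- length(bw_days)

  temps <- vector("list", n); visits <- vector("list", n)
  dmi_mat <- matrix(NA_real_, T_, n)
  dailyT_mat <- matrix(NA_real_, T_, n)
  fat_m <- pro_m <- lac_m <- yld_m <- matrix(NA_real_, n_weeks, n)
  bw_m <- matrix(NA_real_, n_bw, n)
  parity_v <- mid_dim_v <- integer(n)
  latent_v <- realized_v <- milke_v <- mbw_v <- dbw_v <- dmi_v <-
    e_v <- numeric(n)
  tmin_grid <- seq(0, T_ * 1440 - config$sampling_interval,
                   by = config$sampling_interval)

  # mirrors impute_bw() + metabolic_bw() + delta_bw() on bare vectors
  bw_traits <- function(day, bw) {
    mxd <- mean(day); myb <- mean(bw)
    sxx <- sum((day - mxd)^2)
    sl <- sum((day - mxd) * (bw - myb)) / sxx
    a <- myb - sl * mxd
    series <- a + sl * seq_len(T_)
    hit <- match(seq_len(T_), day)
    series[!is.na(hit)] <- bw[hit[!is.na(hit)]]
    list(mbw = mean(series)^0.75, dbw = series[T_] - series[1L])
  }

  for (i in seq_len(n)) {
    set.seed(derive_seed(config$seed, i))
    latent <- stats::rnorm(1, config$temp_baseline_mean,
                           config$temp_baseline_sd_between_cows)
    day_eff <- stats::rnorm(T_, 0, config$day_effect_sd)
    parity_v[i] <- sample(1:6, 1, prob = c(.35, .27, .18, .12, .05, .03))
    mid_dim_v[i] <- round(stats::runif(1, 60, 195))
    bw0 <- max(stats::rnorm(1, 650, 60), 420)
    bw_slope <- stats::rnorm(1, 0.3, 0.4)

    # milk composition: cow level + weekly noise
    fat_c <- stats::rnorm(1, 4.0, 0.35); pro_c <- stats::rnorm(1, 3.15, 0.18)
    lac_c <- stats::rnorm(1, 4.85, 0.10); yld_c <- max(stats::rnorm(1, 40, 6), 8)
    fat_m[, i] <- pmax(round(fat_c + stats::rnorm(n_weeks, 0, .12), 2), 1)
    pro_m[, i] <- pmax(round(pro_c + stats::rnorm(n_weeks, 0, .05), 2), 1)
    lac_m[, i] <- pmax(round(lac_c + stats::rnorm(n_weeks, 0, .04), 2), 3)
    yld_m[, i] <- pmax(round(yld_c + stats::rnorm(n_weeks, 0, 1.5), 1), 5)

    # BW observations on the configured schedule
    bw_m[, i] <- round(bw0 + bw_slope * (bw_days - 1) +
                         stats::rnorm(n_bw, 0, config$bw_meas_sd), 1)

    # realized covariates, computed from the emitted (rounded) tables
    milke_v[i] <- mean(milk_energy(fat_m[, i], pro_m[, i], lac_m[, i],
                                   yld_m[, i]))
    bt <- bw_traits(bw_days, bw_m[, i])
    milke_i <- milke_v[i]; mbw_i <- bt$mbw; dbw_i <- bt$dbw
    mbw_v[i] <- mbw_i; dbw_v[i] <- dbw_i

    # temperatures (and visits/meals when traces are on)
    if (traces) {
      vis <- sim_visits_minutes(config)
      vdf <- data.frame(cow_id = cow_id[i],
                        visit_start = trial_start + vis$start_min * 60,
                        visit_end = trial_start + vis$end_min * 60,
                        intake_kg = vis$raw_intake, stringsAsFactors = FALSE)
      meals_i <- merge_visits_to_meals(vdf, crit_true)
      meal_ends <- as.numeric(difftime(meals_i$end, trial_start,
                                       units = "mins"))
      vals <- trace_signal(tmin_grid, latent, day_eff, meal_ends, config)
      vals <- quantize(vals + stats::rnorm(length(tmin_grid), 0,
                                           config$residual_sd),
                       config$quantization_step)
      day_of <- floor(tmin_grid / 1440) + 1L
      daily_means <- as.numeric(tapply(vals, factor(day_of, levels = seq_len(T_)),
                                       mean))
      trial_mean_i <- mean(vals)
    } else {
      vdf <- NULL
      daily_means <- latent + day_eff
      trial_mean_i <- latent
    }

    # DMI: cohort/DIM/lact structure + energy sinks + injected temperature
    # association + cow residual (the true RFI)
    e_i <- stats::rnorm(1, 0, config$dmi_resid_sd)
    dmi_i <- cohort_eff[cohort[i]] + dim_eff[as.integer(dim_class(mid_dim_v[i]))] +
      lact_eff[as.integer(lact_class(parity_v[i]))] +
      b["b1"] * milke_i + b["b2"] * mbw_i + b["b3"] * dbw_i +
      config$dmi_temp_slope * (trial_mean_i - config$temp_baseline_mean) + e_i
    eps_day <- stats::rnorm(T_, 0, config$dmi_daily_sd)
    dmi_days <- dmi_i +
      config$dmi_temp_slope_daily * (daily_means - mean(daily_means)) + eps_day
    dmi_days <- pmax(dmi_days, 2)
    dmi_mat[, i] <- round(dmi_days, 3)
    dailyT_mat[, i] <- daily_means
    latent_v[i] <- latent; realized_v[i] <- trial_mean_i
    dmi_v[i] <- dmi_i; e_v[i] <- e_i

    if (traces) {
      # rescale visit intakes so each day's total matches that day's DMI
      vday <- floor(vis$start_min / 1440) + 1L
      day_tot <- tapply(vdf$intake_kg, vday, sum)
      fac <- dmi_days[vday] / as.numeric(day_tot[as.character(vday)])
      vdf$intake_kg <- round(vdf$intake_kg * fac, 4)
      visits[[i]] <- vdf
      # whole-day dropout applies to the emitted trace only
      drop_day <- stats::runif(T_) < config$missing_day_prob
      keep_rec <- !drop_day[day_of]
      temps[[i]] <- data.frame(cow_id = cow_id[i],
                               timestamp = trial_start + tmin_grid[keep_rec] * 60,
                               temp_c = vals[keep_rec], stringsAsFactors = FALSE)
    }
  }

  dates <- date1 + seq_len(T_) - 1L
  cows <- data.frame(cow_id = cow_id, station = paste0("st", station),
                     cohort = sprintf("coh%02d", cohort), parity = parity_v,
                     midpoint_dim = mid_dim_v, stringsAsFactors = FALSE)
  if (!traces) cows$mean_temp <- realized_v
  dmi_daily <- data.frame(cow_id = rep(cow_id, each = T_),
                          day = rep(seq_len(T_), n),
                          date = rep(dates, n),
                          dmi_kg = as.numeric(dmi_mat),
                          stringsAsFactors = FALSE)
  milk_weekly <- data.frame(cow_id = rep(cow_id, each = n_weeks),
                            week = rep(seq_len(n_weeks), n),
                            fat_pct = as.numeric(fat_m),
                            protein_pct = as.numeric(pro_m),
                            lactose_pct = as.numeric(lac_m),
                            milk_yield_kg = as.numeric(yld_m),
                            stringsAsFactors = FALSE)
  bw_tab <- data.frame(cow_id = rep(cow_id, each = n_bw),
                       day = rep(bw_days, n), bw_kg = as.numeric(bw_m),
                       stringsAsFactors = FALSE)
  daily_temp <- if (!traces)
    data.frame(cow_id = rep(cow_id, each = T_), date = rep(dates, n),
               mean_temp = as.numeric(dailyT_mat), stringsAsFactors = FALSE)
  else NULL
  per_cow <- data.frame(cow_id = cow_id, latent_mean_temp = latent_v,
                        realized_mean_temp = realized_v, milke = milke_v,
                        mbw = mbw_v, dbw = dbw_v, dmi = dmi_v,
                        true_rfi = e_v, stringsAsFactors = FALSE)
  structure(list(
    temps = if (traces) do.call(rbind, temps) else NULL,
    visits = if (traces) do.call(rbind, visits) else NULL,
    dmi_daily = dmi_daily,
    milk_weekly = milk_weekly,
    bw = bw_tab,
    weather = weather,
    cows = cows,
    daily_temp = daily_temp,
    truth = list(per_cow = per_cow,
                 true_meal_criterion = crit_true,
                 dmi_temp_slope = config$dmi_temp_slope,
                 dmi_temp_slope_daily = config$dmi_temp_slope_daily,
                 rfi_true_coefs = b,
                 cohort_effects = cohort_eff,
                 record_variance_expected = config$residual_sd^2 +
                   config$quantization_step^2 / 12,
                 trial_start = trial_start),
    config = config), class = "synthetic_herd")
}

#' @exportS3Method base::print
print.synthetic_herd <- function(x, ...) {
  cat(sprintf("synthetic herd: %d cows, %d d trial, %d cohorts, %d stations\n",
              x$config$n_cows, x$config$trial_days, x$config$n_cohorts,
              x$config$n_stations))
  cat(sprintf("  temperature records: %s; visits: %s\n",
              if (is.null(x$temps)) "none (cow-level mode)"
              else format(nrow(x$temps), big.mark = ","),
              if (is.null(x$visits)) "none"
              else format(nrow(x$visits), big.mark = ",")))
  cat(sprintf("  true meal criterion: %.2f min\n",
              x$truth$true_meal_criterion))
  invisible(x)
}

#' Write a synthetic herd to the pipeline's CSV input schema
#'
#' Emits temperatures.csv, visits.csv, dmi_daily.csv, milk_weekly.csv,
#' bw.csv, weather.csv, cows.csv and truth.json into `dir`.
#'
#' @param ds a `synthetic_herd`
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(d, f) utils::write.csv(d, file.path(dir, f),
                                          row.names = FALSE)
  if (!is.null(ds$temps)) {
    t2 <- ds$temps; t2$timestamp <- fmt_ts(t2$timestamp)
    wcsv(t2, "temperatures.csv")
  }
  if (!is.null(ds$visits)) {
    v2 <- ds$visits
    v2$visit_start <- fmt_ts(v2$visit_start)
    v2$visit_end <- fmt_ts(v2$visit_end)
    wcsv(v2, "visits.csv")
  }
  wcsv(ds$dmi_daily, "dmi_daily.csv")
  wcsv(ds$milk_weekly, "milk_weekly.csv")
  wcsv(ds$bw, "bw.csv")
  wcsv(ds$weather, "weather.csv")
  wcsv(ds$cows, "cows.csv")
  truth <- ds$truth
  truth$trial_start <- fmt_ts(truth$trial_start)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       dataframe = "columns", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a pipeline input directory
#'
#' Reads the CSV schema written by [write_dataset()] (or supplied by the
#' user). Missing optional files (temperatures, visits, truth) yield NULL
#' elements.
#'
#' @param dir input directory
#' @return list shaped like a `synthetic_herd` (truth present only if
#'   truth.json exists)
#' @export
read_dataset <- function(dir) {
  rcsv <- function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) return(NULL)
    utils::read.csv(p, stringsAsFactors = FALSE)
  }
  temps <- rcsv("temperatures.csv")
  if (!is.null(temps)) temps$timestamp <- parse_ts(temps$timestamp)
  visits <- rcsv("visits.csv")
  if (!is.null(visits)) {
    visits$visit_start <- parse_ts(visits$visit_start)
    visits$visit_end <- parse_ts(visits$visit_end)
  }
  dd <- rcsv("dmi_daily.csv")
  if (!is.null(dd) && "date" %in% names(dd)) dd$date <- as.Date(dd$date)
  weather <- rcsv("weather.csv")
  if (!is.null(weather)) weather$date <- as.Date(weather$date)
  truth <- if (file.exists(file.path(dir, "truth.json")))
    jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  else NULL
  list(temps = temps, visits = visits, dmi_daily = dd,
       milk_weekly = rcsv("milk_weekly.csv"), bw = rcsv("bw.csv"),
       weather = weather, cows = rcsv("cows.csv"), truth = truth)
}
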