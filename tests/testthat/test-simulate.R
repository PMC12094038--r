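test_that("interval draws follow the log10 mixture", {
  # equal-weight symmetric mixture: mean of log10 intervals ~ 1.5
  x <- simulate_visit_intervals(c(0.5, 0.5, 0.25, 2.5, 0.25), 1e4, seed = 1)
  lx <- log10(x)
  se <- sd(lx) / sqrt(length(lx))
  expect_lt(abs(mean(lx) - 1.5), 3 * se)
  expect_true(all(x > 0))
  # reproducible under a fixed seed
  expect_identical(x, simulate_visit_intervals(c(0.5, 0.5, 0.25, 2.5, 0.25),
                                               1e4, seed = 1))
})

test_that("degenerate single-component draws are plain Gaussian on log10 scale", {
  rejections <- 0
  for (s in 1:100) {
    x <- simulate_visit_intervals(c(1, 0.5, 0.25, 2.5, 0.25), 100, seed = s)
    if (shapiro.test(log10(x))$p.value < 0.01) rejections <- rejections + 1
  }
  expect_lte(rejections, 5)  # normality retained in >= 95% of seeds
})

test_that("trace with all variation off is the quantized baseline", {
  cfg <- sim_config(n_cows = 1, residual_sd = 0, circadian_amplitude = 0,
                    day_effect_sd = 0, missing_day_prob = 0)
  tr <- simulate_temperature_trace(38.71, numeric(0), cfg, seed = 1)
  expect_identical(nrow(tr), 14L * 288L)
  expect_true(all(tr$temp_c == quantize(38.71, 0.0625)))
})

test_that("post-meal dip reaches its configured depth and decays", {
  cfg <- sim_config(n_cows = 1, residual_sd = 0, circadian_amplitude = 0,
                    day_effect_sd = 0, postmeal_dip_depth = 0.3,
                    postmeal_dip_halflife = 40)
  meal_end <- 600  # minutes into day 1, on the 5-min grid
  tr <- simulate_temperature_trace(38.7, meal_end, cfg, seed = 2)
  tmin <- as.numeric(difftime(tr$timestamp, tr$timestamp[1], units = "mins"))
  win <- tmin >= meal_end & tmin <= meal_end + 120
  expect_equal(min(tr$temp_c[win]), quantize(38.7 - 0.3, 0.0625),
               tolerance = 1e-9)
  # decay: two half-lives later the dip has shrunk to ~a quarter
  at80 <- tr$temp_c[tmin == meal_end + 80]
  expect_lt(abs(at80 - (38.7 - 0.3 / 4)), 0.0625)
})

test_that("every stored temperature sits on the quantization grid", {
  ds <- simulate_herd(sim_config(n_cows = 3, seed = 5))
  on_grid <- abs(ds$temps$temp_c / 0.0625 - round(ds$temps$temp_c / 0.0625))
  expect_lt(max(on_grid), 1e-9)
})

test_that("noise-only trace variance matches residual plus quantization variance", {
  cfg <- sim_config(n_cows = 1, circadian_amplitude = 0, day_effect_sd = 0,
                    residual_sd = 0.12, missing_day_prob = 0)
  tr <- simulate_temperature_trace(38.7, numeric(0), cfg, seed = 3)
  expected <- 0.12^2 + 0.0625^2 / 12
  expect_lt(abs(var(tr$temp_c) / expected - 1), 0.05)
})

test_that("herd generation is deterministic and balanced", {
  cfg <- sim_config(n_cows = 50, n_cohorts = 4, seed = 7)
  ds1 <- simulate_herd(cfg)
  ds2 <- simulate_herd(cfg)
  expect_identical(ds1, ds2)
  sizes <- table(ds1$cows$cohort)
  expect_identical(length(sizes), 4L)
  expect_lte(max(sizes) - min(sizes), 1)
  # every cow in every table exists in metadata
  for (tab in list(ds1$temps, ds1$visits, ds1$dmi_daily, ds1$milk_weekly,
                   ds1$bw))
    expect_true(all(unique(tab$cow_id) %in% ds1$cows$cow_id))
  # all timestamps inside the trial window
  expect_true(all(ds1$temps$timestamp >= ds1$truth$trial_start))
  expect_true(all(ds1$temps$timestamp <
                    ds1$truth$trial_start + 14 * 86400))
})

test_that("cow-level results are invariant to herd size", {
  big <- simulate_herd(sim_config(n_cows = 40, seed = 9), traces = FALSE)
  small <- simulate_herd(sim_config(n_cows = 10, seed = 9), traces = FALSE)
  expect_equal(small$truth$per_cow, big$truth$per_cow[1:10, ],
               ignore_attr = TRUE)
})

test_that("analytic meal criterion lies between the component modes and matches a grid scan", {
  cfg <- sim_config()
  mx <- cfg$meal_interval_mixture
  crit <- true_meal_criterion(cfg)
  expect_gt(crit, 10^mx["mu1"])
  expect_lt(crit, 10^mx["mu2"])
  grid <- seq(mx["mu1"], mx["mu2"], by = 1e-4)
  dd <- mx["w1"] * dnorm(grid, mx["mu1"], mx["sigma1"]) -
    (1 - mx["w1"]) * dnorm(grid, mx["mu2"], mx["sigma2"])
  expect_lt(abs(log10(crit) - grid[which.min(abs(dd))]), 0.01)
})

test_that("generated DMI carries the injected temperature association", {
  ds <- simulate_herd(sim_config(n_cows = 500, seed = 17), traces = FALSE)
  tc <- ds$truth$per_cow
  f <- lm(dmi ~ latent_mean_temp + cohort,
          data = cbind(tc, cohort = ds$cows$cohort))
  est <- coef(f)["latent_mean_temp"]
  se <- summary(f)$coefficients["latent_mean_temp", 2]
  expect_lt(abs(est - (-2.5)), 2 * se)
})

test_that("config invariants are enforced", {
  expect_error(sim_config(n_cows = 0), "invalid")
  expect_error(sim_config(sampling_interval = 7), "invalid")
  expect_error(sim_config(meal_interval_mixture = c(0.5, 2.5, 0.25, 0.5, 0.25)),
               "invalid")
  expect_error(sim_config(missing_day_prob = 1), "invalid")
  cfg <- sim_config(n_cows = 1)
  expect_error(simulate_temperature_trace(38.7, 14 * 1440 + 10, cfg),
               "trial window")
})

test_that("dataset round-trips through the CSV schema", {
  ds <- simulate_herd(sim_config(n_cows = 4, seed = 19))
  dir <- file.path(tempdir(), "herd_rt")
  write_dataset(ds, dir)
  back <- read_dataset(dir)
  expect_equal(back$temps$temp_c, ds$temps$temp_c)
  expect_identical(back$temps$timestamp, ds$temps$timestamp)
  expect_equal(back$visits$intake_kg, ds$visits$intake_kg)
  expect_equal(back$truth$per_cow$milke, ds$truth$per_cow$milke)
  expect_equal(back$truth$true_meal_criterion, ds$truth$true_meal_criterion)
  unlink(dir, recursive = TRUE)
})
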