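test_that("mixture fit recovers well-separated components", {
  x <- simulate_visit_intervals(c(0.5, 0.5, 0.25, 2.5, 0.25), 1e4, seed = 2)
  fit <- fit_interval_mixture(x, seed = 2)
  expect_true(fit$converged)
  expect_lt(abs(fit$means[1] - 0.5), 0.05)
  expect_lt(abs(fit$means[2] - 2.5), 0.05)
  expect_lt(abs(fit$weights[1] - 0.5), 0.05)
  expect_equal(sum(fit$weights), 1, tolerance = 1e-9)
  # nesting: the 2-component ML fit cannot be beaten by a single Gaussian
  lx <- log10(x)
  sd_mle <- sqrt(mean((lx - mean(lx))^2))
  ll1 <- sum(dnorm(lx, mean(lx), sd_mle, log = TRUE))
  expect_gte(fit$loglik, ll1)
})

test_that("mixture fit agrees with an independent EM implementation", {
  skip_if_not_installed("mclust")
  suppressMessages(library(mclust))  # Mclust needs its namespace attached
  x <- simulate_visit_intervals(c(0.6, 0.4, 0.3, 2.2, 0.4), 5e3, seed = 4)
  fit <- fit_interval_mixture(x, seed = 4)
  mc <- Mclust(log10(x), G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(sort(fit$means), sort(as.numeric(mc$parameters$mean)),
               tolerance = 0.02)
  expect_equal(fit$loglik, mc$loglik, tolerance = 1e-3)
})

test_that("degenerate interval sets are flagged, bad inputs rejected", {
  expect_false(fit_interval_mixture(rep(30, 100))$converged)
  expect_error(fit_interval_mixture(c(rep(10, 60), -1)), "positive")
  expect_error(fit_interval_mixture(rep(10, 10)), "at least 50")
  expect_error(simulate_visit_intervals(c(0.5, 2.5, 0.25, 0.5, 0.25), 10),
               "invalid mixture")
  expect_error(simulate_visit_intervals(c(0.5, 0.5, 0.25, 2.5, 0.25), 0),
               ">= 1")
})

test_that("meal criterion: symmetric case and grid-search oracle", {
  # equal weights and sds: intersection at the midpoint of the means
  fit <- structure(list(weights = c(0.5, 0.5), means = c(0.5, 2.5),
                        sds = c(0.25, 0.25), loglik = 0, n = 100,
                        converged = TRUE), class = "mixture_fit")
  expect_equal(meal_criterion(fit), 10^1.5, tolerance = 1e-6)
  # asymmetric case against a brute-force density-difference grid scan
  w1 <- 0.6; mu <- c(0.4, 2.2); s <- c(0.3, 0.4)
  grid <- seq(mu[1], mu[2], by = 1e-4)
  dd <- w1 * dnorm(grid, mu[1], s[1]) - (1 - w1) * dnorm(grid, mu[2], s[2])
  oracle <- grid[which.min(abs(dd))]
  fit2 <- structure(list(weights = c(w1, 1 - w1), means = mu, sds = s,
                         loglik = 0, n = 100, converged = TRUE),
                    class = "mixture_fit")
  expect_equal(log10(meal_criterion(fit2)), oracle, tolerance = 2e-4)
  expect_error(meal_criterion(structure(list(converged = FALSE),
                                        class = "mixture_fit")), "converge")
})

test_that("no-intersection mixtures raise a diagnostic", {
  # component 2 dominates everywhere between the means
  expect_error(mixture_intersection(0.001, 0.5, 0.25, 0.999, 0.9, 3),
               "dominates|intersection")
})

test_that("visits merge into meals by the strict-gap rule", {
  # gaps of 5 and 30 min at criterion 26.4: first two visits merge
  v <- make_visits(c(0, 15, 55), c(10, 10, 10), c(1, 2, 3))
  m <- merge_visits_to_meals(v, 26.4)
  expect_identical(nrow(m), 2L)
  expect_equal(m$intake_kg, c(3, 3))
  expect_identical(m$n_visits, c(2L, 1L))
  # a gap exactly equal to the criterion does NOT merge
  v2 <- make_visits(c(0, 36.4), c(10, 10), c(1, 1))
  expect_identical(nrow(merge_visits_to_meals(v2, 26.4)), 2L)
  expect_identical(nrow(merge_visits_to_meals(v2, 26.4 + 1e-9)), 1L)
  # single visit is its own meal
  v3 <- make_visits(10, 5, 1.5)
  m3 <- merge_visits_to_meals(v3, 26.4)
  expect_identical(nrow(m3), 1L)
  expect_equal(m3$intake_kg, 1.5)
  expect_equal(m3$start, v3$visit_start)
  expect_equal(m3$end, v3$visit_end)
  expect_error(merge_visits_to_meals(make_visits(c(0, 5), c(10, 5), c(1, 1)),
                                     26.4), "overlap")
})

test_that("criterion limits: one meal per visit vs one block; intake conserved", {
  set.seed(21)
  n <- 40L
  starts <- sort(runif(n, 0, 1440 * 3))
  v <- make_visits(starts, rep(0.5, n), runif(n, 0.1, 2))
  tiny <- merge_visits_to_meals(v, 1e-9)
  expect_identical(nrow(tiny), n)
  huge <- merge_visits_to_meals(v, 1e9)
  expect_identical(nrow(huge), 1L)
  for (m in list(tiny, huge))
    expect_equal(sum(m$intake_kg), sum(v$intake_kg), tolerance = 1e-12)
})

test_that("largest-meal flags: argmax, earliest-start ties, empty days absent", {
  v <- make_visits(c(60, 300, 600, 1500, 1700), c(20, 20, 20, 20, 20),
                   c(3, 5, 2, 4, 4))
  m <- largest_meal_per_day(merge_visits_to_meals(v, 26.4))
  d1 <- m[m$date == as.Date("2022-06-01"), ]
  expect_equal(d1$intake_kg[d1$is_largest_of_day], 5)
  # day 2: tie at 4.0 kg, earlier start wins
  d2 <- m[m$date == as.Date("2022-06-02"), ]
  expect_identical(which(d2$is_largest_of_day), 1L)
  expect_identical(sum(m$is_largest_of_day), 2L)
  expect_false(as.Date("2022-06-03") %in% m$date)
})

test_that("post-meal delta: flat trace, analytic ramp, time-reversal", {
  flat <- make_trace(38.7, n_days = 2)
  meal <- data.frame(start = t0_utc + 600 * 60, end = t0_utc + 630 * 60)
  expect_equal(post_meal_delta(flat, meal)$delta, 0)

  # ramp decreasing 0.01 degC per 5-min record; 30-min meal starting on-grid
  # pre window = records at 590, 595, 600 (center 595); post target 630+20 =
  # 650 lands on a record, window 645/650/655 (center 650); 55 min = 11
  # steps between centers
  n <- 2 * 288
  ramp <- make_trace(38.7, n_days = 2)
  ramp$temp_c <- 40 - 0.01 * (seq_len(n) - 1)
  res <- post_meal_delta(ramp, meal)
  pre_oracle <- mean(40 - 0.01 * (c(590, 595, 600) / 5))
  post_oracle <- mean(40 - 0.01 * (c(645, 650, 655) / 5))
  expect_equal(res$delta, post_oracle - pre_oracle, tolerance = 1e-9)
  expect_equal(res$delta, -0.11, tolerance = 1e-9)

  # reversing the monotone trend negates the delta
  rev_ramp <- ramp
  rev_ramp$temp_c <- rev(ramp$temp_c)
  expect_equal(post_meal_delta(rev_ramp, meal)$delta, -res$delta,
               tolerance = 1e-9)
})

test_that("post-meal delta skips meals without coverage", {
  short <- make_trace(38.7, n_days = 1)
  late_meal <- data.frame(start = t0_utc + 1410 * 60, end = t0_utc + 1430 * 60)
  expect_warning(out <- post_meal_delta(short, late_meal), "coverage|gap")
  expect_null(out)
})

test_that("cow-level post-meal trait averages the largest-meal deltas", {
  ds <- simulate_herd(sim_config(n_cows = 4, seed = 11, missing_day_prob = 0))
  qc <- qc_herd(ds$temps)
  meals <- largest_meal_per_day(
    merge_visits_to_meals(ds$visits, ds$truth$true_meal_criterion))
  pm <- post_meal_deltas(qc$temps, meals)
  expect_true(all(pm$per_cow$cow_id %in% ds$cows$cow_id))
  for (cid in pm$per_cow$cow_id) {
    expect_equal(pm$per_cow$postmeal_delta[pm$per_cow$cow_id == cid],
                 mean(pm$per_meal$delta[pm$per_meal$cow_id == cid]),
                 tolerance = 1e-12)
  }
  expect_equal(pm$per_meal$delta,
               pm$per_meal$post_temp - pm$per_meal$pre_temp)
})
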