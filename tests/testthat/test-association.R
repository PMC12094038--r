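make_assoc_data <- function(n = 400, slope = -2.5, seed = 1, n_cohorts = 4) {
  set.seed(seed)
  cohort <- rep_len(paste0("coh", seq_len(n_cohorts)), n)
  station <- ifelse(cohort %in% c("coh1", "coh2"), "stA", "stB")
  thi_cow <- ifelse(station == "stA", 62, 68) + rnorm(n, 0, 1)
  temp <- rnorm(n, 38.7, 0.11)
  dmi <- 26 + c(coh1 = 0, coh2 = 1, coh3 = -1, coh4 = 0.5)[cohort] +
    slope * (temp - 38.7) + rnorm(n, 0, 1)
  data.frame(dmi = dmi, mean_temp = temp, cohort = cohort,
             station = station, thi_cow = thi_cow, stringsAsFactors = FALSE)
}

test_that("trial-level regression recovers an injected slope", {
  d <- make_assoc_data(1000, slope = -2.5, seed = 2)
  r <- regress_trait(d, "dmi", "mean_temp")
  expect_lt(abs(r$slope - (-2.5)), 2 * r$se)
  expect_lt(r$p_value, 0.05)
  expect_identical(r$n, 1000L)
})

test_that("regression slope is invariant to THI centring and cohort relabels", {
  d <- make_assoc_data(300, seed = 3)
  r0 <- regress_trait(d, "dmi", "mean_temp")
  d2 <- d; d2$thi_cow <- d2$thi_cow - 65
  r2 <- regress_trait(d2, "dmi", "mean_temp")
  expect_equal(r2$slope, r0$slope, tolerance = 1e-9)
  expect_equal(r2$se, r0$se, tolerance = 1e-9)
  d3 <- d; d3$cohort <- chartr("1234", "9875", d3$cohort)
  r3 <- regress_trait(d3, "dmi", "mean_temp")
  expect_equal(r3$slope, r0$slope, tolerance = 1e-9)
})

test_that("constant temperature trait raises an explicit error", {
  d <- make_assoc_data(100, seed = 4)
  d$mean_temp <- 38.7
  expect_error(regress_trait(d, "dmi", "mean_temp"), "constant")
})

test_that("single-station data drop the interaction instead of failing", {
  d <- make_assoc_data(200, seed = 5)
  d$station <- "stA"
  r <- regress_trait(d, "dmi", "mean_temp")
  expect_false(grepl("station", r$model))
  expect_true(is.finite(r$slope))
})

test_that("daily mixed model recovers the injected daily slope", {
  set.seed(6)
  n_cow <- 150; n_day <- 14
  cow <- rep(sprintf("c%03d", 1:n_cow), each = n_day)
  cohort <- rep(rep_len(paste0("coh", 1:4), n_cow), each = n_day)
  station <- ifelse(cohort %in% c("coh1", "coh2"), "stA", "stB")
  thi <- ifelse(station == "stA", 62, 68) + rnorm(n_cow * n_day, 0, 1.5)
  cow_int <- rep(rnorm(n_cow, 0, 1.2), each = n_day)
  dtemp <- rnorm(n_cow * n_day, 0, 0.09)
  dmi <- 26 + cow_int - 2.3 * dtemp + rnorm(n_cow * n_day, 0, 1.5)
  d <- data.frame(cow_id = cow, cohort = cohort, station = station,
                  thi = thi, mean_temp = 38.7 + dtemp, dmi_kg = dmi)
  r <- daily_mixed_model(d)
  expect_lt(abs(r$slope - (-2.3)), 2 * r$se)
  expect_identical(r$n_cows, as.integer(n_cow))
})

test_that("with no between-cow variance the mixed slope matches pooled OLS", {
  set.seed(7)
  n_cow <- 80; n_day <- 10
  cow <- rep(sprintf("c%03d", 1:n_cow), each = n_day)
  dtemp <- rnorm(n_cow * n_day, 0, 0.1)
  thi <- 65 + rnorm(n_cow * n_day, 0, 1)
  dmi <- 25 - 2.0 * dtemp + rnorm(n_cow * n_day, 0, 1)
  d <- data.frame(cow_id = cow, cohort = "cohA", station = "stA",
                  thi = thi, mean_temp = 38.7 + dtemp, dmi_kg = dmi)
  r <- daily_mixed_model(d)
  ols <- lm(dmi_kg ~ mean_temp + thi, data = d)
  expect_lt(abs(r$slope - coef(ols)["mean_temp"]), 1e-3)
  expect_match(r$note, "singular")
})

test_that("one record per cow degenerates to OLS exactly", {
  set.seed(8)
  n <- 120
  d <- data.frame(cow_id = sprintf("c%03d", 1:n),
                  cohort = rep_len(paste0("coh", 1:3), n), station = "stA",
                  thi = 65 + rnorm(n), mean_temp = rnorm(n, 38.7, 0.1),
                  dmi_kg = rnorm(n, 26, 2))
  r <- daily_mixed_model(d)
  ols <- lm(dmi_kg ~ mean_temp + cohort + thi, data = d)
  expect_equal(r$slope, unname(coef(ols)["mean_temp"]), tolerance = 1e-6)
  expect_match(r$note, "OLS")
})

test_that("partial correlation equals the two-step residual oracle and is symmetric", {
  set.seed(9)
  n <- 200
  cohort <- rep_len(paste0("coh", 1:5), n)
  x <- rnorm(n) + c(coh1 = 0, coh2 = 2, coh3 = -1, coh4 = 1, coh5 = 0)[cohort]
  y <- rnorm(n) + 0.3 * x
  pc <- partial_correlation(x, y, cohort)
  # brute force: subtract cohort means (residuals of regression on
  # indicators), then plain Pearson
  rx <- x - ave(x, cohort)
  ry <- y - ave(y, cohort)
  expect_equal(pc$r, cor(rx, ry), tolerance = 1e-10)
  pc_swap <- partial_correlation(y, x, cohort)
  expect_identical(pc$r, pc_swap$r)
  expect_identical(pc$p_value, pc_swap$p_value)
})

test_that("partial correlation with one cohort is the plain Pearson correlation", {
  set.seed(10)
  x <- rnorm(50); y <- rnorm(50) + 0.5 * x
  pc <- partial_correlation(x, y, rep("a", 50))
  expect_equal(pc$r, cor(x, y), tolerance = 1e-12)
  expect_equal(pc$p_value, cor.test(x, y)$p.value, tolerance = 1e-9)
})

test_that("cohort-mean confounding is removed by the partial correlation", {
  set.seed(12)
  n <- 500
  cohort <- rep_len(paste0("coh", 1:5), n)
  shift <- c(coh1 = -2, coh2 = -1, coh3 = 0, coh4 = 1, coh5 = 2)[cohort]
  # x and y share cohort-mean structure but are independent within cohort
  x <- shift + rnorm(n)
  y <- shift + rnorm(n)
  expect_gt(cor(x, y), 0.3)                 # raw correlation is confounded
  pc <- partial_correlation(x, y, cohort)
  se <- 1 / sqrt(pc$df)
  expect_lt(abs(pc$r), 2 * se)
})

test_that("adding a noise trait leaves adjusted R2 essentially unchanged", {
  set.seed(13)
  rec <- make_records(500, noise_sd = 1.0, seed = 13)
  noise_trait <- stats::setNames(rnorm(500), rec$cow_id)
  cmp <- compare_rfi_models(rec, noise_trait, "noise")
  expect_lt(abs(cmp$delta), 0.01)
  # unadjusted R2 of the augmented model can never be lower (nesting)
  d2 <- rec; d2$..tt <- as.numeric(noise_trait)
  base <- compute_rfi(rec)
  aug <- lm(update(formula(base$fit), . ~ . + ..tt), data = d2)
  expect_gte(summary(aug)$r.squared, summary(base$fit)$r.squared)
})

test_that("a duplicate of MilkE is aliased and changes nothing", {
  rec <- make_records(200, noise_sd = 1.0, seed = 14)
  dup <- stats::setNames(rec$milke, rec$cow_id)
  cmp <- compare_rfi_models(rec, dup, "milke_copy")
  expect_equal(cmp$delta, 0, tolerance = 1e-12)
})
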