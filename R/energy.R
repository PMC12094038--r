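# Milk energy, body-weight traits, and residual feed intake.

#' Secreted milk energy (Mcal/d)
#'
#' MilkE = (0.0929 x fat% + 0.0585 x true protein% + 0.0395 x lactose%)
#' x milk yield. Computed weekly and averaged per cow upstream.
#'
#' @param fat_pct,protein_pct,lactose_pct milk composition, percent
#' @param milk_yield kg/d
#' @return Mcal/d, vectorized
#' @examples
#' milk_energy(4.0, 3.0, 4.8, 40)  # 29.468
#' @export
milk_energy <- function(fat_pct, protein_pct, lactose_pct, milk_yield) {
  args <- list(fat_pct, protein_pct, lactose_pct, milk_yield)
  if (any(vapply(args, function(a) any(!is.finite(a)) || any(a < 0), TRUE)))
    stop_param("milk components and yield must be finite and >= 0")
  (0.0929 * fat_pct + 0.0585 * protein_pct + 0.0395 * lactose_pct) * milk_yield
}

#' Impute a daily body-weight series from sparse measurements
#'
#' Because trials last only a few weeks, missing BW days are filled from an
#' ordinary least-squares regression of measured BW on day of trial.
#' Measured days keep their measured value (averaged if a day was measured
#' more than once).
#'
#' @param bw_records data.frame with columns day (integer day of trial) and
#'   bw_kg; at least 2 distinct days
#' @param days_out days at which a value is wanted (default: every day from
#'   the first to the last measured day)
#' @return data.frame (day, bw_kg, measured)
#' @export
impute_bw <- function(bw_records, days_out = NULL) {
  if (length(unique(bw_records$day)) < 2L)
    stop_param("need BW measurements on at least 2 distinct days")
  if (any(!is.finite(bw_records$bw_kg)) || any(bw_records$bw_kg <= 0))
    stop_param("BW must be positive and finite")
  meas <- tapply(bw_records$bw_kg, bw_records$day, mean)
  meas_day <- as.integer(names(meas))
  # closed-form simple OLS of BW on day
  mx <- mean(meas_day); my <- mean(meas)
  sxx <- sum((meas_day - mx)^2)
  b <- if (sxx > 0) sum((meas_day - mx) * (meas - my)) / sxx else 0
  a <- my - b * mx
  if (is.null(days_out)) days_out <- seq(min(meas_day), max(meas_day))
  hit <- match(days_out, meas_day)
  out <- data.frame(day = days_out, bw_kg = a + b * days_out,
                    measured = !is.na(hit))
  out$bw_kg[out$measured] <- as.numeric(meas[hit[out$measured]])
  out
}

#' Metabolic body weight
#'
#' The cow's average BW raised to the 0.75 power: (mean BW)^0.75.
#'
#' @param bw_series numeric daily BW values (kg) or the data.frame from
#'   [impute_bw()]
#' @return kg^0.75
#' @export
metabolic_bw <- function(bw_series) {
  bw <- if (is.data.frame(bw_series)) bw_series$bw_kg else bw_series
  if (any(!is.finite(bw)) || any(bw <= 0))
    stop_param("BW series must be positive and finite")
  mean(bw)^0.75
}

#' Body-weight change over the trial
#'
#' Difference of (fitted/imputed) BW between the last and the first trial
#' day.
#'
#' @param bw_series data.frame (day, bw_kg) from [impute_bw()]
#' @return kg
#' @export
delta_bw <- function(bw_series) {
  if (!is.data.frame(bw_series) || nrow(bw_series) < 2L)
    stop_param("need an imputed series covering first and last trial day")
  o <- order(bw_series$day)
  bw_series$bw_kg[o[length(o)]] - bw_series$bw_kg[o[1L]]
}

#' Days-in-milk class
#'
#' Midpoint DIM between 60 and 195 d is binned into nine 15-d periods:
#' class k covers [60 + 15(k-1), 60 + 15k) for k = 1..8 and [180, 195] for
#' k = 9. Values outside [60, 195] are rejected rather than extrapolated.
#'
#' @param dim midpoint days in milk
#' @return factor with levels "1".."9"
#' @export
dim_class <- function(dim) {
  if (any(!is.finite(dim)) || any(dim < 60 | dim > 195))
    stop_param("midpoint DIM must lie in [60, 195]")
  k <- pmin(floor((dim - 60) / 15) + 1, 9)
  factor(k, levels = as.character(1:9))
}

#' Lactation-number class
#'
#' Parities 1, 2 and 3 keep their own level; 4 and above collapse to "4+".
#'
#' @param parity lactation number, >= 1
#' @return factor with levels "1","2","3","4+"
#' @export
lact_class <- function(parity) {
  if (any(!is.finite(parity)) || any(parity < 1))
    stop_param("lactation number must be >= 1")
  factor(ifelse(parity >= 4, "4+", as.character(as.integer(parity))),
         levels = c("1", "2", "3", "4+"))
}

#' Assemble per-cow feed-efficiency records
#'
#' Builds one row per cow from the pipeline's measurement tables: trial
#' average DMI, MilkE as the unweighted mean of weekly milk-energy values,
#' metabolic BW and BW change from the imputed BW line, plus DIM class,
#' lactation class, cohort and station.
#'
#' @param dmi_daily data.frame (cow_id, day, dmi_kg)
#' @param milk_weekly data.frame (cow_id, week, fat_pct, protein_pct,
#'   lactose_pct, milk_yield_kg)
#' @param bw data.frame (cow_id, day, bw_kg)
#' @param cows metadata (cow_id, station, cohort, parity, midpoint_dim)
#' @param trial_days length of the trial; the BW line is evaluated on days
#'   1..trial_days
#' @return data.frame with cow_id, dmi, milke, mbw, dbw, dim_class,
#'   lact_class, cohort, station
#' @export
build_efficiency_records <- function(dmi_daily, milk_weekly, bw, cows,
                                     trial_days = NULL) {
  if (is.null(trial_days)) trial_days <- max(dmi_daily$day)
  rows <- lapply(seq_len(nrow(cows)), function(i) {
    id <- cows$cow_id[i]
    d <- dmi_daily[dmi_daily$cow_id == id, , drop = FALSE]
    m <- milk_weekly[milk_weekly$cow_id == id, , drop = FALSE]
    b <- bw[bw$cow_id == id, , drop = FALSE]
    if (nrow(d) == 0L || nrow(m) == 0L || nrow(b) < 2L) return(NULL)
    series <- impute_bw(b, days_out = seq_len(trial_days))
    data.frame(
      cow_id = id,
      dmi = mean(d$dmi_kg),
      milke = mean(milk_energy(m$fat_pct, m$protein_pct, m$lactose_pct,
                               m$milk_yield_kg)),
      mbw = metabolic_bw(series),
      dbw = delta_bw(series),
      dim_class = dim_class(cows$midpoint_dim[i]),
      lact_class = lact_class(cows$parity[i]),
      cohort = as.character(cows$cohort[i]),
      station = as.character(cows$station[i]),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Residual feed intake from the energy-sink linear model
#'
#' Fits, by ordinary least squares with an intercept,
#' DMI = DIM class + lactation class + cohort + b1 MilkE + b2 mBW
#' + b3 dBW + e, with treatment coding for the categorical effects. The
#' residual e is the cow's RFI: intake not accounted for by milk energy
#' output, maintenance (metabolic BW), body-weight change and management
#' group. Aliased columns are dropped with a warning.
#'
#' @param records data.frame from [build_efficiency_records()]
#' @return object of class `rfi_fit`: the lm fit, coefficients b1 (MilkE),
#'   b2 (mBW), b3 (dBW), per-cow `rfi` residuals, `adj_r2`, `n`, `rank`
#' @export
compute_rfi <- function(records) {
  req <- c("cow_id", "dmi", "milke", "mbw", "dbw", "dim_class", "lact_class",
           "cohort")
  miss <- setdiff(req, names(records))
  if (length(miss))
    stop_param("records missing columns: %s", paste(miss, collapse = ", "))
  d <- records
  d$dim_class <- droplevels(factor(d$dim_class))
  d$lact_class <- droplevels(factor(d$lact_class))
  d$cohort <- droplevels(factor(d$cohort))
  terms <- c(if (nlevels(d$dim_class) > 1L) "dim_class",
             if (nlevels(d$lact_class) > 1L) "lact_class",
             if (nlevels(d$cohort) > 1L) "cohort",
             "milke", "mbw", "dbw")
  form <- stats::reformulate(terms, response = "dmi")
  n_par <- 1L + (nlevels(d$dim_class) - 1L) + (nlevels(d$lact_class) - 1L) +
    (nlevels(d$cohort) - 1L) + 3L
  if (nrow(d) <= n_par)
    stop_param("fewer cows (%d) than model parameters (%d)", nrow(d), n_par)
  fit <- stats::lm(form, data = d)
  if (anyNA(stats::coef(fit)))
    warning("rank-deficient design: aliased columns dropped", call. = FALSE)
  s <- summary(fit)
  structure(list(
    fit = fit,
    coefficients = stats::coef(fit),
    b = c(b1 = unname(stats::coef(fit)["milke"]),
          b2 = unname(stats::coef(fit)["mbw"]),
          b3 = unname(stats::coef(fit)["dbw"])),
    se = c(b1 = s$coefficients["milke", "Std. Error"],
           b2 = s$coefficients["mbw", "Std. Error"],
           b3 = s$coefficients["dbw", "Std. Error"]),
    rfi = stats::setNames(stats::residuals(fit), d$cow_id),
    adj_r2 = s$adj.r.squared,
    n = nrow(d),
    rank = fit$rank), class = "rfi_fit")
}

#' @exportS3Method base::print
print.rfi_fit <- function(x, ...) {
  cat(sprintf("RFI model: n = %d cows, rank %d, adjusted R^2 = %.3f\n",
              x$n, x$rank, x$adj_r2))
  cat(sprintf("  b1 (MilkE) = %.4f, b2 (mBW) = %.4f, b3 (dBW) = %.4f\n",
              x$b["b1"], x$b["b2"], x$b["b3"]))
  invisible(x)
}

#' Adjusted R-squared of the RFI model with and without a temperature trait
#'
#' Refits the RFI model on the cows that have the temperature trait, then
#' again with the trait added as a covariate, and reports both adjusted
#' R-squared values.
#'
#' @param records efficiency records (see [compute_rfi()])
#' @param temp_trait named numeric vector (names = cow_id) or a numeric
#'   vector aligned with `records`
#' @param trait_name label for the added trait
#' @return list(base_adj_r2, augmented_adj_r2, delta, trait_name, n)
#' @export
compare_rfi_models <- function(records, temp_trait, trait_name = "temp_trait") {
  if (!is.null(names(temp_trait)))
    temp_trait <- temp_trait[as.character(records$cow_id)]
  keep <- !is.na(temp_trait)
  d <- records[keep, , drop = FALSE]
  tt <- temp_trait[keep]
  base <- compute_rfi(d)
  d2 <- d
  d2$..tt <- tt
  aug_form <- stats::update(stats::formula(base$fit), . ~ . + ..tt)
  aug <- stats::lm(aug_form, data = d2)
  list(base_adj_r2 = base$adj_r2,
       augmented_adj_r2 = summary(aug)$adj.r.squared,
       delta = summary(aug)$adj.r.squared - base$adj_r2,
       trait_name = trait_name,
       n = nrow(d))
}
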