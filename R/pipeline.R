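# End-to-end orchestration: QC -> temperature phenotypes -> meal criterion
# and post-meal change -> efficiency traits and RFI -> THI covariates ->
# associations, with a manifest for reproducible reruns.

#' Validate a pipeline input directory
#'
#' Checks that the required CSV files are present, carry the expected
#' columns, parse to the expected types, and are key-consistent (every cow
#' appearing in a data table must exist in cows.csv). temperatures.csv and
#' visits.csv are optional: without temperatures only the efficiency side
#' can run; without visits the post-meal trait is skipped.
#'
#' @param dir input directory
#' @return list with `pass` (logical) and `messages` (character vector of
#'   failures, empty when pass)
#' @export
validate_inputs <- function(dir) {
  msgs <- character(0)
  need <- list(
    dmi_daily.csv = c("cow_id", "day", "dmi_kg"),
    milk_weekly.csv = c("cow_id", "week", "fat_pct", "protein_pct",
                        "lactose_pct", "milk_yield_kg"),
    bw.csv = c("cow_id", "day", "bw_kg"),
    weather.csv = c("station", "date", "t_mean_c", "rh_pct"),
    cows.csv = c("cow_id", "station", "cohort", "parity", "midpoint_dim"))
  optional <- list(
    temperatures.csv = c("cow_id", "timestamp", "temp_c"),
    visits.csv = c("cow_id", "visit_start", "visit_end", "intake_kg"))
  tables <- list()
  for (f in names(need)) {
    p <- file.path(dir, f)
    if (!file.exists(p)) { msgs <- c(msgs, sprintf("%s: missing", f)); next }
    d <- utils::read.csv(p, stringsAsFactors = FALSE)
    miss <- setdiff(need[[f]], names(d))
    if (length(miss))
      msgs <- c(msgs, sprintf("%s: missing columns %s", f,
                              paste(miss, collapse = ", ")))
    tables[[f]] <- d
  }
  for (f in names(optional)) {
    p <- file.path(dir, f)
    if (!file.exists(p)) next
    d <- utils::read.csv(p, stringsAsFactors = FALSE)
    miss <- setdiff(optional[[f]], names(d))
    if (length(miss))
      msgs <- c(msgs, sprintf("%s: missing columns %s", f,
                              paste(miss, collapse = ", ")))
    tables[[f]] <- d
  }
  num_cols <- list(temperatures.csv = "temp_c", dmi_daily.csv = "dmi_kg",
                   bw.csv = "bw_kg", visits.csv = "intake_kg",
                   weather.csv = c("t_mean_c", "rh_pct"))
  for (f in names(num_cols)) {
    d <- tables[[f]]
    if (is.null(d)) next
    for (cc in intersect(num_cols[[f]], names(d))) {
      v <- suppressWarnings(as.numeric(d[[cc]]))
      bad <- which(is.na(v) & !is.na(d[[cc]]))
      if (length(bad))
        msgs <- c(msgs, sprintf("%s: column %s not numeric at rows %s", f, cc,
                                paste(utils::head(bad, 5), collapse = ", ")))
    }
  }
  if (!is.null(tables$temperatures.csv)) {
    ts <- parse_ts(tables$temperatures.csv$timestamp)
    bad <- which(is.na(ts))
    if (length(bad))
      msgs <- c(msgs, sprintf("temperatures.csv: unparseable timestamps at rows %s",
                              paste(utils::head(bad, 5), collapse = ", ")))
  }
  if (!is.null(tables$cows.csv)) {
    known <- tables$cows.csv$cow_id
    for (f in setdiff(names(tables), c("cows.csv", "weather.csv"))) {
      if (!"cow_id" %in% names(tables[[f]])) next
      stray <- setdiff(unique(tables[[f]]$cow_id), known)
      if (length(stray))
        msgs <- c(msgs, sprintf("%s: cow(s) absent from cows.csv: %s", f,
                                paste(utils::head(stray, 5), collapse = ", ")))
    }
  }
  list(pass = length(msgs) == 0L, messages = msgs)
}

trial_assoc_grid <- function(eff, trial_phen, postmeal, thi_cow) {
  d <- merge(eff, trial_phen[, c("cow_id", "mean_temp", "logvar")],
             by = "cow_id", all.x = TRUE)
  d <- merge(d, thi_cow, by = "cow_id", all.x = TRUE)
  if (!is.null(postmeal))
    d <- merge(d, postmeal[, c("cow_id", "postmeal_delta")],
               by = "cow_id", all.x = TRUE)
  responses <- c("dmi", "milke", "mbw", "rfi")
  traits <- intersect(c("mean_temp", "logvar", "postmeal_delta"), names(d))
  rows <- list()
  for (tr in traits) for (rsp in responses) {
    res <- tryCatch(regress_trait(d, rsp, tr), error = function(e) NULL)
    if (!is.null(res)) rows[[length(rows) + 1L]] <- res
  }
  list(table = do.call(rbind, rows), data = d, traits = traits)
}

#' Run the full analysis pipeline
#'
#' Executes: input validation; temperature QC (minimum days, SD screen);
#' trial and daily temperature phenotypes; inter-visit interval pooling,
#' mixture fit and meal criterion (unless `criterion` is fixed), meal
#' merging, largest meals, post-meal temperature change; efficiency records
#' and the RFI model; daily and per-cow THI; trial-level association
#' regressions, daily linear mixed models, partial correlations controlling
#' for cohort, and adjusted-R2 comparison of RFI models with and without
#' the temperature traits. All intermediate tables are written to
#' `out_dir` along with a JSON manifest.
#'
#' @param input a directory containing the CSV schema (see
#'   [validate_inputs()]) or a `synthetic_herd` object
#' @param out_dir output directory; NULL skips writing
#' @param min_days,sd_limit QC thresholds (defaults 7 d, 3 SD)
#' @param criterion fixed meal criterion in minutes; NULL (default)
#'   estimates it from the pooled inter-visit intervals
#' @param pad THI window padding in days (default 3)
#' @param seed seed for the mixture-fit restarts
#' @param daily_center baseline for daily consistency (see [consistency()])
#' @return list: qc, phenotypes, mixture_fit, criterion, meals, postmeal,
#'   efficiency, rfi, thi, associations, daily_assoc, partial_cor,
#'   model_comparison, manifest
#' @export
run_pipeline <- function(input, out_dir = NULL, min_days = 7, sd_limit = 3,
                         criterion = NULL, pad = 3, seed = 1,
                         daily_center = "trial") {
  if (is.character(input)) {
    rep <- validate_inputs(input)
    if (!rep$pass)
      stop_param("input validation failed:\n  %s",
                 paste(rep$messages, collapse = "\n  "))
    ds <- read_dataset(input)
  } else ds <- input
  manifest <- list(package_version = as.character(utils::packageVersion("thermofeed")),
                   r_version = as.character(getRversion()),
                   seed = seed, min_days = min_days, sd_limit = sd_limit,
                   thi_pad = pad, stages = list())

  # --- temperature QC and phenotypes -------------------------------------
  qc <- phen <- NULL
  if (!is.null(ds$temps)) {
    qc <- qc_herd(ds$temps, min_days = min_days, sd_limit = sd_limit)
    phen <- temperature_phenotypes(qc$temps, center = daily_center)
    manifest$stages$qc <- list(
      n_cows_in = length(unique(ds$temps$cow_id)),
      n_excluded = sum(qc$reports$excluded),
      n_records_removed = sum(qc$reports$n_removed))
  }

  # --- meal criterion and post-meal change -------------------------------
  fit <- meals <- postmeal <- NULL
  crit <- criterion
  if (!is.null(ds$visits)) {
    if (is.null(crit)) {
      ints <- visit_intervals(ds$visits)
      fit <- fit_interval_mixture(ints, seed = seed)
      crit <- meal_criterion(fit)
      manifest$stages$meal_criterion <-
        list(mode = "estimated", criterion_min = crit,
             n_intervals = length(ints), converged = fit$converged)
    } else {
      manifest$stages$meal_criterion <-
        list(mode = "fixed", criterion_min = crit)
    }
    meals <- largest_meal_per_day(merge_visits_to_meals(ds$visits, crit))
    if (!is.null(qc)) postmeal <- post_meal_deltas(qc$temps, meals)
  } else {
    manifest$stages$meal_criterion <- list(mode = "skipped (no visits.csv)")
  }

  # --- efficiency traits and RFI ----------------------------------------
  eff <- build_efficiency_records(ds$dmi_daily, ds$milk_weekly, ds$bw,
                                  ds$cows,
                                  trial_days = max(ds$dmi_daily$day))
  rfi_fit <- compute_rfi(eff)
  eff$rfi <- as.numeric(rfi_fit$rfi[as.character(eff$cow_id)])
  manifest$stages$rfi <- list(n_cows = rfi_fit$n, adj_r2 = rfi_fit$adj_r2,
                              b = as.list(rfi_fit$b))

  # --- THI ---------------------------------------------------------------
  wx <- thi_daily(ds$weather)
  thi_cow <- NULL
  if (!is.null(phen)) {
    st <- ds$cows$station[match(phen$trial$cow_id, ds$cows$cow_id)]
    thi_cow <- data.frame(
      cow_id = phen$trial$cow_id,
      thi_cow = mapply(function(s, a, b_) window_thi(wx, s, a, b_, pad = pad),
                       st, phen$trial$first_day, phen$trial$last_day))
  }

  # --- associations ------------------------------------------------------
  assoc <- daily_assoc <- pc <- mc <- NULL
  if (!is.null(phen)) {
    ag <- trial_assoc_grid(eff, phen$trial, postmeal$per_cow, thi_cow)
    assoc <- ag$table
    # daily: merge daily phenotypes with daily DMI and daily THI
    dd <- ds$dmi_daily
    if (!"date" %in% names(dd))
      stop_param("dmi_daily needs a date column for the daily models")
    ddm <- merge(phen$daily, dd[, c("cow_id", "date", "dmi_kg")],
                 by = c("cow_id", "date"))
    ddm$station <- ds$cows$station[match(ddm$cow_id, ds$cows$cow_id)]
    ddm$cohort <- ds$cows$cohort[match(ddm$cow_id, ds$cows$cow_id)]
    ddm <- merge(ddm, wx[, c("station", "date", "thi")],
                 by = c("station", "date"), all.x = TRUE)
    daily_assoc <- rbind(
      daily_mixed_model(ddm, temp_trait = "mean_temp"),
      daily_mixed_model(ddm, temp_trait = "logvar"))
    # partial correlations controlling for cohort
    d <- ag$data
    pairs <- expand.grid(temp = ag$traits,
                         efft = c("dmi", "milke", "mbw", "rfi"),
                         stringsAsFactors = FALSE)
    pc <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
      r <- partial_correlation(d[[pairs$temp[i]]], d[[pairs$efft[i]]],
                               d$cohort)
      data.frame(temp_trait = pairs$temp[i], eff_trait = pairs$efft[i],
                 r = r$r, p_value = r$p_value, n = r$n,
                 stringsAsFactors = FALSE)
    }))
    # adjusted-R2 comparison of RFI models with/without temperature traits
    mc <- do.call(rbind, lapply(ag$traits, function(tr) {
      v <- stats::setNames(d[[tr]], d$cow_id)
      cmp <- compare_rfi_models(eff, v, trait_name = tr)
      data.frame(trait = tr, base_adj_r2 = cmp$base_adj_r2,
                 augmented_adj_r2 = cmp$augmented_adj_r2,
                 delta = cmp$delta, n = cmp$n, stringsAsFactors = FALSE)
    }))
  }

  out <- list(qc = qc, phenotypes = phen, mixture_fit = fit, criterion = crit,
              meals = meals, postmeal = postmeal, efficiency = eff,
              rfi = rfi_fit, thi_daily = wx, thi_cow = thi_cow,
              associations = assoc, daily_assoc = daily_assoc,
              partial_cor = pc, model_comparison = mc, manifest = manifest)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wcsv <- function(d, f) if (!is.null(d))
      utils::write.csv(d, file.path(out_dir, f), row.names = FALSE)
    if (!is.null(phen)) {
      wcsv(phen$trial, "phenotypes_trial.csv")
      wcsv(phen$daily, "phenotypes_daily.csv")
    }
    if (!is.null(qc)) jsonlite::write_json(
      qc$reports, file.path(out_dir, "qc_report.json"), dataframe = "rows",
      auto_unbox = TRUE, digits = NA)
    if (!is.null(meals)) {
      m2 <- meals; m2$start <- fmt_ts(m2$start); m2$end <- fmt_ts(m2$end)
      wcsv(m2, "meals.csv")
    }
    if (!is.null(postmeal)) wcsv(postmeal$per_cow, "postmeal_deltas.csv")
    if (!is.null(fit)) jsonlite::write_json(
      list(weights = fit$weights, means = fit$means, sds = fit$sds,
           loglik = fit$loglik, n = fit$n, converged = fit$converged,
           criterion_min = crit),
      file.path(out_dir, "mixture_fit.json"), auto_unbox = TRUE, digits = NA)
    wcsv(eff, "efficiency_traits.csv")
    jsonlite::write_json(
      list(coefficients = as.list(rfi_fit$coefficients),
           adj_r2 = rfi_fit$adj_r2, n = rfi_fit$n),
      file.path(out_dir, "rfi_model.json"), auto_unbox = TRUE, digits = NA)
    wcsv(wx, "thi_daily.csv")
    wcsv(thi_cow, "thi_cow.csv")
    wcsv(assoc, "associations.csv")
    wcsv(daily_assoc, "daily_associations.csv")
    wcsv(pc, "partial_correlations.csv")
    wcsv(mc, "rfi_model_comparison.csv")
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(out)
}
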