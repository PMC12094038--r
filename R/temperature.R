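#' Quality control for a single cow's temperature trace
#'
#' Applies the two screening rules used for high-frequency vaginal
#' temperature records: a cow with fewer than `min_days` distinct calendar
#' days of records is excluded entirely, and individual records further than
#' `sd_limit` standard deviations from the cow's raw mean are removed. The
#' outlier pass is a single pass using the mean and SD of the raw trace; it
#' is idempotent on an already-cleaned trace in the sense that a second pass
#' (recomputing mean/SD on the cleaned records) removes nothing new only when
#' no mass sat near the boundary, so the canonical usage is one pass on raw
#' data.
#'
#' @param trace data.frame with columns cow_id, timestamp (POSIXct),
#'   temp_c for one cow
#' @param min_days minimum number of distinct record days (default 7)
#' @param sd_limit outlier threshold in SD multiples (default 3)
#' @return list with `trace` (cleaned records, empty if the cow is excluded)
#'   and `report` (cow_id, excluded, reason, n_raw, n_removed, n_days)
#' @export
qc_trace <- function(trace, min_days = 7, sd_limit = 3) {
  if (is.null(trace) || nrow(trace) == 0L)
    stop_param("empty temperature trace")
  if (length(unique(trace$cow_id)) != 1L)
    stop_param("qc_trace expects records for exactly one cow")
  if (any(!is.finite(trace$temp_c)))
    stop_param("non-finite temperature values in trace")
  trace <- trace[order(trace$timestamp), , drop = FALSE]
  n_days <- length(unique(ts_date(trace$timestamp)))
  rep <- list(cow_id = trace$cow_id[1L], excluded = FALSE, reason = NA_character_,
              n_raw = nrow(trace), n_removed = 0L, n_days = n_days)
  if (n_days < min_days) {
    rep$excluded <- TRUE
    rep$reason <- "insufficient_days"
    return(list(trace = trace[0, , drop = FALSE], report = rep))
  }
  m <- mean(trace$temp_c)
  s <- stats::sd(trace$temp_c)
  keep <- if (is.na(s) || s == 0) rep(TRUE, nrow(trace))
          else abs(trace$temp_c - m) <= sd_limit * s
  rep$n_removed <- sum(!keep)
  list(trace = trace[keep, , drop = FALSE], report = rep)
}

#' Quality control across a herd of traces
#'
#' @param temps data.frame (cow_id, timestamp, temp_c) for many cows
#' @inheritParams qc_trace
#' @return list with `temps` (cleaned, retained cows only) and `reports`
#'   (one data.frame row per cow)
#' @export
qc_herd <- function(temps, min_days = 7, sd_limit = 3) {
  pieces <- split(temps, temps$cow_id)
  out <- lapply(pieces, qc_trace, min_days = min_days, sd_limit = sd_limit)
  reports <- do.call(rbind, lapply(out, function(o)
    as.data.frame(o$report, stringsAsFactors = FALSE)))
  rownames(reports) <- NULL
  cleaned <- do.call(rbind, lapply(out, `[[`, "trace"))
  rownames(cleaned) <- NULL
  list(temps = cleaned, reports = reports)
}

#' Mean body temperature of a cleaned trace
#'
#' @param trace cleaned single-cow trace (cow_id, timestamp, temp_c)
#' @param resolution "trial" for one scalar, "daily" for one value per
#'   calendar day with records
#' @return numeric scalar, or data.frame (date, mean_temp) for daily
#' @export
mean_temperature <- function(trace, resolution = c("trial", "daily")) {
  resolution <- match.arg(resolution)
  if (nrow(trace) == 0L) stop_param("no retained records")
  if (resolution == "trial") return(mean(trace$temp_c))
  d <- ts_date(trace$timestamp)
  agg <- tapply(trace$temp_c, d, mean)
  data.frame(date = as.Date(names(agg)), mean_temp = as.numeric(agg),
             row.names = NULL)
}

#' Consistency of body temperature, log(var x 100)
#'
#' The consistency statistic is the natural log of 100 times the variance of
#' the deviations of individual records from the cow's trial mean
#' (denominator n - 1). Smaller values mean a more consistent temperature.
#' At daily resolution each day's records are still deviated from the cow's
#' trial mean by default, so a day level-shifted away from the cow's norm
#' scores as inconsistent; set `center = "daily"` to deviate from the day's
#' own mean instead.
#'
#' @param trace cleaned single-cow trace
#' @param resolution "trial" or "daily"
#' @param center baseline for deviations at daily resolution: the cow's
#'   "trial" mean (default) or each "daily" mean
#' @return numeric scalar, or data.frame (date, logvar, n) for daily; `NA`
#'   with a "zero_variance" warning where the deviation variance is zero
#' @export
consistency <- function(trace, resolution = c("trial", "daily"),
                        center = c("trial", "daily")) {
  resolution <- match.arg(resolution)
  center <- match.arg(center)
  if (nrow(trace) < 2L) stop_param("need at least 2 retained records")
  trial_mean <- mean(trace$temp_c)
  logvar1 <- function(dev, n) {
    if (n < 2L) return(NA_real_)
    v <- sum(dev^2) / (n - 1L)
    if (v <= 0) {
      warning("zero_variance: log(var x 100) undefined", call. = FALSE)
      return(NA_real_)
    }
    log(100 * v)
  }
  if (resolution == "trial") {
    v <- stats::var(trace$temp_c)  # deviations from trial mean, n-1
    if (v <= 0) {
      warning("zero_variance: log(var x 100) undefined", call. = FALSE)
      return(NA_real_)
    }
    return(log(100 * v))
  }
  d <- ts_date(trace$timestamp)
  out <- lapply(split(trace$temp_c, d), function(x) {
    mu <- if (center == "trial") trial_mean else mean(x)
    logvar1(x - mu, length(x))
  })
  data.frame(date = as.Date(names(out)), logvar = unname(unlist(out)),
             n = as.integer(lengths(split(trace$temp_c, d))),
             row.names = NULL)
}

#' Trial and daily temperature phenotypes for a cleaned herd
#'
#' @param temps cleaned multi-cow records (cow_id, timestamp, temp_c)
#' @param center see [consistency()]
#' @return list with `trial` (cow_id, mean_temp, logvar, n_records, n_days,
#'   first_day, last_day) and `daily` (cow_id, date, mean_temp, logvar, n)
#' @export
temperature_phenotypes <- function(temps, center = "trial") {
  pieces <- split(temps, temps$cow_id)
  trial <- do.call(rbind, lapply(pieces, function(tr) {
    d <- ts_date(tr$timestamp)
    data.frame(cow_id = tr$cow_id[1L],
               mean_temp = mean_temperature(tr, "trial"),
               logvar = suppressWarnings(consistency(tr, "trial")),
               n_records = nrow(tr),
               n_days = length(unique(d)),
               first_day = min(d), last_day = max(d),
               stringsAsFactors = FALSE)
  }))
  daily <- do.call(rbind, lapply(pieces, function(tr) {
    mm <- mean_temperature(tr, "daily")
    lv <- suppressWarnings(consistency(tr, "daily", center = center))
    cbind(cow_id = tr$cow_id[1L], merge(mm, lv, by = "date"))
  }))
  rownames(trial) <- rownames(daily) <- NULL
  list(trial = trial, daily = daily)
}
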