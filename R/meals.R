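# Meal-criterion estimation and meal construction from feeder-visit logs.
# Inter-visit intervals (previous visit end to next visit start) are modelled
# on the log10-minute scale as a Gaussian mixture: a short within-meal
# component and a long between-meal component. The meal criterion is the
# interval at which the weighted component densities cross.

#' Extract inter-visit intervals from a visit log
#'
#' Intervals are the gaps from one visit's end to the next visit's start,
#' per cow, in minutes. Non-positive gaps (overlapping visits) raise an
#' error.
#'
#' @param visits data.frame with cow_id, visit_start, visit_end (POSIXct)
#' @return numeric vector of intervals in minutes (pooled over cows)
#' @export
visit_intervals <- function(visits) {
  out <- lapply(split(visits, visits$cow_id), function(v) {
    v <- v[order(v$visit_start), , drop = FALSE]
    if (nrow(v) < 2L) return(numeric(0))
    gap <- as.numeric(difftime(v$visit_start[-1L], v$visit_end[-nrow(v)],
                               units = "mins"))
    if (any(gap < 0)) stop_param("overlapping visits for cow %s", v$cow_id[1L])
    gap[gap > 0]
  })
  unlist(out, use.names = FALSE)
}

em_gauss_mix <- function(x, k, w, mu, sigma, max_iter = 500, tol = 1e-8) {
  n <- length(x)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    dens <- vapply(seq_len(k), function(j)
      w[j] * stats::dnorm(x, mu[j], sigma[j]), numeric(n))
    rowsum_ <- rowSums(dens)
    rowsum_[rowsum_ < 1e-300] <- 1e-300
    ll <- sum(log(rowsum_))
    resp <- dens / rowsum_
    nk <- colSums(resp)
    if (any(nk < 1e-8)) return(NULL)          # component collapsed
    w <- nk / n
    mu <- colSums(resp * x) / nk
    sigma <- sqrt(vapply(seq_len(k), function(j)
      sum(resp[, j] * (x - mu[j])^2) / nk[j], numeric(1)))
    if (any(sigma < 1e-4)) return(NULL)        # degenerate spike
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll) + 1))
      return(list(w = w, mu = mu, sigma = sigma, loglik = ll,
                  iter = it, converged = TRUE))
    ll_old <- ll
  }
  list(w = w, mu = mu, sigma = sigma, loglik = ll_old, iter = max_iter,
       converged = FALSE)
}

#' Maximum-likelihood Gaussian mixture fit on log10 inter-visit intervals
#'
#' Fits an `n_components` Gaussian mixture to log10(interval) by EM with
#' multiple restarts (one quantile-based start plus random starts) and
#' returns the best-likelihood solution with components sorted by mean.
#'
#' @param intervals inter-visit intervals in minutes, all > 0, length >= 50
#' @param n_components number of mixture components (default 2)
#' @param seed integer seed controlling the random restarts
#' @param n_restarts number of EM starts (default 5)
#' @param max_iter,tol EM stopping controls
#' @return object of class `mixture_fit`: weights, means, sds (log10-minute
#'   scale, means ascending), loglik, n, converged
#' @export
fit_interval_mixture <- function(intervals, n_components = 2, seed = 1,
                                 n_restarts = 5, max_iter = 500, tol = 1e-8) {
  if (length(intervals) < 50L)
    stop_param("need at least 50 intervals to fit the mixture (got %d)",
               length(intervals))
  if (any(!is.finite(intervals)) || any(intervals <= 0))
    stop_param("all intervals must be positive and finite")
  k <- as.integer(n_components)
  if (k < 1L) stop_param("n_components must be >= 1")
  x <- log10(intervals)
  empty <- structure(list(weights = rep(NA_real_, k), means = rep(NA_real_, k),
                          sds = rep(NA_real_, k), loglik = NA_real_,
                          n = length(x), converged = FALSE),
                     class = "mixture_fit")
  if (stats::sd(x) < 1e-12) return(empty)     # all intervals identical

  best <- NULL
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  qs <- stats::quantile(x, probs = seq(0, 1, length.out = k + 1L))
  for (r in seq_len(n_restarts)) {
    if (r == 1L) {
      grp <- findInterval(x, qs[-c(1L, k + 1L)]) + 1L
      mu <- tapply(x, factor(grp, levels = seq_len(k)), mean)
      mu[is.na(mu)] <- mean(x)
      sg <- tapply(x, factor(grp, levels = seq_len(k)), stats::sd)
      sg[is.na(sg) | sg < 1e-3] <- stats::sd(x) / k
      w <- rep(1 / k, k)
    } else {
      mu <- sort(sample(x, k))
      sg <- rep(stats::sd(x) / sqrt(k), k)
      w <- rep(1 / k, k)
    }
    fit <- em_gauss_mix(x, k, w, as.numeric(mu), as.numeric(sg),
                        max_iter = max_iter, tol = tol)
    if (is.null(fit)) next
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  if (is.null(best)) return(empty)
  ord <- order(best$mu)
  structure(list(weights = best$w[ord], means = best$mu[ord],
                 sds = best$sigma[ord], loglik = best$loglik,
                 n = length(x), converged = best$converged),
            class = "mixture_fit")
}

#' @exportS3Method base::print
print.mixture_fit <- function(x, ...) {
  cat("Gaussian mixture on log10(interval), ", length(x$means),
      " components\n", sep = "")
  print(data.frame(weight = x$weights, mean = x$means, sd = x$sds))
  cat(sprintf("log-likelihood %.3f on n = %d; converged: %s\n",
              x$loglik, x$n, x$converged))
  invisible(x)
}

#' Crossing point of two weighted Gaussian densities
#'
#' Root of w1 N(x; m1, s1) = w2 N(x; m2, s2) between the two means, found by
#' a bracketed root solve. Used both for the estimated meal criterion and
#' for the generator's analytic ground truth.
#'
#' @param w1,mu1,sigma1 weight, mean, sd of the short (within-meal) component
#' @param w2,mu2,sigma2 weight, mean, sd of the long (between-meal) component
#' @return crossing point on the log10-minute scale
#' @export
mixture_intersection <- function(w1, mu1, sigma1, w2, mu2, sigma2) {
  if (mu1 >= mu2) stop_param("component means must satisfy mu1 < mu2")
  f <- function(x) w1 * stats::dnorm(x, mu1, sigma1) -
                   w2 * stats::dnorm(x, mu2, sigma2)
  lo <- mu1; hi <- mu2
  if (f(lo) <= 0 || f(hi) >= 0)
    stop_param("no density intersection between the component means %s",
               "(one component dominates everywhere)")
  stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
}

#' Meal criterion from a fitted two-component mixture
#'
#' The criterion is 10^x* minutes, where x* is the point between the two
#' component means at which the weighted component densities are equal:
#' shorter gaps are more probably within-meal, longer gaps between meals.
#' With three or more fitted components the two components flanking the
#' estimate are the shortest- and longest-mean ones adjacent to the largest
#' gap would be ambiguous, so only the first two (ascending-mean) components
#' are used.
#'
#' @param fit a converged `mixture_fit` with >= 2 components
#' @return criterion in minutes
#' @export
meal_criterion <- function(fit) {
  if (!inherits(fit, "mixture_fit")) stop_param("fit must be a mixture_fit")
  if (!isTRUE(fit$converged)) stop_param("mixture fit did not converge")
  if (length(fit$means) < 2L) stop_param("need >= 2 components")
  xstar <- mixture_intersection(fit$weights[1L], fit$means[1L], fit$sds[1L],
                                fit$weights[2L], fit$means[2L], fit$sds[2L])
  10^xstar
}

#' Merge feeder visits into meals under a criterion
#'
#' Consecutive visits of a cow whose gap (next start minus previous end) is
#' strictly less than the criterion belong to the same meal. Meal intake is
#' the sum of visit intakes; meal start/end are the first start and last
#' end.
#'
#' @param visits data.frame with cow_id, visit_start, visit_end, intake_kg
#' @param criterion gap threshold in minutes, > 0
#' @return data.frame of meals: cow_id, meal_id, start, end, intake_kg,
#'   n_visits, date (calendar day of meal start)
#' @export
merge_visits_to_meals <- function(visits, criterion) {
  if (!is.numeric(criterion) || criterion <= 0)
    stop_param("criterion must be a positive number of minutes")
  out <- lapply(split(visits, visits$cow_id), function(v) {
    v <- v[order(v$visit_start), , drop = FALSE]
    if (any(v$visit_end < v$visit_start)) stop_param("visit ends before start")
    if (nrow(v) > 1L) {
      gap <- as.numeric(difftime(v$visit_start[-1L], v$visit_end[-nrow(v)],
                                 units = "mins"))
      if (any(gap < 0))
        stop_param("overlapping visits for cow %s", v$cow_id[1L])
      meal_id <- cumsum(c(1L, as.integer(gap >= criterion)))
    } else meal_id <- 1L
    # factor with levels in numeric order so aggregates align with meal_id
    mf <- factor(meal_id, levels = unique(meal_id))
    data.frame(
      cow_id = v$cow_id[1L],
      meal_id = unique(meal_id),
      start = as.POSIXct(as.numeric(tapply(as.numeric(v$visit_start), mf, min)),
                         origin = "1970-01-01", tz = "UTC"),
      end = as.POSIXct(as.numeric(tapply(as.numeric(v$visit_end), mf, max)),
                       origin = "1970-01-01", tz = "UTC"),
      intake_kg = as.numeric(tapply(v$intake_kg, mf, sum)),
      n_visits = as.integer(table(mf)),
      row.names = NULL)
  })
  meals <- do.call(rbind, out)
  rownames(meals) <- NULL
  meals$date <- ts_date(meals$start)
  meals
}

#' Flag the largest meal of each cow-day
#'
#' Exactly one meal per cow-day is flagged: the one with the highest intake,
#' ties broken by earliest start.
#'
#' @param meals output of [merge_visits_to_meals()]
#' @return the same table with a logical `is_largest_of_day` column
#' @export
largest_meal_per_day <- function(meals) {
  key <- interaction(meals$cow_id, meals$date, drop = TRUE)
  meals$is_largest_of_day <- FALSE
  for (idx in split(seq_len(nrow(meals)), key)) {
    best <- idx[order(-meals$intake_kg[idx], meals$start[idx])][1L]
    meals$is_largest_of_day[best] <- TRUE
  }
  meals
}

#' Post-meal body-temperature change for one meal
#'
#' The change is the body temperature 20 min after the end of the meal minus
#' the body temperature at the beginning of the meal, each taken as the
#' average of 3 consecutive records: the pre-meal window ends at the last
#' record at or before the meal start (so the meal itself cannot
#' contaminate it) and the post-meal window is centered on the record
#' nearest to meal end + `post_offset` minutes.
#'
#' @param trace cleaned single-cow trace (timestamp, temp_c)
#' @param meal one meal row (start, end as POSIXct)
#' @param post_offset minutes after meal end for the post window (default 20)
#' @param n_avg records averaged per window (default 3)
#' @return list(delta, pre_temp, post_temp), or NULL (with a warning) when
#'   the trace does not cover both windows
#' @export
post_meal_delta <- function(trace, meal, post_offset = 20, n_avg = 3) {
  ts <- trace$timestamp
  n <- length(ts)
  i <- findInterval(as.numeric(meal$start), as.numeric(ts))  # last at/before start
  target <- meal$end + post_offset * 60
  j <- which.min(abs(as.numeric(ts) - as.numeric(target)))
  half <- (n_avg - 1L) %/% 2L
  if (i < n_avg || j - half < 1L || j + half > n) {
    warning("insufficient trace coverage around meal; skipped", call. = FALSE)
    return(NULL)
  }
  pre_idx <- (i - n_avg + 1L):i
  post_idx <- (j - half):(j + half)
  # windows must be contiguous records, not separated by a day gap
  step <- stats::median(diff(as.numeric(ts)))
  if (any(diff(as.numeric(ts[pre_idx])) > 2 * step) ||
      any(diff(as.numeric(ts[post_idx])) > 2 * step)) {
    warning("record gap inside averaging window; meal skipped", call. = FALSE)
    return(NULL)
  }
  pre <- mean(trace$temp_c[pre_idx])
  post <- mean(trace$temp_c[post_idx])
  list(delta = post - pre, pre_temp = pre, post_temp = post)
}

#' Post-meal temperature change trait for a herd
#'
#' Evaluates [post_meal_delta()] for every flagged largest meal of each
#' cow-day and averages per cow.
#'
#' @param temps cleaned multi-cow records
#' @param meals meal table with `is_largest_of_day` flags
#' @inheritParams post_meal_delta
#' @return list with `per_meal` (cow_id, date, delta, pre_temp, post_temp)
#'   and `per_cow` (cow_id, postmeal_delta, n_meals)
#' @export
post_meal_deltas <- function(temps, meals, post_offset = 20, n_avg = 3) {
  lm_ <- meals[meals$is_largest_of_day, , drop = FALSE]
  traces <- split(temps, temps$cow_id)
  rows <- list()
  for (r in seq_len(nrow(lm_))) {
    tr <- traces[[as.character(lm_$cow_id[r])]]
    if (is.null(tr) || nrow(tr) == 0L) next
    res <- suppressWarnings(
      post_meal_delta(tr, lm_[r, ], post_offset = post_offset, n_avg = n_avg))
    if (is.null(res)) next
    rows[[length(rows) + 1L]] <- data.frame(
      cow_id = lm_$cow_id[r], date = lm_$date[r], delta = res$delta,
      pre_temp = res$pre_temp, post_temp = res$post_temp,
      stringsAsFactors = FALSE)
  }
  per_meal <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cow_id = character(0), date = as.Date(character(0)),
               delta = numeric(0), pre_temp = numeric(0),
               post_temp = numeric(0))
  agg <- tapply(per_meal$delta, per_meal$cow_id, mean)
  per_cow <- data.frame(cow_id = names(agg),
                        postmeal_delta = as.numeric(agg),
                        n_meals = as.integer(table(per_meal$cow_id)[names(agg)]),
                        stringsAsFactors = FALSE, row.names = NULL)
  list(per_meal = per_meal, per_cow = per_cow)
}
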