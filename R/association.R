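# Cohort-adjusted associations between body-temperature phenotypes and
# feed-efficiency traits: trial-level OLS with a THI covariate and a
# THI-by-station interaction, daily linear mixed models with a random cow
# intercept, partial correlations controlling for cohort, and adjusted-R2
# comparison of nested RFI models.

drop_single_level <- function(d, vars) {
  keep <- character(0)
  for (v in vars) {
    d[[v]] <- droplevels(factor(d[[v]]))
    if (nlevels(d[[v]]) > 1L) keep <- c(keep, v)
  }
  list(data = d, keep = keep)
}

#' Trial-level association regression
#'
#' OLS of a per-cow efficiency trait on a per-cow temperature trait with
#' cohort as a categorical effect, the per-cow window THI as a covariate,
#' and a THI-by-station interaction (station main effect included whenever
#' the interaction is). Factors with a single observed level are dropped
#' from the model (a single station makes the interaction unidentifiable).
#'
#' @param data data.frame with one row per cow
#' @param response name of the efficiency-trait column (kg/d, Mcal/d, ...)
#' @param temp_trait name of the temperature-trait column
#' @param cohort,thi,station column names (defaults "cohort", "thi_cow",
#'   "station")
#' @return one-row data.frame: response, temp_trait, slope, se, p_value, n,
#'   model (fixed-effect descriptor)
#' @export
regress_trait <- function(data, response, temp_trait, cohort = "cohort",
                          thi = "thi_cow", station = "station") {
  d <- data[stats::complete.cases(data[, c(response, temp_trait, cohort,
                                           thi, station)]), , drop = FALSE]
  if (stats::sd(d[[temp_trait]]) == 0)
    stop_param("temperature trait '%s' is constant across cows", temp_trait)
  ds <- drop_single_level(d, c(cohort, station))
  d <- ds$data
  rhs <- temp_trait
  if (cohort %in% ds$keep) rhs <- c(rhs, cohort)
  rhs <- c(rhs, thi)
  if (station %in% ds$keep) rhs <- c(rhs, station, paste0(thi, ":", station))
  form <- stats::reformulate(rhs, response = response)
  fit <- stats::lm(form, data = d)
  cf <- summary(fit)$coefficients
  if (!temp_trait %in% rownames(cf))
    stop_param("temperature trait dropped as aliased; no slope estimable")
  data.frame(response = response, temp_trait = temp_trait,
             slope = cf[temp_trait, "Estimate"],
             se = cf[temp_trait, "Std. Error"],
             p_value = cf[temp_trait, "Pr(>|t|)"],
             n = nrow(d),
             model = paste(deparse(form), collapse = ""),
             stringsAsFactors = FALSE)
}

#' Daily association via a linear mixed model
#'
#' Association between a daily temperature trait and daily DMI, fitted by
#' REML with cohort, daily THI and a THI-by-station interaction as fixed
#' effects and a random intercept per cow. A singular random-effect fit is
#' reported, not an error. With no repeated measures per cow the model
#' degenerates and the pooled OLS fit is returned with a note.
#'
#' @param data one row per cow-day
#' @param response daily DMI column name
#' @param temp_trait daily temperature-trait column name
#' @param cow,cohort,thi,station column names
#' @return one-row data.frame: response, temp_trait, slope, se, p_value, n,
#'   n_cows, model, note (singular-fit / OLS-fallback annotations)
#' @export
daily_mixed_model <- function(data, response = "dmi_kg",
                              temp_trait = "mean_temp", cow = "cow_id",
                              cohort = "cohort", thi = "thi",
                              station = "station") {
  d <- data[stats::complete.cases(data[, c(response, temp_trait, cow,
                                           cohort, thi, station)]), ,
            drop = FALSE]
  ds <- drop_single_level(d, c(cohort, station))
  d <- ds$data
  rhs <- temp_trait
  if (cohort %in% ds$keep) rhs <- c(rhs, cohort)
  rhs <- c(rhs, thi)
  if (station %in% ds$keep) rhs <- c(rhs, station, paste0(thi, ":", station))
  note <- character(0)
  max_per_cow <- max(table(d[[cow]]))
  if (max_per_cow < 2L) {
    form <- stats::reformulate(rhs, response = response)
    fit <- stats::lm(form, data = d)
    cf <- summary(fit)$coefficients
    return(data.frame(response = response, temp_trait = temp_trait,
                      slope = cf[temp_trait, "Estimate"],
                      se = cf[temp_trait, "Std. Error"],
                      p_value = cf[temp_trait, "Pr(>|t|)"],
                      n = nrow(d), n_cows = length(unique(d[[cow]])),
                      model = paste(deparse(form), collapse = ""),
                      note = "single record per cow; pooled OLS",
                      stringsAsFactors = FALSE))
  }
  form <- stats::as.formula(paste(response, "~", paste(rhs, collapse = " + "),
                                  "+ (1 |", cow, ")"))
  fit <- lme4::lmer(form, data = d, REML = TRUE,
                    control = lme4::lmerControl(check.conv.singular = "ignore"))
  if (lme4::isSingular(fit)) note <- c(note, "singular random-effect fit")
  cf <- summary(fit)$coefficients
  est <- cf[temp_trait, "Estimate"]
  se <- cf[temp_trait, "Std. Error"]
  # Wald z test for the fixed slope; with thousands of cow-days the t and
  # normal references are indistinguishable
  p <- 2 * stats::pnorm(-abs(est / se))
  data.frame(response = response, temp_trait = temp_trait,
             slope = est, se = se, p_value = p,
             n = nrow(d), n_cows = length(unique(d[[cow]])),
             model = paste(deparse(form), collapse = ""),
             note = if (length(note)) paste(note, collapse = "; ") else "",
             stringsAsFactors = FALSE)
}

#' Partial correlation controlling for cohort
#'
#' Pearson correlation of the residuals of x and y after each is regressed
#' on cohort indicators; the p-value uses a t reference with
#' n - (number of cohorts) - 1 degrees of freedom. With a single cohort this
#' reduces to the plain Pearson correlation.
#'
#' @param x,y numeric vectors, one value per cow
#' @param cohort cohort labels, same length
#' @return list(r, p_value, n, df, n_cohorts)
#' @export
partial_correlation <- function(x, y, cohort) {
  keep <- stats::complete.cases(x, y, cohort)
  x <- x[keep]; y <- y[keep]
  g <- droplevels(factor(cohort[keep]))
  n <- length(x)
  k <- nlevels(g)
  if (n < k + 3L) stop_param("need at least %d complete cases", k + 3L)
  if (any(table(g) < 2L))
    warning("cohort(s) with a single cow contribute no within-cohort information",
            call. = FALSE)
  if (k == 1L) {
    rx <- x - mean(x)
    ry <- y - mean(y)
  } else {
    rx <- stats::residuals(stats::lm(x ~ g))
    ry <- stats::residuals(stats::lm(y ~ g))
  }
  r <- stats::cor(rx, ry)
  df <- n - k - 1L
  tval <- r * sqrt(df / (1 - r^2))
  list(r = r, p_value = 2 * stats::pt(-abs(tval), df), n = n, df = df,
       n_cohorts = k)
}
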