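#' Temperature-humidity index
#'
#' Computes the classical THI from daily mean air temperature and relative
#' humidity:
#' \deqn{THI = (1.8 t + 32) - (0.55 - 0.0055\, rh)(1.8 t - 26)}
#' where \eqn{t} is the mean air temperature in degrees Celsius at about 2 m
#' and \eqn{rh} the mean relative humidity in percent.
#'
#' @param t air temperature, degrees Celsius
#' @param rh relative humidity, percent (0-100)
#' @return unitless THI, same length as the inputs
#' @examples
#' thi(30, 50)  # 78.3
#' @export
thi <- function(t, rh) {
  if (!is.numeric(t) || !is.numeric(rh))
    stop_param("t and rh must be numeric")
  if (any(!is.finite(rh)) || any(rh < 0 | rh > 100))
    stop_param("relative humidity must lie in [0, 100]")
  (1.8 * t + 32) - (0.55 - 0.0055 * rh) * (1.8 * t - 26)
}

#' Daily THI table for station weather
#'
#' @param weather data.frame with columns station, date, t_mean_c, rh_pct
#' @return the same table with a `thi` column appended
#' @export
thi_daily <- function(weather) {
  need <- c("station", "date", "t_mean_c", "rh_pct")
  miss <- setdiff(need, names(weather))
  if (length(miss))
    stop_param("weather table is missing columns: %s",
               paste(miss, collapse = ", "))
  weather$date <- as.Date(weather$date)
  weather$thi <- thi(weather$t_mean_c, weather$rh_pct)
  weather
}

#' Mean THI over a cow's padded recording window
#'
#' The per-cow thermal covariate is the unweighted mean of daily THI at the
#' cow's station over the recording window extended by `pad` days on each
#' side.
#'
#' @param weather daily weather (see [thi_daily()]); a `thi` column is added
#'   if absent
#' @param station station identifier of the cow
#' @param start,end first and last calendar day with temperature records
#' @param pad days added on each side of the window (default 3)
#' @return single numeric THI value
#' @export
window_thi <- function(weather, station, start, end, pad = 3) {
  if (pad < 0) stop_param("pad must be >= 0")
  if (!"thi" %in% names(weather)) weather <- thi_daily(weather)
  start <- as.Date(start); end <- as.Date(end)
  if (end < start) stop_param("window end precedes start")
  days <- seq(start - pad, end + pad, by = "1 day")
  w <- weather[weather$station == station, , drop = FALSE]
  hit <- match(days, w$date)
  if (anyNA(hit))
    stop_param("weather is missing station %s on: %s", station,
               paste(format(days[is.na(hit)]), collapse = ", "))
  mean(w$thi[hit])
}
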