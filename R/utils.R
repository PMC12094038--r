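#' @keywords internal
"_PACKAGE"

# shared small helpers; no exported surface here

stop_param <- function(...) stop(sprintf(...), call. = FALSE)

#' Quantize values to a fixed step
#'
#' Rounds each value to the nearest integer multiple of `step`, emulating the
#' fixed-precision output of a temperature logger (default step 0.0625 degC).
#'
#' @param x numeric vector
#' @param step quantization step; must be > 0
#' @return numeric vector on the step grid
#' @export
quantize <- function(x, step = 0.0625) {
  if (!is.numeric(step) || length(step) != 1L || step <= 0)
    stop_param("quantization step must be a single positive number")
  round(x / step) * step
}

# derive a per-unit substream seed from a master seed; keeps every derived
# seed a valid 32-bit integer
derive_seed <- function(master, index) {
  as.integer((as.numeric(master) * 48271 + as.numeric(index) * 16807) %%
               2147483647)
}

# calendar day of a POSIXct timestamp, fixed UTC clock (station-local time is
# modelled as UTC throughout the package)
ts_date <- function(ts) as.Date(ts, tz = "UTC")

fmt_ts <- function(ts) format(ts, "%Y-%m-%dT%H:%M:%S", tz = "UTC")

parse_ts <- function(x) {
  out <- as.POSIXct(x, tz = "UTC", format = "%Y-%m-%dT%H:%M:%S")
  bad <- is.na(out) & !is.na(x)
  if (any(bad)) out[bad] <- as.POSIXct(x[bad], tz = "UTC")
  out
}
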