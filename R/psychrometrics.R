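# Vapor-pressure arithmetic shared by the estimation and simulation stages.
# All pressures in kPa, temperatures in degrees Celsius, RH in percent.

#' Construct an air state
#'
#' Bundles the chamber or canopy air conditions used throughout the package:
#' temperature, relative humidity and total air pressure. Two pressure
#' defaults recur in this workflow: 98.0 kPa for the growth chamber used in
#' drydown experiments and 94.9 kPa for the forest research site.
#'
#' @param temperature Air temperature, degrees C. Must lie within the
#'   validated range of the Magnus vapor-pressure formula (-20 to 60).
#' @param relative_humidity Relative humidity, percent (0-100).
#' @param pressure Total air pressure, kPa. Default 98.0 (growth chamber).
#' @return An object of class `air_state`: a named list with the three fields.
#' @examples
#' chamber <- air_state(20, 69)           # drydown chamber conditions
#' site    <- air_state(32.2, 29.4, 94.9) # hottest 5-min sample of a drought day
#' vpd(site)                              # ~3.4 kPa
#' @export
air_state <- function(temperature, relative_humidity, pressure = 98.0) {
  stopifnot(is.numeric(temperature), is.numeric(relative_humidity),
            is.numeric(pressure), length(pressure) == 1L)
  if (any(relative_humidity < 0 | relative_humidity > 100)) {
    stop("relative_humidity must be within [0, 100] percent", call. = FALSE)
  }
  if (pressure <= 0) stop("pressure must be positive", call. = FALSE)
  .check_temp_range(temperature)
  structure(
    list(temperature = temperature,
         relative_humidity = relative_humidity,
         pressure = pressure),
    class = "air_state"
  )
}

.check_temp_range <- function(temperature) {
  if (any(temperature < -20 | temperature > 60)) {
    stop("temperature outside the validated range -20..60 degrees C",
         call. = FALSE)
  }
  invisible(temperature)
}

#' Saturation vapor pressure of air over water
#'
#' Magnus-form formula `es = 0.6108 * exp(17.27 * T / (T + 237.3))` kPa,
#' the standard micrometeorological parameterization (FAO-56 coefficients).
#' The formula is kept in a single function so alternative parameterizations
#' (Buck, Tetens variants) can be swapped in one place.
#'
#' @param temperature Air temperature, degrees C (vectorized; -20 to 60).
#' @return Saturation vapor pressure, kPa; strictly positive and strictly
#'   increasing in temperature.
#' @examples
#' saturation_vapor_pressure(0)   # ~0.611 kPa
#' saturation_vapor_pressure(25)  # ~3.17 kPa
#' @export
saturation_vapor_pressure <- function(temperature) {
  .check_temp_range(temperature)
  0.6108 * exp(17.27 * temperature / (temperature + 237.3))
}

#' Vapor pressure deficit
#'
#' The drying power of air: `es(T) * (1 - RH/100)`, kPa.
#'
#' @param state An [air_state()], or a temperature (degrees C) if
#'   `relative_humidity` is given directly.
#' @param relative_humidity Optional RH in percent when `state` is a bare
#'   temperature vector.
#' @return VPD in kPa, nonnegative.
#' @examples
#' vpd(air_state(32.2, 29.4, 94.9))  # ~3.4 kPa, a severe hot-drought maximum
#' vpd(20, 69)                       # ~0.72 kPa, drydown chamber
#' @export
vpd <- function(state, relative_humidity = NULL) {
  st <- .as_air(state, relative_humidity)
  saturation_vapor_pressure(st$temperature) * (1 - st$relative_humidity / 100)
}

#' Actual vapor pressure of air
#'
#' `e = es(T) * RH/100`, kPa. Within this package the actual vapor pressure
#' also serves as the conserved "absolute humidity" proxy during temperature
#' elevation of a climate record: at fixed total pressure it tracks the water
#' amount in the air independent of temperature.
#'
#' @inheritParams vpd
#' @return Actual vapor pressure e in kPa, `0 <= e <= es(T)`.
#' @examples
#' actual_vapor_pressure(30, 50)  # ~2.12 kPa
#' @export
actual_vapor_pressure <- function(state, relative_humidity = NULL) {
  st <- .as_air(state, relative_humidity)
  saturation_vapor_pressure(st$temperature) * st$relative_humidity / 100
}

#' Relative humidity from actual vapor pressure
#'
#' Inverts [actual_vapor_pressure()]: `RH = 100 * e / es(T)`, capped at 100%.
#' Supersaturation (e > es) can arise transiently when a measured vapor
#' pressure series is combined with a cooler temperature; it is capped
#' silently but flagged.
#'
#' @param e Actual vapor pressure, kPa (nonnegative, vectorized).
#' @param temperature Air temperature, degrees C.
#' @return A tibble with columns `rh` (percent, capped at 100) and `capped`
#'   (logical flag, TRUE where the uncapped value exceeded 100).
#' @examples
#' rh_from_vapor_pressure(2.12, 35)  # ~37.7 %
#' @export
rh_from_vapor_pressure <- function(e, temperature) {
  stopifnot(all(e >= 0))
  raw <- 100 * e / saturation_vapor_pressure(temperature)
  tibble::tibble(rh = pmin(raw, 100), capped = raw > 100)
}

# Accept either an air_state or (temperature, rh) arguments.
.as_air <- function(state, relative_humidity) {
  if (inherits(state, "air_state")) return(state)
  if (is.null(relative_humidity)) {
    stop("supply an air_state or both temperature and relative_humidity",
         call. = FALSE)
  }
  air_state(state, relative_humidity)
}

#' @export
print.air_state <- function(x, ...) {
  cat(sprintf("<air_state> %.1f degC, %.1f%% RH, %.1f kPa (VPD %.2f kPa)\n",
              x$temperature[1], x$relative_humidity[1], x$pressure,
              vpd(x)[1]))
  invisible(x)
}
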