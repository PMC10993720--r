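# Diurnal canopy climate: container and seeded generator. The generator
# emulates the canopy record of a hot drought day: a smooth diurnal
# temperature arc sampled every 5 min from 08:00 to 20:00 with near-constant
# absolute humidity, so relative humidity bottoms out when temperature peaks.

#' Construct a diurnal climate record
#'
#' A uniformly sampled day of canopy air temperature plus humidity. Supply
#' either a relative-humidity series (`rh`, percent) or an actual
#' vapor-pressure series (`e`, kPa); the other is derived. VPD is always
#' derived.
#'
#' @param time_s Seconds since the first sample; must be uniformly spaced.
#' @param temperature Air temperature series, degrees C.
#' @param rh Relative humidity series, percent (optional if `e` given).
#' @param e Actual vapor pressure series, kPa (optional if `rh` given).
#' @param pressure Site air pressure, kPa (default 94.9, a mid-elevation
#'   forest site).
#' @return A tibble of class `diurnal_climate` with columns `time_s`,
#'   `temperature`, `rh`, `e`, `vpd` and an `rh_capped` flag column;
#'   attribute `pressure`.
#' @export
diurnal_climate <- function(time_s, temperature, rh = NULL, e = NULL,
                            pressure = 94.9) {
  stopifnot(length(time_s) >= 2, length(temperature) == length(time_s))
  steps <- diff(time_s)
  if (any(abs(steps - steps[1]) > 1e-9)) {
    stop("time_s must be uniformly spaced", call. = FALSE)
  }
  capped <- rep(FALSE, length(time_s))
  if (is.null(rh) && is.null(e)) stop("supply rh or e", call. = FALSE)
  if (is.null(e)) {
    if (any(rh < 0 | rh > 100)) stop("rh outside [0, 100]", call. = FALSE)
    e <- actual_vapor_pressure(temperature, rh)
  } else {
    conv <- rh_from_vapor_pressure(e, temperature)
    rh <- conv$rh
    capped <- conv$capped
  }
  out <- tibble::tibble(
    time_s = as.numeric(time_s),
    temperature = temperature,
    rh = rh,
    e = e,
    vpd = saturation_vapor_pressure(temperature) - e,
    rh_capped = capped
  )
  # capped samples are saturated: VPD clamps at zero
  out$vpd[out$rh_capped] <- 0
  structure(out, pressure = pressure,
            class = c("diurnal_climate", class(out)))
}

#' @export
print.diurnal_climate <- function(x, ...) {
  cat(sprintf(
    "<diurnal_climate> %d samples @ %gs | T %.1f-%.1f degC | max VPD %.2f kPa | P %.1f kPa\n",
    nrow(x), x$time_s[2] - x$time_s[1], min(x$temperature),
    max(x$temperature), max(x$vpd), attr(x, "pressure")))
  NextMethod()
}

#' Parameters for a synthetic diurnal climate day
#'
#' @param t_min,t_max Daily minimum and maximum air temperature, degrees C.
#'   The maximum is attained exactly at the mid-day sample.
#' @param vapor_pressure Actual vapor pressure held constant across the day,
#'   kPa. Ignored when `rh_at_tmax` is given.
#' @param rh_at_tmax Convenience: choose the constant vapor pressure such
#'   that RH equals this value (percent) at `t_max`, i.e. the daily RH
#'   minimum. Default 29.4, giving a ~3.4 kPa VPD peak for a 32.2 degC day.
#' @param start,end Clock times bounding the record, seconds of day
#'   (defaults 08:00 and 20:00).
#' @param step Sampling interval, s (default 300 = 5 min).
#' @param noise_sd Gaussian jitter added to the temperature arc, degrees C
#'   (default 0: deterministic).
#' @param pressure Site pressure, kPa.
#' @param seed Integer seed (used only when `noise_sd > 0`).
#' @return A list of class `climate_sim_params`.
#' @export
climate_sim_params <- function(t_min = 18, t_max = 32.2,
                               vapor_pressure = NULL, rh_at_tmax = 29.4,
                               start = 8 * 3600, end = 20 * 3600,
                               step = 300, noise_sd = 0, pressure = 94.9,
                               seed = 1L) {
  if (t_max < t_min) stop("t_max must be >= t_min", call. = FALSE)
  if ((end - start) %% step != 0) {
    stop("step must divide the day span", call. = FALSE)
  }
  if (is.null(vapor_pressure)) {
    vapor_pressure <- actual_vapor_pressure(t_max, rh_at_tmax)
  }
  structure(list(t_min = t_min, t_max = t_max,
                 vapor_pressure = vapor_pressure,
                 start = start, end = end, step = step,
                 noise_sd = noise_sd, pressure = pressure,
                 seed = as.integer(seed)),
            class = "climate_sim_params")
}

#' Simulate a diurnal climate day
#'
#' Temperature follows a half-sine arc from `t_min` at 08:00 up to `t_max` at
#' the mid-point of the record and back; the actual vapor pressure is held
#' constant (the stable-absolute-humidity regime observed on hot drought
#' days), so RH and VPD are derived series.
#'
#' @param params A [climate_sim_params()] object.
#' @return A [diurnal_climate()] record (145 samples for the defaults).
#' @examples
#' day <- simulate_diurnal_climate(climate_sim_params())
#' max(day$temperature)  # 32.2
#' max(day$vpd)          # ~3.4 kPa
#' @export
simulate_diurnal_climate <- function(params = climate_sim_params()) {
  stopifnot(inherits(params, "climate_sim_params"))
  p <- params
  time_s <- seq(0, p$end - p$start, by = p$step)
  frac <- time_s / (p$end - p$start)
  temp <- p$t_min + (p$t_max - p$t_min) * sin(pi * frac)
  if (p$noise_sd > 0) {
    restore <- .Random.seed_exists()
    set.seed(p$seed)
    temp <- temp + stats::rnorm(length(temp), 0, p$noise_sd)
    # jitter must not push the series above the nominal maximum
    temp <- pmin(temp, p$t_max)
    restore()
  }
  diurnal_climate(time_s, temp, e = rep(p$vapor_pressure, length(time_s)),
                  pressure = p$pressure)
}
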