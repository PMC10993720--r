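# Residual whole-tree canopy transpiration at full stomatal closure.
# The kernel is gmin * VPD / P (mmol m-2 leaf s-1); a day is a left-Riemann
# sum over the 5-min climate record, scaled to stem basal area through R
# (canopy projected leaf area per basal area) and converted from mmol of
# water to litres via the molar mass (18.015 g mol-1, density 1 g mL-1).

#' Canopy scaling specification for one species
#'
#' @param species Species label.
#' @param r_leaf_basal Ratio of canopy projected leaf area to stem basal
#'   area, m2 m-2 (the `R` scaling constant).
#' @param basal_area Optional stem basal area of a reference tree, m2; when
#'   given, absolute per-tree totals are reported.
#' @param canopy_leaf_area Optional canopy leaf area, m2, for per-canopy
#'   totals.
#' @return A list of class `canopy_spec`.
#' @export
canopy_spec <- function(species, r_leaf_basal, basal_area = NULL,
                        canopy_leaf_area = NULL) {
  if (r_leaf_basal < 0) stop("r_leaf_basal must be >= 0", call. = FALSE)
  structure(list(species = species, r_leaf_basal = r_leaf_basal,
                 basal_area = basal_area,
                 canopy_leaf_area = canopy_leaf_area),
            class = "canopy_spec")
}

#' Instantaneous residual transpiration flux
#'
#' `gmin * vpd / pressure`, mmol per m2 leaf per second.
#'
#' @param gmin Minimum conductance, mmol m-2 s-1.
#' @param vpd Vapor pressure deficit, kPa.
#' @param pressure Air pressure, kPa (default 94.9, forest site).
#' @return Flux, mmol m-2 s-1.
#' @examples
#' instantaneous_flux(1, 1)  # ~0.0105
#' @export
instantaneous_flux <- function(gmin, vpd, pressure = 94.9) {
  stopifnot(pressure > 0)
  gmin * vpd / pressure
}

# shared mmol -> litre factor (18.015 g mol-1 at 1 g mL-1)
MMOL_TO_L <- MOLAR_MASS_WATER * 1e-6

#' Integrate residual canopy transpiration over one day
#'
#' Left-Riemann sum of the flux kernel over the uniform climate record:
#' each of the `n-1` intervals contributes
#' `gmin(T_i) * VPD_i / P * dt * R` mmol per m2 basal area, using the
#' interval's left endpoint. Leaf temperature is taken equal to air
#' temperature and boundary-layer conductance is neglected.
#'
#' @param model Either a `gmin_exp_fit` (see [fit_exponential()]), a plain
#'   list with `a` and `b`, or a single fixed g_min value (mmol m-2 s-1).
#' @param climate A [diurnal_climate()] record.
#' @param spec A [canopy_spec()].
#' @param extrapolation_margin Warn when the climate exceeds the model's
#'   calibration range by more than this many degrees C (default 5).
#' @return A one-row tibble of class `emin_result`: `species`, `delta`
#'   (temperature elevation attached to the climate, 0 for a measured day),
#'   `e_std` (L per m2 basal area per day), `e_tree` (L per tree, NA without
#'   a basal area), `e_canopy` (L per canopy, NA without a leaf area),
#'   `t_max`, `vpd_max`.
#' @examples
#' day <- simulate_diurnal_climate(climate_sim_params())
#' integrate_emin_day(2.5, day, canopy_spec("Fagus-like", 1161.3))
#' @export
integrate_emin_day <- function(model, climate, spec,
                               extrapolation_margin = 5) {
  stopifnot(inherits(climate, "diurnal_climate"),
            inherits(spec, "canopy_spec"))
  gmin_fun <- .as_gmin_model(model, climate, extrapolation_margin)
  n <- nrow(climate)
  dt <- climate$time_s[2] - climate$time_s[1]
  pressure <- attr(climate, "pressure")
  left <- seq_len(n - 1L)
  flux <- instantaneous_flux(gmin_fun(climate$temperature[left]),
                             climate$vpd[left], pressure)       # mmol m-2 s-1
  per_leaf_area <- sum(flux) * dt * MMOL_TO_L                    # L m-2 leaf
  e_std <- per_leaf_area * spec$r_leaf_basal                     # L m-2 basal
  out <- tibble::tibble(
    species = spec$species,
    delta = attr(climate, "delta") %||% 0,
    e_std = e_std,
    e_tree = if (is.null(spec$basal_area)) NA_real_ else
      e_std * spec$basal_area,
    e_canopy = if (is.null(spec$canopy_leaf_area)) NA_real_ else
      per_leaf_area * spec$canopy_leaf_area,
    t_max = max(climate$temperature),
    vpd_max = max(climate$vpd)
  )
  structure(out, class = c("emin_result", class(out)))
}

.as_gmin_model <- function(model, climate, extrapolation_margin) {
  if (is.numeric(model) && length(model) == 1L) {
    if (model < 0) stop("fixed gmin must be >= 0", call. = FALSE)
    return(function(temp) rep(model, length(temp)))
  }
  if (!is.null(model$a) && !is.null(model$b)) {
    if (inherits(model, "gmin_exp_fit") && !is.null(model$data)) {
      fitted_max <- max(model$data$temperature)
      if (max(climate$temperature) > fitted_max + extrapolation_margin) {
        warning(sprintf(
          "climate reaches %.1f degC, > %.1f degC beyond the fitted range (max %.1f)",
          max(climate$temperature), extrapolation_margin, fitted_max),
          call. = FALSE)
      }
    }
    return(function(temp) predict_gmin(model, temp))
  }
  stop("model must be a fixed gmin or an exponential fit with a and b",
       call. = FALSE)
}

#' Elevate a diurnal temperature record at constant absolute humidity
#'
#' Adds `delta` degrees C to every temperature sample while holding the
#' actual vapor-pressure series fixed, so VPD rises with the elevation;
#' relative humidity is recomputed (capped at 100% where the base day was
#' near saturation, with the cap flagged).
#'
#' @param climate A [diurnal_climate()].
#' @param delta Temperature elevation, degrees C (>= 0).
#' @return A new `diurnal_climate` with attribute `delta`.
#' @export
elevate_climate <- function(climate, delta) {
  stopifnot(inherits(climate, "diurnal_climate"), delta >= 0)
  out <- diurnal_climate(climate$time_s, climate$temperature + delta,
                         e = climate$e, pressure = attr(climate, "pressure"))
  attr(out, "delta") <- (attr(climate, "delta") %||% 0) + delta
  out
}

#' Temperature-elevation scenario sweep
#'
#' Repeats the daily integration while the whole diurnal temperature curve
#' is raised in `step`-degree increments until its maximum reaches `t_cap`,
#' holding absolute humidity fixed throughout.
#'
#' @inheritParams integrate_emin_day
#' @param step Elevation increment, degrees C (default 0.1).
#' @param t_cap Maximum temperature at which the sweep stops, degrees C
#'   (default 50).
#' @return A tibble of [integrate_emin_day()] rows, one per scenario, with
#'   `delta` running from 0 to `t_cap - max(T)` inclusive.
#' @examples
#' day <- simulate_diurnal_climate(climate_sim_params(t_max = 32.2))
#' sweep <- scenario_sweep(2.5, day, canopy_spec("demo", 600))
#' nrow(sweep)  # 179 scenarios
#' @export
scenario_sweep <- function(model, climate, spec, step = 0.1, t_cap = 50,
                           extrapolation_margin = Inf) {
  stopifnot(step > 0)
  t0 <- max(climate$temperature)
  if (t_cap < t0) stop("t_cap is below the base day's maximum", call. = FALSE)
  n_steps <- floor(round((t_cap - t0) / step, 9)) # guard float drift
  deltas <- round(seq(0, by = step, length.out = n_steps + 1L), 9)
  rows <- lapply(deltas, function(d) {
    integrate_emin_day(model, elevate_climate(climate, d), spec,
                       extrapolation_margin = extrapolation_margin)
  })
  dplyr::bind_rows(rows)
}

#' Daily water loss as a function of canopy leaf area
#'
#' The per-leaf-area daily integral scaled to a range of canopy sizes;
#' exactly linear through the origin in area.
#'
#' @inheritParams integrate_emin_day
#' @param areas Canopy leaf areas, m2 (default `seq(10, 200, by = 10)`).
#' @return A tibble with `canopy_leaf_area` and `e_canopy` (L per day).
#' @export
leaf_area_sweep <- function(model, climate, areas = seq(10, 200, by = 10),
                            extrapolation_margin = 5) {
  stopifnot(all(areas >= 0))
  base <- integrate_emin_day(model, climate,
                             canopy_spec("sweep", r_leaf_basal = 1,
                                         canopy_leaf_area = 1),
                             extrapolation_margin = extrapolation_margin)
  tibble::tibble(canopy_leaf_area = areas,
                 e_canopy = base$e_canopy * areas)
}
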