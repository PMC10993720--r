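# Temperature response of minimum conductance. Two models are fitted side by
# side: an exponential g_min(T) = a * exp(b * T) (the default forward model
# for canopy simulation) and a continuous two-segment linear model whose
# breakpoint, when significant, marks the phase-transition temperature of the
# cuticular wax barrier.

#' Fit an exponential temperature response
#'
#' Nonlinear least squares fit of `gmin = a * exp(b * T)` initialized from a
#' log-linear OLS fit. Fitting is on the natural scale so absolute residuals
#' are weighted as measured.
#'
#' @param observations Data frame with columns `temperature` (degrees C) and
#'   `gmin` (mmol m-2 s-1); a `species` column, if present, is carried into
#'   the result label.
#' @return An object of class `gmin_exp_fit`: list with `a`, `b`, `sigma`
#'   (residual SD), `r_squared`, `n`, `data`, `species`.
#' @examples
#' obs <- data.frame(temperature = c(25, 30, 35, 40, 45, 50),
#'                   gmin = 0.5 * exp(0.06 * c(25, 30, 35, 40, 45, 50)))
#' fit_exponential(obs)
#' @export
fit_exponential <- function(observations) {
  obs <- .check_temp_obs(observations, min_temps = 4)
  # log-linear start values; exact when the data are noiseless
  start_fit <- stats::lm(log(gmin) ~ temperature, data = obs)
  start <- list(a = exp(unname(stats::coef(start_fit)[1])),
                b = unname(stats::coef(start_fit)[2]))
  # the log-linear start is already exact for noiseless data; an exact fit
  # makes the nls gradient step degenerate, so accept it directly
  pred0 <- start$a * exp(start$b * obs$temperature)
  if (sum((obs$gmin - pred0)^2) <= 1e-18 * sum(obs$gmin^2)) {
    return(structure(list(a = start$a, b = start$b, sigma = 0,
                          r_squared = 1, n = nrow(obs), data = obs,
                          species = .species_label(obs)),
                     class = "gmin_exp_fit"))
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(gmin ~ a * exp(b * temperature), data = obs,
                      start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) {
      stop(sprintf(
        "exponential fit did not converge (%s); log-linear fallback: a=%.4g, b=%.4g",
        conditionMessage(e), start$a, start$b), call. = FALSE)
    })
  co <- stats::coef(fit)
  resid <- obs$gmin - co["a"] * exp(co["b"] * obs$temperature)
  ss_tot <- sum((obs$gmin - mean(obs$gmin))^2)
  structure(list(a = unname(co["a"]), b = unname(co["b"]),
                 sigma = sqrt(sum(resid^2) / max(nrow(obs) - 2, 1)),
                 r_squared = if (ss_tot > 0) 1 - sum(resid^2) / ss_tot else NA_real_,
                 n = nrow(obs), data = obs,
                 species = .species_label(obs)),
            class = "gmin_exp_fit")
}

.species_label <- function(obs) {
  if ("species" %in% names(obs)) obs$species[1] else NA_character_
}

.check_temp_obs <- function(observations, min_temps, min_n = min_temps) {
  obs <- tibble::as_tibble(observations)
  stopifnot(all(c("temperature", "gmin") %in% names(obs)))
  if (any(obs$gmin <= 0)) stop("gmin must be positive", call. = FALSE)
  if (length(unique(obs$temperature)) < min_temps) {
    stop(sprintf("need observations at >= %d distinct temperatures",
                 min_temps), call. = FALSE)
  }
  if (nrow(obs) < min_n) {
    stop(sprintf("need >= %d observations", min_n), call. = FALSE)
  }
  obs
}

#' Predict minimum conductance from an exponential fit
#'
#' @param fit A `gmin_exp_fit` (from [fit_exponential()]), or a plain list
#'   with elements `a` and `b`.
#' @param temperature Degrees C (vectorized).
#' @return Predicted g_min, mmol m-2 s-1.
#' @export
predict_gmin <- function(fit, temperature) {
  stopifnot(is.numeric(fit$a), is.numeric(fit$b))
  fit$a * exp(fit$b * temperature)
}

#' @export
print.gmin_exp_fit <- function(x, ...) {
  cat(sprintf(
    "<gmin_exp_fit>%s gmin = %.4g * exp(%.4g * T), n = %d, R2 = %.3f\n",
    if (is.na(x$species)) "" else paste0(" ", x$species, ":"),
    x$a, x$b, x$n, x$r_squared))
  invisible(x)
}

#' Ratio between conductances at two temperatures
#'
#' The fold change `g_high / g_low` summarizing the strength of a
#' temperature response over an interval (e.g. 25 to 50 degrees C).
#'
#' @param g_low Conductance at the lower temperature.
#' @param g_high Conductance at the higher temperature.
#' @return The ratio, dimensionless.
#' @examples
#' fold_change(2.8, 9.7)  # ~3.5
#' @export
fold_change <- function(g_low, g_high) {
  stopifnot(g_low > 0)
  g_high / g_low
}

#' Segmented (two-phase) temperature response with breakpoint detection
#'
#' Fits a continuous two-segment linear model
#' `gmin = b0 + b1*T + b2*(T - t_break)+` by profiling the residual sum of
#' squares over candidate breakpoints: a grid search at 0.1 degree C
#' resolution over the interior of the temperature range (a margin at each
#' edge is excluded) followed by golden-section refinement. Significance of
#' the breakpoint is a nested F-test of the two-segment model against the
#' single line, with the breakpoint counted as an estimated parameter
#' (df 2 and n-4). The breakpoint SE comes from a seeded nonparametric
#' bootstrap.
#'
#' @param observations Data frame with `temperature` and `gmin` columns
#'   (>= 6 rows spanning >= 4 distinct temperatures).
#' @param edge_margin Fraction of the temperature range excluded from the
#'   breakpoint search at each edge (default 0.10).
#' @param alpha Significance level for the breakpoint F-test (default 0.05).
#' @param n_boot Bootstrap resamples for the breakpoint SE (default 1000;
#'   0 skips the bootstrap).
#' @param seed Seed for the bootstrap.
#' @return An object of class `gmin_breakpoint_fit`: `t_break`, `slope_low`,
#'   `slope_high`, `t_break_se`, `p_value`, `converged` (FALSE when the
#'   optimum sits at the search edge, i.e. no interior breakpoint),
#'   `significant`, `sse_segmented`, `sse_line`, `n`.
#' @examples
#' set.seed(2)
#' tt <- rep(c(25, 30, 35, 40, 45, 50), each = 3)
#' yy <- 1 + 0.05 * tt + 0.4 * pmax(tt - 40, 0) + rnorm(length(tt), 0, 0.05)
#' fit_segmented(data.frame(temperature = tt, gmin = yy), n_boot = 50)
#' @export
fit_segmented <- function(observations, edge_margin = 0.10, alpha = 0.05,
                          n_boot = 1000, seed = 1L) {
  obs <- .check_temp_obs(observations, min_temps = 4, min_n = 6)
  x <- obs$temperature
  y <- obs$gmin
  core <- .segment_core(x, y, edge_margin)
  n <- length(x)
  sse_line <- sum(.lm.fit(cbind(1, x), y)$residuals^2)
  f_stat <- ((sse_line - core$sse) / 2) / (core$sse / (n - 4))
  p_value <- stats::pf(f_stat, 2, n - 4, lower.tail = FALSE)

  t_break_se <- NA_real_
  if (n_boot > 0 && core$converged) {
    restore <- .Random.seed_exists()
    set.seed(as.integer(seed))
    bps <- vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      # resamples may collapse the temperature spread; skip those
      if (length(unique(x[idx])) < 4) return(NA_real_)
      bc <- .segment_core(x[idx], y[idx], edge_margin, refine = FALSE)
      if (bc$converged) bc$t_break else NA_real_
    }, numeric(1))
    restore()
    t_break_se <- stats::sd(bps, na.rm = TRUE)
  }

  structure(list(t_break = core$t_break,
                 slope_low = core$slope_low, slope_high = core$slope_high,
                 t_break_se = t_break_se, p_value = p_value,
                 converged = core$converged,
                 significant = core$converged && p_value < alpha,
                 sse_segmented = core$sse, sse_line = sse_line, n = n,
                 species = .species_label(obs)),
            class = "gmin_breakpoint_fit")
}

# Profile SSE over breakpoints: grid at 0.1 degC, optional golden-section
# refinement within one grid cell either side of the best grid point.
.segment_core <- function(x, y, edge_margin, refine = TRUE) {
  rng <- range(x)
  margin <- edge_margin * diff(rng)
  lo <- rng[1] + margin
  hi <- rng[2] - margin
  sse_at <- function(bp) {
    f <- .lm.fit(cbind(1, x, pmax(x - bp, 0)), y)
    sum(f$residuals^2)
  }
  grid <- seq(lo, hi, by = 0.1)
  if (length(grid) < 3) {
    return(list(t_break = NA_real_, slope_low = NA_real_,
                slope_high = NA_real_, sse = sse_at(mean(rng)),
                converged = FALSE))
  }
  sse <- vapply(grid, sse_at, numeric(1))
  best <- which.min(sse)
  at_edge <- best == 1L || best == length(grid)
  bp <- grid[best]
  if (refine && !at_edge) {
    opt <- stats::optimize(sse_at, interval = c(grid[best - 1], grid[best + 1]))
    if (opt$objective <= sse[best]) bp <- opt$minimum
  }
  f <- .lm.fit(cbind(1, x, pmax(x - bp, 0)), y)
  co <- f$coefficients
  list(t_break = bp, slope_low = co[2], slope_high = co[2] + co[3],
       sse = sum(f$residuals^2), converged = !at_edge)
}

#' @export
print.gmin_breakpoint_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<gmin_breakpoint_fit> no interior breakpoint\n")
    return(invisible(x))
  }
  cat(sprintf(
    "<gmin_breakpoint_fit>%s t_break = %.1f +- %s degC (p = %.3g%s), slopes %.3g / %.3g\n",
    if (is.na(x$species)) "" else paste0(" ", x$species, ":"),
    x$t_break,
    if (is.na(x$t_break_se)) "?" else sprintf("%.1f", x$t_break_se),
    x$p_value, if (x$significant) ", significant" else "",
    x$slope_low, x$slope_high))
  invisible(x)
}
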