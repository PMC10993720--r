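# Forward simulator for detached-leaf drydown experiments. The generator
# inverts the conductance equation the estimator is built on: conductance is
# prescribed as a function of relative water content (RWC), mass loss is
# integrated through time, then balance noise is added to the weighings.

MOLAR_MASS_WATER <- 18.015 # g mol^-1, i.e. mg mmol^-1

#' Parameters for a synthetic drydown experiment
#'
#' Encodes a two-phase desiccation: an initial stomatal phase with high
#' conductance (`stomatal_g0`) that decays exponentially as RWC falls from 1
#' towards `closure_rwc`, and a cuticular plateau at `true_gmin` below full
#' closure. Full stomatal closure below 80% RWC (reached after roughly 2-3 h)
#' is the default, matching the behaviour of temperate broadleaf trees dried
#' at 20 degC / 69% RH.
#'
#' Defaults describe one rehydrated beech-like leaf: 0.1 g dry mass,
#' 0.28 g saturated mass, 30 cm2 two-sided area, weighed every 2.5 h for 30 h
#' on a +-0.2 mg balance.
#'
#' @param true_gmin Cuticular (minimum) conductance, mmol m-2 s-1.
#' @param stomatal_g0 Conductance before stomatal closure, mmol m-2 s-1.
#' @param closure_rwc RWC below which stomata are fully closed (0.5-1.0].
#'   `1.0` makes the leaf cuticular from the first weighing.
#' @param leaf_area_two_sided Total two-sided leaf area, m2.
#' @param w_sat,w_dry Saturated and oven-dry mass, g.
#' @param chamber An [air_state()] for the drying chamber.
#' @param weighing_interval Seconds between weighings.
#' @param duration Total drydown duration, s.
#' @param balance_sd Additive Gaussian balance noise per weighing, g
#'   (default 2e-4 g = 0.2 mg, a high-precision laboratory balance).
#' @param seed Integer seed; identical seed and parameters give bit-identical
#'   output.
#' @return A list of class `drydown_sim_params`.
#' @export
drydown_sim_params <- function(true_gmin = 2.0,
                               stomatal_g0 = 20,
                               closure_rwc = 0.80,
                               leaf_area_two_sided = 0.003,
                               w_sat = 0.28,
                               w_dry = 0.10,
                               chamber = air_state(20, 69, 98.0),
                               weighing_interval = 9000,
                               duration = 108000,
                               balance_sd = 2e-4,
                               seed = 1L) {
  p <- list(true_gmin = true_gmin, stomatal_g0 = stomatal_g0,
            closure_rwc = closure_rwc,
            leaf_area_two_sided = leaf_area_two_sided,
            w_sat = w_sat, w_dry = w_dry, chamber = chamber,
            weighing_interval = weighing_interval, duration = duration,
            balance_sd = balance_sd, seed = as.integer(seed))
  if (!(p$w_sat > p$w_dry && p$w_dry > 0)) {
    stop("require w_sat > w_dry > 0", call. = FALSE)
  }
  if (p$true_gmin > p$stomatal_g0) {
    stop("true_gmin must not exceed stomatal_g0", call. = FALSE)
  }
  if (p$closure_rwc <= 0.5 || p$closure_rwc > 1.0) {
    stop("closure_rwc must lie in (0.5, 1.0]", call. = FALSE)
  }
  if (p$true_gmin < 0 || p$leaf_area_two_sided <= 0 ||
      p$weighing_interval <= 0 || p$duration < p$weighing_interval ||
      p$balance_sd < 0) {
    stop("invalid drydown simulation parameters", call. = FALSE)
  }
  structure(p, class = "drydown_sim_params")
}

# Conductance as a function of RWC: exponential relaxation from stomatal_g0
# at RWC = 1 to true_gmin at the closure point; pure cuticular below it.
# The decay constant is fixed so the stomatal excess has dropped to 1% at
# closure_rwc, keeping the plateau clean.
.g_of_rwc <- function(rwc, true_gmin, stomatal_g0, closure_rwc) {
  if (closure_rwc >= 1.0) return(rep(true_gmin, length(rwc)))
  k <- log(100) / (1 - closure_rwc)
  excess <- (stomatal_g0 - true_gmin) * exp(-k * pmax(1 - rwc, 0))
  ifelse(rwc <= closure_rwc, true_gmin, true_gmin + excess)
}

#' Simulate one detached-leaf drydown experiment
#'
#' Integrates the mass balance `dm/dt = -g(RWC) * VPD / P * A * M_w` forward
#' in time (explicit Euler at a fine internal step), records masses at the
#' weighing times, then adds truncated Gaussian balance noise. The true
#' cuticular conductance is carried along in the output so recovery tests can
#' compare the downstream estimate against it.
#'
#' @param params A [drydown_sim_params()] object.
#' @param internal_step Internal integration step, s. Must divide the
#'   weighing interval.
#' @return A [drydown_record()] with attributes `true_gmin` and
#'   `masses_noiseless` (the pre-noise weighings).
#' @examples
#' rec <- simulate_drydown(drydown_sim_params(true_gmin = 2, seed = 42))
#' estimate_gmin(conductance_curve(rec))$gmin
#' @export
simulate_drydown <- function(params = drydown_sim_params(),
                             internal_step = 60) {
  stopifnot(inherits(params, "drydown_sim_params"))
  if (params$weighing_interval %% internal_step != 0) {
    stop("internal_step must divide weighing_interval", call. = FALSE)
  }
  p <- params
  vpd_kpa <- vpd(p$chamber)
  pressure <- p$chamber$pressure
  n_weigh <- floor(p$duration / p$weighing_interval) + 1L
  times <- (seq_len(n_weigh) - 1L) * p$weighing_interval

  # g -> mass-loss rate (g s^-1): flux mmol s^-1 times molar mass in g mmol^-1
  rate_of_g <- function(g) g * vpd_kpa / pressure * p$leaf_area_two_sided *
    MOLAR_MASS_WATER * 1e-3

  water <- p$w_sat - p$w_dry
  steps_per_weigh <- p$weighing_interval / internal_step
  masses <- numeric(n_weigh)
  masses[1] <- p$w_sat
  m <- p$w_sat
  for (i in seq_len(n_weigh - 1L)) {
    for (s in seq_len(steps_per_weigh)) {
      rwc <- (m - p$w_dry) / water
      g <- .g_of_rwc(rwc, p$true_gmin, p$stomatal_g0, p$closure_rwc)
      m <- m - rate_of_g(g) * internal_step
      if (m < p$w_dry) { m <- p$w_dry; break }
    }
    masses[i + 1L] <- m
  }

  noisy <- masses
  if (p$balance_sd > 0) {
    old <- .Random.seed_exists()
    set.seed(p$seed)
    noise <- stats::rnorm(n_weigh, 0, p$balance_sd)
    noisy <- masses + noise
    # a weighing may never read higher than the previous one by more than
    # 3 sd: truncate apparent mass gains beyond balance resolution
    for (i in seq_len(n_weigh - 1L)) {
      cap <- noisy[i] + 3 * p$balance_sd
      if (noisy[i + 1L] > cap) noisy[i + 1L] <- cap
    }
    noisy <- pmax(noisy, p$w_dry)  # a reading cannot fall below dry mass
    old() # restore RNG state
  }

  rec <- drydown_record(
    sample_id = sprintf("sim-%d", p$seed),
    species = "synthetic", tree_id = "sim", leaf_age_class = "n/a",
    times = times, masses = noisy,
    w_sat = p$w_sat, w_dry = p$w_dry,
    area_two_sided = p$leaf_area_two_sided,
    chamber = p$chamber
  )
  attr(rec, "true_gmin") <- p$true_gmin
  attr(rec, "masses_noiseless") <- masses
  rec
}

# Save/restore the global RNG state so seeded generators do not perturb the
# caller's random stream. Returns a restore function.
.Random.seed_exists <- function() {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  saved <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  function() {
    if (had) assign(".Random.seed", saved, envir = globalenv())
  }
}
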