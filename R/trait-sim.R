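# Seeded generator for cross-species trait tables with a configurable
# correlation structure between minimum conductance and stomatal/cuticular
# traits: g_min rises with g_max and total cuticle thickness and falls with
# stomatal size, the sign pattern seen across temperate tree species.

#' Parameters for a synthetic species trait table
#'
#' Traits are generated from a latent species axis `z` (standard normal):
#' `log10(gmin)` moves along `z`, and each correlated trait responds to `z`
#' with its own effect size (correlation strength on the log or linear scale)
#' plus independent Gaussian noise. An effect size of 1 with zero noise gives
#' |r| = 1; effect 0 decouples the trait.
#'
#' @param n_species Number of species rows (>= 3).
#' @param effect_gmax Effect of the latent axis on log10(g_max); positive
#'   means g_min and g_max rise together. Default 0.8.
#' @param effect_ct Effect on total cuticular thickness (positive). Default 0.7.
#' @param effect_ss Effect on log10(stomatal size); negative couples large
#'   stomata to low g_min. Default -0.7.
#' @param noise_sd Independent noise added to every generated trait on its
#'   generative scale. Default 0.3.
#' @param seed Integer seed.
#' @return A list of class `trait_sim_params`.
#' @export
trait_sim_params <- function(n_species = 9, effect_gmax = 0.8,
                             effect_ct = 0.7, effect_ss = -0.7,
                             noise_sd = 0.3, seed = 1L) {
  if (n_species < 3) stop("n_species must be >= 3", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be nonnegative", call. = FALSE)
  structure(list(n_species = as.integer(n_species),
                 effect_gmax = effect_gmax, effect_ct = effect_ct,
                 effect_ss = effect_ss, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "trait_sim_params")
}

#' Simulate a species trait table
#'
#' @param params A [trait_sim_params()] object.
#' @return A tibble with one row per species: `species`, `functional_group`,
#'   `gmin_25c` (mmol m-2 s-1), `g_max` (mmol m-2 s-1), `stomatal_density`
#'   (mm-2), `guard_cell_length`, `guard_cell_width` (um), `stomatal_size`
#'   (um2), `f_gc`, `ct_adaxial`, `ct_abaxial`, `ct_total` (um), `sla`
#'   (m2 kg-1).
#' @examples
#' tr <- simulate_trait_table(trait_sim_params(seed = 7))
#' correlate_traits(tr)
#' @export
simulate_trait_table <- function(params = trait_sim_params()) {
  stopifnot(inherits(params, "trait_sim_params"))
  p <- params
  restore <- .Random.seed_exists()
  set.seed(p$seed)
  on.exit(restore())
  n <- p$n_species
  z <- stats::rnorm(n)

  resp <- function(effect, scale_sd = 1) {
    effect * z * scale_sd + stats::rnorm(n, 0, p$noise_sd * scale_sd)
  }

  # centres chosen at the magnitudes typical of temperate canopy trees
  gmin <- 10^(log10(2.2) + 0.25 * z)                 # ~0.8..5 mmol m-2 s-1
  gmax <- 10^(log10(200) + 0.20 * resp(p$effect_gmax))
  ss_um2 <- 10^(log10(450) + 0.20 * resp(p$effect_ss))
  ct_total <- pmax(2.5 + 1.2 * resp(p$effect_ct), 0.3)
  sd_mm2 <- 10^(log10(250) + 0.2 * stats::rnorm(n))   # uncoupled
  sla <- pmax(14 + 3 * stats::rnorm(n), 4)            # uncoupled

  # split stomatal size into length x width of the guard-cell pair (~3:2)
  gc_len <- sqrt(ss_um2 * 1.5)
  gc_wid <- ss_um2 / gc_len
  ct_ad <- ct_total * 4 / 3   # adaxial cuticle about twice abaxial
  ct_ab <- ct_total * 2 / 3

  tibble::tibble(
    species = sprintf("sp%02d", seq_len(n)),
    functional_group = rep_len(c("angiosperm", "gymnosperm"), n),
    gmin_25c = gmin,
    g_max = gmax,
    stomatal_density = sd_mm2,
    guard_cell_length = gc_len,
    guard_cell_width = gc_wid,
    stomatal_size = stomatal_size(gc_len, gc_wid),
    f_gc = guard_cell_fraction(gc_len, gc_wid, sd_mm2),
    ct_adaxial = ct_ad,
    ct_abaxial = ct_ab,
    ct_total = ct_total,
    sla = sla
  )
}
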