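test_that("drydown generator is reproducible and conserves water", {
  p <- drydown_sim_params(seed = 11)
  r1 <- simulate_drydown(p)
  r2 <- simulate_drydown(p)
  expect_identical(r1$masses, r2$masses)
  expect_false(identical(
    r1$masses, simulate_drydown(drydown_sim_params(seed = 12))$masses))

  # noiseless mass-loss budget equals the time integral of the flux at the
  # integration step: recompute the Euler integral independently
  p0 <- drydown_sim_params(true_gmin = 3, stomatal_g0 = 15, balance_sd = 0,
                           seed = 1)
  rec <- simulate_drydown(p0, internal_step = 60)
  masses <- attr(rec, "masses_noiseless")
  vpd_k <- vpd(p0$chamber)
  m <- p0$w_sat
  k <- log(100) / (1 - p0$closure_rwc)
  for (s in seq_len(p0$duration / 60)) {
    rwc <- (m - p0$w_dry) / (p0$w_sat - p0$w_dry)
    g <- if (rwc <= p0$closure_rwc) p0$true_gmin else
      p0$true_gmin + (p0$stomatal_g0 - p0$true_gmin) * exp(-k * (1 - rwc))
    m <- m - g * vpd_k / p0$chamber$pressure * p0$leaf_area_two_sided *
      18.015e-3 * 60
  }
  expect_equal(masses[length(masses)], m, tolerance = 1e-9)
  # monotone nonincreasing before noise, starting at w_sat
  expect_equal(masses[1], p0$w_sat)
  expect_true(all(diff(masses) <= 0))
})

test_that("drydown masses plateau when the cuticular conductance is zero", {
  # long drydown so the stomatal tail fully decays past the closure point
  rec <- simulate_drydown(drydown_sim_params(
    true_gmin = 0, stomatal_g0 = 15, balance_sd = 0, duration = 324000,
    seed = 1))
  m <- attr(rec, "masses_noiseless")
  rwc <- compute_rwc(m, rec$w_sat, rec$w_dry)$rwc
  # RWC never falls meaningfully below the closure point ...
  expect_gt(min(rwc), 0.79)
  # ... and the late drydown is flat: no cuticular loss remains
  late <- utils::tail(m, 5)
  expect_lt(max(late) - min(late), 1e-5)
})

test_that("drydown generator parameter validation rejects bad inputs", {
  expect_error(drydown_sim_params(w_sat = 0.1, w_dry = 0.2), "w_sat")
  expect_error(drydown_sim_params(true_gmin = 30, stomatal_g0 = 20),
               "stomatal_g0")
  expect_error(drydown_sim_params(closure_rwc = 0.3), "closure_rwc")
})

test_that("diurnal climate generator hits its stated shape", {
  day <- simulate_diurnal_climate(climate_sim_params())
  expect_equal(nrow(day), 145)            # 08:00-20:00 at 5 min
  expect_equal(max(day$temperature), 32.2)
  expect_equal(min(round(day$rh, 1)), 29.4)
  expect_equal(round(max(day$vpd), 1), 3.4)
  # vapor pressure constant across the day
  expect_equal(diff(range(day$e)), 0)

  flat <- simulate_diurnal_climate(climate_sim_params(t_min = 25, t_max = 25,
                                                      rh_at_tmax = 50))
  expect_equal(diff(range(flat$temperature)), 0)
  expect_equal(diff(range(flat$vpd)), 0)
})

test_that("trait-table generator reproduces the configured correlation signs", {
  # zero noise: couplings are exact on their generative scales
  ex <- correlate_traits(simulate_trait_table(
    trait_sim_params(noise_sd = 0, seed = 1)))
  expect_equal(ex$r[ex$trait == "g_max"], 1, tolerance = 1e-9)
  expect_equal(ex$r[ex$trait == "ct_total"], 1, tolerance = 1e-9)
  expect_equal(ex$r[ex$trait == "stomatal_size"], -1, tolerance = 1e-9)

  # moderate noise, fixed seed: signs preserved
  co <- correlate_traits(simulate_trait_table(
    trait_sim_params(n_species = 9, noise_sd = 0.3, seed = 42)))
  expect_gt(co$r[co$trait == "g_max"], 0)
  expect_gt(co$r[co$trait == "ct_total"], 0)
  expect_lt(co$r[co$trait == "stomatal_size"], 0)

  # zero effect sizes: |r| small and p large on average over seeds
  rs <- sapply(1:40, function(s) {
    co0 <- correlate_traits(simulate_trait_table(trait_sim_params(
      n_species = 12, effect_gmax = 0, effect_ct = 0, effect_ss = 0,
      noise_sd = 0.3, seed = s)))
    c(r = abs(co0$r[co0$trait == "g_max"]), p = co0$p[co0$trait == "g_max"])
  })
  expect_lt(mean(rs["r", ]), 0.35)
  expect_gt(mean(rs["p", ]), 0.3)

  # reproducibility
  expect_identical(simulate_trait_table(trait_sim_params(seed = 5)),
                   simulate_trait_table(trait_sim_params(seed = 5)))
})

test_that("seeded generators leave the caller's RNG stream untouched", {
  set.seed(123)
  before <- .Random.seed
  invisible(simulate_drydown(drydown_sim_params(seed = 9)))
  invisible(simulate_trait_table(trait_sim_params(seed = 9)))
  expect_identical(.Random.seed, before)
})
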