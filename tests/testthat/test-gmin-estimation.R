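make_plateau_record <- function(gmin = 2, n = 12, rwc_end = 0.45,
                                w_sat = 0.28, w_dry = 0.10, area = 0.003,
                                chamber = air_state(20, 69, 98.0)) {
  # analytic constant-conductance drydown: linear mass decline down to
  # rwc_end, with weighing times implied by the prescribed loss rate
  rate <- gmin * vpd(chamber) / chamber$pressure * area * 18.015e-3
  rwc <- seq(1, rwc_end, length.out = n)
  masses <- w_dry + rwc * (w_sat - w_dry)
  drydown_record("pl", "sp", "t1", "n/a", (w_sat - masses) / rate, masses,
                 w_sat, w_dry, area, chamber)
}

test_that("relative water content arithmetic, clamping and scale invariance", {
  expect_equal(compute_rwc(8.5, 10, 4)$rwc, 0.75)
  expect_equal(compute_rwc(10, 10, 4)$rwc, 1)
  expect_equal(compute_rwc(4, 10, 4)$rwc, 0)
  out <- compute_rwc(c(10.5, 3.5), 10, 4)
  expect_equal(out$rwc, c(1, 0))
  expect_true(all(out$clamped))
  expect_error(compute_rwc(5, 4, 4), "w_sat")
  # multiplying all masses by a constant leaves RWC unchanged
  expect_equal(compute_rwc(8.5 * 3, 30, 12)$rwc, 0.75)
})

test_that("leaf area from SLA applies the sidedness factor", {
  expect_equal(leaf_area_from_sla(15, 0.4e-3), 0.012)
  expect_equal(leaf_area_from_sla(15, 0.4e-3, sidedness_factor = 1), 0.006)
  expect_equal(leaf_area_from_sla(10, 2e-3, sidedness_factor = 2.57),
               2.57 * 10 * 2e-3)
})

test_that("interval conductance matches the hand-evaluated mass-loss formula", {
  # one interval: 0.010 g over 7200 s, A = 0.003 m2, chamber 20 degC / 69%
  # J = (0.010 / 18.015e-3) / (7200 * 0.003 * 0.72487) * 98.0 = 3.4747
  rec <- drydown_record("x", "sp", "t", "n/a",
                        times = c(0, 7200), masses = c(0.26, 0.25),
                        w_sat = 0.28, w_dry = 0.10, area_two_sided = 0.003,
                        chamber = air_state(20, 69, 98.0))
  cc <- conductance_curve(rec)
  expect_equal(cc$j, 3.4747, tolerance = 1e-4)
  expect_equal(cc$rwc_mid, mean(c(16, 15)) / 18, tolerance = 1e-12)

  # doubling area halves J; zero loss gives zero J
  rec2 <- rec; rec2$area_two_sided <- 0.006
  expect_equal(conductance_curve(rec2)$j, cc$j / 2)
  rec0 <- rec; rec0$masses <- c(0.26, 0.26)
  expect_equal(conductance_curve(rec0)$j, 0)

  # apparent mass gain beyond tolerance is flagged for exclusion
  recn <- rec; recn$masses <- c(0.25, 0.26)
  expect_true(conductance_curve(recn)$excluded)
})

test_that("plateau estimator returns the exact value on noiseless plateaus", {
  est <- estimate_gmin(conductance_curve(make_plateau_record(gmin = 2)))
  expect_equal(est$gmin, 2, tolerance = 1e-12)
  expect_equal(abs(est$plateau_slope), 0, tolerance = 1e-8)
  expect_length(est$qc_flags, 0)

  # exact recovery across a parameter sweep (conductance, area, humidity)
  for (g in c(0.5, 2, 10)) {
    for (area in c(0.001, 0.01)) {
      for (rh in c(40, 69, 90)) {
        rec <- make_plateau_record(gmin = g, area = area,
                                   chamber = air_state(20, rh, 98.0))
        est <- estimate_gmin(conductance_curve(rec))
        expect_equal(est$gmin, g, tolerance = 1e-9)
      }
    }
  }
})

test_that("plateau estimator recovers generator truth end to end", {
  est <- estimate_gmin(conductance_curve(
    simulate_drydown(drydown_sim_params(true_gmin = 2.0, seed = 1))))
  expect_lt(abs(est$gmin / 2.0 - 1), 0.05)

  # noiseless and cuticular from the start: sub-0.1% recovery
  est0 <- estimate_gmin(conductance_curve(simulate_drydown(
    drydown_sim_params(true_gmin = 2.0, balance_sd = 0, closure_rwc = 1.0))))
  expect_lt(abs(est0$gmin / 2.0 - 1), 1e-3)
})

test_that("window occupancy is enforced and reported", {
  # only two intervals inside the window: below the occupancy minimum
  rec <- make_plateau_record(n = 8, rwc_end = 0.76)
  expect_error(estimate_gmin(conductance_curve(rec)),
               "RWC window \\[0.50, 0.80\\]")
  # window entirely missed: curve stays above 0.80
  expect_error(
    estimate_gmin(conductance_curve(make_plateau_record(n = 6, rwc_end = 0.85))),
    "interval")
})

test_that("hierarchical aggregation weights trees equally and handles n = 1", {
  df <- data.frame(
    species = rep(c("A", "B"), c(6, 2)),
    tree_id = rep(c("a1", "a2", "b1"), c(4, 2, 2)),
    functional_group = "angiosperm",
    gmin = c(1, 1, 1, 1, 3, 3, 5, 7))
  agg <- aggregate_gmin(df)
  # species A: tree means 1 and 3 -> 2 (not the leaf mean 1.67)
  expect_equal(agg$by_species$mean[agg$by_species$species == "A"], 2)
  expect_equal(agg$by_species$se[agg$by_species$species == "A"],
               sd(c(1, 3)) / sqrt(2))
  # single-tree species: SE undefined
  expect_true(is.na(agg$by_species$se[agg$by_species$species == "B"]))
  expect_equal(agg$by_group$mean, mean(c(2, 6)))
})

test_that("published species means aggregate to the printed group rows", {
  tab <- sccii_species_table()
  agg <- tab |>
    dplyr::group_by(functional_group) |>
    dplyr::summarise(gmin = mean(gmin), gmax = mean(gmax))
  expect_equal(round(agg$gmin[agg$functional_group == "angiosperm"], 1),
               3.2, tolerance = 0.051)
  expect_equal(round(agg$gmin[agg$functional_group == "gymnosperm"], 1), 1.3)
  # exact: (114.6 + 146.7 + 158.1) / 3
  expect_equal(agg$gmax[agg$functional_group == "gymnosperm"], 139.8)
})

test_that("drydown CSV round trip preserves records", {
  rec <- simulate_drydown(drydown_sim_params(seed = 21))
  wdir <- withr::local_tempdir()
  weighings <- data.frame(sample_id = rec$sample_id, species = rec$species,
                          tree_id = rec$tree_id, age_class = "n/a",
                          time_s = rec$times, mass_g = rec$masses)
  samples <- data.frame(sample_id = rec$sample_id, w_sat_g = rec$w_sat,
                        w_dry_g = rec$w_dry, area_m2 = rec$area_two_sided,
                        chamber_t_c = 20, chamber_rh_pct = 69,
                        pressure_kpa = 98.0)
  wcsv <- file.path(wdir, "weighings.csv")
  scsv <- file.path(wdir, "samples.csv")
  write.csv(weighings, wcsv, row.names = FALSE)
  write.csv(samples, scsv, row.names = FALSE)
  back <- read_drydown_csv(wcsv, scsv)
  expect_length(back, 1)
  expect_equal(back[[1]]$masses, rec$masses)
  expect_equal(estimate_gmin(conductance_curve(back[[1]]))$gmin,
               estimate_gmin(conductance_curve(rec))$gmin)
})
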