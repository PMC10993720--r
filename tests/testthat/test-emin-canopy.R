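constant_climate <- function(temp = 25, vpd_target = 1, hours = 12,
                             step = 300, pressure = 94.9) {
  e <- saturation_vapor_pressure(temp) - vpd_target
  n <- hours * 3600 / step + 1
  diurnal_climate(seq(0, hours * 3600, by = step), rep(temp, n),
                  e = rep(e, n), pressure = pressure)
}

test_that("instantaneous flux kernel arithmetic and linearity", {
  expect_equal(instantaneous_flux(1, 1, 94.9), 1 / 94.9)
  expect_equal(instantaneous_flux(2, 0), 0)
  expect_equal(instantaneous_flux(3, 2, 94.9),
               6 * instantaneous_flux(1, 1, 94.9))
})

test_that("daily integral matches the closed form for a constant climate", {
  # fixed gmin = 1, VPD = 1 kPa for 12 h, R = 100, P = 94.9:
  # 1/94.9 * 43200 * 100 * 18.015e-6 L = 0.8200717
  res <- integrate_emin_day(1, constant_climate(), canopy_spec("c", 100))
  expect_equal(res$e_std, 1 / 94.9 * 43200 * 100 * 18.015e-6,
               tolerance = 1e-9)
  expect_equal(round(res$e_std, 3), 0.820)
  # zero scaling ratio: no transpiration
  expect_equal(
    integrate_emin_day(1, constant_climate(), canopy_spec("c", 0))$e_std, 0)
  # per-tree and per-canopy variants scale as declared
  res2 <- integrate_emin_day(1, constant_climate(),
                             canopy_spec("c", 100, basal_area = 0.2,
                                         canopy_leaf_area = 50))
  expect_equal(res2$e_tree, res2$e_std * 0.2)
  expect_equal(res2$e_canopy, res2$e_std / 100 * 50)
})

test_that("halving the time step changes a smooth day by less than 0.5%", {
  p5 <- climate_sim_params(step = 300)
  p25 <- climate_sim_params(step = 150)
  fit <- list(a = 0.3, b = 0.05)
  spec <- canopy_spec("s", 600)
  e5 <- integrate_emin_day(fit, simulate_diurnal_climate(p5), spec)$e_std
  e25 <- integrate_emin_day(fit, simulate_diurnal_climate(p25), spec)$e_std
  expect_lt(abs(e5 / e25 - 1), 0.005)
})

test_that("temperature elevation conserves the vapor-pressure series exactly", {
  day <- simulate_diurnal_climate(climate_sim_params())
  expect_identical(elevate_climate(day, 0)$temperature, day$temperature)
  for (d in c(0.1, 3.7, 17.8)) {
    up <- elevate_climate(day, d)
    expect_identical(up$e, day$e)           # bit-identical conservation
    expect_equal(max(up$temperature), 32.2 + d)
    unsat <- day$rh < 100
    expect_true(all(up$vpd[unsat] > day$vpd[unsat]))
    expect_true(all(up$rh[unsat] < day$rh[unsat]))
  }
  # near-saturated base day: capped samples are flagged, not errors
  wet <- diurnal_climate(seq(0, 3600, 300), rep(20, 13),
                         e = rep(saturation_vapor_pressure(19.9), 13))
  expect_false(any(wet$rh_capped))
  cool <- diurnal_climate(seq(0, 3600, 300), rep(19, 13),
                          e = rep(saturation_vapor_pressure(19.9), 13))
  expect_true(all(cool$rh_capped))
  expect_equal(cool$vpd, rep(0, 13))
})

test_that("elevation sweep has the expected length and is monotone", {
  day <- simulate_diurnal_climate(climate_sim_params(t_max = 32.2))
  sweep <- scenario_sweep(list(a = 0.3, b = 0.05), day, canopy_spec("s", 600))
  expect_equal(nrow(sweep), 179)   # deltas 0, 0.1, ..., 17.8
  expect_equal(sweep$delta[179], 17.8)
  expect_equal(sweep$t_max[179], 50, tolerance = 1e-9)
  expect_true(all(diff(sweep$e_std) > 0))

  # even a temperature-blind model transpires more in hotter scenarios,
  # because VPD rises at constant absolute humidity
  sweep_flat <- scenario_sweep(2.0, day, canopy_spec("s", 600), step = 1)
  expect_true(all(diff(sweep_flat$e_std) > 0))
})

test_that("canopy water loss is linear through the origin in leaf area", {
  day <- simulate_diurnal_climate(climate_sim_params())
  out <- leaf_area_sweep(2.0, day, areas = c(0, 10, 20, 100, 200))
  expect_equal(out$e_canopy[1], 0)
  expect_equal(out$e_canopy[3], 2 * out$e_canopy[2], tolerance = 1e-12)
  expect_equal(out$e_canopy[5], 20 * out$e_canopy[2], tolerance = 1e-12)
  # cross-check against the constant-climate closed form
  cl <- constant_climate()
  out_c <- leaf_area_sweep(1, cl, areas = 50)
  expect_equal(out_c$e_canopy, 1 / 94.9 * 43200 * 18.015e-6 * 50,
               tolerance = 1e-9)
})

test_that("extrapolation beyond the fitted range warns but still integrates", {
  fit <- fit_exponential(data.frame(temperature = c(25, 30, 35, 40),
                                    gmin = 0.5 * exp(0.05 * c(25, 30, 35, 40))))
  hot <- elevate_climate(simulate_diurnal_climate(climate_sim_params()), 17)
  expect_warning(res <- integrate_emin_day(fit, hot, canopy_spec("s", 100)),
                 "beyond the fitted range")
  expect_gt(res$e_std, 0)
})

test_that("cross-species spread at the measured day is about 18-fold", {
  ref <- sccii_emin_table()
  spread <- max(ref$`e_std_32.2`) / min(ref$`e_std_32.2`)
  expect_equal(round(spread), 18)
})
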