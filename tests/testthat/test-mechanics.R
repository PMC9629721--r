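# Mechanics: printed-equation implementations and their closed-form oracles.

test_that("cross-sectional area follows A = pi d^2 / 4", {
  expect_equal(area_from_diameter(2.43), pi * 2.43^2 / 4)
  expect_equal(area_from_diameter(2.43), 4.638, tolerance = 1e-3)
  expect_equal(area_from_diameter(2), pi)
  expect_error(area_from_diameter(0), "> 0")
  expect_error(area_from_diameter(-1), "> 0")
})

test_that("stress and strain are the engineering definitions", {
  geom <- tendon_geometry(l0_mm = 8, diameter_mm = 2.43)
  tr <- data.frame(time_s = 0:2, force_N = c(0, 0.1, 0.2),
                   displacement_mm = c(0, 6.96, 8))
  cur <- to_stress_strain(tr, geom)
  expect_equal(cur$strain, c(0, 0.87, 1))  # 6.96/8 = the printed 87% max
  expect_equal(cur$stress_kPa[1], 0)
  expect_equal(cur$stress_kPa[2], 0.1 / geom$area_mm2 * 1000)
  expect_error(to_stress_strain(tr[, 1:2], geom), "missing column")
  tr2 <- tr; tr2$time_s <- c(2, 1, 0)
  expect_error(to_stress_strain(tr2, geom), "monotone")
})

test_that("failure metrics locate the peak and honour rupture overrides", {
  cur <- data.frame(time_s = 1:5, strain = (1:5) / 10,
                    stress_kPa = c(1, 3, 5, 4, 2), phase = "loading")
  fm <- failure_metrics(cur)
  expect_equal(fm$sigma_max_kPa, 5)
  expect_equal(fm$epsilon_max, 0.3)
  fm2 <- failure_metrics(cur, rupture_index = 5)
  expect_equal(fm2$epsilon_max, 0.5)
  # monotone curve: last point is both maxima
  cur2 <- data.frame(time_s = 1:11, strain = (0:10) / 10,
                     stress_kPa = 0:10, phase = "loading")
  expect_equal(failure_metrics(cur2)$epsilon_max, 1)
  expect_error(failure_metrics(cur[0, ]), "2 points")
})

test_that("Young's modulus is exact on a linear curve", {
  e <- seq(0, 0.5, length.out = 100)
  cur <- data.frame(time_s = e, strain = e, stress_kPa = 100 * e,
                    phase = "loading")
  ym <- youngs_modulus(cur)
  expect_equal(ym$E_kPa, 100, tolerance = 1e-10)
  expect_equal(ym$r_squared, 1, tolerance = 1e-10)
  expect_false(ym$low_r2)
})

test_that("the max-R2 window lands in the linear limb past the toe", {
  e1 <- seq(0, 0.3, length.out = 60)       # toe: sigma = 50 e^2
  e2 <- seq(0.3, 0.8, length.out = 100)    # limb: slope 100
  cur <- data.frame(time_s = seq_along(c(e1, e2)),
                    strain = c(e1, e2),
                    stress_kPa = c(50 * e1^2, 50 * 0.3^2 + 100 * (e2 - 0.3)),
                    phase = "loading")
  ym <- youngs_modulus(cur, window_fraction = 0.2)
  expect_equal(ym$E_kPa, 100, tolerance = 0.02)
  expect_gte(ym$region["start"], 60)
})

test_that("slope-free noise is flagged as a poor fit", {
  set.seed(3)
  cur <- data.frame(time_s = 1:200, strain = seq(0, 1, length.out = 200),
                    stress_kPa = rnorm(200, sd = 0.1), phase = "loading")
  ym <- youngs_modulus(cur)
  expect_true(ym$low_r2)
  expect_lt(abs(ym$E_kPa), 2)
})

test_that("hysteresis integrals match analytic areas", {
  e <- seq(0, 1, by = 1e-3)
  cur <- data.frame(time_s = c(e, 1 + e),
                    strain = c(e, rev(e)),
                    stress_kPa = c(e, rev(e)^2),
                    phase = rep(c("loading", "unloading"), each = length(e)))
  hm <- hysteresis_metrics(cur)
  expect_equal(hm$area_loading, 1 / 2, tolerance = 1e-5)
  expect_equal(hm$area_unloading, 1 / 3, tolerance = 1e-5)
  expect_equal(hm$energy_loss_pct, 100 / 3, tolerance = 1e-4)
  # path-identical loop dissipates nothing
  cur0 <- cur
  cur0$stress_kPa <- c(e, rev(e))
  hm0 <- hysteresis_metrics(cur0)
  expect_equal(hm0$hysteresis_kJ_m3, 0, tolerance = 1e-12)
  expect_equal(hm0$energy_loss_pct, 0, tolerance = 1e-12)
  expect_error(hysteresis_metrics(cur[cur$phase == "loading", ]), "phases")
})

test_that("stress relaxation rate matches the exponential closed form", {
  t <- seq(0, 90, by = 0.01)
  cur <- data.frame(time_s = t, strain = 0.1,
                    stress_kPa = 50 + 30 * exp(-t / 20), phase = "hold")
  rx <- stress_relaxation_rate(cur, T_s = 60)
  expect_equal(rx$rate_kPa_s, 30 * (1 - exp(-3)) / 60, tolerance = 1e-6)
  # constant stress relaxes at rate 0
  cur0 <- cur; cur0$stress_kPa <- 42
  expect_equal(stress_relaxation_rate(cur0)$rate_kPa_s, 0)
  expect_error(stress_relaxation_rate(cur[t < 50, ]), "spans only")
})

test_that("metrics are linear in force and inverse in area", {
  res <- gen_sls_trace(sls_params(protocol = "triangle", tau = 20))
  geom <- res$geometry
  ms1 <- mechanical_summary(res$trace, geom)
  tr2 <- res$trace; tr2$force_N <- 3 * tr2$force_N
  ms2 <- mechanical_summary(tr2, geom)
  expect_equal(ms2$sigma_max_kPa, 3 * ms1$sigma_max_kPa)
  expect_equal(ms2$E_kPa, 3 * ms1$E_kPa)
  expect_equal(ms2$hysteresis$hysteresis_kJ_m3,
               3 * ms1$hysteresis$hysteresis_kJ_m3)
  expect_equal(ms2$hysteresis$energy_loss_pct,
               ms1$hysteresis$energy_loss_pct)
  geom_half <- tendon_geometry(l0_mm = 8, area_mm2 = geom$area_mm2 / 2)
  ms3 <- mechanical_summary(res$trace, geom_half)
  expect_equal(ms3$sigma_max_kPa, 2 * ms1$sigma_max_kPa)
})

test_that("SLS traces round-trip their closed-form expectations", {
  res <- gen_sls_trace(sls_params(protocol = "ramp_hold", ramp_rate = 0.05,
                                  tau = 20, hold_duration_s = 90))
  ms <- mechanical_summary(res$trace, res$geometry)
  expect_equal(ms$relaxation$rate_kPa_s, res$expected$relax_rate_kPa_s,
               tolerance = 0.01)
  expect_equal(ms$sigma_max_kPa, res$expected$sigma_max_kPa,
               tolerance = 0.005)
  tri <- gen_sls_trace(sls_params(protocol = "triangle", tau = 20))
  mst <- mechanical_summary(tri$trace, tri$geometry)
  expect_equal(mst$sigma_max_kPa, tri$expected$sigma_max_kPa,
               tolerance = 0.005)
  loss <- mst$hysteresis$energy_loss_pct
  expect_gt(loss, 0); expect_lt(loss, 100)
  # loss decreases as tau grows at fixed rate
  tri2 <- gen_sls_trace(sls_params(protocol = "triangle", tau = 200))
  loss2 <- mechanical_summary(tri2$trace,
                              tri2$geometry)$hysteresis$energy_loss_pct
  expect_lt(loss2, loss)
})
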