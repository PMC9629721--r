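# Synthetic generators: determinism, truth records, distributional laws,
# and the closed-form SLS oracle.

test_that("fibre image generation is a pure function of params + seed", {
  p <- fibre_field_params(image_size = 64, n_fibres = 10, seed = 42)
  r1 <- gen_fibre_image(p)
  r2 <- gen_fibre_image(p)
  expect_identical(r1$image, r2$image)
  expect_identical(r1$truth, r2$truth)
  p2 <- p; p2$seed <- 43L
  expect_false(identical(gen_fibre_image(p2)$image, r1$image))
  expect_equal(dim(r1$image), c(64, 64))
  expect_equal(nrow(r1$truth), 10)
})

test_that("very large kappa concentrates truth angles at the mean", {
  p <- fibre_field_params(image_size = 64, n_fibres = 50, kappa = 1e6,
                          mean_angle_deg = 30, seed = 5)
  tr <- gen_fibre_image(p)$truth
  expect_true(all(abs(tr$angle_deg - 30) < 0.5))
})

test_that("kappa = 0 gives uniform axial orientations", {
  p <- fibre_field_params(image_size = 64, n_fibres = 2000, kappa = 0,
                          fibre_width_px = 1, seed = 99)
  a <- gen_fibre_image(p)$truth$angle_deg
  expect_true(all(a > -90 & a <= 90))
  ks <- suppressWarnings(ks.test(a, "punif", -90, 90))
  expect_gt(ks$p.value, 0.01)
})

test_that("fibre params are validated", {
  expect_error(fibre_field_params(kappa = -1), "kappa")
  expect_error(fibre_field_params(image_size = 32), "image_size")
  expect_error(fibre_field_params(undulation_wavelength_px = 0),
               "undulation_wavelength_px")
  expect_error(fibre_field_params(mean_angle_deg = 120), "mean_angle_deg")
})

test_that("group dataset is labelled, seeded and kappa-ordered", {
  mk <- function(lab, kappa) {
    group_recipe(lab, fibre_field_params(image_size = 64, n_fibres = 60,
                                         kappa = kappa), n_images = 8L)
  }
  recipes <- list(mk("g1", 0.5), mk("g2", 1), mk("g3", 2), mk("g4", 4))
  ds <- gen_group_dataset(recipes, master_seed = 7)
  expect_length(ds$images, 32)
  expect_equal(as.vector(table(ds$labels)[c("g1", "g2", "g3", "g4")]),
               rep(8L, 4))
  # circular mean resultant length on doubled angles, per group
  rbar <- vapply(c("g1", "g2", "g3", "g4"), function(g) {
    a2 <- unlist(lapply(ds$truth[ds$labels == g],
                        function(t) t$angle_deg)) * 2 * pi / 180
    sqrt(mean(cos(a2))^2 + mean(sin(a2))^2)
  }, numeric(1))
  expect_true(all(diff(rbar) > 0))
  # changing the master seed changes at least one image
  ds2 <- gen_group_dataset(recipes, master_seed = 8)
  expect_false(identical(ds$images, ds2$images))
  # duplicate labels refused
  expect_error(gen_group_dataset(list(mk("g1", 1), mk("g1", 2))),
               "duplicate")
})

test_that("axial statistics recover the doubled mean angle for kappa >= 4", {
  for (mu in c(-40, 0, 25)) {
    p <- fibre_field_params(image_size = 64, n_fibres = 400, kappa = 4,
                            mean_angle_deg = mu, fibre_width_px = 1,
                            seed = 11)
    a2 <- gen_fibre_image(p)$truth$angle_deg * 2 * pi / 180
    mean2 <- atan2(mean(sin(a2)), mean(cos(a2))) * 180 / pi
    delta <- (mean2 - 2 * mu + 180) %% 360 - 180
    expect_lt(abs(delta), 2 * 2)  # 2 deg on the axial scale = 4 on doubled
  }
})

test_that("single fibril renders as a disc of the requested diameter", {
  p <- fibril_field_params(image_size = 128, pixel_size_nm = 1,
                           n_fibrils = 1, diameter_median_nm = 40,
                           diameter_log_sd = 0, axial_ratio_range = c(1, 1),
                           seed = 2)
  res <- gen_fibril_mask(p)
  expect_equal(res$truth$minor_nm, 40)
  expect_equal(sum(res$mask), pi * 20^2, tolerance = 0.05)
})

test_that("fibril placement respects the gap and conserves truth", {
  p <- fibril_field_params(image_size = 256, n_fibrils = 25,
                           diameter_median_nm = 30, min_gap_px = 2,
                           seed = 3)
  res <- gen_fibril_mask(p)
  expect_equal(nrow(res$truth), 25)
  seg <- segment_components(res$mask)
  expect_equal(seg$n_components, 25)  # non-touching by construction
  # pairwise centre distances exceed the summed semi-majors + gap
  tr <- res$truth
  a_px <- tr$major_nm / (2 * p$pixel_size_nm)
  d <- as.matrix(dist(cbind(tr$centre_r, tr$centre_c)))
  gap <- d - outer(a_px, a_px, "+")
  diag(gap) <- Inf
  expect_true(all(gap >= p$min_gap_px))
})

test_that("impossible fibril density errors with the achievable count", {
  p <- fibril_field_params(image_size = 64, n_fibrils = 500,
                           diameter_median_nm = 20, seed = 1)
  expect_error(gen_fibril_mask(p), "could only place")
})

test_that("SLS ramp_hold trace matches its closed form and expectations", {
  # instantaneous step: sigma(t) = eps0 (E_eq + E_m exp(-t/tau))
  p <- sls_params(E_eq = 50, E_m = 30, tau = 20, ramp_rate = Inf,
                  hold_strain = 0.1, hold_duration_s = 90)
  res <- gen_sls_trace(p)
  geom <- res$geometry
  sig <- res$trace$force_N / geom$area_mm2 * 1000
  t <- res$trace$time_s
  expect_equal(sig, 0.1 * (50 + 30 * exp(-t / 20)), tolerance = 1e-12)
  expect_equal(res$expected$relax_rate_kPa_s, 0.1 * 30 * (1 - exp(-3)) / 60,
               tolerance = 1e-12)
  # elastic limit: E_m = 0 holds constant stress, zero relaxation
  p0 <- sls_params(E_eq = 50, E_m = 0, tau = 20, ramp_rate = Inf)
  res0 <- gen_sls_trace(p0)
  s0 <- res0$trace$force_N[res0$trace$phase == "hold"]
  expect_equal(diff(range(s0)), 0)
  expect_equal(res0$expected$relax_rate_kPa_s, 0)
})

test_that("triangle protocol with huge tau is reversible", {
  p <- sls_params(protocol = "triangle", tau = 1e9, ramp_rate = 0.01,
                  hold_strain = 0.1)
  res <- gen_sls_trace(p)
  cur <- to_stress_strain(res$trace, res$geometry)
  ld <- cur[cur$phase == "loading", ]
  ul <- cur[cur$phase == "unloading", ]
  # compare on the strain range both branches sample (the apex sample
  # belongs to the loading phase only)
  ld <- ld[ld$strain <= max(ul$strain), ]
  s_ul <- approx(ul$strain, ul$stress_kPa, xout = ld$strain, rule = 2)$y
  expect_lt(max(abs(ld$stress_kPa - s_ul)) / max(ld$stress_kPa), 1e-4)
})

test_that("undersampled traces warn; tau invariant enforced", {
  expect_warning(gen_sls_trace(sls_params(tau = 0.05, sample_rate_hz = 10)),
                 "10 samples")
  expect_error(sls_params(E_m = 30, eta = 600, tau = 10), "eta")
  p <- sls_params(E_m = 30, eta = 600)
  expect_equal(p$tau, 20)
})
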