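# Gel-level calibration: Darcy permeability, volume fraction, fiber radius,
# power-law fitting and hindered-diffusion models.

test_that("Darcy permeability round-trips noise-free synthetic flow", {
  # hand-built series: k = 10 um^2, L = 1 cm, A = 1.767 mm^2, dP = 100 Pa
  L <- 0.01; A <- 1.767e-6; dP <- 100; mu <- 1e-3
  k_true <- 10
  Q <- k_true * 1e-12 * A * dP / (mu * L)               # m^3/s, by hand
  times <- seq(30, 600, by = 30)
  m <- permeation_measurement(L, A, dP, mu,
                              data.frame(time_s = times,
                                         mass_g = Q * 998 * 1000 * times))
  expect_equal(darcy_permeability(m), k_true, tolerance = 1e-12)
  # invariant under subsampling of a noise-free linear series
  m_sub <- permeation_measurement(L, A, dP, mu,
                                  m$flow_series[c(1, 7, 20), ])
  expect_equal(darcy_permeability(m_sub), k_true, tolerance = 1e-12)
})

test_that("Darcy round trip holds across physical parameter ranges", {
  grid <- expand.grid(k = c(0.5, 10, 500), dP = c(50, 200), L = c(0.01, 0.019))
  for (i in seq_len(nrow(grid))) {
    m <- gen_permeation(grid$k[i], clot_length = grid$L[i],
                        pressure_drop = grid$dP[i], noise = 0)
    expect_equal(darcy_permeability(m), grid$k[i], tolerance = 1e-9)
  }
})

test_that("degenerate and invalid permeation inputs are handled", {
  fs <- data.frame(time_s = c(1, 2, 3), mass_g = c(0, 0, 0))
  m <- permeation_measurement(0.01, 1.767e-6, 100, 1e-3, fs)
  k0 <- darcy_permeability(m)
  expect_identical(as.numeric(k0), 0)
  expect_true(isTRUE(attr(k0, "degenerate")))
  expect_error(permeation_measurement(0.01, 1.767e-6, 100, 1e-3,
                                      data.frame(time_s = c(2, 1),
                                                 mass_g = c(0, 1))),
               "strictly increasing")
  expect_error(permeation_measurement(0.01, 1.767e-6, -5, 1e-3, fs),
               "pressure_drop")
  expect_error(permeation_measurement(0.01, 1.767e-6, 100, 1e-3, fs[1, ]),
               "at least 2")
})

test_that("fibrin volume fraction follows the preparation volume balance", {
  expect_identical(fibrin_volume_fraction(0, 1, 0), 0)
  # 4 mg fibrinogen in 1 mL solvent, defaults 0.725 / 1.02 cm^3/g, factor 1.25
  phi4 <- fibrin_volume_fraction(0.004, 1, 0)
  expect_equal(phi4, 1.25 * 0.004 * 0.725 / (0.004 * 0.725 + 1.02),
               tolerance = 1e-12)
  expect_equal(phi4, 3.55e-3, tolerance = 0.01)
  # doubling the fibrinogen dose at fixed solvent strictly increases phi
  expect_gt(fibrin_volume_fraction(0.008, 1, 0), phi4)
  expect_error(fibrin_volume_fraction(0, 0, 0), "zero")
})

test_that("fiber-radius relation is an exact bijection in r_f", {
  for (phi in c(5e-4, 0.002, 0.01, 0.1)) {
    for (r_nm in c(150, 300, 500)) {
      k <- permeability_from_fiber_radius(r_nm, phi)
      expect_equal(fiber_radius_from_permeability(k, phi), r_nm,
                   tolerance = 1e-10)
    }
  }
  expect_error(fiber_radius_from_permeability(10, 0.5),
               "random-fibre")
  expect_error(fiber_radius_from_permeability(-1, 0.01), "positive")
})

test_that("derived radii stay in the observed band and shrink with density", {
  panel <- gen_gel_panel(seq(0.2, 4, length.out = 12))
  expect_true(all(panel$k_s >= 1 & panel$k_s <= 1000))
  expect_true(all(panel$r_f >= 150 & panel$r_f <= 500))
  r1 <- gen_gel_panel(1)$r_f
  r4 <- gen_gel_panel(4)$r_f
  expect_lt(r4, r1)
})

test_that("power-law fit recovers generating parameters", {
  phi <- seq(3e-4, 3e-3, length.out = 10)
  # zero offset, exact recovery
  k <- 2e-4 * phi^(-1.7)
  fit <- fit_permeability_power_law(data.frame(phi = phi, k_s = k))
  expect_equal(fit$prefactor, 2e-4, tolerance = 1e-6)
  expect_equal(fit$exponent, -1.7, tolerance = 1e-6)
  expect_identical(fit$offset, 0)
  # non-zero offset
  k2 <- 5e-5 * (phi - 1e-4)^(-1.5)
  fit2 <- fit_permeability_power_law(data.frame(phi = phi, k_s = k2))
  expect_equal(fit2$offset, 1e-4, tolerance = 1e-4)
  expect_equal(fit2$exponent, -1.5, tolerance = 1e-4)
  # fitted curve decreases in phi over the measured range
  pred <- predict(fit, phi)
  expect_true(all(diff(pred) < 0))
  expect_error(fit_permeability_power_law(
    data.frame(phi = c(1e-3, 1e-3, 1e-3), k_s = c(1, 2, 3))), "distinct")
})

test_that("power-law exponent estimator has small bias under 5% noise", {
  phi <- seq(2e-4, 3.5e-3, length.out = 20)
  k_true <- 3e-4 * phi^(-1.7)
  exps <- vapply(1:200, function(s) {
    k <- k_true * withr::with_seed(s, pmax(1 + rnorm(20, sd = 0.05), 0.05))
    fit_permeability_power_law(data.frame(phi = phi, k_s = k))$exponent
  }, numeric(1))
  expect_lt(abs(mean(exps) - (-1.7)) / 1.7, 0.02)
})

test_that("Stokes-Einstein diffusivity scales and evaluates correctly", {
  expect_equal(stokes_einstein_diffusivity(8.2), stokes_einstein_diffusivity(4.1) / 2)
  # direct formula oracle, d_h = 4.1 nm at 30 C in water (mu = 0.797e-3 Pa.s)
  D_hand <- 1.380649e-23 * 303.15 / (3 * pi * 0.797e-3 * 4.1e-9) * 1e12
  expect_equal(stokes_einstein_diffusivity(4.1, T_K = 303.15, mu = 0.797e-3),
               D_hand, tolerance = 1e-12)
  # size ratio consistent with the measured free-solution diffusivity ratio
  ratio_sizes <- 11.2 / 4.1
  ratio_D <- stokes_einstein_diffusivity(4.1) / stokes_einstein_diffusivity(11.2)
  expect_equal(ratio_D, ratio_sizes, tolerance = 1e-12)
  expect_equal(ratio_D, 110 / 40, tolerance = 0.05)
})

test_that("both hindered-diffusion models are bounded, monotone and ordered", {
  thrombin <- probe_spec("thrombin", d_h = 4.1, D0 = 110, alpha = 0.1,
                         beta = 1, s = 17)
  fab <- probe_spec("fab", d_h = 11.2, D0 = 40, alpha = 0.1, beta = 1, s = 27)
  # phi = 0: no retardation under either model
  g0 <- gel_sample(phi = 0, r_f = 200, k_s = 100)
  expect_identical(ogston_diffusivity(thrombin, g0), 1)
  expect_equal(johnson_diffusivity(thrombin,
                                   gel_sample(phi = 0, r_f = 200, k_s = 1e12)),
               1, tolerance = 1e-6)
  phis <- c(1e-4, 5e-4, 1e-3, 2e-3, 3.5e-3)
  for (p in list(thrombin, fab)) {
    og <- vapply(phis, function(ph)
      ogston_diffusivity(p, gel_sample(phi = ph, r_f = 200)), numeric(1))
    jo <- vapply(phis, function(ph)
      johnson_diffusivity(p, gel_sample(phi = ph, r_f = 200, k_s = 10)),
      numeric(1))
    expect_true(all(og > 0 & og <= 1))
    expect_true(all(jo > 0 & jo <= 1))
    expect_true(all(diff(og) < 0))   # monotone decreasing in phi
    expect_true(all(diff(jo) < 0))
  }
  # larger probes are retarded more at any fixed gel
  g <- gel_sample(phi = 3.5e-3, r_f = 180, k_s = 6)
  expect_lt(ogston_diffusivity(fab, g), ogston_diffusivity(thrombin, g))
  # monotone non-increasing in d_h under both models
  dhs <- c(2, 4.1, 8, 11.2)
  og_d <- vapply(dhs, function(d)
    ogston_diffusivity(probe_spec("x", d, 100, s = 17), g), numeric(1))
  jo_d <- vapply(dhs, function(d)
    johnson_diffusivity(probe_spec("x", d, 100, s = 17), g), numeric(1))
  expect_true(all(diff(og_d) < 0))
  expect_true(all(diff(jo_d) < 0))
  # effective-medium model predicts milder retardation than the obstruction fit
  panel <- gen_gel_panel(seq(0.5, 4, length.out = 6))
  for (i in seq_len(nrow(panel))) {
    gi <- gel_sample(phi = panel$phi[i], r_f = panel$r_f[i], k_s = panel$k_s[i])
    expect_gte(johnson_diffusivity(thrombin, gi),
               ogston_diffusivity(thrombin, gi))
  }
})

test_that("hydrodynamic hindrance is negligible at measured permeabilities", {
  thrombin <- probe_spec("thrombin", d_h = 4.1, D0 = 110, s = 17)
  for (k in c(1, 10, 100, 1000)) {
    g <- gel_sample(phi = 1e-3, r_f = 200, k_s = k)
    H <- johnson_diffusivity(thrombin, g) /
      johnson_diffusivity(thrombin, g, include_hydrodynamic = FALSE)
    expect_gt(H, 0.99)
  }
})

test_that("tortuosity reproduces the printed in-gel reductions", {
  expect_identical(tortuosity(100, 100), 1)
  expect_equal(tortuosity(110, 110 * (1 - 0.13)), 1.14, tolerance = 0.01)
  expect_equal(tortuosity(40, 40 * (1 - 0.22)), 1.28, tolerance = 0.01)
  expect_error(tortuosity(100, 101), "exceed")
})
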