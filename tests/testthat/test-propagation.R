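test_that("Fresnel transmission: matched, silica, reciprocity, degenerate", {
  expect_equal(fresnel_transmission(1.5 + 0i, 1.5 + 0i), 1 + 0i)
  expect_lt(abs(fresnel_transmission(1 + 0i, 1.95 + 0i) - 2 / 2.95), 1e-3)
  # lossless pair: power transmittance (n2/n1)|t|^2 = 1 - |r|^2
  n1 <- 1; n2 <- 2.48
  t12 <- fresnel_transmission(n1 + 0i, n2 + 0i)
  r12 <- (n1 - n2) / (n1 + n2)
  expect_equal(n2 / n1 * Mod(t12)^2, 1 - Mod(r12)^2, tolerance = 1e-12)
  expect_error(fresnel_transmission(1 + 0i, -1 + 0i), "degenerate")
})

test_that("all-vacuum stacks propagate as a pure time delay", {
  vac <- get_material("vacuum")
  # L chosen so the full-depth delay is exactly 50 grid steps of 0.02 ps
  L <- tke_constants$c * 1e-12
  stack <- layer_stack(list(list(material = vac, d_m = 0),
                            list(material = vac, d_m = L)), 2)
  p <- synth_single_cycle(5.1e7, 0.25)
  fm <- field_in_liquid(p, stack, n_z = 2)
  expect_lt(max(abs(fm$E[1, ] - p$field)) / max(abs(p$field)), 1e-8)
  shifted <- c(rep(0, 50), p$field[seq_len(nrow(p) - 50)])
  expect_lt(max(abs(fm$E[2, ] - shifted)) / max(abs(p$field)), 1e-8)
})

test_that("spectral amplitude decays as exp(-kappa omega z / c) in the liquid", {
  wat <- get_material("water-296K")
  stack <- cuvette_stack("water-296K", window_thickness_m = 0)
  p <- synth_single_cycle(5.1e7, 0.25)
  fm <- field_in_liquid(p, stack, n_z = 3)
  n <- nrow(p); dt <- trace_dt(p)
  f_bin <- 26                                   # ~0.714 THz
  f0 <- (f_bin - 1) / (n * dt)
  A0 <- stats::fft(fm$E[1, ], inverse = TRUE)[f_bin]
  Az <- stats::fft(fm$E[3, ], inverse = TRUE)[f_bin]
  kappa <- Im(complex_refractive_index(wat, f0))
  expected <- exp(-kappa * 2 * pi * f0 * 1e12 * fm$z_m[3] / tke_constants$c)
  expect_equal(Mod(Az / A0), expected, tolerance = 1e-8)
})

test_that("propagation through the water cell is passive", {
  stack <- cuvette_stack("water-296K")
  p <- synth_single_cycle(5.1e7, 0.25)
  fm <- field_in_liquid(p, stack, n_z = 8)
  energy <- rowSums(fm$E^2)
  expect_lt(energy[8], energy[1])
  # and no spectral component is amplified across the liquid
  A0 <- Mod(stats::fft(fm$E[1, ], inverse = TRUE))
  AL <- Mod(stats::fft(fm$E[8, ], inverse = TRUE))
  big <- A0 > 1e-6 * max(A0)
  expect_true(all(AL[big] <= A0[big] * (1 + 1e-9)))
})

test_that("probe phase integral: null, uniform and velocity-matched limits", {
  t <- seq(-2, 10, by = 0.02)
  z <- seq(0, 2e-4, length.out = 33)
  zero <- matrix(0, 33, length(t))
  ph0 <- probe_phase(zero, z, t, n_group = 1.33)
  expect_true(all(ph0$phase_mrad == 0))
  # z-uniform, t-constant birefringence integrates to (2 pi L / lambda) dn
  dn0 <- 1e-8
  ph1 <- probe_phase(matrix(dn0, 33, length(t)), z, t, n_group = 1.33)
  expect_equal(ph1$phase_mrad,
               rep(2 * pi / 800e-9 * dn0 * 2e-4 * 1e3, nrow(ph1)),
               tolerance = 1e-12)
  # velocity-matched: dn carried at the probe group velocity is not smeared
  ng <- 2.48
  g <- function(tt) exp(-tt^2 / 0.5)
  dn <- outer(z, t, function(zz, tt) dn0 * g(tt - ng * zz / tke_constants$c * 1e12))
  ph2 <- probe_phase(dn, z, t, n_group = ng)
  expect_equal(ph2$phase_mrad,
               2 * pi / 800e-9 * dn0 * 2e-4 * 1e3 * g(ph2$time_ps),
               tolerance = 1e-3)
})

test_that("walk-off smears an impulsive birefringence into a ~0.77 ps rectangle", {
  t <- seq(-2, 10, by = 0.01)
  z <- seq(0, 2e-4, length.out = 129)
  n_thz <- 2.48; ng <- 1.33
  sig <- 0.02
  dn <- outer(z, t, function(zz, tt)
    1e-8 * exp(-(tt - n_thz * zz / tke_constants$c * 1e12)^2 / (2 * sig^2)))
  ph <- probe_phase(dn, z, t, n_group = ng)
  width_expect <- (n_thz - ng) * 2e-4 / tke_constants$c * 1e12  # 0.767 ps
  above <- ph$time_ps[ph$phase_mrad > max(ph$phase_mrad) / 2]
  expect_equal(diff(range(above)), width_expect, tolerance = 0.08)
  # walk-off exceeding the time grid is an explicit error naming the padding
  t_short <- seq(0, 0.3, by = 0.01)
  z_long <- seq(0, 0.5, length.out = 5)     # 0.5 m of liquid: ~2.2 ns shift
  expect_error(probe_phase(matrix(1e-8, 5, length(t_short)), z_long, t_short,
                           n_group = 1.33), "pad")
})

test_that("probe phase is linear and the forward model converges under grid refinement", {
  stack <- cuvette_stack("water-296K")
  kp <- kerr_params(B_e = 0.01e-14, B_m2 = -0.025e-14, tau2_ps = 1.1)
  p1 <- synth_single_cycle(5.1e7, 0.25, seq(-6, 18, by = 0.04))
  ph1 <- forward_phase_model(kp, p1, stack, n_z = 32)
  # additivity of the electronic and molecular components
  expect_equal(ph1$phase_mrad, ph1$electronic_mrad + ph1$molecular_mrad,
               tolerance = 1e-12)
  # linearity in dn: scaling both coefficients scales the phase
  kp2 <- kerr_params(B_e = 0.02e-14, B_m2 = -0.05e-14, tau2_ps = 1.1)
  ph2 <- forward_phase_model(kp2, p1, stack, n_z = 32)
  expect_equal(ph2$phase_mrad, 2 * ph1$phase_mrad, tolerance = 1e-9)
  # halving dz and dt changes the peak by < 0.5%
  p_fine <- synth_single_cycle(5.1e7, 0.25, seq(-6, 18, by = 0.02))
  ph_fine <- forward_phase_model(kp, p_fine, stack, n_z = 64)
  expect_lt(abs(max(abs(ph_fine$phase_mrad)) - max(abs(ph1$phase_mrad))) /
              max(abs(ph_fine$phase_mrad)), 0.005)
})
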