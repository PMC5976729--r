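water_model <- function() debye_model(3.5, c(71.0, 2.5, 1.5), c(9.01, 1.03, 0.085))

test_that("Debye models obey the static sum rule and high-frequency limit", {
  wm <- water_model()
  expect_equal(Re(evaluate_epsilon(wm, 0)), 78.5)
  expect_equal(Im(evaluate_epsilon(wm, 0)), 0)
  expect_lt(abs(evaluate_epsilon(wm, 1e4) - 3.5), 1e-3)
  expect_error(evaluate_epsilon(wm, -0.1), "non-negative")
  # absorption sign convention: Im eps >= 0 for all omega >= 0
  f <- seq(0, 5, by = 0.01)
  expect_true(all(Im(evaluate_epsilon(wm, f)) >= 0))
})

test_that("shipped parametrizations reproduce the tabulated 0.37 THz indices", {
  targets <- c(`water-296K` = 2.48, d2o = 2.34, silica = 1.95, cs2 = 1.70,
               benzene = 1.51, methanol = 1.806, ethanol = 1.60,
               `2-propanol` = 1.54, `nai-1M` = 2.51, `nai-3M` = 2.63,
               `nai-5M` = 2.76, `nai-9.5M` = 2.91)
  for (nm in names(targets)) {
    n <- Re(complex_refractive_index(get_material(nm), 0.37))
    expect_lt(abs(n - targets[[nm]]), 0.10, label = paste(nm, "index"))
  }
})

test_that("complex refractive index is the principal square root of epsilon", {
  m <- material("t", debye_model(4), n_probe = 1.4)
  expect_equal(complex_refractive_index(m, 0.5), 2 + 0i)
  # hand algebra: (1+i)^2 = 2i
  expect_equal(eps_to_index(0 + 2i), 1 + 1i)
  # round trip over a 0-3 THz grid
  wm <- water_model()
  f <- seq(0, 3, by = 0.05)
  nt <- eps_to_index(evaluate_epsilon(wm, f))
  expect_lt(max(Mod(nt^2 - evaluate_epsilon(wm, f))), 1e-12)
  expect_true(all(Re(nt) >= 0) && all(Im(nt) >= 0))
})

test_that("Re epsilon decreases monotonically over 0-3 THz for multi-Debye models", {
  f <- seq(0, 3, by = 0.01)
  for (nm in c("water-296K", "methanol", "ethanol")) {
    re <- Re(evaluate_epsilon(get_material(nm)$debye, f))
    expect_true(all(diff(re) < 0), label = paste(nm, "monotone"))
  }
})

test_that("a single Debye term is Kramers-Kronig consistent", {
  dm <- debye_model(2, 10, 1)
  # dense wide grid; eval frequencies sit halfway between nodes so the
  # principal-value cancellation around the pole is symmetric
  fg <- seq(0.005, 2000, by = 0.01)
  im <- Im(evaluate_epsilon(dm, fg))
  for (f0 in c(0.3, 0.7, 1.5)) {
    keep <- abs(fg - f0) > 0.008
    recon <- 2 / pi * sum(fg[keep] * im[keep] /
                            (fg[keep]^2 - f0^2)) * 0.01
    expect_lt(abs(recon - (Re(evaluate_epsilon(dm, f0)) - 2)) /
                abs(Re(evaluate_epsilon(dm, f0)) - 2), 0.02)
  }
})

test_that("TDS transfer function handles identity and degenerate geometries", {
  silica <- get_material("silica")
  f <- seq(0.2, 1.5, by = 0.1)
  samp <- list(list(index = silica, d_m = 1.2e-3),
               list(index = 2 + 0.1i, d_m = 2e-4),
               list(index = silica, d_m = 1.2e-3))
  expect_equal(tds_transfer_function(samp, samp, f),
               rep(1 + 0i, length(f)))
  # d = 0 liquid gap: interface factors only, no propagation phase
  s0 <- list(list(index = 2 + 0.1i, d_m = 0))
  r0 <- list(list(index = 1 + 0i, d_m = 0))
  H0 <- tds_transfer_function(s0, r0, 0.5)
  t_in <- 2 / (1 + (2 + 0.1i)); t_out <- 2 * (2 + 0.1i) / ((2 + 0.1i) + 1)
  expect_equal(H0, t_in * t_out, tolerance = 1e-12)
})

test_that("single-slab transfer matches the closed-form hand computation", {
  # liquid slab (n = 2 + 0.5i, d = 0.2 mm) vs vacuum gap of the same length
  n <- 2 + 0.5i; d <- 2e-4; f <- 0.8
  H <- tds_transfer_function(list(list(index = n, d_m = d)),
                             list(list(index = 1 + 0i, d_m = d)), f)
  omega <- 2 * pi * f * 1e12
  hand <- (2 / (1 + n)) * (2 * n / (n + 1)) *
    exp(1i * (n - 1) * omega * d / tke_constants$c)
  expect_equal(H, hand, tolerance = 1e-12)
  expect_equal(Mod(H),
               Mod(4 * n / (1 + n)^2) * exp(-0.5 * omega * d / tke_constants$c),
               tolerance = 1e-12)
})

test_that("permittivity extraction inverts the forward transfer model", {
  silica <- get_material("silica")
  wm <- water_model()
  d_liq <- 2e-4; d_win <- 1.2e-3
  geom <- function(eps, f) {
    samp <- list(list(index = silica, d_m = d_win),
                 list(index = eps_to_index(eps), d_m = d_liq),
                 list(index = silica, d_m = d_win))
    ref <- list(list(index = silica, d_m = d_win),
                list(index = 1 + 0i, d_m = d_liq),
                list(index = silica, d_m = d_win))
    tds_transfer_function(samp, ref, f)
  }
  f <- seq(0.2, 1.5, by = 0.05)
  eps_true <- evaluate_epsilon(wm, f)
  H <- vapply(seq_along(f), function(j) geom(eps_true[j], f[j]), complex(1))
  tbl <- extract_epsilon_from_transfer(H, f, geom)
  expect_true(all(tbl$converged))
  eps_hat <- complex(real = tbl$eps_real, imaginary = tbl$eps_imag)
  expect_lt(max(Mod(eps_hat - eps_true) / Mod(eps_true)), 1e-6)

  # H identically 1 (sample = reference) recovers the reference medium
  tbl1 <- extract_epsilon_from_transfer(rep(1 + 0i, length(f)), f, geom)
  eps1 <- complex(real = tbl1$eps_real, imaginary = tbl1$eps_imag)
  expect_lt(max(Mod(eps1 - 1)), 1e-6)

  # 0.1% multiplicative noise: median recovery error < 1%
  set.seed(42)
  Hn <- H * (1 + 0.001 * stats::rnorm(length(H)))
  tbln <- extract_epsilon_from_transfer(Hn, f, geom)
  epsn <- complex(real = tbln$eps_real, imaginary = tbln$eps_imag)
  expect_lt(stats::median(Mod(epsn - eps_true) / Mod(eps_true)), 0.01)
})

test_that("dielectric tables round-trip through the delimited-text format", {
  f <- seq(0.2, 1.0, by = 0.2)
  eps <- evaluate_epsilon(water_model(), f)
  path <- tempfile(fileext = ".tsv")
  write_dielectric_table(dielectric_table(f, eps), path)
  back <- read_dielectric_table(path)
  expect_equal(back$eps_real, Re(eps), tolerance = 1e-6)
  expect_equal(back$eps_imag, Im(eps), tolerance = 1e-6)
  expect_error(get_material("kryptonite"), "built-ins")
})
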