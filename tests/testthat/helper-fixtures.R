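# Shared test helpers: reduced problem sizes for fast unit tests.
# The acceptance tests use the full default grids.

# coarse delay grid / depth sampling for fitting tests
coarse_grid <- function() seq(-5, 20, by = 0.04)

coarse_water <- function(seed = 1L, ...) {
  water_fixture(seed = seed, t_grid_ps = coarse_grid(), n_z = 32, ...)
}

fit_coarse <- function(ds, model = "polar", ...) {
  fit_kerr_trace(ds$noisy, ds$pulse, ds$stack, model = model, n_z = 32, ...)
}

# random smooth zero-area pulse on a small grid (for sign-theorem checks)
random_zero_area_pulse <- function(n = 400, dt = 0.05) {
  x <- stats::rnorm(n)
  k <- stats::dnorm(seq(-20, 20), sd = 6)
  x <- stats::filter(c(rep(0, 20), x, rep(0, 20)), k / sum(k), sides = 2)
  x <- as.numeric(x[21:(20 + n)])
  w <- exp(-((seq_len(n) - n / 2) / (n / 5))^2)   # taper to zero at edges
  x <- x * w
  x <- x - mean(x)   # exact zero area (uniform grid)
  x * 1e7
}
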