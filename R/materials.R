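#' Multi-Debye dielectric models
#'
#' A Debye model is the sum of relaxation terms
#' \deqn{\varepsilon(f) = \varepsilon_\infty + \sum_k
#'   \frac{\Delta\varepsilon_k}{1 - i\,2\pi f\,\tau_k},}
#' with the \eqn{e^{-i\omega t}} time convention, so absorption corresponds to
#' \eqn{\mathrm{Im}\,\varepsilon \ge 0}. The static limit obeys the sum rule
#' \eqn{\varepsilon(0) = \varepsilon_\infty + \sum_k \Delta\varepsilon_k}.
#'
#' @param eps_inf dimensionless high-frequency permittivity.
#' @param delta_eps numeric vector of relaxation amplitudes, each `>= 0`.
#' @param tau_ps numeric vector of relaxation times in ps, each `> 0`.
#' @return An object of class `debye_model`.
#' @examples
#' wm <- debye_model(3.5, c(71.0, 2.5, 1.5), c(9.01, 1.03, 0.085))
#' evaluate_epsilon(wm, 0)      # static sum rule: 78.5
#' evaluate_epsilon(wm, 0.37)   # complex permittivity at 0.37 THz
#' @export
debye_model <- function(eps_inf, delta_eps = numeric(), tau_ps = numeric()) {
  stopifnot(is.numeric(eps_inf), length(eps_inf) == 1, eps_inf >= 1,
            length(delta_eps) == length(tau_ps),
            all(delta_eps >= 0), all(tau_ps > 0))
  structure(list(eps_inf = eps_inf, delta_eps = as.numeric(delta_eps),
                 tau_ps = as.numeric(tau_ps)),
            class = "debye_model")
}

#' Evaluate a Debye model
#'
#' @param model a [debye_model()].
#' @param freq_THz frequency in THz, `>= 0` (vectorized).
#' @return Complex permittivity \eqn{\varepsilon(f)}.
#' @export
evaluate_epsilon <- function(model, freq_THz) {
  stopifnot(inherits(model, "debye_model"))
  if (any(freq_THz < 0)) stop("frequency must be non-negative")
  eps <- rep(complex(real = model$eps_inf), length(freq_THz))
  for (k in seq_along(model$delta_eps)) {
    eps <- eps + model$delta_eps[k] /
      (1 - 1i * 2 * pi * freq_THz * model$tau_ps[k])
  }
  eps
}

#' Materials: dielectric model plus optical constants
#'
#' Bundles a THz-regime Debye model with the probe-wavelength (800 nm)
#' refractive index, the probe group index used for walk-off, and the molar
#' volume needed for molecular Kerr constants.
#'
#' @param name identifier.
#' @param debye a [debye_model()].
#' @param n_probe refractive index at the probe wavelength (800 nm), `>= 1`.
#' @param n_group_probe probe group index; defaults to `n_probe` (liquid
#'   dispersion at 800 nm is small).
#' @param molar_volume_cm3 molar volume in cm^3/mol, `> 0`, or `NA`.
#' @param notes free text (provenance of the shipped numbers).
#' @return An object of class `tke_material`.
#' @export
material <- function(name, debye, n_probe, n_group_probe = n_probe,
                     molar_volume_cm3 = NA_real_, notes = "") {
  stopifnot(inherits(debye, "debye_model"), n_probe >= 1,
            is.na(molar_volume_cm3) || molar_volume_cm3 > 0)
  structure(list(name = name, debye = debye, n_probe = n_probe,
                 n_group_probe = n_group_probe,
                 molar_volume_cm3 = molar_volume_cm3, notes = notes),
            class = "tke_material")
}

#' @export
print.tke_material <- function(x, ...) {
  n037 <- Re(complex_refractive_index(x, 0.37))
  cat(sprintf("<tke_material> %s  n(800 nm) = %.4f  n(0.37 THz) = %.3f\n",
              x$name, x$n_probe, n037))
  invisible(x)
}

#' Complex refractive index of a material
#'
#' Principal square root of the permittivity, \eqn{\tilde n = n + i\kappa}
#' with \eqn{n \ge 0} and \eqn{\kappa \ge 0} under the package sign
#' convention.
#'
#' @inheritParams material
#' @param mat a [tke_material()] (or a `debye_model`).
#' @param freq_THz frequency in THz (vectorized).
#' @return Complex \eqn{\tilde n} with `Re >= 0`, `Im >= 0`.
#' @export
complex_refractive_index <- function(mat, freq_THz) {
  dm <- if (inherits(mat, "tke_material")) mat$debye else mat
  eps_to_index(evaluate_epsilon(dm, freq_THz))
}

# principal root in the upper-right quadrant (n >= 0, kappa >= 0)
eps_to_index <- function(eps) {
  nt <- sqrt(eps)
  flip <- Re(nt) < 0
  nt[flip] <- -nt[flip]
  nt
}

# ---- built-in materials --------------------------------------------------
# The relaxation amplitudes below are literature-style fixtures, chosen so the
# 0.37 THz refractive index matches the tabulated experimental values; the
# paper-grade quantities are the relaxation times and the probe indices.

material_builtins <- function() {
  nai_debye <- function(d3) debye_model(3.5, c(71.0, 2.5, d3), c(9.01, 1.03, 0.085))
  list(
    `water-296K` = material(
      "water-296K",
      debye_model(3.5, c(71.15, 2.5, 1.35), c(9.01, 1.03, 0.085)),
      n_probe = 1.3282, molar_volume_cm3 = 18.07,
      notes = "three-mechanism Debye fixture; relaxation times 9.01/1.03/0.085 ps at 23 C"),
    d2o = material(
      "d2o",
      debye_model(3.5, c(71.3, 2.3, 1.0), c(12.1, 1.5, 0.1)),
      n_probe = 1.324, molar_volume_cm3 = 18.13,
      notes = "heavy-water Debye fixture, slower principal relaxation"),
    silica = material(
      "silica",
      debye_model(1.95^2),
      n_probe = 1.453, molar_volume_cm3 = NA_real_,
      notes = "fused-silica cuvette window; nearly dispersionless, lossless fixture"),
    cs2 = material(
      "cs2",
      debye_model(1.70^2),
      n_probe = 1.6058, molar_volume_cm3 = 60.3,
      notes = "non-polar reference liquid, flat THz index fixture"),
    benzene = material(
      "benzene",
      debye_model(1.51^2),
      n_probe = 1.489, molar_volume_cm3 = 89.4,
      notes = "non-polar reference liquid, flat THz index fixture"),
    methanol = material(
      "methanol",
      debye_model(1.9, c(28.3, 4.0, 0.8), c(51.5, 1.25, 0.16)),
      n_probe = 1.323, molar_volume_cm3 = 40.5,
      notes = "alcohol Debye fixture"),
    ethanol = material(
      "ethanol",
      debye_model(1.85, c(20.9, 2.2, 0.6), c(161, 3.3, 0.22)),
      n_probe = 1.3573, molar_volume_cm3 = 58.4,
      notes = "alcohol Debye fixture"),
    `2-propanol` = material(
      "2-propanol",
      debye_model(1.9, c(17.0, 1.0, 0.5), c(350, 3.0, 0.3)),
      n_probe = 1.379, molar_volume_cm3 = 76.5,
      notes = "alcohol Debye fixture"),
    `nai-1M` = material(
      "nai-1M", nai_debye(1.5), n_probe = 1.347, molar_volume_cm3 = 18.07,
      notes = "aqueous NaI fixture, 1 M"),
    `nai-3M` = material(
      "nai-3M", nai_debye(2.2), n_probe = 1.388, molar_volume_cm3 = 18.07,
      notes = "aqueous NaI fixture, 3 M"),
    `nai-5M` = material(
      "nai-5M", nai_debye(3.0), n_probe = 1.420, molar_volume_cm3 = 18.07,
      notes = "aqueous NaI fixture, 5 M"),
    `nai-9.5M` = material(
      "nai-9.5M", nai_debye(4.0), n_probe = 1.475, molar_volume_cm3 = 18.07,
      notes = "aqueous NaI fixture, 9.5 M"),
    vacuum = material(
      "vacuum", debye_model(1), n_probe = 1, molar_volume_cm3 = NA_real_,
      notes = "ideal reference medium")
  )
}

#' Look up a built-in material by name
#'
#' @param name one of the built-in identifiers (see
#'   `names(list_materials())`), e.g. `"water-296K"`, `"silica"`, `"cs2"`,
#'   `"methanol"`, `"nai-9.5M"`.
#' @return A [material()].
#' @export
get_material <- function(name) {
  db <- material_builtins()
  if (!name %in% names(db))
    stop("unknown material '", name, "'; built-ins: ",
         paste(names(db), collapse = ", "))
  db[[name]]
}

#' @rdname get_material
#' @export
list_materials <- function() material_builtins()

# ---- dielectric tables ---------------------------------------------------

#' Tabulated complex permittivity
#'
#' @param freq_THz strictly increasing frequency grid, THz.
#' @param eps complex permittivity values.
#' @param converged optional logical vector flagging per-frequency inversion
#'   convergence.
#' @param tbl a `dielectric_table` to write.
#' @return A tibble of class `dielectric_table` with columns `freq_THz`,
#'   `eps_real`, `eps_imag` and (if flagged by the extractor) `converged`.
#' @export
dielectric_table <- function(freq_THz, eps, converged = NULL) {
  stopifnot(all(diff(freq_THz) > 0), all(is.finite(freq_THz)),
            all(is.finite(Re(eps))), all(is.finite(Im(eps))))
  out <- tibble::tibble(freq_THz = freq_THz,
                        eps_real = Re(eps), eps_imag = Im(eps))
  if (!is.null(converged)) out$converged <- converged
  class(out) <- c("dielectric_table", class(out))
  out
}

#' @rdname dielectric_table
#' @param path delimited-text file with mandatory header
#'   `freq_THz eps_real eps_imag`.
#' @export
read_dielectric_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, comment.char = "#")
  stopifnot(all(c("freq_THz", "eps_real", "eps_imag") %in% names(df)))
  dielectric_table(df$freq_THz, complex(real = df$eps_real, imaginary = df$eps_imag))
}

#' @rdname dielectric_table
#' @export
write_dielectric_table <- function(tbl, path) {
  utils::write.table(as.data.frame(tbl)[c("freq_THz", "eps_real", "eps_imag")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- TDS transfer function and inversion ---------------------------------

# A stack description for TDS purposes: list of list(index = function(f) or
# constant complex, d_m = thickness). Helper to evaluate index.
stack_index <- function(layer, freq_THz) {
  ix <- layer$index
  if (is.function(ix)) ix(freq_THz)
  else if (inherits(ix, "tke_material") || inherits(ix, "debye_model"))
    complex_refractive_index(ix, freq_THz)
  else as.complex(ix)
}

#' Layered transmission spectrum and TDS transfer function
#'
#' `stack_transmission()` evaluates the first-pass (no-echo) complex
#' transmission of a planar stack at normal incidence: the product of Fresnel
#' amplitude coefficients at every interface (including entry from and exit to
#' the surrounding medium) and of the propagation factors
#' \eqn{\exp(i \tilde n \omega d / c)} through every layer.
#' `tds_transfer_function()` is the ratio sample/reference of two such
#' transmissions, the quantity measured by terahertz time-domain spectroscopy
#' when the reference scan replaces the liquid by a known medium.
#'
#' @param stack list of layers, each `list(index = , d_m = )` where `index` is
#'   a constant complex index, a [material()], a `debye_model`, or a
#'   `function(freq_THz)`; `d_m` in metres, `>= 0`.
#' @param freq_THz frequency in THz (vectorized).
#' @param n_outer complex index of the surrounding half-spaces (shared by
#'   sample and reference).
#' @return Complex amplitude transmission (or transfer ratio) per frequency.
#' @export
stack_transmission <- function(stack, freq_THz, n_outer = 1 + 0i) {
  omega <- 2 * pi * freq_THz * 1e12
  tr <- rep(complex(real = 1), length(freq_THz))
  n_prev <- rep(as.complex(n_outer), length(freq_THz))
  for (layer in stack) {
    stopifnot(layer$d_m >= 0)
    n_here <- rep_len(stack_index(layer, freq_THz), length(freq_THz))
    tr <- tr * fresnel_transmission(n_prev, n_here) *
      exp(1i * n_here * omega * layer$d_m / .c0)
    n_prev <- n_here
  }
  tr * fresnel_transmission(n_prev, rep(as.complex(n_outer), length(freq_THz)))
}

#' @rdname stack_transmission
#' @param stack_sample,stack_reference layer lists sharing the outer media.
#' @export
tds_transfer_function <- function(stack_sample, stack_reference, freq_THz,
                                  n_outer = 1 + 0i) {
  stack_transmission(stack_sample, freq_THz, n_outer) /
    stack_transmission(stack_reference, freq_THz, n_outer)
}

#' Extract a permittivity spectrum from a measured transfer function
#'
#' Per-frequency numerical inversion of the first-pass transfer-function
#' forward model for the permittivity of one unknown layer (the liquid) inside
#' an otherwise known geometry — this is how cuvette-window interfaces are
#' removed from TDS data. A damped Newton iteration in the complex
#' permittivity is used, initialized at each frequency from the converged
#' solution of the previous one.
#'
#' @param H complex transfer ratios, same length as `freq_THz`.
#' @param freq_THz frequency grid, THz.
#' @param geometry a function `function(eps, freq_THz)` returning the model
#'   transfer ratio for a trial liquid permittivity `eps` at one frequency —
#'   typically a closure over [tds_transfer_function()].
#' @param eps_init complex starting value for the first frequency.
#' @param tol convergence tolerance on `|H_model - H|`.
#' @param max_iter Newton iterations per frequency.
#' @return A [dielectric_table()] with a logical `converged` column;
#'   non-converged frequencies are flagged, never silently dropped.
#' @export
extract_epsilon_from_transfer <- function(H, freq_THz, geometry,
                                          eps_init = 5 + 2i, tol = 1e-8,
                                          max_iter = 60) {
  stopifnot(length(H) == length(freq_THz))
  eps_hat <- complex(length(freq_THz))
  conv <- logical(length(freq_THz))
  eps <- as.complex(eps_init)
  for (j in seq_along(freq_THz)) {
    f <- freq_THz[j]
    target <- H[j]
    ok <- FALSE
    resid <- geometry(eps, f) - target
    for (it in seq_len(max_iter)) {
      if (Mod(resid) < tol) { ok <- TRUE; break }
      h <- 1e-6 * max(1, Mod(eps))
      dH <- (geometry(eps + h, f) - geometry(eps, f)) / h
      if (!is.finite(Mod(dH)) || Mod(dH) == 0) break
      step <- resid / dH
      # damped update: halve until the residual actually decreases
      lam <- 1
      repeat {
        eps_try <- eps - lam * step
        resid_try <- geometry(eps_try, f) - target
        if (Mod(resid_try) < Mod(resid) || lam < 1 / 64) break
        lam <- lam / 2
      }
      eps <- eps_try
      resid <- resid_try
    }
    if (!ok && Mod(resid) < tol) ok <- TRUE
    eps_hat[j] <- eps
    conv[j] <- ok
    # next frequency starts from this solution (continuation)
  }
  dielectric_table(freq_THz, eps_hat, converged = conv)
}
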