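#' Kerr response coefficient set
#'
#' The parameter set of the birefringence model. The electronic term is
#' instantaneous and temperature-independent,
#' \deqn{\Delta n_e(z,t) = \lambda\,B_e\,E^2(z,t),}
#' while the molecular term carries Langevin memory through two causal
#' exponential kernels \eqn{K_i(s) = \tau_i^{-1} e^{-s/\tau_i}}:
#' \deqn{\Delta n_m = \lambda \frac{T_{ref}}{T} B_m^{(1)} \left[K_2 \ast E^2\right]
#'   + \lambda \left(\frac{T_{ref}}{T}\right)^{\!2} B_m^{(2)}
#'   \left[K_2 \ast \big(E \cdot (K_1 \ast E)\big)\right].}
#' The alignment coefficient \eqn{B_m^{(1)} \propto \Delta\alpha^2 \ge 0}
#' describes field-induced alignment of the most polarizable axis; the
#' orientation coefficient \eqn{B_m^{(2)} \propto \mu^2 \Delta\alpha} carries
#' the sign of the polarizability anisotropy and describes orientation of the
#' permanent dipole. The kernels are normalized, so the coefficients are
#' defined at the reference temperature `T_ref` (296 K) and the Boltzmann
#' factors of the underlying Langevin model appear as the
#' \eqn{(T_{ref}/T)^k} scalings. In the fast-inner-kernel limit
#' \eqn{\tau_1 \to 0} both terms share one functional form,
#' \eqn{K_2 \ast E^2}.
#'
#' @param B_e electronic Kerr coefficient, m/V^2.
#' @param B_m1 molecular alignment coefficient, m/V^2, `>= 0`.
#' @param B_m2 molecular orientation coefficient, m/V^2 (sign of
#'   \eqn{\Delta\alpha} for polar liquids).
#' @param tau1_ps inner (orientation drive) relaxation time, ps, `>= 0`
#'   (0 selects the analytic delta limit).
#' @param tau2_ps birefringence relaxation time, ps, `> 0`.
#' @param T_K sample temperature, K.
#' @param T_ref_K reference temperature at which the coefficients are defined.
#' @param lambda_probe_m probe wavelength, metres.
#' @return An object of class `kerr_params`.
#' @examples
#' kp <- kerr_params(B_e = 0, B_m2 = -0.025e-14, tau2_ps = 1.1)
#' @export
kerr_params <- function(B_e = 0, B_m1 = 0, B_m2 = 0, tau1_ps = 0,
                        tau2_ps = 1, T_K = 296, T_ref_K = 296,
                        lambda_probe_m = 800e-9) {
  stopifnot(tau2_ps > 0, tau1_ps >= 0, T_K > 0, T_ref_K > 0, B_m1 >= 0,
            lambda_probe_m > 0)
  structure(list(B_e = B_e, B_m1 = B_m1, B_m2 = B_m2, tau1_ps = tau1_ps,
                 tau2_ps = tau2_ps, T_K = T_K, T_ref_K = T_ref_K,
                 lambda_probe_m = lambda_probe_m),
            class = "kerr_params")
}

#' @export
print.kerr_params <- function(x, ...) {
  cat(sprintf(
    "<kerr_params> B_e = %.4g, B_m1 = %.4g, B_m2 = %.4g (1e-14 m/V^2), tau1 = %.3g ps, tau2 = %.3g ps, T = %.1f K\n",
    x$B_e * 1e14, x$B_m1 * 1e14, x$B_m2 * 1e14, x$tau1_ps, x$tau2_ps, x$T_K))
  invisible(x)
}

#' Electronic (instantaneous) birefringence
#'
#' \eqn{\Delta n_e = \lambda B_e E^2}: memoryless, quadratic in the field and
#' temperature-independent (hyperpolarizability response).
#'
#' @param params a [kerr_params()].
#' @param E field values, V/m (vector or `z` x `t` matrix).
#' @return \eqn{\Delta n_e}, same shape as `E`.
#' @export
electronic_birefringence <- function(params, E) {
  params$lambda_probe_m * params$B_e * E^2
}

# Causal normalized exponential filter, trapezoid-exact: for each row of `x`
# (time along columns, uniform step dt) returns
#   y_n = sum_j w_j (dt/tau) exp(-(t_n - t_j)/tau) x_j,
# trapezoid weights w (1/2 at both ends). Evaluated by the exact recursion
#   y_{n+1} = a y_n + (dt/tau) (a x_n + x_{n+1}) / 2,  a = exp(-dt/tau),
# so it agrees with direct quadrature to machine precision at any step size.
exp_kernel_filter <- function(x, tau_ps, dt_ps) {
  stopifnot(tau_ps > 0)
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, nrow = 1)
  a <- exp(-dt_ps / tau_ps)
  g <- dt_ps / tau_ps
  n <- ncol(x)
  u <- cbind(0, g * (a * x[, -n, drop = FALSE] + x[, -1, drop = FALSE]) / 2)
  y <- t(apply(u, 1, function(r) stats::filter(r, a, method = "recursive")))
  if (vec) as.vector(y) else y
}

#' Molecular (delayed) birefringence
#'
#' Evaluates the two-kernel molecular response (see [kerr_params()]) on a
#' field map or a single field trace. Uses exact recursive exponential
#' filtering on the uniform time grid; the quadrature is identical to the
#' brute-force reference [molecular_birefringence_oracle()]. When
#' `0 < tau1_ps <` the grid step the inner kernel is unresolvable and the
#' analytic delta limit is substituted (with a message).
#'
#' @param params a [kerr_params()].
#' @param E field values, V/m: vector (one depth) or `z` x `t` matrix.
#' @param dt_ps time-grid step, ps.
#' @return \eqn{\Delta n_m}, same shape as `E`.
#' @export
molecular_birefringence <- function(params, E, dt_ps) {
  vec <- is.null(dim(E))
  if (vec) E <- matrix(E, nrow = 1)
  s <- params$T_ref_K / params$T_K
  lam <- params$lambda_probe_m
  tau1 <- params$tau1_ps
  if (tau1 > 0 && tau1 < dt_ps) {
    message("tau1 = ", tau1, " ps is below the grid step ", dt_ps,
            " ps; using the analytic delta limit")
    tau1 <- 0
  }
  align <- if (params$B_m1 != 0) {
    lam * s * params$B_m1 * exp_kernel_filter(E^2, params$tau2_ps, dt_ps)
  } else 0
  orient <- if (params$B_m2 != 0) {
    inner <- if (tau1 == 0) E else exp_kernel_filter(E, tau1, dt_ps)
    lam * s^2 * params$B_m2 *
      exp_kernel_filter(E * inner, params$tau2_ps, dt_ps)
  } else 0
  out <- align + orient
  if (identical(out, 0)) out <- matrix(0, nrow(E), ncol(E))
  if (vec) as.vector(out) else out
}

#' Brute-force reference for the molecular response
#'
#' Direct trapezoid evaluation of the nested response integrals at a single
#' depth — O(n^2), intended only for small grids (<= 1e3 points) as the
#' independent check of the fast recursive path.
#'
#' @param params a [kerr_params()].
#' @param E field trace at one depth, V/m.
#' @param dt_ps grid step, ps.
#' @return \eqn{\Delta n_m(t)} vector.
#' @export
molecular_birefringence_oracle <- function(params, E, dt_ps) {
  n <- length(E)
  stopifnot(n <= 1000)
  t <- (seq_len(n) - 1) * dt_ps
  s <- params$T_ref_K / params$T_K
  lam <- params$lambda_probe_m
  tau2 <- params$tau2_ps
  tau1 <- if (params$tau1_ps > 0 && params$tau1_ps < dt_ps) 0 else params$tau1_ps

  trap <- function(v) {         # trapezoid cumulative weights applied to v[1..m]
    if (length(v) < 2) return(0)
    w <- rep(1, length(v)); w[1] <- w[length(v)] <- 0.5
    sum(w * v)
  }
  K <- function(sarg, tau) exp(-sarg / tau) / tau
  inner <- if (tau1 == 0) E else {
    vapply(seq_len(n), function(m)
      dt_ps * trap(E[seq_len(m)] * K(t[m] - t[seq_len(m)], tau1)), numeric(1))
  }
  g1 <- E^2
  g2 <- E * inner
  out <- numeric(n)
  for (m in seq_len(n)) {
    k2 <- K(t[m] - t[seq_len(m)], tau2)
    out[m] <- lam * s * params$B_m1 * dt_ps * trap(g1[seq_len(m)] * k2) +
      lam * s^2 * params$B_m2 * dt_ps * trap(g2[seq_len(m)] * k2)
  }
  out
}

#' Composed forward model: pulse to probe phase trace
#'
#' Chains [field_in_liquid()], the electronic and molecular birefringence, and
#' [probe_phase()] into the full pump-probe observable. The total is exactly
#' the sum of the two component traces (the model is linear in the
#' birefringence).
#'
#' @param params a [kerr_params()].
#' @param pulse incident [field_trace()].
#' @param stack a [cuvette_stack()].
#' @param n_z depth samples in the liquid.
#' @param field_map optionally, a precomputed [field_in_liquid()] result for
#'   this pulse/stack (the map does not depend on the Kerr coefficients, so
#'   fitting loops reuse it).
#' @return A [phase_trace()] with additional columns `electronic_mrad` and
#'   `molecular_mrad` summing to `phase_mrad`.
#' @export
forward_phase_model <- function(params, pulse, stack, n_z = 64,
                                field_map = NULL) {
  if (is.null(field_map)) field_map <- field_in_liquid(pulse, stack, n_z = n_z)
  dt <- field_map$time_ps[2] - field_map$time_ps[1]
  ng <- stack_liquid(stack)$n_group_probe
  dn_e <- electronic_birefringence(params, field_map$E)
  dn_m <- molecular_birefringence(params, field_map$E, dt)
  ph_e <- probe_phase(dn_e, field_map$z_m, field_map$time_ps, n_group = ng,
                      lambda_probe_m = params$lambda_probe_m)
  ph_m <- probe_phase(dn_m, field_map$z_m, field_map$time_ps, n_group = ng,
                      lambda_probe_m = params$lambda_probe_m)
  out <- phase_trace(ph_e$time_ps, ph_e$phase_mrad + ph_m$phase_mrad,
                     meta = list(params = params))
  out$electronic_mrad <- ph_e$phase_mrad
  out$molecular_mrad <- ph_m$phase_mrad
  out
}

#' Molecular Kerr constant
#'
#' Converts the fitted orientation coefficient into the molar molecular Kerr
#' constant used to compare liquids:
#' \deqn{K^{(m)} = \frac{6 n V_m \lambda}{(n^2+2)^2 (\varepsilon+2)^2}
#'   B_m^{(2)} N_A,}
#' with \eqn{n} the refractive index at the probe wavelength,
#' \eqn{\varepsilon} the real THz-regime permittivity (square of the THz
#' index), \eqn{V_m} the molar volume, and the Avogadro factor expressing the
#' per-mole convention. Result in cm^5/V^2 per mole; the sign follows
#' \eqn{B_m^{(2)}}.
#'
#' @param mat a [material()] (needs `n_probe` and a molar volume).
#' @param B_m2 orientation coefficient, m/V^2.
#' @param lambda_probe_m probe wavelength, metres.
#' @param f_THz frequency at which the THz index is taken (0.37 THz, the
#'   tabulated band).
#' @param n_thz optionally override the THz refractive index.
#' @return \eqn{K^{(m)}} in cm^5/V^2.
#' @examples
#' molecular_kerr_constant(get_material("water-296K"), -0.025e-14, n_thz = 2.48)
#' @export
molecular_kerr_constant <- function(mat, B_m2, lambda_probe_m = 800e-9,
                                    f_THz = 0.37, n_thz = NULL) {
  if (is.character(mat)) mat <- get_material(mat)
  if (is.na(mat$molar_volume_cm3))
    stop("material '", mat$name, "' has no molar volume")
  if (is.null(n_thz)) n_thz <- Re(complex_refractive_index(mat, f_THz))
  n <- mat$n_probe
  eps <- n_thz^2
  lambda_cm <- lambda_probe_m * 100
  B_cm <- B_m2 * 100                       # m/V^2 -> cm/V^2
  6 * n * mat$molar_volume_cm3 * lambda_cm /
    ((n^2 + 2)^2 * (eps + 2)^2) * B_cm * .NAvo
}
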