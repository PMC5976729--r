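#' Configuration of the rotational Brownian ensemble
#'
#' Parameters of the overdamped (inertia-free) rotational Langevin model of
#' dilute rigid rotors carrying a permanent dipole `mu` along the body axis
#' and a polarizability anisotropy `delta_alpha`. The field exerts the torque
#' \deqn{\mathbf{T} = \mu\,(\mathbf{u}\times\mathbf{E}) +
#'   \Delta\alpha\,(\mathbf{u}\cdot\mathbf{E})\,(\mathbf{u}\times\mathbf{E}),}
#' and the deterministic angular velocity is \eqn{\beta D_r \mathbf{T}}
#' (rotational mobility \eqn{D_r/k_BT}), on top of isotropic rotational
#' diffusion of total angular variance \eqn{4 D_r\,dt} per step.
#'
#' @param mu dipole moment, C m (water: 6.17e-30).
#' @param delta_alpha polarizability anisotropy coupling, C m^2/V.
#' @param D_r rotational diffusion coefficient, rad^2/ps.
#' @param T_K temperature, K.
#' @param n_rotors ensemble size.
#' @param dt_ps integrator step, ps; must satisfy `dt * D_r < 0.05`
#'   (small-angle regime).
#' @param seed RNG seed.
#' @return An object of class `rotor_config`.
#' @export
rotor_config <- function(mu = 6.17e-30, delta_alpha = 0, D_r = 0.1,
                         T_K = 296, n_rotors = 1e4, dt_ps = 0.05,
                         seed = 1L) {
  stopifnot(D_r > 0, dt_ps > 0, n_rotors >= 1)
  if (dt_ps * D_r >= 0.05)
    stop("stability bound violated: dt * D_r = ", dt_ps * D_r,
         " must be < 0.05")
  structure(list(mu = mu, delta_alpha = delta_alpha, D_r = D_r, T_K = T_K,
                 n_rotors = as.integer(n_rotors), dt_ps = dt_ps,
                 seed = as.integer(seed)),
            class = "rotor_config")
}

# uniform sample on the unit sphere (n x 3)
runif_sphere <- function(n) {
  z <- stats::rnorm(n * 3)
  u <- matrix(z, n, 3)
  u / sqrt(rowSums(u^2))
}

# sample cos(theta) from density prop. to exp(a * cos) (orientational start)
# or exp(b * cos^2) (aligned start), azimuthal angle uniform
sample_tilted <- function(n, a = 0, b = 0) {
  ct <- if (a == 0 && b == 0) stats::runif(n, -1, 1) else {
    # rejection from uniform with envelope at the density maximum
    f <- function(x) exp(a * x + b * x^2)
    M <- max(f(seq(-1, 1, length.out = 501)))
    out <- numeric(0)
    while (length(out) < n) {
      x <- stats::runif(2 * n, -1, 1)
      keep <- stats::runif(2 * n) < f(x) / M
      out <- c(out, x[keep])
    }
    out[seq_len(n)]
  }
  st <- sqrt(pmax(0, 1 - ct^2))
  phi <- stats::runif(n, 0, 2 * pi)
  cbind(st * cos(phi), st * sin(phi), ct)
}

#' Simulate the rotor ensemble under a time-dependent field
#'
#' Euler-Maruyama integration of the overdamped rotational Langevin equation
#' for `n_rotors` independent rotors in a field `E(t)` polarized along `z`.
#' Each step applies the deterministic torque drift, adds a tangent-plane
#' Gaussian kick of per-axis variance \eqn{2 D_r dt}, and renormalizes the
#' orientation vectors. Observables are the orientational moment
#' \eqn{\langle\cos\theta\rangle} and the alignment excess
#' \eqn{\langle\cos^2\theta\rangle - 1/3}, with ensemble standard errors.
#'
#' @param config a [rotor_config()].
#' @param field a [field_trace()] (resampled internally to the integrator
#'   step), a constant field in V/m, or `NULL` for free diffusion.
#' @param t_max_ps simulated span when `field` is not a trace.
#' @param init `"isotropic"`, or a list `list(a =, b =)` tilting the initial
#'   distribution towards orientation (`a`) or alignment (`b`).
#' @param thin record every `thin`-th step.
#' @return A tibble of class `rotor_observables` with columns `time_ps`,
#'   `mean_cos`, `mean_cos2_excess`, `se_cos`, `se_cos2`.
#' @examples
#' obs <- simulate_ensemble(rotor_config(n_rotors = 1000, seed = 2),
#'                          field = NULL, t_max_ps = 2)
#' @export
simulate_ensemble <- function(config, field = NULL, t_max_ps = 10,
                              init = "isotropic", thin = 1L) {
  stopifnot(inherits(config, "rotor_config"))
  set.seed(config$seed)
  dt <- config$dt_ps
  if (inherits(field, "field_trace")) {
    tgrid <- seq(min(field$time_ps), max(field$time_ps), by = dt)
    Et <- stats::approx(field$time_ps, field$field, xout = tgrid)$y
  } else {
    tgrid <- seq(0, t_max_ps, by = dt)
    Et <- rep(if (is.null(field)) 0 else as.numeric(field), length(tgrid))
  }
  n <- config$n_rotors
  u <- if (identical(init, "isotropic")) runif_sphere(n)
  else sample_tilted(n, a = init$a %||% 0, b = init$b %||% 0)

  beta_Dr_dt <- config$D_r * dt / (.kB * config$T_K)
  sd_kick <- sqrt(2 * config$D_r * dt)
  keep <- seq(1, length(tgrid), by = thin)
  n_keep <- length(keep)
  mc <- mc2 <- sec <- sec2 <- numeric(n_keep)
  ik <- 1L
  for (i in seq_along(tgrid)) {
    if (ik <= n_keep && i == keep[ik]) {
      ct <- u[, 3]
      mc[ik] <- mean(ct)
      mc2[ik] <- mean(ct^2) - 1 / 3
      sec[ik] <- stats::sd(ct) / sqrt(n)
      sec2[ik] <- stats::sd(ct^2) / sqrt(n)
      ik <- ik + 1L
    }
    if (i == length(tgrid)) break
    E <- Et[i]
    if (E != 0) {
      udotE <- u[, 3] * E
      # (T x u)/|.| = (mu + dalpha u.E) (E_vec - u (u.E)); E_vec = (0,0,E)
      coef <- beta_Dr_dt * (config$mu + config$delta_alpha * udotE)
      drift <- cbind(-coef * udotE * u[, 1],
                     -coef * udotE * u[, 2],
                     coef * (E - udotE * u[, 3]))
    } else drift <- 0
    g <- matrix(stats::rnorm(3 * n, sd = sd_kick), n, 3)
    g <- g - u * rowSums(g * u)          # project to tangent plane
    u <- u + drift + g
    u <- u / sqrt(rowSums(u^2))
  }
  out <- tibble::tibble(time_ps = tgrid[keep], mean_cos = mc,
                        mean_cos2_excess = mc2, se_cos = sec, se_cos2 = sec2)
  class(out) <- c("rotor_observables", class(out))
  attr(out, "config") <- config
  attr(out, "final_u") <- u
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Orientational relaxation times of the free rotor
#'
#' Simulates field-free decay from a weakly oriented and aligned start and
#' fits single exponentials to \eqn{\langle\cos\theta\rangle(t)} and
#' \eqn{\langle\cos^2\theta\rangle(t) - 1/3}. For isotropic diffusion the
#' eigenvalue spectrum \eqn{l(l+1)D_r} gives the analytic targets
#' \eqn{\tau_1 = 1/(2 D_r)} (the Debye dielectric relaxation time) and
#' \eqn{\tau_2 = 1/(6 D_r) = \tau_1/3} (the birefringence relaxation time).
#'
#' @param config a [rotor_config()].
#' @param t_max_ps decay span; default \eqn{2.5/(2 D_r)}.
#' @param init_a,init_b initial tilt strengths (see [simulate_ensemble()]).
#' @return List with `tau1_ps`, `tau2_ps`, `ratio`, the observables tibble,
#'   and `converged`.
#' @export
relaxation_times <- function(config, t_max_ps = NULL, init_a = 1, init_b = 1) {
  if (is.null(t_max_ps)) t_max_ps <- 2.5 / (2 * config$D_r)
  obs <- simulate_ensemble(config, field = NULL, t_max_ps = t_max_ps,
                           init = list(a = init_a, b = init_b))
  fit_exp <- function(t, y, tau0) {
    st <- list(A = y[1], tau = tau0)
    fit <- tryCatch(
      stats::nls(y ~ A * exp(-t / tau), start = st,
                 control = stats::nls.control(maxiter = 200, warnOnly = TRUE)),
      error = function(e) NULL)
    if (is.null(fit)) return(NA_real_)
    stats::coef(fit)[["tau"]]
  }
  tau1 <- fit_exp(obs$time_ps, obs$mean_cos, 1 / (2 * config$D_r))
  tau2 <- fit_exp(obs$time_ps, obs$mean_cos2_excess, 1 / (6 * config$D_r))
  list(tau1_ps = tau1, tau2_ps = tau2, ratio = tau1 / tau2,
       observables = obs, converged = is.finite(tau1) && is.finite(tau2))
}

#' Birefringence proxy from alignment observables
#'
#' The transient birefringence scales as
#' \eqn{\Delta n \propto \Delta\alpha\,(\langle\cos^2\theta\rangle - 1/3)}:
#' a negative anisotropy turns net alignment/orientation into negative
#' birefringence. Returns the pointwise product as a tibble.
#'
#' @param obs a `rotor_observables` tibble.
#' @param delta_alpha polarizability anisotropy (any proportional unit).
#' @return Tibble with `time_ps`, `proxy`.
#' @export
birefringence_proxy <- function(obs, delta_alpha) {
  tibble::tibble(time_ps = obs$time_ps,
                 proxy = delta_alpha * obs$mean_cos2_excess)
}
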