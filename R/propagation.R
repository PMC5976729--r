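#' Cuvette layer stacks
#'
#' Describes the planar sample geometry at normal incidence: an ordered list
#' of layers, exactly one of which is designated as the liquid under study.
#' The standard cell is 1.2 mm silica window / 0.2 mm liquid / 1.2 mm silica
#' window (2 mm liquid for the weakly absorbing CS2 cell).
#'
#' @param liquid a [material()] or built-in material name.
#' @param liquid_thickness_m liquid sheet thickness, metres.
#' @param window a [material()] or name for the windows.
#' @param window_thickness_m window thickness, metres.
#' @return An object of class `layer_stack` with fields `layers` (list of
#'   `list(material, d_m)`) and `liquid_index` (position of the liquid layer).
#' @export
cuvette_stack <- function(liquid, liquid_thickness_m = 0.2e-3,
                          window = "silica", window_thickness_m = 1.2e-3) {
  if (is.character(liquid)) liquid <- get_material(liquid)
  if (is.character(window)) window <- get_material(window)
  stopifnot(liquid_thickness_m > 0, window_thickness_m >= 0)
  structure(list(
    layers = list(list(material = window, d_m = window_thickness_m),
                  list(material = liquid, d_m = liquid_thickness_m),
                  list(material = window, d_m = window_thickness_m)),
    liquid_index = 2L), class = "layer_stack")
}

#' @rdname cuvette_stack
#' @param layers list of `list(material =, d_m =)`.
#' @param liquid_index which layer is the liquid.
#' @export
layer_stack <- function(layers, liquid_index) {
  stopifnot(liquid_index >= 1, liquid_index <= length(layers),
            all(vapply(layers, function(l) l$d_m >= 0, logical(1))))
  structure(list(layers = layers, liquid_index = as.integer(liquid_index)),
            class = "layer_stack")
}

stack_liquid <- function(stack) stack$layers[[stack$liquid_index]]$material

#' Fresnel amplitude transmission at normal incidence
#'
#' \eqn{t_{12} = 2\tilde n_1 / (\tilde n_1 + \tilde n_2)} for a wave going
#' from medium 1 into medium 2.
#'
#' @param n1,n2 complex refractive indices (vectorized).
#' @return Complex amplitude transmission coefficient.
#' @export
fresnel_transmission <- function(n1, n2) {
  s <- n1 + n2
  if (any(Mod(s) == 0)) stop("degenerate interface: n1 + n2 = 0")
  2 * n1 / s
}

#' Propagate the pump pulse into the liquid layer
#'
#' Frequency-domain, first-pass propagation: the incident spectrum is
#' multiplied by the Fresnel transmissions of every interface up to the liquid
#' entrance, by the absorption and differential dispersion of the layers in
#' front of the liquid, and by \eqn{\exp(i\tilde n(\omega)\omega z/c)} inside
#' the liquid, then transformed back per depth. Echo orders are excluded by
#' default (window echoes fall outside the analysis window for millimetre
#' silica).
#'
#' Delay-origin convention: the time axis is co-moving at the vacuum speed of
#' light, and the rigid group delay of the layers in front of the liquid is
#' removed by referencing their propagation phase to their real index at
#' `f_ref_THz`. `t = 0` therefore remains (to within window dispersion) the
#' arrival of the incident pulse peak at the liquid entrance, the `z = 0`
#' plane.
#'
#' @param pulse a [field_trace()], the incident free-space waveform.
#' @param stack a [cuvette_stack()]/[layer_stack()].
#' @param n_z number of depth samples across the liquid.
#' @param f_ref_THz reference frequency for the delay-origin convention;
#'   defaults to the pulse center frequency recorded in its metadata (0.25 THz
#'   otherwise).
#' @return An object of class `field_map`: list with `z_m` (length `n_z`),
#'   `time_ps`, and `E` (`n_z` x `n_t` matrix, V/m), plus the stack.
#' @export
field_in_liquid <- function(pulse, stack, n_z = 64, f_ref_THz = NULL) {
  stopifnot(inherits(stack, "layer_stack"))
  if (is.null(f_ref_THz)) {
    meta <- attr(pulse, "meta")
    f_ref_THz <- if (!is.null(meta$center_freq_THz)) meta$center_freq_THz else 0.25
  }
  n <- nrow(pulse)
  dt <- trace_dt(pulse)
  A <- stats::fft(pulse$field, inverse = TRUE) * dt
  nf <- floor(n / 2) + 1
  f_pos <- (seq_len(nf) - 1) / (n * dt)          # THz (1/ps)
  omega <- 2 * pi * f_pos * 1e12                 # rad/s

  # cumulative pre-liquid transfer at positive frequencies
  Tin <- rep(complex(real = 1), nf)
  n_prev <- rep(1 + 0i, nf)
  for (j in seq_len(stack$liquid_index - 1)) {
    lay <- stack$layers[[j]]
    nj <- complex_refractive_index(lay$material, f_pos)
    nref <- Re(complex_refractive_index(lay$material, f_ref_THz))
    Tin <- Tin * fresnel_transmission(n_prev, nj) *
      exp(1i * (nj - nref) * omega * lay$d_m / .c0)
    n_prev <- nj
  }
  liq <- stack_liquid(stack)
  n_liq <- complex_refractive_index(liq, f_pos)
  Tin <- Tin * fresnel_transmission(n_prev, n_liq)

  # aliasing guard: spectral energy in the top half of the band
  p <- Mod(A[seq_len(nf)])^2
  hi <- sum(p[f_pos > max(f_pos) / 2])
  if (hi > 0.01 * sum(p))
    warning("more than 1% of pulse energy above half the Nyquist frequency; ",
            "refine the time grid")

  L <- stack$layers[[stack$liquid_index]]$d_m
  z <- seq(0, L, length.out = n_z)
  E <- matrix(0, n_z, n)
  base <- A[seq_len(nf)] * Tin
  for (iz in seq_len(n_z)) {
    Az <- base * exp(1i * n_liq * omega * z[iz] / .c0)
    full <- spectrum_two_sided(Az, n)
    E[iz, ] <- Re(stats::fft(full)) / (n * dt)
  }
  structure(list(z_m = z, time_ps = pulse$time_ps, E = E, stack = stack),
            class = "field_map")
}

#' @export
print.field_map <- function(x, ...) {
  cat(sprintf("<field_map> %d depths x %d delays, liquid '%s', L = %.3g mm\n",
              length(x$z_m), length(x$time_ps), stack_liquid(x$stack)$name,
              max(x$z_m) * 1e3), ...)
  invisible(x)
}

#' Tidy a field map into long format
#'
#' @param x a `field_map`.
#' @param ... unused.
#' @return Tibble with columns `z_m`, `time_ps`, `field`.
#' @export
tidy.field_map <- function(x, ...) {
  tibble::tibble(z_m = rep(x$z_m, times = length(x$time_ps)),
                 time_ps = rep(x$time_ps, each = length(x$z_m)),
                 field = as.vector(x$E))
}

#' Probe phase shift with group-velocity walk-off
#'
#' Integrates a birefringence map over the liquid thickness as seen by a probe
#' pulse travelling at the group velocity \eqn{c/n_g}:
#' \deqn{\Delta\phi(t_d) = \frac{2\pi}{\lambda}
#'   \int_0^L \Delta n\!\left(z,\; t_d + \frac{n_g z}{c}\right) dz,}
#' with delay \eqn{t_d} referenced to the probe's arrival at the liquid
#' entrance. Trapezoid quadrature in `z`, linear interpolation along the time
#' axis. Delays whose walk-off sampling would leave the time grid are dropped;
#' an error names the required padding if nothing remains.
#'
#' @param dn_map matrix `length(z_m)` x `length(time_ps)` of birefringence
#'   values \eqn{\Delta n(z, t)} (dimensionless), or a `field_map`-shaped list
#'   with elements `z_m`, `time_ps`, `E` reused as \eqn{\Delta n}.
#' @param z_m depth grid, metres (ignored when `dn_map` carries its own).
#' @param time_ps time grid, ps.
#' @param n_group probe group index of the liquid.
#' @param lambda_probe_m probe wavelength, metres.
#' @return A [phase_trace()] (mrad) on the largest delay grid for which the
#'   walk-off sampling stays inside `time_ps`.
#' @export
probe_phase <- function(dn_map, z_m = NULL, time_ps = NULL, n_group,
                        lambda_probe_m = 800e-9) {
  if (is.list(dn_map) && !is.null(dn_map$E)) {
    z_m <- dn_map$z_m; time_ps <- dn_map$time_ps; dn_map <- dn_map$E
  }
  stopifnot(is.matrix(dn_map), nrow(dn_map) == length(z_m),
            ncol(dn_map) == length(time_ps), n_group >= 1)
  shift_ps <- n_group * z_m / .c0 * 1e12
  t_max_out <- max(time_ps) - max(shift_ps)
  keep <- time_ps <= t_max_out + 1e-12
  if (!any(keep))
    stop("walk-off (", signif(max(shift_ps), 3), " ps) exceeds the time grid; ",
         "pad the traces by at least ", signif(max(shift_ps), 3), " ps")
  t_out <- time_ps[keep]
  nz <- length(z_m)
  sampled <- matrix(0, nz, length(t_out))
  for (iz in seq_len(nz)) {
    sampled[iz, ] <- stats::approx(time_ps, dn_map[iz, ],
                                   xout = t_out + shift_ps[iz], rule = 2)$y
  }
  w <- trapezoid_weights(z_m)
  phi <- (2 * pi / lambda_probe_m) * as.vector(crossprod(sampled, w))
  phase_trace(t_out, phi * 1e3)   # rad -> mrad
}

trapezoid_weights <- function(x) {
  n <- length(x)
  if (n == 1) return(0)
  w <- numeric(n)
  dx <- diff(x)
  w[1] <- dx[1] / 2
  w[n] <- dx[n - 1] / 2
  if (n > 2) w[2:(n - 1)] <- (dx[-1] + dx[-(n - 1)]) / 2
  w
}
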