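#' Synthesize a single-cycle terahertz pulse
#'
#' Generates a carrier-envelope-phase-stable single-cycle waveform as the
#' first derivative of a Gaussian,
#' \deqn{E(t) \propto -t\, e^{-t^2 / (2\sigma^2)}, \qquad
#'       \sigma = \frac{1}{2\pi f_0},}
#' normalized so that \eqn{\max|E| =} `peak_field`. The amplitude spectrum
#' \eqn{|\hat E(\omega)| \propto \omega e^{-\omega^2\sigma^2/2}} peaks at
#' \eqn{\omega = 1/\sigma}, i.e. at the requested center frequency, and the
#' waveform is odd, so its time integral vanishes — the zero-area property of
#' any pulse that has propagated in free space.
#'
#' @param peak_field peak electric field, V/m (510 kV/cm = 5.1e7 V/m is the
#'   experimental scale).
#' @param center_freq_THz spectral-amplitude peak frequency, THz.
#' @param t_grid_ps uniform time grid in ps; must span at least 6 periods of
#'   the center frequency. Default: 0.02 ps steps from -10 to +25 ps.
#' @param t0_ps temporal center of the waveform.
#' @return A [field_trace()].
#' @examples
#' p <- synth_single_cycle(5.1e7, 0.25)
#' center_frequency(p)
#' @export
synth_single_cycle <- function(peak_field, center_freq_THz,
                               t_grid_ps = seq(-10, 25, by = 0.02),
                               t0_ps = 0) {
  stopifnot(peak_field > 0, center_freq_THz > 0)
  check_uniform_grid(t_grid_ps)
  span <- diff(range(t_grid_ps))
  if (span < 6 / center_freq_THz)
    stop("time grid spans ", signif(span, 3), " ps but at least ",
         signif(6 / center_freq_THz, 3),
         " ps (6 cycles of the center frequency) are required")
  sigma <- 1 / (2 * pi * center_freq_THz)
  s <- (t_grid_ps - t0_ps) / sigma
  e <- -s * exp(-s^2 / 2)
  # normalize to the sampled extremum so max|E| = peak_field on this grid
  e <- e * peak_field / max(abs(e))
  field_trace(t_grid_ps, e,
              meta = list(peak_field = peak_field,
                          center_freq_THz = center_freq_THz,
                          shape = "gaussian-derivative"))
}

#' Center frequency of a field trace
#'
#' Defined as the argmax of the single-sided amplitude spectrum, refined by
#' parabolic interpolation between the neighbouring frequency bins. Invariant
#' under time shifts of the waveform.
#'
#' @param trace a [field_trace()].
#' @return Frequency in THz.
#' @export
center_frequency <- function(trace) {
  if (all(trace$field == 0)) stop("cannot locate a spectral peak of an all-zero trace")
  sp <- to_spectrum(trace)
  a <- Mod(sp$amplitude)
  k <- which.max(a)
  f <- sp$freq_THz
  if (k > 1 && k < length(a)) {
    # parabola through the three bins around the maximum
    d <- (a[k - 1] - a[k + 1]) / (2 * (a[k - 1] - 2 * a[k] + a[k + 1]))
    f[k] + d * (f[2] - f[1])
  } else f[k]
}

#' Fourier-domain view of a trace
#'
#' `to_spectrum()` returns the single-sided complex spectrum of a real trace
#' under the package's \eqn{e^{-i\omega t}} convention (analysis transform
#' \eqn{\hat E(f) = \sum_n E_n e^{+2\pi i f t_n}\Delta t});
#' `from_spectrum()` inverts it exactly on the original grid. Parseval's
#' identity links the two representations.
#'
#' @param trace a [field_trace()] (uniform grid required).
#' @return `to_spectrum()`: a tibble of class `tke_spectrum` with columns
#'   `freq_THz`, `amplitude` (complex, units V/m * ps) and attributes carrying
#'   the original grid; `from_spectrum()`: the reconstructed [field_trace()].
#' @export
to_spectrum <- function(trace) {
  check_uniform_grid(trace$time_ps)
  n <- nrow(trace)
  dt <- trace_dt(trace)
  # analysis transform with e^{+i omega t}: unnormalized inverse FFT
  A <- stats::fft(trace$field, inverse = TRUE) * dt
  nf <- floor(n / 2) + 1
  f <- (seq_len(nf) - 1) / (n * dt)
  out <- tibble::tibble(freq_THz = f, amplitude = A[seq_len(nf)])
  class(out) <- c("tke_spectrum", class(out))
  attr(out, "time_ps") <- trace$time_ps
  attr(out, "n") <- n
  out
}

#' @rdname to_spectrum
#' @param spec a `tke_spectrum` produced by `to_spectrum()`.
#' @export
from_spectrum <- function(spec) {
  n <- attr(spec, "n")
  t <- attr(spec, "time_ps")
  dt <- t[2] - t[1]
  A <- spectrum_two_sided(spec$amplitude, n)
  e <- Re(stats::fft(A)) / (n * dt)
  field_trace(t, e)
}

# rebuild the conjugate-symmetric full spectrum from the single-sided half
spectrum_two_sided <- function(A_half, n) {
  nf <- length(A_half)
  A <- complex(n)
  A[seq_len(nf)] <- A_half
  if (n %% 2 == 0) {
    A[seq(nf + 1, n)] <- Conj(A_half[seq(nf - 1, 2)])
  } else {
    A[seq(nf + 1, n)] <- Conj(A_half[seq(nf, 2)])
  }
  A
}
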