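---
title: "Modelling and decomposing the terahertz-induced Kerr effect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and decomposing the terahertz-induced Kerr effect}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thzkerr)
```

## The physical picture

A single-cycle terahertz (THz) pulse with a carrier-envelope-stable field
$E(t)$ exerts two torques on a molecule in a liquid: one through the
permanent dipole moment $\mu$ (odd in the field) and one through the
anisotropic part of the polarizability tensor, $\Delta\alpha$ (even in the
field). The first *orients* dipoles along the instantaneous field; the
second *aligns* the most polarizable molecular axis with the field without
picking a direction. Both perturb the orientational distribution and hence
produce a transient birefringence $\Delta n = n_\parallel - n_\perp$, read
out as the phase shift of a co-propagating, 45°-polarized 800 nm probe.
Because the orientation mechanism contributes with the sign of
$\mu^2\Delta\alpha$ while alignment contributes $\propto\Delta\alpha^2 > 0$,
the *sign* of the measured molecular response determines the sign of
$\Delta\alpha$ — the quantity an optical Kerr experiment cannot access.

The package implements this chain as composable stages, each individually
testable:

1. **materials** — multi-Debye dielectric models $\varepsilon(\omega)$,
   optical constants, and THz time-domain spectroscopy (TDS) transfer
   functions with numerical inversion;
2. **pulse** — parametric single-cycle waveform synthesis and spectral
   utilities;
3. **propagation** — frequency-domain transport of the pump through the
   cuvette stack giving $E(z,t)$, and the probe phase integral with
   group-velocity walk-off;
4. **response** — the electronic and two-kernel molecular birefringence;
5. **fitting** — decomposition of phase traces into $B_e$ and a molecular
   coefficient plus relaxation time, with diagnostics;
6. **rotor** — an overdamped rotational Brownian-dynamics simulator linking
   the response kernels to microscopic relaxation;
7. **synthetic data** — a generator producing complete noisy experiments
   with known ground truth.

## Response model and its assumptions

The electronic term is memoryless and temperature independent,
$\Delta n_e = \lambda B_e E^2(z,t)$. The molecular term follows from a
Langevin description of rotational diffusion in the overdamped, dilute
limit with an isotropic diffusion tensor $D_r$:

$$
\Delta n_m(z,t) = \lambda\,\frac{T_{\mathrm{ref}}}{T}\,B_m^{(1)}
  \left[K_2 \ast E^2\right](z,t)
  + \lambda\left(\frac{T_{\mathrm{ref}}}{T}\right)^{2} B_m^{(2)}
  \left[K_2 \ast \big(E\cdot(K_1\ast E)\big)\right](z,t),
$$

with normalized causal kernels $K_i(s) = \tau_i^{-1}e^{-s/\tau_i}$,
$\tau_1 = 1/(2D_r) = \tau_D$ and $\tau_2 = 1/(6D_r) = \tau_D/3$. Two
formulation choices deserve emphasis:

* **Temperature prefactors.** The underlying Langevin derivation produces
  Boltzmann factors $\beta = (k_BT)^{-1}$ (orientation $\propto\beta^2$,
  alignment $\propto\beta$). Writing those factors verbatim next to
  coefficients in m/V² is not dimensionally closed, so the package defines
  the coefficients *at a reference temperature* $T_{\mathrm{ref}} = 296$ K
  and carries the temperature dependence as $(T_{\mathrm{ref}}/T)^k$,
  $k = 1$ for alignment and $k = 2$ for orientation. Tabulated coefficients
  are therefore reproduced exactly at the experimental temperature while
  the physical $\beta$/$\beta^2$ scaling — the basis of the
  temperature-derivative decomposition — is preserved.
* **Causal inner kernel.** The inner (drive) kernel is implemented as the
  decaying exponential of the time *difference into the past*; a kernel
  growing into the past would violate causality. In the limit
  $\tau_1 \to 0$ the inner convolution collapses to the identity and both
  molecular terms share the single functional form $K_2 \ast E^2$ — this
  is also the regime found for water, so the polar fitting default is
  $\tau_1 = 0$ (options: tied $\tau_1 = 3\tau_2$, or a fixed value).

Useful identities the tests exploit: for a DC field the molecular response
reaches $\lambda E^2[(T_{\mathrm{ref}}/T)B_m^{(1)} +
(T_{\mathrm{ref}}/T)^2B_m^{(2)}]$; for any zero-area pulse the
time-averaged orientation term has the sign of $B_m^{(2)}$, because
$\int E\,(K_1\!\ast\!E)\,dt = \int |\hat E(\omega)|^2\,
\mathrm{Re}[1/(1-i\omega\tau_1)]\,d\omega > 0$.

## Propagation and the probe integral

The pump spectrum is multiplied per frequency by the Fresnel amplitude
transmissions of the interfaces ahead of the liquid and by
$\exp(i\tilde n(\omega)\omega z/c)$ inside it, then transformed back at
each of $n_z$ depths. Multiple reflections are excluded by default: for
1.2 mm silica windows the first etalon echo arrives roughly 16 ps after
the main pass and far outside the few-picosecond response window, and the
liquid itself is strongly absorbing. The probe integral

$$
\Delta\phi(t_d) = \frac{2\pi}{\lambda}\int_0^L
  \Delta n\!\left(z,\,t_d + \frac{n_g z}{c}\right)\mathrm{d}z
$$

uses the probe *group* index $n_g$ for the walk-off; the default equates
it to the tabulated 800 nm phase index, since liquid dispersion at 800 nm
shifts the walk-off time by far less than the pump period. For water the
walk-off spread $L(n_{\mathrm{THz}} - n_g)/c \approx 0.77$ ps is
comparable to $\tau_2$ and materially shapes the trace — this is why the
propagation stage matters at all.

**Delay-origin convention.** The time axis co-moves at the vacuum speed of
light and the rigid group delay of the windows is referenced away (their
propagation phase is taken relative to the real index at the pulse center
frequency), so $t = 0$ is the arrival of the incident pulse peak at the
liquid entrance. Output files state this in their provenance headers.

## Numerical choices

* **Exponential filtering.** The response convolutions are evaluated by the
  exact recursion $y_{n+1} = a y_n + \tfrac{\Delta t}{\tau}\,
  (a f_n + f_{n+1})/2$, $a = e^{-\Delta t/\tau}$, which reproduces
  trapezoid quadrature of the kernel integral to machine precision at any
  step. A brute-force $O(n^2)$ double-quadrature oracle
  (`molecular_birefringence_oracle()`) provides the independent reference;
  the two agree to better than $10^{-8}$ on random fields. An inner
  $\tau_1$ below the grid step is replaced by its analytic delta limit
  (with a message) rather than being sampled unresolved.
* **Grids.** Defaults: 0.02 ps time step over −10…+25 ps (the 0.25 THz
  single cycle is ~40 samples per period, and spectral leakage above half
  the Nyquist band triggers a warning), and $n_z = 64$ depths across the
  liquid. Halving both changes the water-fixture peak phase by < 0.5 %
  (convergence-tested).
* **Square root and sign conventions.** All modules share the
  $e^{-i\omega t}$ convention: absorption means
  $\mathrm{Im}\,\varepsilon \ge 0$ and $\mathrm{Im}\,\tilde n \ge 0$; the
  principal branch of $\sqrt{\varepsilon}$ is taken.
* **TDS inversion.** Per-frequency damped Newton iteration in the complex
  permittivity, initialized from the previous frequency (continuation);
  non-converged frequencies are flagged in the output table, never
  dropped silently.

## Fitting by variable projection

At fixed $\tau_2$ the model phase is *linear* in $(B_e, B_m)$, so the
decomposition solves an exact weighted linear least-squares problem inside
a one-dimensional search over $\tau_2$ (coarse logarithmic scan to bracket
the global optimum, then golden-section refinement). This replaces a
generic three-parameter trust-region optimizer: the inner solve cannot be
trapped in a local minimum, and the scan guards the single remaining
dimension, making multi-start unnecessary. Standard errors come from the
finite-difference Gauss–Newton covariance with column equilibration
(coefficient and relaxation-time sensitivities differ by ~13 orders of
magnitude). Weighting is inverse-variance when the trace carries
uncertainties, uniform otherwise.

The `polar` model frees $B_m^{(2)}$ with $B_m^{(1)} = 0$ — for polar
liquids the orientation term dominates because the alignment coefficient
carries an extra factor of the small $\Delta\alpha$ — while `nonpolar`
frees $B_m^{(1)}$ with $B_m^{(2)} = 0$ ($\mu = 0$).

Two auxiliary analyses mirror the experimental practice:

* **The RMS-doubling bound.** Because electronic and (walk-off-smeared)
  molecular traces are substantially collinear, $B_e$ can be weakly
  identified; `bound_electronic_coefficient()` reports the smallest
  $|B_e|$ at which the residual RMS, after refitting the remaining
  parameters, reaches twice the free-fit minimum (geometric scan, both
  signs, bisection refinement).
* **Temperature decomposition.** The electronic term is
  temperature-independent while orientation scales as
  $(T_{\mathrm{ref}}/T)^2$, so the per-delay derivative
  $-\mathrm{d}\Delta\phi/\mathrm{d}T$ isolates the molecular trace. The
  default is a per-delay quadratic fit in $T$ with the derivative
  evaluated at the lowest temperature: over a 296–341 K series the
  curvature of $T^{-2}$ biases a straight-line slope by ~20 %, whereas
  the quadratic recovers the endpoint derivative to a few per cent; a
  polynomial fit is also more noise-robust than two-point differences.

## The Brownian rotor surrogate

`simulate_ensemble()` integrates $N$ independent rigid rotors
(Euler–Maruyama): deterministic angular velocity $\beta D_r$ times the
torque $\mu(\mathbf u\times\mathbf E) + \Delta\alpha(\mathbf u\cdot\mathbf
E)(\mathbf u\times\mathbf E)$, plus a tangent-plane Gaussian kick of
per-axis variance $2D_r\Delta t$, with renormalization each step and the
stability bound $D_r\Delta t < 0.05$ enforced. It reproduces, from the
dynamics alone, the eigenvalue structure behind the response kernels
($\langle\cos\theta\rangle$ relaxes at $2D_r$,
$\langle\cos^2\theta\rangle - 1/3$ at $6D_r$, ratio 3), Boltzmann
equilibrium in a DC field, the linear-response convolution for weak
drive, and the few-hundred-femtosecond lag of peak orientation behind the
driving field. Rotor–rotor correlations, inertia and hydrogen-bond
network dynamics are deliberately outside this surrogate; it supports the
*mechanism*, not quantitative water dynamics.

## What the synthetic generator does and does not emulate

`generate_experiment()` runs the exact forward model and adds (i)
per-delay-point squared amplitude jitter $(1+\epsilon)^2$,
$\epsilon\sim N(0, 1\%)$ — a delay scan samples a fresh pulse at every
point — and (ii) additive white phase noise of 0.01 mrad, the scale of
balanced-detection noise. The jitter fraction and noise floor are
calibration knobs of this package (no published noise specification
exists); the defaults make water-fixture recovery non-trivial but
achievable, which is what the recovery tests quantify. The generator does
**not** emulate electro-optic detector response, lock-in demodulation,
probe depletion, pointing drift, or slow baseline wander, and the fit
consumes the same forward model that generated the data — so passing
recovery tests demonstrates estimator correctness and noise robustness,
not immunity to model misspecification in real data. The shipped Debye
amplitude sets are literature-style fixtures chosen to reproduce the
tabulated 0.37 THz refractive indices within ±0.10 (the relaxation times
9.01/1.03/0.085 ps for water are the physically anchored quantities);
molar volumes (18.07, 40.5, 58.4, 76.5 cm³/mol for water and the
alcohols) are standard constants. One reference-liquid table cell (the
CS₂ relaxation time, parsed as 1.84 ps) is typographically ambiguous in
its source and is marked low-confidence in the fixture documentation.

## Problem sizes and reproducibility

The test suite and the acceptance script choose desk-scale sizes: 20
noisy replicates per recovery study on the default grids, $10^5$ rotors
for relaxation-time estimates (a few per cent Monte-Carlo error),
$2\times10^4$–$10^5$ rotors for distributional checks. Every stochastic
path takes an explicit integer seed, and generated datasets echo their
seed and a content hash in their manifest, so any reported number can be
regenerated bit-identically.

## Known limitations

* Normal incidence, first-pass propagation; no etalon echoes, focusing,
  or Gouy-phase effects (an echo-order hook exists in the transfer-function
  code path but the analysis default is first pass).
* The molecular kernel model assumes isotropic rotational diffusion; the
  simulator offers user-supplied anisotropic rates, but the response
  kernels do not.
* Coefficients are empirical: the microscopic prefactors linking
  $B_m^{(1,2)}$ to $(\Delta\alpha, \mu)$ are not evaluated.
* `center_frequency()` is defined as the spectral-amplitude argmax (with
  parabolic refinement); centroid-based definitions of "center frequency"
  differ for broadband single-cycle pulses.
* No Bayesian uncertainty propagation; standard errors are local
  Gauss–Newton estimates.
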