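---
title: "Harmonic vibronic and nuclear-ensemble lineshapes: models, numerics, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Harmonic vibronic and nuclear-ensemble lineshapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vibronic)
```

# The model

An absorption band of a chromophore with one bright electronic transition is
determined, under the Born–Oppenheimer and Condon approximations, by the two
nuclear potential-energy surfaces and the (constant) transition dipole
$\mu$. This package treats both surfaces as harmonic. In the mass-weighted
normal coordinates $Q$ of the initial state (frequencies $\omega$), the
final-state surface is

$$V'(Q) = E_{00} + \tfrac12\, \lVert \Omega' J (Q - K) \rVert^2,$$

a Duschinsky rotation $J$ plus displacement $K$ ($K$ is the final-state
minimum expressed in initial-state coordinates; $\Omega' =
\mathrm{diag}(\omega')$). Everything downstream — Franck–Condon factors,
correlation functions, vertical-excitation statistics — is a functional of
$(J, K, \omega, \omega', E_{00}, \mu)$.

Four standard constructions of the map are implemented in `build_map()`:

| model | needs | gives |
|---|---|---|
| AH | final minimum + Hessian | full $J$, $K$, $\omega'$ |
| AS | final minimum | $J = I$, $\omega' = \omega$, $K$ from geometry |
| VH | final Hessian + gradient at initial minimum | $J$, $\omega'$ extrapolated; $K = -H_Q^{-1} g_Q$ |
| VG | final gradient at initial minimum | $J = I$, $\omega' = \omega$, $K = -g_Q/\omega^2$ |

The adiabatic pair uses real information about the relaxed excited state; the
vertical pair extrapolates it from the ground-state minimum. The package's
method-comparison tests show the consequence on a cyanine-like model: the
adiabatic FC spectrum resolves the vibronic progression, while vertical
sampling (either ensemble) cannot, because no ground-state ensemble carries
final-state shape information.

Two derived energies matter and differ whenever $K \neq 0$:
$E_\mathrm{vert} = E_{00} + \lambda$ (vertical excitation energy,
$\lambda = \tfrac12\sum \omega_k'^2 (JK)_k^2$ the reorganization energy) and
the 0–0 line $E_{00} + \tfrac12\sum(\omega' - \omega)$. For a single
displaced mode with Huang–Rhys factor $S = \omega K^2/2 < 1$ the absorption
maximum sits on the 0–0 line, a full $S\omega$ below $E_\mathrm{vert}$ —
which is why benchmarking vertical excitation energies against experimental
band maxima is unreliable.

# Franck–Condon engines

**Time-independent.** The overlaps $\langle v | v' \rangle$ are generated
from the Gaussian generating function of the two oscillator ladders; its
quadratic-form matrices come from one $3N$-dimensional Gaussian integral and
yield two-term recursions that raise one quantum at a time while only
referencing equal-or-lower states (memoized, numerically stable; an explicit
instability check aborts rather than returning garbage at extreme quanta).
For $J = I$ the overlap factorizes over modes and the engine switches to
cached one-dimensional tables, which is what makes the 6-mode enumerations
cheap. Correctness is pinned by three independent oracles in the test suite:
the Poisson law $e^{-S}S^n/n!$ for displaced modes, the closed form
$2\sqrt{\omega\omega'}/(\omega+\omega')$ for a pure frequency change, and
brute-force Gauss–Hermite quadrature of the explicit wavefunction product on
rotated, displaced, thermally excited maps (agreement $\sim 10^{-15}$).

Enumeration at 0 K is organized by excitation class (number of
simultaneously excited final modes, default cap 4) with a per-mode quanta cap
(default 10) and an intensity floor ($10^{-8}$ of the strongest stick); the
captured fraction of the FC sum rule is reported and warned about below
0.99. At finite temperature, initial vectors come from per-mode geometric
distributions $p_v = (1-q)q^v$, $q = e^{-\omega/k_BT}$, pruned at a
population floor with the kept fraction reported. Hot bands are labelled on
both sides (`"6^1<-1^2"`).

**Time-dependent.** The thermal dipole correlation function

$$\chi(t) = e^{-iE_{00}t}\,
\mathrm{Tr}\!\left[e^{-(\beta - it)H} e^{-itH'}\right] / \mathrm{Tr}\,
e^{-\beta H}$$

is evaluated in closed form: both propagators have Gaussian (Mehler) position
kernels, so the trace is a $2n$-dimensional complex Gaussian integral, which
the symmetric block structure reduces to two $n \times n$ determinants and
one linear solve per time point. Two numerical choices matter:

* All hyperbolic ratios are written in $q = e^{-\beta\omega}$,
  $u = e^{-i\omega t}$, $p = e^{-i\omega' t}$, so nothing overflows at
  arbitrarily low temperature ($T = 0$ sets $q = 0$ exactly).
* $\chi$ is accumulated as a complex logarithm and the physical square root
  is taken by unwrapping the accumulated phase along the time grid, after
  stripping the fast mid-spectrum phase $e^{-i\bar E t}$,
  $\bar E = (E_\mathrm{vert} + E_{0\text{-}0})/2$. Per-factor branch
  tracking fails at the lineshape resonances $\sin(\omega' t) = 0$; global
  unwrapping does not. The automatically chosen time step is additionally
  multiplied by an irrational factor so that round-number frequency grids
  cannot place a sample exactly on a resonance (an exact hit raises an
  error suggesting a different step, rather than returning a wrong branch).

The spectrum is the Gaussian-windowed Fourier transform
$I(\nu) = \pi^{-1}\,\mathrm{Re}\int_0^\infty \chi(t)\,
e^{-\sigma_\mathrm{au}^2 t^2/2} e^{i\nu t}\,dt$, evaluated by FFT. $\chi$ is
computed only up to the time where the window has decayed below $10^{-8}$
(typically 1–3k points at a Nyquist-oversampled step), then zero-padded to
$\ge 2^{15}$ transform points — mathematically equivalent to transforming the
long grid, at a fraction of the cost — and spline-interpolated onto the
requested wavenumber grid. An aliasing guard errors if the damped signal has
not decayed at the end of the window.

**Prefactor convention.** Stick intensities store
$\nu_\mathrm{stick}\,|\mu|^2\, p_v\, |\langle v|v'\rangle|^2$; at convolution
time the frequency factor is re-weighted to the observation frequency,
$\varepsilon(\nu) = \nu |\mu|^2 \sum_i p_i\,\mathrm{FC}_i\,
G_\sigma(\nu - \nu_i)$, which is the standard absorption convention and makes
the broadened TI spectrum *identical* to the TD spectrum rather than equal
only to $O(\sigma/\nu)$. `prefactor = FALSE` drops the factor everywhere
(used by the sum-rule and first-moment invariants). Broadening accepts both
`sigma` and `hwhm` ($\mathrm{HWHM} = \sigma\sqrt{2\ln 2}$); every output
records which convention was used, because the two conventions (e.g. 250
cm⁻¹ standard deviation for ensemble spectra vs 150 cm⁻¹ HWHM for FC
spectra) are easy to conflate.

# Nuclear-ensemble route

`wigner_sample()` draws normal-coordinate displacements from per-mode
Gaussians with variance $\frac{1}{2\omega}\coth\frac{\omega}{2k_BT}$ (the
coordinate marginal of the harmonic Wigner distribution; $T = 0$ gives the
zero-point value $1/2\omega$, the default — whether a production Wigner run
samples 0 K or finite $T$ is a choice the caller makes explicitly).
`classical_sample()` uses the classical variance $k_BT/\omega^2$, an explicit
harmonic surrogate for sampling geometries from equilibrated classical MD —
no MD engine is re-implemented, and real QM/MM excitation tables enter
through the records CSV instead. For every mode with $\omega > k_BT$ the
classical ensemble is strictly narrower than the Wigner one.

Vertical excitations are evaluated analytically on the final surface,
$\Delta E(Q) = E_{00} + V'(Q) - V(Q)$, which is *linear* in $Q$ when
$J = I,\ \omega' = \omega$: the $\Delta E$ distribution is then exactly
Gaussian with mean $E_\mathrm{vert}$ and standard deviation
$\sqrt{\sum_i S_i \omega_i^2\,(2\omega_i \mathrm{var}\,Q_i)}$
($= \omega\sqrt{S}$ per mode at 0 K) — convolving with the phenomenological
Gaussian gives a unimodal band by construction. That is the structural
reason ensemble methods cannot show a vibronic progression, independent of
sampling quality. The spectrum is
$\varepsilon(\nu) = \sum_i f_i\, e^{-(\nu-\nu_i)^2/2\sigma^2}$ with
$f = \tfrac23 \Delta E |\mu|^2$ (a.u.) under Condon.

Line accumulation uses exact windowed evaluation up to 20k lines and, above
that, linear-split binning on a kernel-radius-extended grid followed by a
single kernel convolution (binning error $O((\Delta\nu/2\sigma)^2) \sim
10^{-5}$ at the defaults; lines outside the extended grid are dropped, never
clamped). `convergence_series()` subsets the records as nested prefixes of
one seeded permutation — frames accumulating along a trajectory — and
reports successive peak-normalized L1 distances (grid mean of $|a-b|$ for
unit-peak curves).

# Synthetic systems: what they emulate and what they do not

`make_displaced_oscillators()` is the canonical oracle (J = I, closed-form
everything). `make_duschinsky_rotated()` builds a *Cartesian* bundle pair
whose AH reconstruction reproduces the emitted $(J, K)$ to machine
precision; this required displacing the final minimum along the breathing
direction (uniform scaling about the COM), the one displacement family that
leaves the translation/rotation subspace unchanged. Generic displacements
rotate the Eckart frame slightly and make $J$ non-orthogonal at the
$10^{-4}$ level — real electronic-structure data behaves like that too, which
is why `build_map()` only warns (rather than errors) above $10^{-8}$
non-orthogonality and why the package performs no axis-switching correction
(a documented limitation).

`make_cy3_like()` fixes the six excited-state frequencies of a trimethine
cyanine (34.9, 354, 1136, 1378, 1415, 1525 cm⁻¹): a soft global
backbone-bending mode, a dimethyl-twisting mode, and a cluster of
polymethine C–C stretches. The Huang–Rhys profile is **illustrative, not
measured** — no displacements are established data for the real dye. The
default $S = (0.7, 0.05, 0.15, 0.15, 0.15, 0.15)$ was chosen once, a priori:
the dye family's 0–1/0–0 band ratio implies an effective one-mode $S
\approx 0.6$ for the $\sim$1300 cm⁻¹ cluster (split evenly over its four
members), and the soft bending mode is the strongest single contributor.
Ground-state frequencies default to the excited-state values. A green test
on this fixture therefore establishes that the *methods* behave as claimed
(progression resolved by FC, missed by ensembles, hot bands dominated by the
soft mode), not that any number matches the real dye's spectrum —
reproducing the real dye would need its unpublished Hessians and
electronic-structure energetics.

# Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| `max_quanta` | 10 | quanta/mode | captures $\ge 0.9999$ of a Poisson tail at $S \le 0.6$ |
| `max_simultaneous` | 4 | modes | excitation-class cap; combination bands beyond 4 modes are negligible at these $S$ |
| stick `floor` | 1e-8 | of max stick | output hygiene, not physics |
| `completeness_floor` | 0.99 | FC weight | warn threshold on truncation |
| `population_floor` | 1e-6 | probability | prunes initial thermal vectors; kept fraction reported, warn < 0.95 |
| FC broadening | 150 | cm⁻¹ HWHM | conventional satisfactory FC width |
| ensemble σ | 500 / 250 | cm⁻¹ | Wigner-style / MD-style smoothing |
| `oversample` | 2 | — | Nyquist margin keeping the unwrapped phase step ≪ π |
| peak `prominence_fraction` | 0.05 | of max | peak detection on broadened spectra only |
| BLA definition | mean abs consecutive difference | Å | reversal-invariant; odd/even-mean difference available behind a flag |

Fixed constants: $k_B = 0.695034800$ cm⁻¹/K, 1 hartree $= 219474.6313632$
cm⁻¹, 1 amu $= 1822.888486\,m_e$, 1 bohr $= 0.529177210903$ Å.

# Numerical choices, ties, degenerate inputs

* Mode-vector phases are fixed by making the largest-magnitude component
  positive; intensities are invariant (tested), but intermediate $(J, K)$
  comparisons are reproducible only because of this convention.
* Ranking ties in `assignment_report()` break toward lower transition
  energy, then lexicographic quanta; `lambda_max()` and plateau peaks break
  toward lower wavenumber.
* VH imaginary extrapolated frequencies are a hard error by default;
  `drop_imaginary = TRUE` removes those final modes plus the
  maximally-overlapping initial columns and re-orthogonalizes $J$ by SVD —
  explicitly approximate, logged, never silent.
* Linearity is detected by a principal moment of inertia below
  $10^{-10}$ amu Å² (then $3N-5$ modes); $T = 0$ bypasses all
  thermal ratios exactly rather than via a small-$T$ limit.
* Every sampling function takes an explicit integer seed; equal seeds give
  bitwise-equal output.

# Known limitations

* Harmonic surfaces only; no anharmonicity, no multiple conformers.
* Condon approximation only — no Herzberg–Teller intensity terms (for
  strongly allowed transitions their effect is negligible; for weak ones
  this package is the wrong tool).
* Gaussian broadening only (the window descriptor leaves a hook for
  Lorentzian/Voigt lifetimes).
* No Eckart/axis-switching rotation between arbitrarily oriented geometry
  pairs: both bundles must be expressed in the same Cartesian frame.
* The TI engine's cost grows combinatorially with simultaneously excited
  modes under large Duschinsky mixing (no vendor-style adaptive
  prescreening beyond the class/quanta/floor caps); the TD engine is the
  intended route for high temperature or many modes.
* Imaginary initial-state frequencies stop all engines by design — a
  non-minimum reference geometry is a modelling error, not a numerical one.
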