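---
title: "Modeling and quantifying cortical Rho/F-actin waves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling and quantifying cortical Rho/F-actin waves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cortexwave)
```

## The circuit and its assumptions

The cell cortex of large embryonic cells behaves as an excitable medium.
`cortexwave` implements the minimal circuit behind this excitability:
membrane-bound active Rho (`RT`) is produced from the inactive membrane
pool (`RD`) by a basal pathway (`k0`) and by GEF-mediated autocatalysis
whose strength scales with the nondimensional Ect2 level `alpha`; active
Rho stimulates assembly of dynamic cortical F-actin (`F`), which in turn
accelerates Rho inactivation with strength `k4 (1 + beta)`, where `beta`
is the nondimensional RGA-3/4 (GAP) level. The `1 +` in that factor is a
modeling assumption: F-actin exerts some inhibition on Rho even with no
GAP present, attributing part of the negative feedback to the polymer
itself or to other actin-binding proteins. Newly assembled F-actin
disassembles at rate `k10`, modulated by a stochastic field `W` standing
in for the many unmodeled regulators of actin turnover.

The full model carries a cytoplasmic inactive pool `RDc` exchanging with
the membrane; because the membrane shell is a vanishing fraction of the
cytoplasmic volume in these cells (volume ratio `eta` of order 1e-5 for a
1.2-mm oocyte — a quoted constant, not derived here), the cytoplasm is an
effectively infinite reservoir. `cortexwave` treats the reduced
(`eta -> 0`) three-field model as primary; the full model is retained for
the conservation and limit checks (`rhs_full`, `simulate_full`), since the
circuit neither produces nor degrades Rho and must conserve
`RT + RD + RDc/eta` exactly.

Units: seconds, micrometres; concentrations are nondimensional.

## Calibrated default parameters

The source supplement's parameter table was not available in the text this
package was built from, so the defaults in `cw_params()` were calibrated
de novo and then frozen, with two requirements taken from the described
phenomenology:

1. at `alpha = 1`, sweeping `beta` must produce exactly the succession
   *higher uniform -> wave instability -> oscillatory -> lower uniform*;
2. in the wave-instability window the most unstable mode should have a
   wavelength near 20 um and a period near 30 s, the scales of immature
   frog oocyte waves the original model was matched to.

The calibration searched kinetic constants randomly under a unique-root
constraint, then scanned diffusivities for a finite-wavenumber oscillatory
band preceding the Hopf band. Two honest caveats, also recorded in the
package's development ledger:

* the wave-instability band requires a substantial diffusivity contrast
  (`D_RT = 0.9`, `D_RD = 9` um²/s here). The biological statement that
  active Rho diffuses only mildly slower than inactive Rho is respected in
  sign (`D_RT <= D_RD` is enforced) but not in magnitude; with a mild
  contrast this kinetic set produces no wave band before the Hopf.
* just above the oscillatory domain the diagram has a small fold (three
  steady states): the oscillatory branch ends by colliding with the lower
  uniform state, which is the model's version of the waves "crashing"
  onto the quiescent state at high GAP. `uniform_steady_state()` reports
  all roots and flags as canonical the one reached by relaxation from
  small positive concentrations; `classify_regime()` classifies that root.

With the defaults, the refined regime boundaries sit at `beta` = 0.686
(higher | wave instability), 0.802 (wave instability | oscillatory) and
1.255 (oscillatory | lower).

## Linear stability analysis

`dispersion()` evaluates the eigenvalues of `J - q^2 diag(D)` on a
wavenumber grid (default: `q = 0` plus 200 log-spaced points spanning the
lattice-resolvable band), with `J` the analytic reaction Jacobian at the
canonical steady state. Classification rules:

* unstable at `q = 0` with complex eigenvalues -> **oscillatory**; when
  both `q = 0` and finite `q` are unstable the label is still oscillatory
  (matching the published ordering in which the oscillation domain follows
  the wave-instability domain);
* stable at `q = 0` but a growing finite-`q` mode with nonzero frequency
  -> **wave instability**;
* otherwise stable, split into **higher**/**lower** uniform by comparing
  `RT_ss` with the steady state at the midpoint of the unstable window of
  an internal coarse `beta` scan (zone 1 = high Rho, zone 2 = low Rho).
  When no instability exists anywhere (e.g. `alpha = 0`) the split falls
  back to the geometric mean of the extreme-`beta` states.

A stationary (real, Turing-like) finite-`q` instability falls outside the
four-regime vocabulary and raises an error carrying the dispersion data
rather than guessing a label.

## The stochastic simulator

Explicit forward Euler with the 5-point periodic Laplacian. The choice is
deliberate: the discrete Laplacian sums to zero on the torus, so the
full-model conservation identity holds exactly per step, and the scheme's
first-order convergence is verified by Richardson refinement in the test
suite. The default step is `min(0.2 dx^2/(4 D_max), 0.05/k_max)`; the hard
bound `dx^2/(4 D_max)` is enforced with an informative error. Fields are
floored at zero after each step; the noise field is *not* clipped (at the
default `sigma` the probability of `W < 0` is negligible).

The noise field is built by convolving white Gaussian noise with a
periodic Gaussian kernel of standard deviation `s`, then renormalizing
affinely to exact sample mean 1 and sample standard deviation `sigma` —
exact renormalization makes the moment invariants assertable rather than
approximate. With this construction the spatial autocorrelation is
Gaussian and e-folds at `2 s`; that relation is the package's operational
definition of the correlation length and is what the noise-statistics
acceptance check measures. The field is piecewise constant in time and
regenerated independently every `f` seconds.

Noise defaults (`sigma = 0.15`, `s = 2` um, `f = 10` s) were chosen, once,
so that the noisy model reproduces the described phenomenology: sustained
spiral turbulence on the boundary between the higher uniform state and the
wave-instability domain, flickers (localized, non-propagating flashes)
deeper in zone 1, and ordered wave trains inside the unstable window.
Weaker noise (`sigma <= 0.06`) fails to nucleate turbulence reliably on
the boundary; the calibration trade-offs are discussed under
*Limitations*.

All randomness flows from the R RNG: identical `(params, grid, seed, dt)`
give bit-identical trajectories.

## The wave-quantification pipeline

`summarize()` reproduces the classic box workflow: the movie is tiled into
`box_px` squares (default 15 px, ~4 um at 0.267 um/px; partial edge boxes
are dropped so all box statistics are identically distributed), each box
trace is analyzed, and means/SDs are pooled over boxes.

* **Period** — lag of the first local maximum of the mean-removed,
  lag-0-normalized autocorrelation. "First maximum" needs a noise-rejection
  rule: a candidate must rise at least 0.05 above the running minimum of
  the autocorrelation *and* exceed a white-noise floor of three standard
  errors (`3 sqrt(n - lag)/n`). Records shorter than three putative cycles
  report no period. The floor keeps pure-noise traces (flickers, the
  quiescent state) from contaminating pooled periods.
* **Temporal width** — mean FWHM over detected peaks (prominence at least
  10% of the trace range), measured at half-prominence height with linear
  interpolation of the crossings; consistent with common peak-measurement
  conventions, and exact on rectangles, triangles and raised sinusoids.
* **Relative amplitude** — mean over sliding windows (length: the box's
  own period, else the movie-wide median period) of `max - min`, divided
  by the trace minimum. The fallback window matters: giving non-oscillating
  boxes the whole record as a window would hand them the movie's largest
  excursion and systematically inflate the amplitude of flicker states.
  `amplitude_normalize = "none"` gives the raw windowed excursion (the
  older workflow's definition), which is the right variant for comparing
  amplitudes across conditions whose baselines differ.
* **Shift** — cross-correlation lag nearest zero among prominent maxima,
  positive when the second channel trails the first. Note the aliasing
  caveat: a delay longer than half the oscillation period is reported
  modulo the period, so follower delays should be measured on records with
  period more than twice the expected lag.

`kymograph()` reslices the movie along a 1-px row or column without
interpolation.

## Phase reconstruction and defects

Per-pixel phase is the analytic-signal angle of the mean-removed trace,
band-passed to 0.5-2 times the dominant frequency (the pooled spectral
peak). Pixels whose intensity range is below 10% of the movie's median
range are masked — phase is meaningless on quiescent cortex. The original
study defers its phase method to earlier work; equivalence is claimed only
at the level of defect counts and charges, not pixelwise phase values.

Defects are plaquette winding numbers: wrapped phase differences summed
around each 2x2 cell, divided by 2 pi. The sign convention is fixed and
stated rather than guessed from figure orientation: positive charge means
phase increasing along the counterclockwise loop in array coordinates with
the row index increasing downward. On a periodic frame the total winding
is identically zero — a topological identity the acceptance suite asserts
on every simulated frame. Tracking is greedy nearest-neighbour linking
(same charge, bounded step); track births and deaths in the same frame are
resolved into opposite-charge creation/annihilation pairs within a pairing
radius, and anything unmatched is flagged rather than silently paired.

## Synthetic movies and what a green test establishes

Every generator returns its ground truth: analytic period, wavelength,
speed, FWHM (the raised-cosine profile with duty cycle `d` has FWHM
`d T/2` exactly), amplitude ratio, follower lag, spiral core position and
charge, or the full pulse event list. The regression suite closes the
loop: generator -> pipeline -> recovered truth within stated tolerances.

The generators emulate the *statistical structure* of cortical-wave
movies — periodicity, propagation, spiral topology, lagged followers,
Poisson flickers — at the classic imaging scale (0.267 um/px, 4-s frames).
They do not mimic yolk autofluorescence, photobleaching, optical
sectioning, or cortical drift; a green metric-recovery test therefore
establishes correctness of the measurement code, not robustness to every
imaging artifact. Motion correction and manual wave segmentation are out
of scope.

## Numerical choices and degenerate inputs

* Steady-state roots: `RD_ss = k5/k6` always; `F_ss` is a closed form of
  `RT_ss`, so root finding reduces to a sign-change scan of one scalar
  function on a log grid (4000 points over `RT` in `[1e-8, 1e4]`) with
  bracketed polishing to 1e-15; residuals are verified below 1e-10.
* The relaxation that selects the canonical root runs the compiled
  integrator on a tiny uniform lattice (diffusion is inert on a uniform
  field), and only when several roots exist.
* Regime boundaries are refined by geometric bisection to relative 1e-3.
* Flat traces: `normalize01` and `xcorr_shift` error on constant input;
  `period_autocorr`/`temporal_width` return `NA` ("absent" is a value);
  `relative_amplitude` errors on nonpositive minima in ratio mode.
* Aliasing: generators reject wavelengths below `2 dx`.
* TIFF: a deliberately minimal, self-contained baseline reader/writer
  (uncompressed grayscale, 8/16-bit unsigned and 32/64-bit float, either
  endianness, one file per channel) because no R TIFF package is available
  in the target environment; it was cross-validated against Python's
  `tifffile` in both directions during development. Calibration (`dt`,
  `dx`, channel) travels in the ImageDescription tag.

## Acceptance-measurement conventions

Two operationalizations deserve explicit statement:

* **Period vs dispersion prediction.** The simulated period is compared
  with `2 pi / Im lambda(q*)` inside the exponential-growth window of a
  noise-free run seeded with a small perturbation (pattern amplitude
  between 2% and 50% of its final value), where the linearization is
  valid; there the agreement is within ~10%. Fully saturated nonlinear
  waves oscillate 20-30% slower than the marginal mode — a real physical
  renormalization, reported in the README example, not a measurement
  error.
* **Noise neutrality.** Multiplicative disassembly noise biases the mean
  F-actin level upward by order `sigma^2` (Jensen: `E[1/W] > 1/E[W]`), so
  ensemble means are tested against an `O(sigma^2)` bound plus Monte-Carlo
  error, with the bias required to shrink as `sigma` decreases; exact
  equality with the deterministic steady state would be the wrong
  assertion.

## Known limitations

* The calibrated defaults are a stand-in for the original supplement's
  table; quantities tied to absolute concentrations are comparable only in
  scaled form. The regime succession, wave scales and phenomenology are
  calibrated; rate constants individually are not identifiable from that.
* With noise strong enough to nucleate boundary turbulence, the flicker
  state at `beta = 0` already has substantial temporal amplitude, so the
  noisy amplitude profile rises modestly (rather than sharply) from
  `beta = 0` before declining; the sharp onset is crisp only in the
  deterministic limit, where stable states hold zero sustained amplitude.
* No 3D or curved-cortex geometry, no implicit or spectral integrators,
  no parameter fitting to experimental movies, and no automated scoring of
  the 10 morphological features (scored by eye in the source study; this
  package only encodes the vocabulary and the histogram arithmetic).
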