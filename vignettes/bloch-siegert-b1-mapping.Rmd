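---
title: "Phase-based B1+ mapping for multi-peak 31P spectroscopy: models, design choices, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-based B1+ mapping for multi-peak 31P spectroscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsb1map)
```

## The problem

Quantitative phosphorus spectroscopy with surface coils needs a per-voxel
measurement of the transmit field: the flip angle (and hence the
partial-saturation correction) depends on the local radiofrequency
amplitude, which falls off steeply with distance from a loop coil.
Magnitude-based flip-angle methods (variable flip angle, multi-TR,
dual-TR) need long repetition times or known metabolite T1 values --
both problematic for nuclei with T1 of several seconds and exchange-
sensitive resonances such as phosphocreatine. `bsb1map` implements the
phase-based alternative: an off-resonance "sensitizing" pulse inserted
between excitation and readout produces a transient Bloch-Siegert shift,
and the accumulated phase encodes the square of the local transmit
amplitude, independently of TR and T1.

Throughout, the transmit amplitude is quoted as a nutation frequency
$\gamma B_1^+$ in Hz (for $^{31}$P, $\gamma = 17.235$ MHz/T).

## Phase model

For a unit-peak-normalized pulse envelope $f(t)$ with peak amplitude
$\gamma B_1^+$ (Hz) at frequency offset $\omega_{RF}$ (Hz) from a spectral
peak, the linear-regime phase accumulated by that peak is

$$\phi_{BS} = \frac{\pi\,(\gamma B_1^+)^2\,\tilde B}{\omega_{RF}},
  \qquad \tilde B = \int |f(t)|^2\,dt ,$$

with the sign of $\omega_{RF}$. $\tilde B$ (seconds) is computed by
trapezoidal quadrature on the sampled envelope
(`normalized_squared_integral()`); for the optimized sensitizing pulse
below it is $1.3197\times10^{-3}$ s, which reproduces the worked-example
inversions (55.6° at 2000 Hz → 484 Hz, 86.9° → 605 Hz) and the wrap
limits (873 Hz at a $\pi$ phase difference, 1231 Hz after one manual
unwrap).

Four acquisition strategies turn fitted peak phases into $\gamma B_1^+$:

* **A** -- two acquisitions with the pulse at $\pm\omega$ around one peak;
  $\gamma B_1^+ = \sqrt{\Delta\phi\,\omega/(2\pi\tilde B)}$.
* **B′** -- one sensitized and one unsensitized acquisition, single peak.
* **B″** -- the on/off pair using every peak, combined by inverse-variance
  weights $\omega_i^{-2}$ (equal phase variances assumed).
* **C** -- a single sensitized acquisition, using the phase differences of
  every peak pair, combined with weights
  $(\omega_j^{-1}-\omega_i^{-1})^2$. This equals the least-squares slope
  of phase against $1/\omega$ with a free intercept, so a common receiver
  phase cancels exactly.

The published determination equations for B″ and C are typographically
garbled in their source; the maximum-likelihood reconstructions above are
validated by exact single-peak reductions and Monte Carlo cross-checks.
A negative combined $(\gamma B_1^+)^2$ is returned as an invalid estimate
with reason `negative_phase_diff`, never as a complex number.

## Sensitizing pulse design

The sensitizing pulse is a Fermi envelope
$f(t) = [1 + e^{(|t|-T_0)/a}]^{-1}$ on $[-T_P/2, T_P/2]$. Its passband
must not touch the spectral peaks, which for the dual-acquisition
protocol sit 1500-2500 Hz from the pulse. Direct excitation is scored by
the stop-band metric: the windowed mean of $|M_{xy}|^2$ after the pulse
from thermal equilibrium, normalized to the 1-Hz-spacing convention
(1001 offsets over 1500-2500 Hz divided by 1000; coarser grids are
rescaled by `1001/n`).

`optimize_fermi()` searches $T_P$ = 1-10 ms (0.5 ms steps), $T_0$ =
0.1-0.5 $T_P$ (0.05 $T_P$ steps), $a$ = 0.01-0.3 $T_P$ (0.001 $T_P$
steps) at peak amplitudes 100-1000 Hz, aggregates across amplitudes by
the worst case (a conservative design choice; mean aggregation is
available), and returns the shortest feasible duration with its argmin
shape. The feasibility threshold is exposed as configuration because its
printed scale (0.01 vs 0.01%) is ambiguous in the source material; the
argmin is threshold-free. Our search reproduces $T_P = 3.5$ ms and
$T_0 = 0.875$ ms exactly; the transition width lands at $a = 0.2065$ ms,
five grid cells (8%) from the published 0.224 ms, and is stable under
integration-step refinement (5 µs → 1 µs), offset-sampling refinement
(101 → 1001 points), and every aggregation variant we tried. The metric
landscape between those two cells is shallow (~25%), so we report our
argmin rather than tuning integration details to match.

Units: the transition width is interpreted as milliseconds wherever the
source prints "a = 0.224" without units, consistent with its Methods
text.

## Bloch simulator

`simulate_pulse()` integrates the relaxation-free Bloch equation by
piecewise-constant ("hard pulse") rotations in the pulse carrier frame,
exact for sampled envelopes; envelope samples are grid-point values and
the integrator uses interval midpoints, so a rectangular pulse of 250 Hz
for 1 ms flips exactly 90°. A resolution guard rejects steps that rotate
more than 36° per sample. Sign convention: a spin at positive offset from
the carrier accrues positive free-precession phase, hence a positive
Bloch-Siegert phase at positive $\omega_{RF}$; with `derotate = TRUE`
(default) the trivial free-precession phase is removed so a zero-
amplitude pulse is the identity. The integrator agrees with an
independent adaptive ODE solution to $3\times10^{-6}$ rad and with the
linear phase model to 0.4% at $\omega_{RF}/\gamma B_1^+ = 7$.

One published figure we cannot reproduce: a 19% estimator error from
direct excitation for Method C with peaks at $\pm 975$ Hz and
$\gamma B_1^+ = 277$ Hz. Our simulation (cross-checked by the ODE
oracle) gives +0.9%: the phase perturbation at $\pm975$ Hz is ~0.006 rad
against a 0.326 rad signal, and the residual-Mz contribution is even in
the offset, so it cancels in the pair difference at any excitation flip
angle (verified 20-90°). The corresponding acceptance check asserts the
published value and fails; the analysis lives with the test rather than
being hidden.

## Error analysis

`propagate_error()` applies first-order propagation with numerically
evaluated gradients -- one code path for all strategies, checked against
closed forms for A and B′ and a finite-difference oracle for C.
`mc_evaluate()` draws per-peak phases from Normal distributions centered
on the linear-model phases (default $10^6$ draws, seeded, invalid draws
excluded and counted) and reports bias and coefficient of variation.

Two subtleties worth stating explicitly:

* First-order propagation is exact only as $\Delta\phi/\phi_{BS}\to 0$;
  at the phase noise of a realistic in vivo acquisition (~0.045 rad) the
  square-root nonlinearity already shifts Monte Carlo SDs by ~2%.
  Agreement between the two routes is therefore asserted at
  $\Delta\phi = 0.02$ rad, where the residual is below the Monte Carlo
  resolution of the test.
* At matched total scan time, Method C with the pulse midway between two
  peaks is $\sqrt2$ more precise than Method A (its single acquisition
  receives both scans' averages), which we reproduce. The analogous
  published claim that B′ is only $\sqrt2$ worse than A is internally
  inconsistent with exact propagation, which gives a factor 2 at equal
  per-phase noise (the published bias columns, which scale as the square,
  show the matching factor ~4). We implement the self-consistent factor
  2; the acceptance check asserting $\sqrt2$ fails and says so.

Phase noise levels are derived from first principles rather than assumed:
`crlb_phase()` builds the Fisher information of the damped
complex-exponential FID model (amplitude, frequency, damping, phase per
peak group; white complex Gaussian noise, per-channel SD $\sigma$, FIM
$= \mathrm{Re}(J^\dagger J)/\sigma^2$) and returns the phase CRLB divided
by $\sqrt{N_\mathrm{scans}}$. The noise factor convention was fixed by
simulation: the empirical SD of fitted phases attains this bound at
ratio 1.04 over 400 realizations. Exact reproduction of the published
strategy-comparison table is out of reach by design: its phase-noise
inputs derive from unpublished lineshape statistics, so the table is
bracketed by properties (round trips, scaling laws, MC-vs-analytic
agreement) instead of cell values.

## Synthetic spectra and reference methods

`default_31p_model()` places PCr at 0 Hz and γ/α/β-ATP at -300, -900,
-1950 Hz (the 7T layout), with ATP doublet/doublet/triplet multiplets at
J = 16.3 Hz and binomial amplitude ratios -- literature conventions, not
values from the source paper, and configurable. Default amplitudes give
PCr/ATP = 2 and 20 Hz Lorentzian linewidths, representative of 7T
cardiac spectra. Noise is calibrated by `noise_sd_for_snr()` so the
tallest magnitude-spectrum peak over the spectral noise SD hits the
stated amplitude SNRs (18/31/44), verified empirically to 5%.

`fit_amares()` performs time-domain Levenberg-Marquardt fitting with the
multiplet ratios and couplings fixed by parameterization (four free
parameters per group), returning CRLBs from the Fisher matrix at the
solution. The reference flip-angle methods invert the partial saturation
equation
$S = M_0 \sin\theta\,(1-E_1)/(1-E_1\cos\theta)$, $E_1 = e^{-TR/T_1}$:
`fit_multi_tr()` (profile-likelihood over $M_0$, eight-TR phantom
protocol, T1 = 8.57 s), `fit_dual_tr()` (bracketed root finding on the
signal ratio, literature T1), and `fit_multi_fa()` (fully relaxed
$\sin\alpha$ sweep over transmit voltage, 10-200 V through the signal
null, grid-then-refine to handle the multimodal objective). Magnitude
data are treated as noise-free sinusoids (no Rician floor correction),
appropriate at the SNR of the validation protocols.

## Phantom and coil simulation

`loop_field()` evaluates the Biot-Savart integral of a circular loop by
polygon segmentation (≥360 segments; on-axis agreement with the closed
form to $10^{-6}$ after refinement), calibrated by quoting
$\gamma B_1^+$ at a named reference point. By reciprocity the same
magnitude serves as the receive weight of the transmit-receive loop.
Coordinates are right-handed with the coil plane at z = 0 and the axis
along +z; CSI grids place their first matrix dimension along the axis,
with voxel centers at cell centers.

`simulate_csi()` builds per-voxel FIDs for box-compartment scenes: each
voxel is subdivided into isochromats seeing the local field; the model
applies the local excitation flip, steady-state saturation, the
linear-model Bloch-Siegert phase of each arm for each peak, and receive
weighting; acquisition weighting (Hanning-shaped averages, k = 0 count
rounded up to ≥1) enters in `"psf"` mode as a separable k-space window.
With `subgrid = 1` ("ideal voxel" -- the sense in which per-voxel map
values are displayed) the full two-arm pipeline inverts back to the
ground-truth field to machine precision; with intravoxel subdivision the
recovered values exceed the receive-weighted mean by up to ~6% in
steep-gradient voxels, because the phase encodes $(\gamma B_1^+)^2$ --
the squared-field weighting the method's own limitations analysis bounds
at 7% for a cardiac voxel.

`intravoxel_analysis()` quantifies that effect directly: for a
15 × 30 × 25 mm voxel 10 cm on-axis (the cardiac protocol), 64³
isochromats (scaled down from 512³; 32³ agrees to <1%), Method-A phase
$2\phi_{BS}$ per isochromat and field-proportional weights, the
summed-signal value deviates from the receive-weighted mean by ≤0.6%
across center amplitudes up to 1000 Hz, and phase cancellation costs 33%
of the SNR at 1000 Hz. The published figure for the same narrative is
50%; our value is converged and matches the analytic axial phase-spread
estimate, and the gap plausibly reflects the unstated inclusion of the
CSI point-spread (wider than the box voxel) or lateral placement -- the
acceptance check asserts the published number and reports the miss.

## Voxel masking and outputs

`mask_voxels()` applies the protocol exclusion rules -- negative phase
difference (low field or uncorrected wrap), phase CRLB above threshold
(20° phantom, 10° muscle, 15° cardiac defaults), outside a geometry
mask -- while retaining every value with its exclusion reason. Wraps are
undone explicitly per voxel with `unwrap_phase_diff()` (k = 1 extends
the range by $\sqrt2$), mirroring manual unwrapping practice; no
automatic spatial unwrapping is attempted. Maps export to NIfTI with a
JSON sidecar (method, $\omega_{RF}$, $\tilde B$, thresholds, exclusion
counts); FID arrays use a documented plain-text container (JSON header
plus long-format CSV) chosen for a dependency-free, diff-friendly
interchange; pulses and prior-knowledge tables are CSV.

## What the synthetic data do and do not show

The generators emulate multi-peak Lorentzian FIDs with white complex
Gaussian noise, linear-model Bloch-Siegert phases, steady-state
saturation, and a reciprocal single-loop field. They do not emulate B0
inhomogeneity, eddy currents or baseline distortions, non-Lorentzian
lineshapes, chemical exchange during the pulse, motion, or
subject-dependent dielectric field distortion. Passing tests therefore
demonstrate the internal consistency and statistical calibration of the
estimators under the stated model, not robustness to everything an
in vivo acquisition can do.

## Problem sizes

The test suite and the acceptance script use: 1 µs pulse sampling for
synthesis and 5 µs for the design search; a 101-point stop-band window;
the full 9 × 291 (T0, a) slice at TP = 3.5 ms over ten amplitudes;
$10^5$-$10^6$ Monte Carlo draws; 100-120 noise realizations for CRLB
attainment; 64³ isochromats for the intravoxel analysis; and a 16 × 8 × 8
uniform-phantom CSI simulation. These sizes were chosen so every
quantity is converged (refinement checks are part of the suite) while a
complete run stays interactive.
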