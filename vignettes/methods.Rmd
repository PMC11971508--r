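---
title: "Models, corrections and design choices in vfat1"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, corrections and design choices in vfat1}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the signal models, the correction chain, the
tunable parameters with their defaults, the numerical choices, and the
places where the design was genuinely open and a choice had to be
made. All units follow one convention at the API surface: relaxation
times and TR/TE/TI in milliseconds, frequencies in Hz, gradients in
Hz/mm, angles in degrees (radians are used internally).

## Signal models

**SPGR steady state.** `spgr_signal()` is the Ernst steady state
S = M0 sin a (1 − E1)/(1 − E1 cos a) with E1 = exp(−TR/T1). It assumes
perfect spoiling: all transverse magnetization is destroyed each TR.
The test suite checks it against an independent oracle, the plain
longitudinal Bloch recursion iterated to convergence.

**Incomplete spoiling (EPG).** RF-plus-gradient spoiling does not
realise that assumption exactly: transverse coherences survive across
TRs and make the true steady state deviate from the Ernst value by up
to several percent at liver T2. `epg_spgr_steady_state()` simulates
the sequence in the configuration-state basis with quadratic RF phase
φ_n = φ_inc·n(n−1)/2 and a unit gradient shift per TR, and
`build_spoiling_correction()` tabulates c(α, T1) = S_EPG/S_ideal on a
grid (default α ∈ [1°, 25°] in 2° steps, T1 ∈ [300, 2000] ms in
100 ms steps) that is bilinearly interpolated inside the fit;
off-grid queries are clamped with a warning. Defaults that the
protocol does not pin down and are therefore configurable:

* `phi_inc_deg = 50` — the vendor-typical RF-spoiling increment;
* `t2` of the correction — 45 ms for the agar phantom (its stated
  value), 34 ms as a literature liver T2 at 3 T for in-vivo work;
* `k_max = 60` retained dephasing orders, convergence tolerance 1e−8
  on the demodulated F0, diffusion ignored.

The correction is applied one-pass — c is interpolated in T1 at each
optimizer iterate rather than iterating fit↔table to a joint fixed
point; the table is smooth enough that the difference is far below
the fit tolerance. The EPG engine is validated against a brute-force
isochromat simulation (2000 spins with quadratic RF phase and uniform
intra-voxel gradient dephasing) to better than 0.2%.

**Fat.** `fat_model()` provides a six-peak liver triglyceride
spectrum (Hamilton-type relative amplitudes at −3.80, −3.40, −2.60,
−1.94, −0.50 and +0.60 ppm relative to water) and a single-peak
variant at −3.4 ppm. The fat pool's T1 defaults to 400 ms at 3 T, a
mid-range literature value for adipose triglyceride. These choices
matter only for simulation studies — the in-vivo pipeline consumes
vendor water images — and both are configurable.

## The correction chain

`run_pipeline()` executes, in order: B0 mapping → EPI distortion
correction → B1+ mapping → resampling to the SPGR grid → Dixon
separation → spoiling-corrected NLLS fit. Order matters: the B1+ EPI
pair must be unwarped before the per-voxel double-angle ratio is
taken, and the B1+ map must be on the SPGR grid before nominal angles
are scaled.

**B0.** Off-resonance is the phase of echo2·conj(echo1) over
2π·ΔTE. Phase is unwrapped per slice with a quality-guided flood
fill (quality = magnitude product); the algorithm was an open choice
since only the need for unwrapping at liver edges is documented.
Unwrapping determines phase only up to a global 2π multiple, which is
anchored by the shim convention: the FOV-median off-resonance lies
within ±1/(2ΔTE). Voxels below 5× the background noise SD (Rayleigh
estimate from the darkest decile) are masked; the factor is
configurable.

**EPI unwarp.** The pixel shift along the phase encode is
f·esp·N_pe; resampling is 1-D linear interpolation per column. The
native implementation replaces an external distortion-correction tool
with the same first-order pixel-shift model.

**2D DAM B1+.** The naive double-angle inversion
α = acos(S(2a)/2S(a)) is exact only for a non-selective excitation.
For slice-selective EPI the package Bloch-simulates the excitation
profile α(z) for both nominal angles over a grid of candidate B1+
factors and integrates sin(α(z)) through slice with a complex weight
w(z) = exp(i·2π·g·z·TE) encoding a through-slice B0 gradient g,
estimated per voxel by central finite differences across neighbouring
slice centers (one-sided at the ends, constant within a slice). The
resulting monotone ratio lookup R(b1; g) is inverted per voxel. The
dephasing weight is a deliberately simple, documented model of
through-slice dropout — an independent choice, since the original
estimator it emulates is not described in detail in the protocol
sources available here. The lookup spans b1 ∈ [0.3, 1.3] by default:
beyond ≈1.35 the 130° branch folds back (sin passes its maximum) and
R(b1) stops being monotone, so the table refuses to build there and
measured ratios outside the tabulated range are masked rather than
extrapolated.

**Excitation pulse.** The vendor's pulse shape is unpublished; the
default is a Hanning-windowed sinc with time-bandwidth product 8,
1 ms duration, 256 hard-pulse segments, with the half-area rephasing
lobe applied analytically. The slice-select gradient is scaled so the
pulse bandwidth maps onto the nominal thickness; the simulated
small-angle FWHM then reproduces the nominal slice width, and the
small-angle profile matches the scaled Fourier transform of the
envelope to well under 2%. The descriptor is a configurable object,
so a measured vendor pulse can be substituted.

**Dixon.** Complex inputs are combined after removal of the
B0-induced phase at each echo (W, F = half sum/difference
magnitudes); magnitude-only inputs use the in/opposed-phase sum and
difference under the water-dominant assumption, with fat-dominant
(F > W) voxels flagged rather than silently swapped. Both paths exist
because whether the vendor water images derive from complex or
magnitude processing is not documented; the digital phantom exercises
the complex path.

**VFA fit.** Per voxel, Levenberg–Marquardt (via `minpack.lm`) on
(T1, M0) with bounds T1 ∈ [100, 5000] ms, tolerances 1e−8, initialised
from the closed-form two-point DESPOT1 linearisation. Repeated flip
angles enter as separate observations (four points, two residual
degrees of freedom) rather than being pre-averaged. Voxels with a
masked B1+ factor or sub-threshold signal are excluded and counted in
the stage report.

## MOLLI forward model

`simulate_molli()` is a time-stepped Bloch simulation of the
5(1)1(1)1 scheme (TIs 100, 100+RR, …, 100+4RR, 180, 260 ms at
RR ≈ 1000 ms; single-shot bSSFP readouts at 35°, TR 2.6 ms, 72
phase-encode lines). Modelling choices, each configurable:

* inversion is instantaneous with efficiency 0.96 (the adiabatic
  vendor pulse is private);
* the readout block runs a −α/2 catalyzation, a TR/2 gap, then
  alternating ±α pulses; the k-space-center excitation falls exactly
  at the nominal TI, and the recorded sample is the pooled transverse
  magnetization at that pulse;
* fat peaks are parallel pools with their own frequencies and T1,
  summed at PDFF weight;
* iron enters as exp(−TE/T2*) echo decay plus a Lorentzian broadening
  term R2' = 1/T2* − 1/T2 added to the transverse decay during the
  readout;
* magnetization transfer is a two-pool longitudinal model
  (bound-pool fraction 0.07, exchange 40 s⁻¹, 2% bound-pool
  saturation per readout pulse) — literature-scale liver values, not
  the unpublished parameters of any specific product simulator.

`fit_molli()` fits S(TI) = A − B·exp(−TI/T1*) to the five samples of
the first inversion group (the protocol's choice; a flag includes all
seven) and applies the Deichmann–Haase correction
T1 = T1*·(B/A − 1). The no-readout sanity limit deserves a note: as
the readout angle goes to zero the excitation perturbation vanishes,
but transverse magnetization excited by *previous* readout pulses
still carries a T2-weighted memory into each sample. The package
therefore defines the no-readout limit as vanishing flip *and*
quenched transverse carry-over (a short readout T2 in the test), in
which case the samples fall exactly on 1 − 2·exp(−TI/T1) and the
fitted T1 is exact. Because the vendor inversion pulse, MT parameters
and fat model behind any specific published simulator are
unavailable, fixed per-subject simulated-MOLLI values should be read
as plausibility anchors rather than bit-exact targets.

## ROI statistics

The subject summary weights every ROI by w = n_pixels/sd², the
inverse squared standard error of its mean. Two printed denominators
differ deliberately and are implemented exactly as defined: the
pixel-level weighted mean and SD divide by Σ n·w, while the ROI-level
dispersion (homogeneity) divides by Σ w; both are verified against
independently coded brute-force sums to 1e−12. ROIs with zero SD —
possible on noiseless synthetic data, never on scanner data — get
their weight capped at the 99th percentile of the finite weights
(equal weights if none exist), with a warning.

The residual B1+ sensitivity is an OLS regression of ROI-mean T1 on
ROI-mean B1+; the T1 variation is slope × ΔB1+ with a CI from the
slope standard error. The CI's t quantile uses n − 2 degrees of
freedom — the standard d.o.f. for a two-parameter line — although one
printed formulation of this interval elsewhere quotes two degrees of
freedom; the `df` argument exposes the alternative rather than
resolving the ambiguity silently. The correlation test also uses
n − 2. The repeatability coefficient comes from a one-way ANOVA with
subjects as groups: σ_within² is the residual mean square (equal, for
the balanced two-run case, to mean((a−b)²)/2 — asserted as an
algebraic identity in the tests) and RC = 1.96·√2·σ_within.
Bland–Altman limits of agreement are reported as the half-width
1.96·SD of the differences. All tests are two-sided at α = 0.05.

## The digital phantom

`phantom_spec()` describes two objects: a 14-vial layout (T1 367 to
1699 ms in ≈100 ms steps, T2 45 ms, no fat) embedded in a
signal-bearing gel body (T1 1000 ms) so that the field-mapping
acquisitions see signal everywhere, and a uniform abdomen-like
ellipse (T1 800 ms, T2 34 ms). The transmit field is a smooth 2D
Gaussian depression whose depth sets the B1+ range (default
[0.8, 1.05]; [0.6, 1.1] reproduces a strongly shaded body coil); B0
is a smooth in-plane ramp (default 60 Hz peak-to-peak) plus an
optional through-slice gradient. Noise is Rician: complex Gaussian
added before the modulus, with the SNR defined on the peak
15°-flip-angle vial signal. Every realization is fixed by the seed.

The default geometry is deliberately small — a 64×64×4 SPGR grid with
a half-resolution, 10 mm-spaced EPI/B0 grid — so that the end-to-end
closed loop (generation → full pipeline → ROI statistics) runs in
tens of seconds; the full-size protocol matrix is reachable through
`dim` and `spacing` for anyone with patience. The EPI and B0 slices
extend axially past the thin SPGR slab by clamping the object along
z, as a real phantom or abdomen extends past the imaging volume.

What the phantom does *not* emulate — and hence what a passing
end-to-end test does not demonstrate about scanner data — includes:
respiratory motion and breath-hold misregistration between flip
angles, receive-field (B1−) variation, partial-volume mixtures at
vessel boundaries, eddy-current and gradient-nonlinearity effects,
vendor reconstruction filters, and structured (non-Rician) noise from
parallel imaging. The phantom validates the mathematics of the
correction chain, not its robustness to physiology.

## Numerical conventions and degenerate inputs

Voxel indices are 0-based half-open in the geometry convention
(voxel (0,0,0) sits at the origin of the axis-aligned affine);
resampling is trilinear in physical coordinates with conservative
mask propagation (a target voxel is valid only if every contributing
source voxel is), complemented by an explicit, bounded
`fill_na_nearest()` hole fill for smooth field maps so that one-voxel
mask losses do not eat whole regions after resampling. Degenerate
inputs follow a consistent policy: out-of-domain double-angle ratios,
sub-threshold magnitudes and non-converged fits are masked/flagged
and *counted* in the stage report, never silently imputed. IR
magnitude fits restore polarity by trying the sign flips around the
minimum-signal TI and keeping the lowest residual.

## Known limitations

The spoiling correction applies to the water signal only; fat keeps
the ideal-spoiling model inside simulations. PDFF itself is not
estimated (two echoes cannot support a T2*-corrected multi-peak fit);
fat fraction and T2* enter as per-subject scalars where needed. Iron
is not corrected in the VFA T1 itself. The two-echo Dixon water
channel retains a small fat-model-dependent T1 bias at high fat
fraction; the acceptance machinery quantifies it for both bundled
fat spectra. Registration between breath-holds is out of scope, as
is any vendor-specific reconstruction.
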