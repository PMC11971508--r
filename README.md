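# vfat1 — accurate 3D variable-flip-angle liver T1 mapping

`vfat1` implements a complete quantitative-MRI processing chain for
accurate and precise 3D liver T1 mapping at 3 T from variable flip
angle (VFA) spoiled gradient-recalled echo (SPGR) acquisitions, for MR
physicists and image-analysis developers who want a tested, scriptable
reference implementation of every correction the method needs.

## The problem and the method

The ideally spoiled SPGR steady state follows the Ernst equation

    S(α) = M0 · sin α · (1 − E1) / (1 − E1 · cos α),   E1 = exp(−TR/T1),

so T1 can be estimated from signals at two or more flip angles (the
protocol uses nominal 2°, 2°, 15°, 15° at TR = 4.1 ms). In practice
four confounds bias the estimate, and the package implements a
correction for each:

- **B1+ inhomogeneity.** The achieved flip angle differs from the
  nominal one by the transmit factor `b1`; in the small-angle regime
  the fractional T1 error is `b1² − 1` (−64 % at `b1 = 0.6`). The
  factor is mapped with the double-angle method (DAM): a long-TR 3D
  pair (gold standard) and a fast 2D GRE-EPI pair at 65°/130° with
  Bloch-simulated slice-profile and through-slice-B0-gradient
  corrections, inverted through a monotone signal-ratio lookup.
- **B0 off-resonance.** A dual-echo GRE phase map
  (ΔTE = 2.39 ms) with quality-guided 2D unwrapping feeds EPI
  distortion correction (pixel shift = f·esp·N_pe along the phase
  encode) and the through-slice dephasing model of the B1+ map.
- **Incomplete spoiling.** RF-spoiled SPGR does not reach the Ernst
  steady state exactly; an extended-phase-graph (EPG) simulation
  tabulates the correction factor c(α, T1) = S_EPG/S_ideal that
  multiplies the model inside the fit.
- **Fat.** Two-echo Dixon separation (opposed/in-phase TEs 1.23 and
  2.46 ms) isolates the water signal before fitting; a configurable
  single- or six-peak liver fat spectrum supports simulation studies.

The per-voxel T1 is then a Levenberg–Marquardt NLLS fit of
c(α,T1)·S(α) with α = b1·α_nominal. A Bloch-simulated MOLLI 5(1)1(1)1
forward model (with off-resonance, T2*, fat and magnetization-transfer
terms and the Deichmann–Haase correction T1 = T1*·(B/A − 1)) converts
VFA water T1 into the value a MOLLI scan would report, and an ROI
statistics layer provides the weighted subject summaries, residual
T1-vs-B1+ regression, one-way-ANOVA repeatability coefficient
(RC = 1.96·√2·σ_within) and Bland–Altman metrics used to validate such
maps. A seeded digital phantom (14-vial T1 phantom or abdomen-like
slab, smooth B1+/B0 fields, Rician noise) generates every acquisition
the pipeline consumes, together with ground truth.

## Worked example

```r
library(vfat1)

spec <- phantom_spec(layout = "vials", snr = 100, seed = 1)
acq  <- generate_acquisitions(spec)                 # EPG-realistic
corr <- build_spoiling_correction(t2 = 45, tr = 4.1)
res  <- run_pipeline(acq, correction = corr)
pa   <- phantom_accuracy(acq, res$t1)
cat(sprintf("slope: %.3f  intercept: %.1f ms  wRMSNE: %.2f%%\n",
            pa$slope, pa$intercept, 100 * pa$wrmsne))
```

```
b0map: 895 voxels masked
unwarp: 0 voxels flagged
b1map: 938 voxels masked
resample: 3488 target voxels without B1 coverage
fit: 11377 voxels fitted, 11377 converged
slope: 0.999  intercept: 0.6 ms  wRMSNE: 0.14%
```

The slope is the weighted least-squares regression of the pipeline T1
against the gold-standard IR-SE T1 across all vial ROIs (weights
1/SD²); a value of 1 means the corrected VFA map reproduces the gold
standard, and the weighted RMS normalized error summarises the
per-vial residuals. The MOLLI forward model works the same way from a
known water T1:

```r
f <- fit_molli(simulate_molli(1000,
        conf = molli_confounders(t2star_ms = 15, pdff = 0.02)))
cat(sprintf("T1* = %.0f ms, T1_LL = %.0f ms\n", f$t1_star, f$t1_ll))
#> T1* = 461 ms, T1_LL = 700 ms
```

i.e. a 1000 ms liver would read ~700 ms on MOLLI under those
confounders — the familiar MOLLI underestimation.

A command-line driver wrapping the same functions ships in
`inst/cli/vfat1.R` with subcommands `simulate-phantom`, `b0map`,
`b1map`, `dixon`, `fit-t1`, `fit-ir`, `simulate-molli`, `roi-stats`,
`repeatability` and `run` (the full pipeline):

```sh
Rscript inst/cli/vfat1.R simulate-phantom --snr 100 --seed 4 --out ph
Rscript inst/cli/vfat1.R run --dir ph --out t1.nii.gz --report report.json
```

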