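---
title: "Methods: desk-scale TUS planning and beta-band analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: desk-scale TUS planning and beta-band analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the models behind `betalens`, the parameters that
matter, the numerical choices, and what the synthetic-data tests do and do
not establish about real data. It states no empirical number that the test
suite or `scripts/acceptance.R` does not itself compute.

## The problem

Deep-brain stimulation of the subthalamic nucleus (STN) suppresses
beta-band (13–30 Hz) local field potential (LFP) power, a Parkinsonian
biomarker. Pulsed transcranial ultrasound (TUS) aimed at the globus
pallidus internus (GPi) with DBS-like timing (90 µs pulses at 130 Hz PRF,
800 ms trains every 2.5 s, 500 kHz carrier, 600 kPa in-brain peak) is a
candidate non-invasive analogue. Planning such a sonication requires a
per-participant acoustic lens that undoes skull aberration; analysing its
effect requires sham-normalised spectral contrasts of multi-rate
LFP/EEG recordings. This package implements both halves at desk scale,
plus the synthetic data needed to test them with known ground truth.

## Acoustic model and solver

The solver time-steps linear first-order acoustics (pressure + particle
velocity) on a staggered grid with a split-field PML, drives a ramped
continuous sinusoid, and demodulates the last `record_cycles` carrier
cycles (an exact integer number of steps) into a complex amplitude
`P` with `p(t) = Re(P e^{-iωt})`, so phase grows as `+2πf r/c` with
distance. Key numerical choices:

* **Resolution and stability.** 0.5 mm spacing (≈ 5.9 points per
  wavelength in water at 500 kHz) and CFL 0.28 against the fastest
  medium; the solver refuses media below 5 points per wavelength and
  reports the spacing that would be needed.
* **Single-frequency dispersion compensation.** A 2nd-order scheme at
  6 points per wavelength is dispersive; because exactly one frequency is
  ever simulated, the sound-speed map is pre-warped so the numerical
  phase velocity at f₀ equals the physical one along grid axes. Residual
  *angular* dispersion (of order 1 % off-axis) remains; absolute phases
  are therefore oracle-accurate near-axially, while lens design is
  unaffected because time reversal is self-consistent within the
  discrete medium (backward and forward runs share the operator).
* **Absorption** is a single-frequency pressure relaxation
  (γ = 2αc, giving `e^{-αr}` plane-wave decay at f₀), not a dispersive
  power law: no other frequency is ever present.
* **Fluid model.** Shear waves in bone are neglected, following common
  fluid-model practice in transcranial simulation toolboxes.
* **2D default.** The full pipeline runs 2D (a 221×221 grid plans in a
  few seconds); the kernels also support 3D on grids up to 128³, where
  the free-field 1/r oracle is tested. The published workflow this
  emulates ran 3D on a GPU; all 2D results carry that caveat, noted in
  every report.

An energy-conserving closed-box mode (PML off, pulsed source) verifies
the discrete conservation law to machine precision; reciprocity in lossless
heterogeneous media holds within 2 %.

## Head phantom

A labelled 2D phantom stands in for a segmented CT: water exterior,
scalp-equivalent soft tissue, a bone shell whose thickness varies
sinusoidally with angle (`mean(range) + A sin(kθ + φ)`, k and φ drawn
from the seed, clamped to the stated range), brain interior, an embedded
electrode rod, and GPi-like / ventricle-like targets. The head is
**elliptical** (46 × 40 mm semi-axes): a circular shell is a degenerate
internal resonator whose whispering-gallery caustic produces a
non-converging reverberant steady state that real (and elliptical) heads
do not have. Material properties ship as a user-editable YAML of
literature substitute values (the emulated study's own table is not
printed in its main text) — water 1482 m/s, soft tissue 1540/1040,
bone 2800/1900 with high absorption, metal-like electrode.

## Lens design and verification

`place_transducer` maximises the aperture-footprint mean of backward
amplitude by exhaustive search (ties take the first candidate and set a
flag). `design_lens` negates the receiver phase, re-references it to its
circular mean (the lens encodes only relative aberration), and converts
phase to thickness with the wrap step `t_2π = 1/(f₀|1/c_lens − 1/c_med|)`.
`forward_verify` drives the aperture uniformly with the lens phase as a
thin screen (a voxelised-slab mode exists as a cross-check), rescales the
field linearly so the in-brain peak equals the protocol pressure — the
unique factor, by linearity — and computes focal metrics.

Peak localisation is voxel-level by design, so targeting errors are
quantised to the grid. Two desk-scale effects dominate the residual
error: the proximal focal shift of a strongly focused finite aperture
(present even in the homogeneous control, where the error is one voxel)
and aberration residuals of phase-only correction. The suite's lens
criterion records this honestly: the mean error over the four default
phantoms sits above the sub-voxel level a 3D clinical-resolution
pipeline reports, while the lens-benefit property (with-lens target
pressure ≥ without, per phantom) holds throughout.

## Thermal model

`heat_source` uses the standard plane-wave relation `Q = α|p|²/(ρc)` —
the emulated study does not print its source term, so this is a stated
assumption — with either time-averaged duty scaling
(`0.0117 × 0.32 = 0.003744` for the default protocol) or train-resolved
gating. `simulate_bioheat` integrates Pennes' equation explicitly at 0.9×
the diffusion stability bound (≥ 8 steps per train when gated; zero-flux
boundaries; blood-side ρC defaults to local tissue values). Closed-form
checks: conduction-free heating `ΔT = Qt/ρC` to 0.5 %, perfusion-only
exponential decay to 1 %, heat-kernel variance growth to 2 %, linearity
in Q exactly. Electrode voxels conduct but generate no extra heat;
ultrasound–electrode interaction heating is out of scope. The safety
gate is strict: rise < 2 °C and clearance > 5 mm.

## Synthetic sessions and what they can show

Each channel is `1/f background + Σ band-limited stochastic oscillations
+ white noise`. Oscillations are Gaussian-envelope spectral shapes
(FWHM = bandwidth) with per-block log-normal gains; the ipsilateral M1
channel shares the STN log-gain weighted by the coupling; active blocks
on the stimulated day multiply beta amplitudes by the suppression factor
(M1 receives `s^coupling`); the second day carries a multiplicative
drift. The generator records, per block/channel/band, the realised
oscillation, background and noise band powers (direct Fourier sums on the
clean constituents) — the oracle for recovery tests.

Calibration choices, made once: the aperiodic `offset` is the in-band
(4–45 Hz) background RMS, so normalised beta shares are realistic rather
than ~1 (broadband normalisation cancels any effect when beta dominates
the analysed band); block-gain σ = 0.05 so the planted site-contrast
dispersion matches the reported group CI width of the emulated study;
default suppression (0.80 low, 0.90 high beta) then plants a group-mean
site contrast at the study's headline level (~10 %). Reaction-time
effects are planted *in the measured domain* — the requested
normalised-median reduction is converted to a multiplicative factor via
the expected day minimum (fixed-point on the log-normal mixture) — so
`rt_contrast` recovers the planted number directly.

Passing recovery tests show the pipeline is unbiased against its own
generative model (planted suppression 0.7–1.0 recovered within ±2
percentage points; coupling structure R² high/low as planted). They do
not establish robustness to real-data features the generator omits:
beta bursting and waveform asymmetry, non-stationary artefacts, line
noise, electrode drift, volume conduction, or true coupling dynamics.

## Artefact model

Direct sonication of the electrode is modelled as a rectangular pulse
train (amplitude = coupling(pressure); quadratic coupling by default,
matching a dose response of recorded power with pressure) gated by the
train envelope, filtered by the device's causal 100 Hz low-pass
(order 2 — unpublished, configurable), and decimated by subsampling so
residual aliasing is preserved as in hardware. The analytic rectangular-
train Fourier series (`2d·|sinc(kd)|`) times the filter response predicts
the measured harmonics to 3 %. The therapeutic 130 Hz PRF places its first
harmonic above the cutoff (the 250 Hz sampling folds it to 120 Hz,
attenuated by the filter's 130 Hz response), so beta-band power stays at
the baseline noise floor; a 5 Hz PRF control places harmonics directly in
the beta band and scales with pressure.

## Statistics

Lilliefors normality uses the KS statistic with estimated moments and a
Monte Carlo null (closed forms do not exist; 10 000 draws by default,
seeded). Paired contrasts are two-sided one-sample t tests with
Student-t CIs (df = n−1). BH-FDR is applied within the family of tests a
run emits, and the family is printed in the report — the emulated study
does not enumerate its own family. Post-hoc power is Monte Carlo. The
reaction-time contrast min/max-normalises each participant-day's 240
trials, takes block medians, normalises active to same-day sham and
contrasts the days; both the per-day relative reduction and the site
contrast are reported.

## Problem sizes and determinism

Default desk-scale sizes: 221×221 phantom (a planning chain in ~5 s),
5-minute blocks for the thermal gate, 60 s rest blocks and 20-seed
repetitions for recovery tests, 10 kHz internal rate for the artefact
model. Every generator consumes one master seed; per-component child
streams are derived from fixed labels so adding a component never
perturbs existing draws, and identical config + seed reproduces every
table bitwise.

## Known limitations

2D acoustics and thermals (3D kernel available but not integrated with
phantom/lens placement); phase-only lens with uniform drive (no
amplitude shaping); no nonlinear propagation, no shear conversion, no
dispersive absorption; voxel-level peaks; synthetic signals lack burst
dynamics; the proprietary device export format is deliberately not
parsed; material values are literature substitutes.
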