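---
title: "Methods: simulating and analyzing mobile fNIRS dual-task experiments"
author: "fnirsdual"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analyzing mobile fNIRS dual-task experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fnirsdual)
```

## The experiment this package models

`fnirsdual` implements an end-to-end analysis for a mobile neuroergonomic
dual-task paradigm: participants navigate outdoors with one of two
navigation aids — an augmented-reality wearable display (ARWD) or a
hand-held display (HHD), a between-subject factor with 10 participants per
group — while cortical hemodynamics over bilateral prefrontal cortex are
recorded with a four-optode, two-wavelength (730/850 nm) fNIRS montage
sampled at 4 Hz. Cognitive load and situation awareness are probed with two
secondary tasks embedded in the navigation: 37 auditory 1-back blocks of
60 s and 10 scenery-probe trials of about 30 s, separated by at least 15 s
of pure navigation. The workload logic of the paradigm is that secondary
task performance and the accompanying prefrontal hemodynamics index the
attentional cost of the primary task.

Because no recordings from the original experiment are publicly available,
the package ships a first-class synthetic-data module that generates
complete experiments with the statistical structure the analysis assumes.
Every stage of the pipeline is validated by parameter recovery and
round-trip properties on these simulations, not by comparison to withheld
human data.

## Signal chain

### Filtering

Raw intensities are low-pass filtered with a linear-phase FIR filter of
order 20 and cutoff 0.1 Hz at fs = 4 Hz. The design is a Hamming
windowed sinc, normalized to exactly unit DC gain so constant baseline
intensity is invariant. We interpret the stated cutoff as the **passband
edge** (the convention used by MNE-Python's filter design): the ideal sinc
cutoff sits at `cutoff + transition/2` with `transition = 3.3 fs / order`,
the Hamming main-lobe width. With this convention the response is flat to
better than 0.1% over the hemodynamic band (≤ 0.05 Hz) and more than 40 dB
down at and above 1 Hz, where the cardiac rhythm (~1.1 Hz at walking pace)
lives. A consequence worth stating plainly: an order-20 filter at 4 Hz has
a transition band of about 0.66 Hz, so respiration (~0.25 Hz) is only
mildly attenuated (gain ≈ 0.89) and Mayer waves (~0.10 Hz) pass almost
untouched. No order-20 filter at this rate can both preserve 0.05 Hz and
suppress 0.25 Hz; block averaging and the mixed models carry the residual
physiological variance instead.

Filtering is zero-lag: the `order/2`-sample group delay of the symmetric
kernel is compensated and edges are reflect-padded, so filtered samples
stay aligned with the task markers.

### Quality screening

Three screens run on the raw (unfiltered) recording:

* **Saturation** — any sample at or above the ADC ceiling is flagged.
* **Motion artifacts** — a sliding-window coefficient of variation,
  `CoV = 100·sd/mean`, with defaults of 20 s windows, 5 s steps and a 10%
  threshold. All three are configuration keys. The scan targets the
  intensity scale of mobile recordings, whose broadband detector noise
  (shot noise, stray light, coupling changes) sits at a few percent of the
  mean; short spikes of ten signal-SDs then lift a window's CoV past the
  threshold while clean windows stay below it.
* **Ambient light** — an optode is flagged when the median of its ambient
  channel exceeds a configurable fraction (default 10%) of its median
  detector intensity.

Flags annotate blocks; by default any block overlapping a saturated sample
or flagged CoV window (or sitting on an ambient-contaminated optode) is
excluded from analysis with its reason logged, and a `"warn"` policy keeps
it. Whether the original analysis excluded or corrected such blocks is not
documented; exclusion is the package default because it is auditable.

### Modified Beer-Lambert conversion with local baselines

Each secondary-task block is cut out at its synchronization markers
(half-open sample windows, marker seconds rounded to the nearest sample).
Optical density changes are computed against the **local baseline**, the
mean intensity over the first 10 s of the same block — during which the
participant is already walking — so each block measures change relative to
its own mobile context:

$$\Delta OD(\lambda, t) = -\log_{10}\frac{I_\lambda(t)}{\bar I_{\lambda,\text{base}}},\qquad
\varepsilon\begin{bmatrix}\Delta HbO\\\Delta HbR\end{bmatrix}
 = \begin{bmatrix}\Delta OD(730)/(d\,DPF_{730})\\ \Delta OD(850)/(d\,DPF_{850})\end{bmatrix}$$

The packaged extinction coefficients are the OMLC (Prahl) hemoglobin
compilation at 730/850 nm in 1/(mM·cm); source-detector separation
defaults to 2.5 cm and DPF to 6.0 at both wavelengths, typical
adult-forehead values. None of the pipeline's correctness properties
depend on the specific table: all conversion tests are forward-inverse
round trips that hold for any nonsingular ε. Solutions are scaled from mM
to µM. Each block is then divided into consecutive 10 s sub-blocks whose
time-averages (trailing partial bin dropped) form the down-sampled
hemodynamic response; the block mean of ΔHbO ("HbO") and ΔHbR ("HbR") per
optode summarizes the block.

## Statistical models

Hemodynamic summaries are analyzed with linear mixed models per secondary
task × chromophore × optode; behavioral accuracy with binomial GLMMs per
task (logit link, log-odds coefficients, Wald z). Fitting is delegated to
`lme4`/`lmerTest`, the same stack the original analysis used; Satterthwaite
denominator degrees of freedom are used for all gaussian t-tests.

**Model selection.** Fixed and random effects are chosen by BIC
(`-2·logLik + k·log n`), all candidates fitted with maximum likelihood, the
null model being no fixed effects with a participant random intercept. A
BIC difference above 2 is treated as meaningful evidence (the conventional
strength-of-evidence cut); when a richer model beats a simpler one by less
than 2 BIC the simpler model is retained and the comparison is flagged
"not meaningful". The chosen gaussian model is refitted with REML for
coefficient reporting. The candidate ladder is configurable; the default
grows from the null through device condition, accuracy, their interaction
and a block slope, crossed with random structures {intercept, intercept +
uncorrelated block slope, block slope only}. The slope-only structure is
included because the reported HbR models name only a participant block
slope; whether an intercept was also intended is ambiguous, and BIC decides
per dataset here.

**Contrast tables.** Models are fitted reference-coded (HHD and "correct"
as references, matching the reported coding) and translated into the
report vocabulary — cell means (`ARWD: Correct`, …), marginal means, and
the differences `Incorrect-Correct`, `HHD-ARWD`, within-device accuracy
differences and between-device differences at fixed accuracy. Every row is
a linear contrast of one coefficient vector, so cells and differences are
exactly consistent; SEs are `sqrt(c'Vc)`; covariates such as the centered
block index are evaluated at their center.

**Multiple comparisons.** p-values are corrected with the
Benjamini-Hochberg step-up rule at α = 0.05 within families defined as one
secondary task × one chromophore, pooling hypotheses across optodes and
contrast rows. The descriptive grand-mean row of a null-selected model is
not a device/accuracy hypothesis and is excluded from families by default;
family membership is configurable and logged.

## The synthetic-data generator

The generator emulates the study design exactly by default (20 subjects
10/10, 37 × 60 s 1-back blocks, 10 × 30 s probes, ≥ 15 s gaps, 4 Hz, four
optodes). Its layers:

* **Behavior** — per-trial binary accuracy from a logistic model with
  subject random intercepts (and optional uncorrelated trial slopes).
  Default fixed effects are the reported log-odds estimates (1-back:
  intercept 0.528, device effect 0.551; probe: 0.914 and −0.155) with a
  subject intercept SD of 0.5, a mid-range value for binary group data.
* **Hemodynamics** — block-locked boxcars scaled by (condition × accuracy)
  cell amplitudes in µM, convolved with a canonical double-gamma HRF
  (peak 6 s, undershoot 16 s, ratio 1:6, unit area so sustained blocks
  plateau at the cell amplitude). The reported coefficients do not identify
  generating cell means, so the default amplitudes (0.4–0.9 µM HbO,
  HbR = −⅓·HbO) are free parameters of the simulation, not claims about
  the original data. A boxcar (no-HRF) mode provides piecewise-constant
  truth for exact round-trip checks.
* **Optics** — intensities follow the inverse Beer-Lambert map
  `I = I₀·10^(−ΔOD)`; with all noise off the forward-inverse round trip
  recovers the truth to numerical precision.
* **Noise** — cardiac (1.1 Hz), respiratory (0.25 Hz) and Mayer (0.10 Hz)
  sinusoids with random phase, linear drift and white noise in
  µM-equivalents, plus multiplicative detector noise at 7.5% relative SD.
  The detector component dominates the raw-intensity coefficient of
  variation (~7–8%), the regime in which a CoV screen with a 10% threshold
  is informative, and it propagates to sub-block residual SDs of a few
  tenths of a µM up to ~1 µM — the scale of the residual variances the
  reference tables report.
* **Artifacts** — motion spikes (1–3 samples, amplitude in channel SDs),
  step shifts, and saturation events clipped at the ADC ceiling, all
  logged so screens can be validated against ground truth.
* **Reproducibility** — every generator is a pure function of
  (design, parameters, seed); each subject × stage draws from its own
  derived RNG stream, so subject subsets reproduce exactly.

What the generator does **not** emulate: auditory stimulus acoustics, GPS
and route geography, short-separation channels, systemic physiology
regressors, serially correlated gait artifacts, or spatially correlated
noise across optodes. Passing tests therefore demonstrate the pipeline's
internal correctness and calibration under this noise model, not
performance on any particular human dataset.

## Numerical and design choices

* Sample indexing is 0-based in seconds→samples arithmetic, half-open per
  block; marker times are rounded to the nearest sample.
* ΔOD uses base-10 logarithms (Beer-Lambert convention).
* BIC uses the parameter count from the fit's log-likelihood object and is
  verified against `stats::BIC` to 1e-6.
* Singular (boundary) variance fits are reported with a flag, never
  auto-simplified — the BIC ladder already penalizes overparameterization.
  Complete separation in binomial fits yields non-finite estimates with a
  diagnostic rather than a misleading finite fit.
* Ties within 2 BIC resolve toward fewer parameters, then toward the
  earlier candidate in the ladder.
* The analysis grain defaults to sub-block rows (supporting the reported
  "block slope" random term); a block-mean grain is available. Sub-block
  rows of low-pass-filtered noise are serially dependent, which iid-residual
  mixed models do not capture: at sub-block grain, intercept-style tests are
  mildly anti-conservative. The calibration studies in the test suite
  therefore run at block grain, where local baselines and ≥ 15 s gaps
  decorrelate rows; this limitation is inherited from the modeling
  convention, not introduced by the implementation.
* Post-selection inference: p-values reported for a BIC-selected model are
  conditional on selection and slightly optimistic — a property of the
  select-then-report procedure itself. Under a global null the selected
  model is almost always the null model, and the end-to-end familywise
  rejection rate stays at the nominal α (verified at 200 task×chromophore
  families across 50 simulated null experiments).

## Problem sizes used in validation

The test suite and the acceptance script scale simulations to sizes chosen
to estimate each property precisely without waste: 1000 random vectors for
solver equivalence; 2 subjects × 4 blocks for round trips; 2000 replicates
of m = 100 for FDR calibration; 200 (tests) or 100 (script) replicates of
the full 20 × 37 behavioral design for GLMM recovery; a 2 × 2 grid of
{effect × subjects} with 20 replicates per cell for selection consistency;
and 50 (tests) or 20 (script) seeded null experiments of 10 subjects ×
11 blocks for the end-to-end calibration. These are the package's own
validation sizes; all generator defaults remain the full study design.

## A worked miniature

```{r example, eval = FALSE}
design <- make_design(n_subjects = 6, n_oneback_blocks = 6,
                      n_probe_trials = 2)
ex <- simulate_experiment(design = design, seed = 1)
cfg <- run_config(hemo_fixed = c("1", "condition", "condition * accuracy"),
                  hemo_random = "intercept", grain = "block")
bundle <- run_analysis(cfg, experiment = ex)
bundle
write_report(bundle, "fnirsdual_report")
```

The bundle holds the 2 tasks × 2 chromophores × 4 optode contrast tables
with FDR decisions, the behavioral log-odds tables, the BIC selection
ledger, variance components, and a QC summary whose counts reconcile with
the input markers (analyzed + excluded = markers × optodes).
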