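---
title: "Methods: simulated categorical loudness scaling and the neural-ensemble-averaging loudness model"
author: "loudsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulated categorical loudness scaling and the NEA loudness model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## What the package models

Narrow-band sounds — a quarter-octave noise, say — are perceived as softer
than a pure tone of the same sound pressure level and center frequency, by
several dB of equivalent level. This *mid-bandwidth loudness depression*
(MBLD) peaks for moderate levels near 1 kHz and shrinks in sensorineural
hearing loss, where recruitment compresses the usable dynamic range.
`loudsim` provides a complete simulated test bench for the phenomenon:

1. **stimuli** — the test sounds (pure tones, Rayleigh-spectrum band
   noise, five-tone complexes, low-noise noise, SAM tones) with exact
   level, ramp, duration and spectral conventions;
2. **listeners** — a synthetic-cohort generator whose categorical
   loudness surfaces encode the group-level effects of interest;
3. **qcls** — a Bayesian adaptive categorical loudness-scaling procedure
   placing 100 trials over frequency x level;
4. **profiles** — a maximum-a-posteriori fit of each run, yielding the
   10 category-boundary levels at 10 frequencies (0.25–8 kHz);
5. **analysis** — loudness-growth slopes, loudness reduction/summation,
   equal-loudness contours, loudness loss, hearing-aid gain, and the
   REML mixed model with Satterthwaite Type III tests;
6. **nea** — a neural-ensemble-averaging (NEA) loudness model that
   predicts MBLD from envelope fluctuation, fast-acting peripheral
   compression, synaptic adaptation, and central expansion.

Because no human data ship with the package, every quantitative claim is
checked by parameter recovery: the generator plants known effects, the
pipeline must find them.

## The categorical scale and the synthetic listeners

Loudness is reported on the 11-category scale (categorical units, CU,
0–10; 0 = "Can't Hear", 10 = "Too Loud" — the historical label for the
top category). A listener is a ground-truth surface CU(f, L): a
two-segment piecewise-linear function of level at each frequency
(shallower below CU 2.5, twice as steep above — a standard categorical
loudness-scaling parameterization), anchored by thresholds and slopes at
0.5, 1 and 4 kHz with linear interpolation in log-frequency. The nominal
slope parameter is scaled so that the least-squares regression of CU on
level over boundaries 2–9 returns exactly the nominal value; group means
default to 0.10 cat/dB (NH) and 0.12 cat/dB (HL), with between-subject
SD 0.025 cat/dB. That SD was chosen by decomposing the published
group-comparison t statistic for 32 + 68 listeners into between-subject
and measurement components; it reproduces a comparable group separation
at cohort scale.

Narrow-band stimuli are softer: their effective level is reduced by a
smooth bandwidth-offset surface, a Gaussian bump in (log2 f, L) peaking
at 7 dB for quarter-octave noise at (1 kHz, 60 dB SPL) in NH listeners,
with log-frequency spread 1.5 octaves. The one-octave offset is 4/7 of
the quarter-octave offset (so the two bandwidths differ by 3 dB at the
peak), and HL listeners carry 0.6 of the NH offset. The level spread
(default 27.42 dB) is the one deliberately *calibrated* constant: it is
solved once, against generator ground truth only, so that the population
expectation — over the NH cohort-sampling distribution of thresholds,
slopes and listener-specific offset scale — of the offset averaged over
a listener's ten 1-kHz category boundaries equals 4.08 dB, the value the
pooled mixed-model bandwidth contrast is designed to recover, while the
60-dB point offset stays exactly 7 dB. (Targeting the *default*
listener instead of the population expectation would leave the cohort
contrast about 0.24 dB low: between-subject jitter moves boundaries
away from the 60-dB peak, and the Gaussian's concavity makes that a
one-sided loss.) Responses are
`round(CU + e)` clamped to 0..10 with Gaussian `e` (SD 0.8 CU); the
analytic category probabilities are normal-CDF differences at the
half-integer cut points.

What the generator does *not* emulate: lapses, category biases,
attention drift, ear asymmetries, age effects, or audiogram fine
structure. Passing tests therefore demonstrate that the pipeline's
estimators are consistent and correctly calibrated for this response
model, not that they are robust to every behaviour of real listeners.

## The adaptive procedure

The procedure maintains a posterior over a discrete hypothesis space
that realizes the "correlated loudness surface" assumption: the 1-kHz
anchor threshold on a 5-dB grid, the 0.5- and 4-kHz anchors as bounded
offsets from it (audiograms are smooth), and a single nominal slope
shared across anchors. Each trial selects, from nine frequencies
(0.25–6 kHz; 8 kHz is never presented) by 2-dB level steps over
0–100 dB SPL, the candidate maximizing the expected reduction in
posterior entropy — the mutual information between the next categorical
response and the hypothesis — with ties broken toward the lowest level,
then the lowest frequency. Updates are exact Bayes with an 11-category
discretized-Gaussian likelihood floored at 1e-6 (a guard against
responses outside the model). Numerical notes: category-probability
tables are precomputed per configuration (quantized to 2^-20, far below
response noise); the information-gain pass runs over the smallest
hypothesis set covering all but 1e-9 of the posterior mass; updates are
never pruned.

Greedy entropy reduction on a discrete grid is a design choice, and its
character is worth stating plainly: it concentrates trials at the most
discriminative frequencies (often the extremes of the lattice) and, once
the posterior has collapsed, the tie-break resamples a single point.
Against uniform random placement it is clearly more accurate for
hearing-impaired listeners (whose dynamic range random placement mostly
misses) and about comparable for normal-hearing listeners; pooled over a
mixed cohort it wins on boundary RMSE. For noiseless responders it
degenerates (the posterior collapses and exploration stops), which is
why the parameter-recovery tests at zero response noise use uniform
placement.

## Profile fitting

Each 100-trial run is refit by continuous maximum a posteriori
estimation in the same family the procedure assumes, with the anchor
slopes freed (a weak Gaussian penalty, SD 0.03 cat/dB, ties them
together) and, for noise runs, one additional parameter: the amplitude
of the canonical bandwidth-offset bump (fixed peak location and
spreads). Without that parameter the fitted family cannot represent the
level dependence of the offset, and the 60-dB loudness reduction read
off the profiles would be biased toward the level-average. The amplitude
and a uniform threshold shift are only weakly separable from 100 trials;
this matters little downstream because the reported quantities
(boundaries, reductions, contrasts) are functionals of the fitted
surface near the data, not of the decomposition. Optimization is
L-BFGS-B from several starts (discrete posterior mode and posterior
mean, crossed with amplitude starts); a weakly-informative Gaussian
prior (mid-single-digit dB) keeps the amplitude off its bounds where a
single run cannot identify it. Boundary levels solve `CU = k - 0.5`
through the offset fixed point, and a monotone projection guards the
(never observed in practice) case of a non-monotone fitted surface. The
8-kHz column extrapolates the anchor structure in log-frequency and is
flagged in the diagnostics.

For quantities that compare conditions within a listener,
`fit_profiles_joint()` fits the listener's three runs together with
shared anchor thresholds and slopes and one offset amplitude per noise
condition. The tone run pins the surface, which breaks the
amplitude/shift ambiguity, and the amplitudes are then fitted by pure
maximum likelihood (no amplitude prior, multi-start L-BFGS-B): with the
anchors shared, a prior centered away from a listener's amplitude would
shrink the estimate along the residual amplitude–threshold ridge and
bias cohort medians, whereas the unpenalized estimates are centered on
the planted values (cohort recovery simulations: mean quarter-octave
amplitude error +0.06 dB, per-listener SD ≈ 2.5 dB — the medians and
mixed-model contrasts the package reports depend on the center, not the
spread). The package's experiment driver and the cohort-level
statistics therefore use the joint fit; single-run fitting remains
available and fully supported for analyses of one run in isolation.

## Group statistics

`loudness_slope()` regresses CU on boundary level over boundaries 2–9
(extremes excluded to avoid floor/ceiling distortion; an optional level
ceiling, e.g. 80 dB SPL, restricts the window). `loudness_reduction()`
inverts the two fitted loudness functions: the narrow-band profile is
read at (f, L), the tone profile inverted at that loudness, and the
difference `L - L_tone` is positive when the noise is softer.
`loudness_summation()` does the same for one-octave vs quarter-octave
noise. Cohort summaries use medians with inter-quartile ranges. The
mixed model `level ~ group * bandwidth * category + (1 | participant)`
is fitted by REML (`lmerTest`), Type III F tests use Satterthwaite
degrees of freedom, and the quarter-octave-vs-tone contrast is pooled
across category boundaries within each group (`emmeans`). The published
human F and t statistics themselves are not reproduction targets — they
depend on the human cohort's variance structure — but the design is
powered so the group-by-bandwidth interaction is detected in essentially
every simulated replicate.

## The NEA loudness model

The model implements loudness as
`L = sum_ensembles expand( mean_fibers,time compress(R) )`,
with `compress(x) = x^p` (p = 0.5) applied to single-fiber Poisson rates
and `expand(m) = c m^q` applied to the ensemble mean. Ensembles are
non-overlapping 2-mm tiles of a 35-mm Greenwood place axis (17
ensembles; a critical band spans roughly 0.9 mm, so an ensemble is
deliberately wider than a critical band). Channels default to 0.5-mm
spacing (70) and can be thinned to ~20 for coarse work; the grid is
aligned so a channel sits exactly at the 1-kHz place, keeping the
discretized excitation pattern symmetric around the standard test
frequency. Averaging over fibers *and* time happens inside the ensemble
*before* expansion — that ordering is what converts envelope fluctuation
into loudness reduction, via Jensen's inequality on the concave
compression.

The periphery is a gammatone filterbank with *fast-acting* compression:
each channel's gain follows a 50-ms running envelope average raised to
`exponent - 1` above a 20-dB SPL knee, then half-wave rectification, a
600-Hz inner-hair-cell low-pass, and 1-ms rate bins. The dynamic
(rather than memoryless) compressor is essential, and finding that was a
genuine design lesson: a memoryless power law compresses the envelope
exactly as much as it compresses sustained level, so the
fluctuation-induced loudness loss and the level-growth slope shrink
together and the equivalent-level shift saturates near 2–3 dB whatever
the exponent (a Rayleigh-envelope calculation shows the shift is
`ln Gamma(1 + g/2) / (0.115 g)`, nearly constant in the exponent `g`).
A gain control slower than the envelope fluctuations decouples the two:
sustained level is compressed, fluctuations pass at full contrast and
are then clipped by the saturating synapse. This is precisely the
combination of fast-acting compression and synaptic adaptation the
model exists to probe.

Synaptic adaptation is a three-store diffusion cascade
(source -> local -> immediate, time constants 200 / 60 / 8 ms) with
release permeability a saturating function of drive; its constant-drive
equilibrium has the closed form
`S = 1 / (1/p_source + 1/p_local + 1/p_immediate + 1/p_release)`, used
as an analytic oracle in the tests. Onset overshoot, adaptation to
steady state, and post-offset depression (forward masking) all emerge
from the cascade.

### Calibration

Three constants are free and are set by `nea_calibrate()`:

* the expansion exponent `q`, from requiring tone loudness to double per
  10 dB at mid levels (50–70 dB SPL);
* the expansion scale `c`, from anchoring a 40-dB SPL 1-kHz tone at
  1 sone;
* the peripheral compression exponent, tuned (by root finding) so the
  equal-loudness level difference for flat quarter-octave noise at
  (1 kHz, 60 dB SPL) is 7 dB. The exponent lands near 0.17–0.18,
  within the range usually quoted for basilar-membrane growth.

`q` and `c` cannot themselves move the flat-noise target — they cancel
in equal-loudness matching up to second-order ensemble-summation effects
— which is why the peripheral exponent is the third calibration knob.
With the shallow post-compression rate growth, the doubling criterion
pushes `q` to ~15; a large central expansion exponent is the price this
architecture pays for its compressed rate code, and it amplifies
Poisson noise in single-trial loudness. Two numerical devices keep
calibration and matching stable: an analytic expected-compressed-rate
path (the infinite-replication limit, used inside calibration), and
quantile-coupled Poisson draws so that test and reference stimuli in a
match share spike noise (common random numbers). Equal-loudness levels
are found by bisection to 0.1 dB on a 0–100 dB bracket; the steady-state
analysis window is 0.2–0.8 s of the 1-s stimulus.

Predictions at the reduced scale (20 channels, 20 fibers/ensemble, 10
replicates): flat quarter-octave noise ~7 dB reduction (calibrated),
five-tone complex ~4.3–5.5 dB across seeds, low-noise noise small, SAM
tone largest — reduction increases with the envelope-fluctuation index
(std/mean of the Hilbert envelope: SAM 0.71 > band noise ~0.53 >
five-tone 0.48 >> low-noise noise < 0.2). Very narrow Rayleigh noise
fluctuates slower than the 50-ms gain control, which then tracks and
flattens the envelope, so the reduction collapses toward the tone limit
as bandwidth shrinks.

## Problem sizes and runtime choices

The simulated study is 32 NH + 68 HL listeners, three stimulus
conditions (tone, quarter-octave, one-octave), one 100-trial adaptive
run per condition. That full pipeline (300 runs plus fits) takes a few
minutes on one core and is what the acceptance script recomputes. The
test suite runs the same full pipeline once and reuses it across
checks; the replicate check of the group-by-bandwidth interaction uses
ten fresh reduced cohorts (8 NH + 12 HL) — size is the only reduction,
all generator defaults untouched — and the NEA checks use the reduced
20-channel model. Stimulus-level unit tests shorten durations or sample
counts where the convention under test does not fix them.

## Known limitations

* The response model is a discretized Gaussian without lapses; real
  listeners are messier, and the procedure's likelihood floor is the
  only defence.
* The adaptive placement is greedy one-step entropy reduction on a
  discrete grid; it can resample a single point once the posterior has
  collapsed.
* The bandwidth-offset amplitude and threshold shift of a noise run are
  only weakly separable at 100 trials; per-listener amplitude estimates
  are noisy even though cohort medians are stable.
* The NEA periphery is a functional stand-in (gammatone + AGC) behind a
  substitutable interface, not a time-domain cochlear-mechanics model;
  absolute loudness values in sones inherit the 1-sone anchor rather
  than being predicted ab initio, and the expansion exponent is large.
* One-octave NEA predictions share the quarter-octave machinery but the
  model is only exercised on a coarse bandwidth sweep.
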