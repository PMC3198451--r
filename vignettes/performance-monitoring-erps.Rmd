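---
title: "Simulating and quantifying performance-monitoring ERPs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and quantifying performance-monitoring ERPs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erpmon)
```

# Scope and rationale

`erpmon` implements, end to end, the analysis chain of a combined
time-estimation / stop-signal paradigm used to elicit three
performance-monitoring event-related potentials — the feedback-related
negativity (FRN), the stop-signal N2 and the error-related negativity
(ERN) — together with a synthetic behavior-and-EEG generator that stands
in for recorded data. Every stage (staircase task dynamics, epoch
generation, referencing and baseline handling, component quantification,
topographic permutation statistics, reliability, regressions) is
ordinary, exported, tested package code; nothing in the analysis chain
knows it is being fed simulated data.

The generator exists because raw recordings for this paradigm are not
publicly available. Its role is to provide inputs with *known ground
truth* so that every analysis stage can be verified by
injection–recovery, by independent brute-force oracles, and by sampling
theory. It makes no claim to biophysical realism (see *Limitations*).

# The task model

An agent reproduces a 1000 ms interval. A response is *on time* when it
falls inside an adaptive response time window (RTW) centered on 1000 ms;
the total window width is staircased per condition:

| condition | width on error | width on correct | equilibrium accuracy |
|-----------|----------------|------------------|----------------------|
| control   | +10 ms         | −10 ms           | 1/2                  |
| easy      | +12 ms         | −4 ms            | 3/4                  |
| hard      | +4 ms          | −12 ms           | 1/4                  |

because at equilibrium the expected width change vanishes:
`p_err · step_err = (1 − p_err) · step_corr`. The session comprises 8
blocks × 30 trials per condition (720 trials), control first; the width
reached at the end of the control condition seeds both later conditions.
Hands alternate per block. A fifth of the trials are stop trials: a
stop-signal is delivered `lead` ms before the expected response (the
mean of the last 8 estimation RTs), and the lead is staircased by ±7 ms
(tightened after successful inhibition) so that inhibition tracks 50%.
Inhibition itself follows a horse race: it succeeds iff
`onset + SSRT < planned RT`, with SSRT ~ Normal(190, 30²) ms.

Agent response times are `1000 + bias + ε`, `ε ~ Normal(0, 140²)` ms;
`bias` random-walks with an 8 ms/trial step and, after error feedback,
is pulled 50% toward zero with an extra Normal(0, 60²) recentring kick.
These three numbers are the only "behavioral physiology" in the model:
the 140 ms timing noise reproduces the observed relation between
equilibrium window widths (≈320 ms easy / ≈110 ms hard) and accuracy,
while drift plus post-error recentring degrade the idealized 75%/25%
equilibria to the empirically observed ≈72%/≈30% (adaptive windows lag a
non-stationary RT distribution) and make RT adjustments larger after
errors than after correct feedback. Window boundaries are inclusive, the
width floor is 20 ms, the lead floor 0 ms, stop trials never update the
RTW, and failed-stop RTs do not enter the 8-trial running mean — the
source material is silent on all of these, so they are package
conventions, stated here once.

A note on the stop staircase: read literally as an *onset time*,
"decrease after correct inhibition" would make stopping easier after
every success and the tracked rate would not converge to one half. Read
as the *lead* before the expected response (which the initialization
"mean of the last 8 responses minus 150 ms" suggests), the ±7 ms rule is
a standard tracking staircase and converges to ≈50% regardless of the
SSRT mean. The package implements lead tracking.

# The EEG generator

Epochs span −200…600 ms around their locking event at 600 Hz (480
samples, 80-channel extended 10-20 montage on a unit-disc projection).
Three event classes are emitted per trial log: feedback-locked epochs
for every estimation trial, stop-locked epochs for every stop trial, and
response-locked epochs for failed stops (which also carry a link to
their stop-locked sibling, used for the ERN baseline).

Each component is a biphasic temporal kernel (negative Gaussian preceded
by a smaller positive one — the measures below are trough/peak based, so
the waveform needs both lobes) times a Gaussian scalp topography
centered at FCz. Kernels are rescaled so that the component's own
measurement operator applied to the noiseless kernel returns exactly −1;
injecting an amplitude `a` therefore *recovers* `a` exactly when noise
is off, which is the package's primary correctness invariant.
Topographies are spatially mean-centered (so common-average referencing
leaves them untouched) and scaled to 1 at their maximal electrode.

Defaults (microvolts, ms):

* FRN: mean −5.62, between-subject SD 2.98, trough at 280; injected on
  error feedback only with gains 1.0 (easy), 3.78/5.62 (hard), 0.85
  (control), so the unexpected difference wave (easy-error −
  hard-correct) recovers −5.62 and the expected one −3.78.
* N2: mean −6.14, SD 2.94, trough at 200 after the stop-signal, with a
  ±0.06 layout-unit ipsilateral shift of the topography by stop-signal
  hand; failed stops receive a half-gain N2.
* ERN: mean −5.69, SD 2.97, trough at 60 after the erroneous response.

Between-subject amplitudes are one trivariate normal draw per subject
with correlations ρ(N2, ERN) = 0.75, ρ(ERN, FRN) = 0.55,
ρ(N2, FRN) = 0.43 — generator choices mirroring the regression structure
the paradigm is meant to expose, not measured facts. Trial-to-trial
amplitude jitter (SD 1.5 µV) and noise — temporally 1/f, spatially
correlated with a 0.4 layout-unit Gaussian scale, 2 µV RMS per channel —
sit on top. The RMS default was calibrated once against two demands: at
the study's trial counts (≈27 trials per FRN cell) split-half
reliabilities must land at or above .85, and the residual noise in
per-subject averages must stay small enough that extremum-picking bias
(picking the minimum of a noisy wave is biased negative) does not
distort grand means beyond their sampling error. A deliberately
unrealistic aspect: real single-trial EEG noise is an order of magnitude
larger; matching it would require artifact rejection and more trials,
which are outside this package's scope, so passing tests certify the
*analysis chain*, not robustness to raw-EEG noise levels.

The generator intentionally does not model a global rightward N2
topography bias: left- and right-hand N2 maps are exact mirror images by
construction (a property the tests rely on), so hand contrasts are
driven by the ipsilateral shift alone.

# Quantification

All epochs are re-referenced to the common average, then baseline
corrected: feedback- and stop-locked epochs against their own −200…0 ms,
response-locked epochs against the −200…0 ms of their *linked*
stop-locked epoch (a baseline-independent window preceding the
stop-signal). Measures, all at FCz by default:

* **FRN** — the most negative deflection of a feedback difference wave
  in 0–600 ms (raw minimum, not trough-to-peak).
* **N2** — trough-to-peak: the most negative deflection 120–280 ms after
  the stop-signal minus the preceding maximal deflection, searched from
  0 ms.
* **ERN** — trough-to-peak in the first 120 ms after the erroneous
  response.

Numerical conventions: window endpoints inclusive; the 0 ms sample is
excluded from post-event searches; ties resolve to the earliest sample;
the preceding-positivity search starts at 0 ms (configurable — nothing
in the source pins it down).

# Topographic statistics

Scalp maps are normalized by average reference plus division by global
field power (GFP, the RMS over electrodes). The global map dissimilarity
between two normalized maps is the RMS of their difference: 0 for
proportional maps, 2 for inverted ones, √2 for spatially uncorrelated
ones, via the identity GMD² = 2(1 − r_spatial). The permutation test
(TANOVA) flips each subject's pair independently, recomputes grand
averages and their GMD, and reports a one-sided p value: exact
enumeration of all 2ⁿ flips when that space fits in the permutation
budget, otherwise sampled flips with the add-one estimator (so p is
never 0). Grand averages are normalized *after* averaging — per-subject
normalization before averaging is available but not the default, since
the procedure being mirrored normalizes the recalculated group ERPs.
Maps enter at the component's grand-average peak latency; a
window-average option exists.

# Reliability and regressions

Split-half reliability forms odd/even half averages per subject — for
the FRN, within each constituent cell of the difference wave before
subtracting, so both halves are balanced — applies the component's
measure to each half, correlates halves across subjects and corrects
with the Spearman–Brown prophecy formula `2r/(1 + r)`. Subjects lacking
a trial in a half are excluded with a warning, never imputed. Bivariate
regressions between components z-normalize both variables (n − 1
denominator), so the slope equals the Pearson correlation and
β² = R².

# Problem sizes and determinism

The shipped defaults are the study's own scale: 24 subjects, 720 trials,
80 channels at 600 Hz, and 100,000 permutations in the `study` profile
(10,000 in `fast`). Tests and examples run reduced scales (fewer blocks,
temporal decimation) chosen to exercise every code path at full fidelity
of the algorithms; all equilibrium and calibration checks use
tolerances from sampling theory (3 standard errors plus a small
transient allowance) rather than tuned constants. Every stochastic stage
consumes an explicit seed; a root seed fans out to per-subject substreams
by drawing 31-bit integers, and `runStudy()` is bit-reproducible given
its config.

This is an analysis package, not a command-line tool: the orchestration
surface is `runStudy()` with `defaultRunConfig()` or a YAML file via
`readRunConfig()`, and the per-stage functions compose directly.

# Limitations

* No biophysical forward model, no artifact model, unrealistically low
  noise floor (see above): conclusions transfer to the *algorithms*,
  not to raw-EEG robustness.
* Component waveforms are stylized Gaussians; latency jitter across
  trials is not modelled, so latency recovery is easier than in real
  data.
* Single-trial measures, source localization, spherical-spline
  interpolation, ICA cleaning and repeated-measures ANOVA machinery are
  intentionally out of scope.
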