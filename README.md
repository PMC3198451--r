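# erpmon

Simulation and analysis of three performance-monitoring event-related
potentials — the feedback-related negativity (FRN), the stop-signal N2
and the error-related negativity (ERN) — as elicited by an adaptive
time-estimation task with interspersed stop-signal trials.

The package is aimed at EEG methodologists who want a fully verifiable
re-implementation of this paradigm's analysis chain. Because no recorded
data for the paradigm are public, a synthetic generator with known
ground truth drives every stage: you can inject components with chosen
amplitudes, run the exact analysis a recorded study would run, and check
what comes out.

## What it implements

**Task simulation.** Agents reproduce a 1000 ms interval; a response is
on time inside an adaptive response-time window (RTW) centered on
1000 ms. The total width is staircased per condition — control ±10 ms,
easy +12/−4, hard +4/−12 (ms, grow on error / shrink on correct) — so
error rates equilibrate near 1/2, 1/4 and 3/4: at equilibrium
`p_err · step_err = (1 − p_err) · step_corr`. 20% of trials are stop
trials: a stop-signal arrives `lead` ms before the expected response
(mean of the last 8 estimation RTs), the lead staircased ±7 ms to track
50% inhibition, with success decided by a horse race
(`onset + SSRT < planned RT`).

**Synthetic EEG.** 80-channel, 600 Hz epochs (−200…600 ms) with biphasic
component kernels on Gaussian fronto-central topographies, correlated
between-subject amplitudes, per-trial jitter, and spatially smooth 1/f
noise. Noiseless injection–recovery is exact by construction.

**Quantification.** Common-average reference; baseline correction
(response-locked ERN epochs use the window preceding their linked
stop-signal); condition averages and difference waves (unexpected =
easy-error − hard-correct); FRN as the most negative deflection of the
difference wave in 0–600 ms; N2 and ERN as trough-to-peak measures
(120–280 ms post-stop, 0–120 ms post-response).

**Statistics.** Global map dissimilarity between GFP-normalized maps,
`GMD = sqrt(mean((â − b̂)²))` ∈ [0, 2], with a within-subject
permutation (TANOVA) test; split-half reliability with the
Spearman–Brown correction `2r/(1+r)`; z-normalized bivariate regressions
between component amplitudes; behavioral summaries (accuracy, window
widths, post-feedback RT adjustment, stop performance, transfer).

## Worked example

```r
library(erpmon)

## one agent's session
log <- runSession(taskConfig(), agentParams(), seed = 1)
table(log$trial_type)
#> estimation       stop
#>        576        144

## synthetic epochs -> preprocessing -> component measures
eps <- prepareEpochs(generateEpochs(log, seed = 1))
measureFrn(eps, "unexpected")
#>        component subject hand channel amplitude_uV latency_ms method n_trials
#> 1 FRN.unexpected     s01 both     FCz    -8.200413   283.3333   peak       53
```

The FRN row says: this subject's unexpected-feedback difference wave
(infrequent error minus infrequent correct, 53 trials in its smaller
cell) reaches its most negative point, −8.2 µV, 283 ms after feedback at
electrode FCz. Amplitudes vary across subjects (between-subject SD
≈ 3 µV around the −5.62 µV generator mean); a cohort mean comes back to
the injected value:

```r
co <- simulateCohort(nSubjects = 24, seed = 1)
bs <- behaviorSummary(co)
bs$conditions[, c("condition", "hand", "percent_correct", "median_rtw_width")]
#>   condition  hand percent_correct median_rtw_width
#> 1   control  left        48.82812              200
#> 2      easy  left        69.09722              328
#> 3      hard  left        29.29688              120
#> 4   control right        50.43403              210
#> 5      easy right        71.48438              336
#> 6      hard right        27.95139              112
```

Accuracy sits at the staircase equilibria degraded by response-time
drift (easy ≈ 70% rather than the stationary 75%), and the equilibrium
window widths (~330 ms easy, ~110 ms hard) follow from the 140 ms
timing-noise SD. A full study — epochs for all 24 subjects, GMD tests,
reliabilities, regressions, JSON report — is one call:

```r
report <- runStudy(defaultRunConfig(profile = "fast", seed = 1))
report$reliability
report$regressions
```

## Layout

- `R/` — task simulation, layout/generator, quantification, topographic
  statistics, reliability/regression, orchestration (S4 classes
  `EpochSet`, `ErpAverage`, `PermutationResult`).
- `tests/testthat/` — unit, property and study-level suites with
  independent brute-force oracles in `helper-oracles.R`.
- `vignettes/performance-monitoring-erps.Rmd` — the model, the
  generator's assumptions and every numerical convention.
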