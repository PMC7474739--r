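---
title: "Directed frontoparietal connectivity from windowed spectral Granger causality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Directed frontoparietal connectivity from windowed spectral Granger causality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcnet)
```

## The analysis problem

gcnet studies how directed influence between frontal and parietal cortical
sources evolves over the course of a multi-phase cognitive trial. A trial is
1000 ms of pre-stimulus baseline followed by 9000 ms of task, split into
three phases (premise coding, premise integration, conclusion). The task
period is divided into 90 nonoverlapping 100 ms windows; within each window
a bivariate vector autoregression (VAR) is fitted to every
(frontal, parietal) source pair, and the frequency-domain (Geweke) Granger
causality

$$f_{Y \to X}(\omega) \;=\; -\ln\!\Big(1 - \frac{\Sigma_{Y|X}\,
  |H_{XY}(\omega)|^2}{S_{XX}(\omega)}\Big), \qquad
  \Sigma_{Y|X} = \Sigma_{YY} - \Sigma_{YX}\Sigma_{XX}^{-1}\Sigma_{XY},$$

is averaged over the theta (4–8 Hz) and gamma (30–60 Hz) bands. Here
$H(\omega) = (I - \sum_{k=1}^{p} A_k e^{-ik\omega})^{-1}$ is the VAR
transfer function, $S(\omega) = H(\omega)\Sigma H^*(\omega)$ the implied
cross-power spectral density, and $\Sigma_{Y|X}$ the partial covariance
that removes the instantaneous residual correlation. All causality values
are in nats (natural log).

Each window's causality is contrasted with the same pair's baseline-window
causality across trials; windows significantly above baseline (by
cluster-based permutation) become the 1-entries of a binary directed
network over the 40 region-of-interest pairs. The binary networks and the
raw causality matrices are summarized by three graph quantities:

* **causal density** — the mean directed causality over ordered pairs,
  $CD = \frac{1}{n(n-1)}\sum_{i \ne j} F_{x_i \to x_j}$;
* **characteristic path length** — $L = \frac{1}{n}\sum_i L_i$ with
  $L_i = \sum_{j \ne i} m_{ij}/(n-1)$, $m_{ij}$ the directed shortest-path
  length on the binary network;
* **causal flow** — per node, outgoing minus incoming influence
  (out-degree minus in-degree on a binary network).

Group differences in these metric series are assessed by a per-window
one-way ANOVA on subject-level values, and by phase-by-band summary tables
with Welch tests between bands.

Because the cohort EEG that motivates this design is not publicly
deposited, the package ships a first-class synthetic-data generator that
emulates the study's structure, and every claim the package makes about
its own procedures is validated against that generator or against
independent oracles.

## The synthetic-data generator

`trial_design()` fixes the montage (8 frontal + 5 parietal labelled
sources by default), the sampling rate, and the trial timing.
`coupling_scenario()` adds dynamics: each node is a damped oscillator — an
AR(2) block whose complex pole pair has argument $2\pi f_0/f_s$ (theta
nodes at 6 Hz, gamma nodes at 40 Hz) — and scheduled directed couplings
enter as lag-1 off-diagonal VAR coefficients that are exactly zero outside
their active interval. `build_tv_var()` assembles the piecewise-constant
coefficient schedule, rejecting any segment whose companion matrix has
spectral radius at or above 1, and `simulate_trial()` /
`generate_cohort()` iterate it with Gaussian innovations after a 2 s
discarded burn-in. All randomness is derived from a single master seed.

Default cohort sizes mirror the emulated study: one group of 20 subjects
with 20 trials each (400 trials) and one of 18 subjects totalling 380
trials.

### Why the default oscillator bandwidth is broad

The oscillator pole modulus `osc_r` controls the resonance bandwidth, and
its default (0.7) was chosen deliberately after a calibration analysis
that exposed a real tension:

* A genuine spectral *maximum* inside 4–8 Hz requires a pole modulus of
  roughly 0.95 or more at a 500 Hz sampling rate — a nearly integrated
  process whose autocorrelation persists across an entire 100 ms window.
* The analysis method, however, *assumes* that 100 ms windows are
  approximately stationary. At `osc_r = 0.95` the ADF/KPSS gate rejects
  the overwhelming majority of windows, and 50-sample VAR fits on such
  data are so noisy that a designed coupling of 0.4 is detected in well
  under half of its active windows, while strong couplings spill spurious
  causality into the reverse direction.

With `osc_r = 0.7` the autocorrelation decays within a few samples,
windows pass the stationarity gate, and the edge-detection procedure
recovers designed couplings reliably in the correct direction. The price
is that the node spectrum is then a broad low-frequency resonance rather
than a narrow theta peak; narrowband content remains available per
scenario (`coupling_scenario(osc_r = 0.96)`), and is exercised in the test
suite, where trial-averaged periodograms peak near 5 Hz.

### What the generator does and does not emulate

It emulates: band-tuned oscillatory sources, group- and phase-dependent
directed coupling, trial-to-trial variability, the retained-trial counts,
and (optionally, via `inst_cor`) instantaneous innovation correlation. It
does **not** emulate volume conduction or scalp mixing, 1/f background
spectra, artifacts, subject-level heterogeneity beyond sampling noise, or
nonlinear/nonstationary coupling. Passing validation on this generator
therefore demonstrates that the *procedures* behave as claimed on data
satisfying the method's assumptions — not that real EEG satisfies those
assumptions.

## Signal conditioning and the stationarity gate

The per-trial protocol is fixed and logged: zero-phase 1–60 Hz Butterworth
bandpass (4th order, forward–backward so group delay cancels), baseline
correction by the mean of the first 1000 ms, then per window:
detrend/demean, an ADF + KPSS stationarity gate, and — for failing
windows — exactly one first difference followed by re-detrending and
re-gating. Windows still failing are retained but flagged; windows that
are degenerate (zero variance) are excluded as unusable and propagate as
missing values, never as zeros.

Details worth knowing:

* The ADF and KPSS tests are implemented from their defining regressions
  (no unit-root package ships with this toolchain), with the standard 5%
  critical values: Dickey–Fuller $\tau_\mu$ interpolated in $1/n$, KPSS
  level statistic against 0.463 with a Bartlett bandwidth of
  $\lfloor 4 (n/100)^{1/4}\rfloor$. The ADF lag is fixed at 1 because
  automatic lag selection is unstable on 50-sample windows.
* The gate rule is the conservative conjunction (ADF rejects a unit root
  AND KPSS does not reject stationarity); `rule = "either"` is available.
  The two tests have complementary null hypotheses, which is why both are
  consulted.
* A measured caveat, documented rather than hidden: zero-phase filtering
  interacts badly with short-window VAR fits. On pure white noise, the
  1–60 Hz filter inflates the null window causality from about 0.02 to
  about 0.5 nats, because the filtered process needs a far longer
  autoregression than a 50-sample window can support. The permutation
  edge test is *calibrated* regardless (task and baseline windows share
  the inflation, and the null edge rate stays at its nominal level), but
  absolute causality values from filtered short windows should be
  interpreted as relative, not physical, quantities.

## Per-window causality estimation

Within each conditioned window, the VAR order is chosen by BIC over
1..`p_max` (default 3 — a bivariate VAR(3) keeps 12 coefficients against
~47 observations), with all candidate orders compared on the same
trimmed sample and ties broken toward the smaller order. The selected
model is refitted by least squares on the window's maximal sample; the
residual covariance uses the degrees-of-freedom denominator. Edges and
causal density use the bivariate (pairwise) spectral measure — the printed
equations of the source analysis are Geweke's bivariate form — while a
conditional *time-domain* estimator (`time_domain_gc(conditional = TRUE)`,
nested full-network regressions) is available as the alternative the
causal-density notation suggests. Conditional *spectral* causality would
require partitioned spectral factorization machinery that the analysis
never specifies, and is deliberately out of scope.

Numerical conventions: the frequency grid is 128 equally spaced points in
(0, Nyquist]; band membership is half-open ($\mathrm{low} \le f <
\mathrm{high}$); estimates below zero by at most $10^{-10}$ are clipped to
zero and counted; grid points with a numerically singular characteristic
matrix or nonpositive spectrum are masked; a fully masked window is
unusable. Both directions of a pair come from one fit.

The batch path through a cohort runs in compiled code (RcppArmadillo) for
speed — roughly 10 µs per window against ~4 ms for the reference R path —
and the test suite verifies that the two paths produce identical gate
decisions, orders, and spectra to 1e-8 on white noise, coupled
oscillators, near-unit-root data, and degenerate windows.

### The integral identity, and how it is checked

The mean of $f_{Y\to X}(\omega)$ over the full grid should equal the
time-domain log variance ratio $\ln(\hat\sigma^2_{restricted} /
\hat\sigma^2_{full})$. Two details make this check behave:

* the restricted autoregression uses three times the full order, because
  the implied marginal process of a VAR carries a moving-average part
  that a same-order truncation misses (measured: same-order truncation
  leaves up to 13% mismatch on bidirectional VAR(2) models; triple order
  brings the worst case under 3%, while very long restricted models
  re-inflate the variance);
* the random test processes carry lag-1 cross-coefficients of magnitude
  0.3–0.6, because a *relative*-error comparison is ill-posed when the
  true causality is near zero (clipping bias and independent sampling
  noise then dominate a vanishing denominator).

## Binary networks and the cluster permutation test

For each group, band and directed pair, the per-window task causality
(across trials) is contrasted with the pooled baseline-window causality by
a one-sided Welch $t$ (edges mean "significantly *above* baseline").
Windows past the pointwise $t$ threshold (5%) form contiguous clusters;
cluster mass (summed $t$) is referred to the permutation distribution of
the maximum cluster mass, with labels permuted *within trial* — under the
null, a trial's task- and baseline-window values are exchangeable. The
default 200 permutations bound the attainable cluster p-value at 1/201;
the count is configurable upward. Significant-cluster windows become 1s in
the adjacency stack; missing windows contribute no edge and are reported
in a coverage matrix.

Two conventions the analysis leaves open were resolved as follows: trials
are pooled per group (one network stack per group) rather than binarized
per trial and averaged; and baseline causality comes from the same
per-window estimator on the 10 baseline windows, so task and baseline
share estimation bias.

## Graph metrics

Shortest paths are computed by breadth-first search per source node;
unreachable pairs are marked missing, not given a number. For the
characteristic path length the unreachable-pair rule is configurable, and
the default counts unreachable pairs as 0 — the only rule under which a
sparse network can produce the sub-1 path lengths that the emulated
study's tables print (every counted pair otherwise contributes at least
1). The reachable-pair fraction is always reported alongside, and
`"exclude"` and `"harmonic"` rules are available. Causal flow uses the
standard out-minus-in definition, which the source analysis names but
never prints; it is labelled as such in outputs.

## Group statistics

The per-window ANOVA operates on subject-level causal density (each
subject's trial-averaged pair-mean causality per window). With two groups
it reduces to the squared pooled t statistic, which the suite verifies
against `stats::aov`. Reported significance spans require at least two
consecutive significant windows; p-values are uncorrected by default
(the permutation machinery already guards the edge tests; a
Benjamini–Hochberg switch is provided). Phase-by-band tables report
mean ± SD over the window-level group values within each phase — SDs
therefore describe variation over time, not subjects — with Welch tests
between bands and the conventional star thresholds (0.05, 0.01, 0.001).

Zero-variance cells are tie-handled explicitly: equal means give p = 1,
separated means with zero within-group variance are flagged degenerate.

## Designed group effect and its recovery

`group_effect_scenarios()` encodes the qualitative group contrast the
package is built to detect: stronger gifted-group theta coupling during
premise integration and the early conclusion (task time 3000–6500 ms),
weaker coupling late in the conclusion (7500–9000 ms), with the control
group mirrored. The default strengths are 0.3 versus 0.05 because the
short-window estimator's response to coupling strength saturates above
roughly 0.2 (measured response: mean theta causality 0.67 at zero
coupling, 0.80 at 0.10, 0.90 at 0.45) — a contrast of 0.45 versus 0.25, though nominally larger,
is invisible to it. These strengths are generator conventions, not claims
about cortex.

## Validation studies and problem sizes

The `*_study()` functions regenerate every validation quantity from
scratch and are what both the test suite and `scripts/acceptance.R` run:

* `gc_consistency_study()` — 20 random stable bivariate VAR(2) processes,
  5000 samples each; worst-case relative gap between the spectral
  integral and the time-domain ratio (tolerance 5%).
* `null_edge_rate_study()` — 200 no-coupling cohorts of 20 trials per
  group on a two-node montage; overall edge rate of the full binarization
  procedure (must stay at or below 0.075 at $\alpha = 0.05$).
* `direction_recovery_study()` — one 20-trial cohort with a single
  theta-band coupling of 0.4 active 3000–6000 ms; fraction of active
  windows detected (at least 0.8) and reverse-direction edge rate (at
  most twice $\alpha$).
* `graph_metric_oracle_study()` — 100 random 10-node digraphs against
  Floyd–Warshall, plus the exact 3-cycle and single-edge values.
* `group_effect_recovery_study()` — 20 cohorts (20 + 18 subjects, 6
  trials each, compact 2 + 2 montage); fraction of cohorts whose ANOVA
  significance spans cover at least 70% of the designed effect windows.
* `anova_type1_study()` — 200 Gaussian null replicates of the per-window
  comparison; false-positive rate within [0.03, 0.07].

The montage and trial counts of the heavier studies are deliberately
compact — they are chosen so a full validation pass completes in minutes
while keeping every statistical property (trial counts per group, window
count, permutation count) at its study value.

## Known limitations

* Absolute causality from filtered 50-sample windows is bias-inflated;
  all inference is relative to baseline or between groups.
* The bivariate measure does not distinguish direct from mediated
  influence; the conditional time-domain estimator is provided, but no
  conditional spectral decomposition.
* Narrowband (high-Q) sources and 100 ms windows are fundamentally in
  tension; analyses of strongly rhythmic data should consider longer
  windows than the default grid.
* Cohort-scale runs with the full 13-node montage and 780 trials are
  compute-intensive; the compiled kernel makes them feasible but not
  instant.
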