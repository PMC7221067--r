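---
title: "Methods: from CO2 traces to metabolic homeostasis and lifespan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from CO2 traces to metabolic homeostasis and lifespan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flymet)
```

## What the package computes

flymet turns single-fly flow-through respirometry recordings into
mass-independent metabolic rate and an activity index, asks whether a
group of flies holds its metabolic rate constant across activity levels
("metabolic-rate homeostasis"), and provides the survival-analysis
machinery used in fly aging studies: Kaplan–Meier curves, log-rank and
Gehan–Wilcoxon comparisons with multiple-testing correction, median and
maximum lifespan, and a double-mutant additivity report. A synthetic-data
generator with known ground truth makes the whole chain testable end to
end.

## The respirometry model

A fly sits in a flow-through chamber flushed with CO2-scrubbed air at an
STP-corrected flow rate (50 mL/min by default). The downstream infrared
analyzer samples CO2 (ppm), an activity analog, and chamber temperature
at 1 Hz. Each recording is an empty-chamber *baseline* window, a fly
segment of 20–50 min, and a second baseline window.

**Baseline drift.** The analyzer zero drifts slowly. We assume the drift
is linear over the recording and estimate it as the straight line through
the two points (center of pre-window, mean pre-window ppm) and (center of
post-window, mean post-window ppm). This two-point fit is the simplest
model consistent with a linear drift and has the exact property that the
corrected series averages to zero over each baseline window; a
least-squares fit over all baseline samples is available via
`baseline_correct(method = "ols")`. Negative corrected values are
retained — clipping them would bias every mean upward. For the same
reason the internal pipeline converts negative ppm excursions through the
chain (`allow_negative = TRUE`), while the user-facing
`flux_to_power()` rejects negative fluxes by default as a guard against
passing raw (uncorrected) data.

**Unit chain.** With excess CO2 in ppm and flow F in mL/min,

* V̇CO2 (µL/h) = ppm × 10⁻⁶ × F × 60 × 1000 = ppm × F × 0.06;
* at respiratory quotient RQ = 1 (ad libitum, carbohydrate-dominated
  catabolism) V̇O2 = V̇CO2, and power (µW) = V̇O2 × (16 + 5.164·RQ) J/mL
  × 10⁻³/3600 × 10⁶.

The oxyjoule coefficient (21.164 J/mL at RQ = 1) is a single explicit
constant (`oxyjoule_coefficient()`, overridable through
`joule_coefficient` everywhere), so alternates such as 20.1 J/mL are a
one-line change. At F = 50 mL/min, 1 ppm of excess CO2 is exactly
3.0 µL/h and 17.637 µW. Mass-independent MR divides power by live mass
(mg) raised to 0.856, the inter-specific scaling exponent for tracheate
arthropods; the exponent is a parameter (`mass_exponent`).

**Activity index.** The activity analog is reduced to its absolute
difference sum, ADS(k) = Σ|x(i) − x(i−1)|, and the index of a window of N
1-Hz samples is (ADS range)/N × 60 — the mean absolute first difference
per minute. The published formula "ADS range/N∗60" is ambiguous between
(range/N)·60 and range/(N·60); we adopt the former because it makes the
index invariant to the sampling duration, and no printed example anchors
the absolute scale. Only relative comparisons are affected; the parse is
a deliberate, documented choice. The index is invariant to constant
offsets of the analog (so analyzer zero does not matter) but not to gain;
recordings from one rig share a gain, and cross-rig normalization is the
user's responsibility.

**Segmentation.** The fly segment is tiled into consecutive
non-overlapping 300-s windows ("each point is a 5-min recording"); a
trailing partial window is dropped rather than down-weighted. Each window
yields (mean mass-corrected MR, activity index).

**Standard metabolic rate.** No standard operational definition exists in
the source literature for this assay, so flymet uses the conventional
lowest-running-average estimator: sliding 300-s windows at 1-s steps,
restricted to "quiescent" windows whose activity index lies in the lowest
0.2 quantile for that recording; the SMR is the minimum mean over those
windows. Both parameters are arguments and are echoed as attributes of
the result; if no window qualifies, the global minimum is returned with a
`fallback` flag.

**Homeostasis regression.** Segments are pooled across flies within a
group — matching the pooled scatter-plus-single-line presentation this
assay is normally given — and mean MR is regressed on activity index by
OLS. A mixed-effects extension (per-fly random intercepts) is an explicit
non-goal. The result carries slope, intercept, R², the two-sided t-test
p-value for the slope, and a 95% CI. The verdict is `"lost"` exactly when
p < α and the slope is positive: a significant *negative* slope is not
evidence that activity drives metabolic rate up, so it does not count
against homeostasis.

## The synthetic generator

`gen_resp_trace()` builds a recording as baseline level + linear drift +
Gaussian analyzer noise, plus, during the fly segment, the fly's signal
back-converted from power through the exact inverse of the unit chain.
Activity is a two-state telegraph process (rest/active; geometric dwell
times parameterized by a bout rate per minute and a mean bout duration)
with Gaussian accelerometer-like jitter only during active states —
reproducing the bout structure that makes the ADS range meaningful.

The activity-coupled power component is driven by the per-sample absolute
activity increment scaled to per-minute units (60·|Δa|), with the
increment zeroed at 300-s grid boundaries of the fly segment. This makes
every 5-min window's mean power equal `smr_uW + activity_coupling_uW ×
(that window's activity index)` *exactly*, so that on noise-free traces
the analysis chain recovers both ground-truth parameters to floating-point
precision — an exact-inverse property the test suite relies on. The
grid length is the `grid_s` field of `resp_synth_spec()` and should match
the `segment_s` used in analysis. Ground truth is stamped into the
trace's `truth` field so tests never re-derive it.

Survival cohorts use the Gompertz mortality model, hazard h(t) = a·e^(bt),
sampled by inverting S(t) = exp(−(a/b)(e^(bt) − 1)); b = 0 degenerates to
an exponential with rate a. Censoring is administrative (a fixed study
end) plus independent random loss — a fly lost with probability
`censor_prob` is censored uniformly before its death time, emulating
vial-change losses. Climbing trials are Gaussian heights clipped to
[0, 1].

What the generator does *not* emulate: chamber washout dynamics (the CO2
signal responds instantaneously to power), temperature dependence of MR,
diet, discontinuous gas exchange, or any genotype biology. Passing tests
therefore demonstrate that the *pipeline arithmetic and inference* are
correct under the stated statistical shapes, not that the generator is a
faithful fly.

### Default study conditions

Chosen once for realism and testability: 1800-s recordings with 180-s
baselines; baseline 5 ppm with 0.001 ppm/s drift; SMR 17.637 µW (the
1-ppm-excess fly, ≈ a 1-mg fly's resting output); bouts at 0.3/min
lasting 60 s on average; analyzer noise 0.5 ppm SD in simulation studies
(five times the nominal 0.1-ppm analyzer resolution, allowing for
whole-system noise); cohorts of 100 flies per group, inside the 61–149
range typical of fly lifespan experiments. Simulation studies in the
tests and the acceptance script use groups of 6 flies × 5 segments
(25-min fly segments), i.e. 30 pooled segments per group.

## Survival methods

Kaplan–Meier estimation delegates to `survival::survfit()` (ties by
simultaneous decrement; no jittering) and is re-shaped into a plain
tibble. Median lifespan is the first time S(t) ≤ 0.5; with heavy
censoring it is reported `NA` and flagged rather than extrapolated.
"Maximum lifespan" has no canonical definition, so every output carries
its definition tag: `top_decile_mean` (default; mean death age of the
longest-lived 10% of dying flies), `last_death`, or `percentile_90`
(linear-interpolation percentile). With fewer than 10 deaths the default
falls back to `last_death`, flagged.

The log-rank and Gehan–Wilcoxon statistics are computed directly from the
risk-set sums U = Σ w_j (d1_j − d_j n1_j/n_j) and the hypergeometric
variance, with w = 1 (log-rank) and w = n_j (Gehan–Breslow: early deaths,
when many flies are still at risk, get more weight). They are authored
here rather than delegated because `survival::survdiff()`'s ρ-family
implements Peto–Peto rather than Gehan weighting; `survdiff` serves as an
independent cross-check of the log-rank route in the tests, and a
brute-force risk-set enumerator is the oracle for both.

Multiple comparisons are corrected within each test family across the
requested pairs; Bonferroni is the default (the most conservative
reproducible choice), Holm is available. Time units (days vs hours, for
starvation assays) are declared per table, never inferred; both analyses
share the identical code path and the statistics are invariant to
monotone time rescaling.

The additivity report encodes the genetic-interaction logic for a double
mutant: *non-additive* when both singles differ from control (corrected
p < α) while the double differs from neither single; *additive-consistent*
when the double outlives and differs from both singles;
*inconclusive* otherwise. The verdict uses the corrected log-rank
p-values (over the five component comparisons) with medians for
direction; all component results are returned.

## Phenotype statistics

`dispatch_test()` reproduces the normality-gated convention: Shapiro–Wilk
per group; the parametric branch (pooled unpaired t-test, or one-way
ANOVA for > 2 groups) only when *every* group passes at `alpha_norm` —
one failing group switches the whole comparison to Mann–Whitney /
Kruskal–Wallis. Requiring all groups to pass is the conservative reading
of common practice. Variance homogeneity is deliberately not tested, and
the Welch correction is off by default to mirror the classical unpaired
t-test; both are one-argument changes. A constant group (zero variance)
is treated as failing normality. The gate decision and per-group p-values
are always in the output.

`two_way_anova_sidak()` fits the two-factor ANOVA with interaction and
compares levels of the first factor within each level of the second using
t contrasts on the pooled residual mean square, Sidak-adjusted
(p_adj = 1 − (1−p)^m) over all such comparisons; the tests cross-check
these contrasts against emmeans. `climbing_score()` reduces a 5-trial
negative-geotaxis session to the mean over trials of the mean per-fly
height — one scalar per vial session.

## Numerical choices and degenerate inputs

* Quantile computations (quiescence threshold, `percentile_90`) use R's
  default type-7 linear interpolation.
* Regression requires ≥ 3 points and a non-degenerate regressor; both are
  hard errors, as is a missing baseline window, a non-finite sample
  (reported with its index), or a sampling gap (reported with the first
  bad index).
* Rank-test variance terms with n_j = 1 are skipped (their variance is
  zero); a zero total variance yields statistic 0, p = 1.
* All generators draw through `withr::with_seed()`, so they are pure
  functions of (spec, seed) and never disturb the caller's RNG state.
* File writes are atomic (temp file + rename), and `run_pipeline()`
  serializes the resolved configuration next to its outputs; identical
  (config, seed) reruns are byte-identical.

## Problem sizes used in validation

Simulation studies are sized for desk-scale reproducibility: homeostasis
null calibration uses 1000 replicates of 30-segment groups (observed
type-I ≈ 0.05), power at coupling 0.5 µW/index-unit uses 300 replicates,
slope-bias estimation 500 replicates, survival-test null calibration 500
replicate pairs of n = 100 cohorts, and sampler validation n = 5000
(Kolmogorov sup-norm < 0.02) and n = 2000 (exponential median). The
headline regression outcomes of the original assay (slopes with
p ≈ 10⁻³–10⁻⁴, R² ≈ 0.3 from ~30 pooled recordings) depend on unreleased
raw recordings and are not targets; the package validates the machinery
by parameter recovery and calibration instead.

## Known limitations

Pooling segments across flies ignores within-fly correlation; with few
flies and many segments per fly the slope test can be anticonservative
with respect to between-fly heterogeneity the generator does not emulate.
No chamber washout deconvolution is applied, so rapid activity bursts are
smeared in real recordings in a way synthetic traces do not show. The
activity index is gain-sensitive across rigs. Parametric survival fitting
to real cohorts, Cox models, and interval censoring are out of scope.
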