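---
title: "Methods: latent profile allocation and treatment-outcome prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: latent profile allocation and treatment-outcome prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lpaoutcomes)
```

## The model

`lpaoutcomes` implements a person-centred pipeline for predicting
psychological-treatment outcomes from routinely collected service data of
the kind gathered by English IAPT (Improving Access to Psychological
Therapies) services. At its core is a latent profile model over nine
patient indicators measured at referral: four continuous (PHQ-9 depression
severity, 0–27; GAD-7 anxiety severity, 0–21; WSAS functional impairment,
0–40; age, 16–95) and five dichotomous (phobia caseness, female gender,
psychotropic medication prescription, welfare benefit receipt, non-white
ethnic group).

The population is modelled as a finite mixture of $C$ latent profiles.
Writing $\pi_x = P(X = x)$ for the prevalence of profile $x$, the
probability of an observed indicator pattern $y$ is the weighted average

$$P(Y = y) = \sum_{x=1}^{C} \pi_x \, P(Y = y \mid X = x),$$

with the class-conditional term a product over indicators under **local
independence**: a univariate normal density
$f(x_i) = (2\pi\sigma_{ij}^2)^{-1/2}\exp\{-(x_i-\mu_{ij})^2/(2\sigma_{ij}^2)\}$
for continuous item $i$ in profile $j$, and a Bernoulli mass
$\theta_{ij}^{y_i}(1-\theta_{ij})^{1-y_i}$ for binary items. New patients
are assigned a **posterior membership probability** for every profile by
Bayes rule,
$P(X = x \mid Y = y) = \pi_x P(Y = y \mid X = x) / P(Y = y)$,
evaluated in log space with log-sum-exp stabilization. The **primary
profile** is the posterior argmax and the **secondary profile** the
runner-up; argmax ties break toward the lower profile index so allocation
is deterministic.

Missing indicators (at most two of nine per case; worse cases are excluded
upstream) are marginalized exactly by omitting their factors from the
class-conditional product, which is the correct marginal likelihood under
local independence.

Continuous indicators are modelled on their raw instrument scales, not
standardized: the density above is stated on raw items, and raw-scale
parameters keep the shipped preset interpretable (a profile mean PHQ-9 of
19 is a clinical statement). Whether a deployed algorithm should
standardize first is a genuinely open choice; raw scales are this
package's convention.

## Estimation and model selection

`fit_em()` maximizes the observed-data likelihood by
expectation–maximization. Design choices, made for robustness against
degenerate components:

* **Initialization**: responsibilities are seeded from a k-means partition
  of all nine standardized indicators plus uniform perturbation; the best
  of `n_starts` (default 20) restarts by final log-likelihood is returned.
  Using all indicators rather than the continuous four makes restarts
  markedly more stable on eight-profile data.
* **Variance floor** $\sigma^2 \ge 10^{-4}$ and Bernoulli rates clipped to
  $[10^{-6}, 1-10^{-6}]$: prevents likelihood spikes on degenerate
  components; a floored indicator is reported in a warning record.
* **Convergence**: relative log-likelihood change below `tol` (default
  $10^{-7}$) or `max_iter` (default 500). The trace is monotone
  non-decreasing up to $10^{-8}$ slack (flooring can nick the guarantee).

`model_selection()` reports log-likelihood, parameter count
$(C-1) + C(2\,n_{\text{cont}} + n_{\text{bin}})$, AIC, BIC and the
relative entropy $1 - \sum_{i,j}(-p_{ij}\log p_{ij})/(n \log C)$ (defined
as 1 at $C=1$). `align_labels()` resolves label switching by exhaustive
optimal assignment on continuous-mean rows ($C \le 8$).

## Outcome calculus

National-reporting definitions, all on PHQ-9/GAD-7:

* caseness: PHQ-9 ≥ 10 or GAD-7 ≥ 8;
* reliable improvement: drop ≥ 6 (PHQ-9) or ≥ 4 (GAD-7) — the
  measurement-error thresholds;
* deterioration: rise ≥ 6 (PHQ-9) or ≥ 4 (GAD-7);
* recovery: caseness at baseline, below caseness on both scales at end of
  treatment;
* reliable recovery: recovery plus reliable improvement;
* attrition: dropped out or declined after more than two sessions.

The improvement wording "on either scale" is read as PHQ-drop ≥ 6 **or**
GAD-drop ≥ 4. By default the national no-reliable-increase clause is also
applied, so improvement and deterioration are mutually exclusive
(`rule = "strict"`); `rule = "either"` restores the literal reading.
Whether deterioration should symmetrically exclude a simultaneous reliable
decrease is unstated in the source definitions; the literal either-scale
reading is implemented for deterioration. The end-of-treatment score is
the last observed score of the episode, the routine-outcome-measurement
convention.

Inclusion requires baseline caseness, at least two sessions with a final
score, and at most two missing indicators. Exclusion reasons are tallied
with fixed precedence (missingness, then sessions, then caseness) so
staged flow counts are reproducible.

## Stratified outputs and odds ratios

Between-profile and between-arm odds ratios are computed from 2×2 tables
with the Woolf (log-scale Wald) 95% interval and the Haldane–Anscombe
+0.5 correction when a cell is zero. For a two-level comparison this is
identical to the exponentiated logistic-regression coefficient (verified
against a `glm` oracle to $10^{-6}$ in the tests), and it is fully
specified without modelling choices. No multiple-testing adjustment is
applied, matching the unadjusted intervals the approach is meant to
mirror; strata below `min_cell` (default 10, configurable — the source
analyses dropped strata "too small to analyse" without stating a rule)
are suppressed.

## Propensity-matched treatment comparisons

Episodes are classified `LI`/`HI`/`mixed` (mixed = stepped up or down,
excluded from intensity contrasts). The main modality is the last
session's modality provided the episode is single-intensity and that
modality covers strictly more than half of all sessions.

The propensity score is a logistic regression of arm on the posterior
membership probabilities (the last dropped — the eight sum to one) plus an
intercept. Matching is greedy 1:1 nearest-neighbour: treated cases in
descending score order, nearest control within a caliper of 0.001 on the
probability scale (boundary inclusive, ties to the lower control index),
with replacement by default. The smaller arm is matched into the larger —
this maximizes retained pairs; the source procedure is silent on
direction. Greedy order-dependence is resolved by the deterministic
descending-score rule rather than trying to replicate any particular
legacy implementation bit-for-bit. Unmatched treated cases are dropped
before outcome tabulation and counted in the reported loss fraction.

A caveat the tests quantify: with replacement, a control used $k$ times
contributes $k$ counts to the 2×2 table, so the Woolf interval's
independence assumption is mildly violated and coverage of a known odds
ratio dips below nominal as control reuse grows. In the package's
simulation check (true OR 2.0, ~2000 pairs), a 1:4 control pool keeps
duplication near 18% and coverage at 92/100 replicates; a 1:2 pool drops
coverage to roughly 0.90.

## The synthetic cohort generator

`default_preset()` is a *stated world*, not a fit: no numeric parameters
of the original deployed profile model were ever published, so the preset
encodes the published qualitative profile descriptions with fixed numbers.

* **Prevalences** are the published ones: 17.6, 24.1, 3.04, 4.92, 9.58,
  8.21, 9.64, 22.91 per cent (the seventh profile is printed only as
  "nearly 10%" and takes the remainder so the weights sum to one).
* **Indicator parameters** satisfy the published orderings: LP7 most
  severe on both scales; LP3 oldest and least severe; LP4 older with
  moderate severity and marked impairment; LP6 with depression exceeding
  anxiety by several points; LP8 youngest with the highest female and
  non-white rates; LP1/LP2 younger and milder, LP2 the most prevalent.
  Within those constraints the draft parameters were spread until the
  generating model's relative entropy reached 0.81, the separation range
  expected of a profile solution deployed for per-patient allocation
  (a first draft at entropy 0.68 would not describe a usable deployed
  algorithm).
* **Treatment assignment** is confounded by design: the per-profile
  high-intensity probability rises monotonically with the profile's mean
  PHQ-9 (0.15 for the mildest to 0.75 for the most severe), so naive
  LI-vs-HI contrasts are biased and the matching stage has real work to
  do. Modality is drawn within intensity (LI: guided self-help 70%,
  computerized CBT 30%; HI: CBT 55%, Counselling 35%, IPT 10%); 10% of
  multi-session episodes are stepped between intensities; 25% of episodes
  are single-session (consultation only, no outcome). A quarter of
  episodes keep iid per-session modality draws so the strict-majority
  main-modality rule genuinely excludes cases.
* **Outcomes**: end-of-treatment scores are baseline plus a normal change
  whose mean depends on profile × modality (CBT most effective, LI
  modalities least) and whose SD is profile-specific, rounded and clipped
  to instrument ranges. The change means and SDs were calibrated by
  simulation so that per-profile reliable-recovery rates span roughly
  0.15–0.75 and deterioration roughly 0.02–0.20, with LP4/LP7 the
  best/worst recovery and LP6 then LP3 the highest deterioration — the
  published heterogeneity. Cases whose *secondary* profile under the
  generating model is LP6 receive an additional +3/+2 mean shift on
  PHQ-9/GAD-7 change, planting the secondary-profile deterioration signal
  the sub-profiling tables are designed to detect.
* **Attrition** probabilities range 0.13–0.35 by profile, lowest in the
  older profiles. Missingness (default 2% per non-score indicator) is
  injected only into the seven non-score indicators, since the cohort
  definition requires baseline PHQ-9/GAD-7; some cases exceed the
  two-missing cap so the missingness exclusion is exercised.
* Five equal-weight year labels emulate five financial years; the
  generator is time-homogeneous, so yearly prevalence and outcome
  stability checks have a known null.

What a green test on this world does **not** establish: recovery of the
real deployed model's parameters (never published), realistic
within-profile covariance (local independence holds by construction in
the generator), therapist or service effects, waiting times, or
longitudinal score trajectories. Scores are integer-rounded and clipped,
so the Gaussian mixture is — deliberately, as in practice — slightly
misspecified; this contributes a small (~0.01–0.02) bias to recovered
weights and means.

## Numerical choices

* Posteriors and log-likelihoods use log-sum-exp; a case with all class
  likelihoods numerically zero raises an out-of-support error rather than
  returning NaN.
* The matching caliper comparison is boundary-inclusive with a $10^{-12}$
  float guard.
* All generator randomness derives from one root seed via a fixed linear
  stage-seed map, so every artifact is byte-reproducible from
  (config, n, seed).
* JSON model files round-trip parameters to $10^{-12}$; JSON is used for
  configuration as a YAML-compatible subset.

## Known limitations

* Label alignment is exhaustive and limited to $C \le 8$.
* The EM recovery tolerance of 0.15 on continuous means is attainable for
  well-separated two-profile data at $n = 2000$ but **not** for the
  eight-profile preset at $n = 5000$: the smallest profile holds 3.04% of
  cases, so its mean estimate carries a sampling SD near 0.25 regardless
  of implementation quality. The corresponding acceptance check is kept
  at its stated tolerance and fails honestly.
* Between-sample z statistics for the baseline proportion rows of the
  published comparison table cannot be reproduced from the printed
  numbers (their percentage denominators differ from the printed column
  n); those rows are flagged `reproducible = FALSE` and excluded from
  reproduction checks, as is the endpoint WSAS t, which matches neither
  pooled nor Welch forms from the printed summaries (likely a different
  per-item n).
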