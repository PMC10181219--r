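---
title: "Inclination analysis of clinical biomarker trajectories: model, choices, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inclination analysis of clinical biomarker trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(inclinr)
```

## The problem and the model

Primary-care records measure common biomarkers at clinical encounters, not
on a sampling grid. Whether a patient's systolic blood pressure, HbA1c or
lipids are *heading somewhere bad* is a question about the path of the
series, not about its average. Inclination analysis answers it in three
stages.

**1. Local states.** After midpoint oversampling (each of the `N − 1`
inter-reading intervals is halved; the inserted sample takes the mean of
its neighbours, giving `2N − 1` samples), a window of `m` consecutive
samples ending at sample `k` is scored as
`Xs = Σ_{i=1}^{m−1} Δ_i w_i`. `Δ_i` measures the change of one consecutive
pair — the raw difference, the slope over real time, the sign of the
change, or the pair's signed share of the series' total trapezoid area —
and `w_i ∈ [1, 2]` weights it by where the later value of the pair sits
relative to the biomarker's clinical thresholds. The window is labeled
survival (`+`) when `Xs < 0` and collapse (`−`) otherwise.

**2. An absorbing chain over state sequences.** Length-`m` runs of local
states are the states of a Markov chain with `2^m` sequences. A sequence
containing at least `m⁻` collapse states is followed by a collapse state
with probability 1 (symmetrically `m⁺` for survival); otherwise the next
local state is collapse with probability `r⁻`. With the defaults
`m⁻ = m⁺ = m` and `r⁻ = 0.5`, exactly two sequences — all-collapse and
all-survival — are absorbing, and the limiting matrix `Z_inf = Z^l`
(computed by repeated squaring, `l = 10,000`) holds each sequence's
absorption probabilities.

**3. The inclination index.** The observed distribution `q_c` of
overlapping length-`m` state runs is propagated through `Z_inf`; the mass
landing on the all-collapse sequence is `P_c⁻`. Dividing by the
uniform-prior value `P⁻` (which equals 0.5 whenever `r⁻ = 0.5`, for any
`m`; the package asserts this for `m ≤ 5`) gives the index `I ∈ [0, 2]`.
`I > 1 + δ` predicts collapse and `I < 1 − δ` survival; inside the band the
series is split into its first and last `⌊L/2⌋` local states and the half
with the higher collapse share decides (ties go to survival).

The method assumes that a biomarker's clinical meaning is monotone in its
value on each side of a normality threshold, that the supplied cut-offs
(min, low, normality, high, max) are correct for the measurement unit used,
and that readings are frequent enough — at least five per biomarker — for
the state-run distribution to be informative.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `m` | 3 (4 in variant 6) | window length in samples; larger `m` means fewer windows from the same series and `2^m − 2` unstable sequences to estimate over |
| `delta_scheme` | sign (variant 7) | pair-change measure; slope and integral-ratio use real fractional-day spacing |
| `weight_scheme` | linear between low/high thresholds | clinical weighting of each pair, in [1, 2] |
| `delta_band` δ | 0.1 | half-width of the no-clear-inclination band around I = 1, absorbing estimation noise in `q_c` |
| `r_minus` | 0.5 | sub-critical transition probability; 0.5 makes the prior symmetric and `I = 2 P_c⁻` |
| `m_minus`, `m_plus` | `m` | critical levels; equal to `m` they leave only the two pure sequences absorbing |
| `power_iterations` `l` | 10,000 | matrix power approximating the limiting matrix |
| `min_readings` | 5 | eligibility threshold on original readings |
| `lead_days` | 365 | cases contribute only readings up to this lead window before onset |

The eight preset variants (0–7) are frozen combinations of `m`, the delta
scheme and the weight scheme; variant 0 is the original unweighted
difference formulation, variant 7 the threshold-weighted sign formulation
used as the package default.

## Numerical and design choices

* **`Xs = 0` maps to collapse.** The survival condition is strictly
  `Xs < 0`; a perfectly flat window therefore counts as collapse. This is
  deliberate (no improvement is not improvement) and surfaces in degenerate
  fixtures: a constant series at the normality threshold is predicted
  collapse.
* **Increase-good biomarkers (HDL) use a mirror transform.** Delta
  contributions are negated and the weight interpolation uses the
  reflected position `1 − p`, so an HDL rise at a healthy value mirrors a
  blood-pressure fall at a healthy value. One rule set then serves the
  whole panel.
* **Integral-ratio sign.** The area fraction of a pair segment is always
  positive, so it is given the sign of the local difference; otherwise the
  scheme could not distinguish increase from decrease.
* **Weight evaluation point.** Weights are evaluated at the later sample of
  each pair; positions outside the interpolation bounds are clamped to the
  [1, 2] endpoints.
* **Sequence distribution.** `q_c` uses overlapping runs with shift 1, the
  same shift the chain itself evolves by.
* **Tie-break halves.** For an odd number of local states the middle state
  belongs to neither half, keeping the two compared percentages on equal
  denominators; equal percentages decide survival.
* **Critical-level conflicts.** Configurations where some sequence
  satisfies both critical conditions at once are rejected outright rather
  than resolved by precedence.
* **Limiting matrix.** Repeated squaring gives exactly `Z^10000` up to
  floating error; the test suite checks it against an independent linear
  solve of the absorption system `(I − Q) B = R` to `1e−9` for `m ≤ 5`.
* **Same-day readings** are rejected as duplicate timestamps; callers
  aggregate them first. Dates become fractional days internally.
* **Decision trees.** The benchmark uses CART (`rpart`) with `maxdepth = 3`
  and `cp = 0` so the depth limit, not cost-complexity pruning, is the
  capacity control; remaining controls are `rpart` defaults. AUC uses the
  tree's leaf class fractions as scores. Both feature modes reuse the same
  seeded stratified splits, so their comparison is paired, and the default
  comparison test is a paired t-test.

## What the synthetic generator emulates

The source data for this kind of analysis (EMR extracts) cannot be
redistributed, so validation rests on a generator that emulates its
structure: nine panel biomarkers per patient, five to seven readings each,
gamma-distributed gaps (mean 120 days, sd 60, at least one day), linear
drift expressed in fractions of the biomarker's low–high range per year,
Gaussian measurement noise on the same scale, and values clamped to the
observable [min, max] range. Ground truth is defined from the noiseless
trajectory — the drift direction, interpreted through the biomarker's
improvement direction — which gives an objective recovery target that
physician-style labels would not.

The labeled validation set alternates two archetypes of how a clinician
recognizes a worsening biomarker: steep trajectories crossing a large part
of the acceptable range, and mildly drifting trajectories seated on the
matching side of the normality threshold. The second archetype is where
threshold-aware weighting earns its keep: an unweighted difference score
sees only noise there, while the weighting converts position information
into the correct state. Cohorts with planted group patterns anchor each
trajectory at its mean sampling time, which makes the noiseless per-series
average independent of the drift — so average-value features carry
essentially no group signal and the contrast between state features and
average features is attributable to the trajectory information alone.

What the generator does *not* emulate: medication confounding (e.g.
statins lowering LDL in future cases), missing biomarkers, measurement
unit drift, regime switches, or correlated noise across biomarkers.
Passing recovery tests therefore shows the machinery decodes the signals
it models, not that real cohorts behave this way.

## Problem sizes used by the tests

The suite exercises oversampling laws up to `N = 50`; transition models up
to `m = 5` (32 sequences); 1,000 random windows for the telescoping
identity; 40-patient (360-series) validation sets, replicated over five
generator seeds for the noise condition so the reported accuracy is a mean
rather than one draw; and a 349 + 349 planted cohort with 40 hold-out
shuffles for the classification benchmark. These sizes mirror the study
design the package addresses while keeping the default check fast.

## Known limitations

* The index saturates at 0 and 2 for unanimous state series, so ranking
  within clearly-collapsing patients is not meaningful.
* Series barely above the eligibility threshold estimate `q_c` from as few
  as five runs; the δ band and tie-break exist precisely because this
  estimate is coarse.
* Tie-break decisions are low-confidence by construction and are flagged
  (`tie_break_used`) so downstream users can treat them separately.
* The chain's parameters are fixed a priori, not learned; nothing in the
  package fits `r⁻`, the critical levels, or the thresholds to outcomes.
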