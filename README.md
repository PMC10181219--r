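# inclinr

Inclination analysis of longitudinal clinical biomarkers: predicting whether
an irregularly sampled biomarker trajectory is heading towards long-term
clinical worsening ("collapse") or improvement ("survival"), and using those
per-biomarker predictions as features for chronic-disease onset models.

Routine primary-care records hold repeated measurements of common biomarkers
— BMI, blood pressure, fasting glucose, HbA1c, lipids — taken at uneven
intervals. `inclinr` is aimed at biostatisticians and clinical-informatics
researchers who want a trend summary of such trajectories that is
path-dependent (it looks at the sequence of local ups and downs, not just
start and end), threshold-aware (an increase at a clinically bad value
counts for more than the same increase at a good value), and explainable.

## The method

For a series `x(1..N)` (densified to `2N − 1` samples by midpoint
oversampling), each sliding window of `m` samples is scored as

    Xs = Σ_i Δ_i · w_i ,   i = 1, …, m − 1

where `Δ_i` measures the local change of a consecutive pair (difference,
slope, sign, or signed area fraction) and `w_i ∈ [1, 2]` weights it by the
clinical position of the later value relative to the biomarker's cut-off
thresholds (min/low/normality/high/max). The window's local state is
survival (`+`) if `Xs < 0`, collapse (`−`) otherwise. Eight preset scoring
variants (0–7) combine these choices; variant 7 (`m = 3`, sign deltas,
weights linear between the low and high thresholds) is the default.

The empirical distribution `q_c` of length-`m` state sequences is then
propagated through an absorbing Markov chain over the `2^m` sequences —
built from critical levels `m⁻ = m⁺ = m` and transition probability
`r⁻ = 0.5`, with limiting matrix `Z_inf = Z^l`, `l = 10,000` — giving the
collapse probability `P_c⁻` (Eq. `P_c = Z_inf × q_c`). The inclination index

    I = P_c⁻ / P⁻  ∈ [0, 2]

compares it with the uniform-prior baseline `P⁻ = 0.5`. `I > 1 + δ`
predicts collapse, `I < 1 − δ` survival (δ = 0.1), and inside the band a
half-series tie-break compares the collapse share in the first and second
half of the local-state series.

The package also provides cohort analytics (per-group collapse rates with
chi-square tests, 0–7 similarity scores against the case-typical pattern),
a depth-3 decision-tree benchmark comparing state features with
average-value features over 40 stratified 75/25 hold-out shuffles, a
synthetic EMR-like cohort generator with known ground truth, and a thin
command-line interface (`inst/cli/inclinr.R`).

## Worked example

```r
library(inclinr)
sbp <- default_panel()$sBP
s <- biomarker_series("sBP", c(0, 90, 200, 290, 400),
                      c(128, 135, 141, 150, 158))
summary(inclination(s, sbp))
#> <inclination> sBP (variant 7): collapse
#>   index I = 2.000 (Pc- = 1.000, P- = 0.500)
#>   readings: 5 original -> 9 oversampled -> 7 local states
#>   local states: -------
#>   observed sequence distribution:
#>     ---  1.000
```

Five systolic blood-pressure readings rising from 128 to 158 mmHg over 400
days are oversampled to nine samples; every length-3 window scores
positive (a rise above the 120 mmHg normality threshold is weighted
towards 2), so all seven local states are collapse, the observed sequence
distribution is a point mass on `---`, and the index reaches its maximum
I = 2: a clear collapse prediction.

On a synthetic labeled validation set the threshold-weighted variant
recovers planted truths well even under noise:

```r
lab <- labeled_validation_set(6, noise_sd = 0.05, seed = 3)
version_performance(lab, inclination_config(7))$overall
#>    accuracy sensitivity specificity         ppv
#>   0.9444444   0.9629630   0.9259259   0.9444444
```

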