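# facedamp

Analysis toolkit for studying **cardiovascular emotional dampening (CED) in
the production of facial emotional expressions** — the hypothesis that
people with elevated resting blood pressure pose the six basic emotions
less accurately and less intensely than normotensive people.

The package is written for researchers who have, for each participant,

1. repeated blood-pressure readings (4 per day over 2 days),
2. a certified human coder's FACS Action-Unit (AU) intensities (integer
   0–5) for one posed photograph per emotion, and
3. an automated coder's output in the OpenFace column dialect
   (`AU01_r … AU45_r`, continuous 0–5, with `success`/`confidence`),

and who want the full analysis chain: JNC-7 blood-pressure stratification,
prototype-based emotion classification and accuracy scoring, expression
intensity indices, a five-index human–machine agreement panel, and
group-level inference. Because such datasets are rarely shareable
(photographs of faces), a synthetic-study generator with known ground truth
is a first-class component, used for end-to-end validation and power/type-I
simulations.

## The model and statistics

**BP stratification.** The first reading of each day is discarded (cuff
first readings run high) and the remaining six readings averaged. JNC-7
categories: normotensive (SBP < 120 and DBP < 80), prehypertensive
(SBP 120–139 and/or DBP 80–89), stage-1 hypertensive (SBP 140–159 and/or
DBP 90–99); stage-2 levels are flagged out of range.

**Accuracy.** An expression is *accurate* when the coder's emotion label
matches the intended emotion. Labels derive from prototypical AU
combinations (happiness = AU6+AU12+AU25, etc., EMFACS-style and
user-overridable). The classifier scores each emotion by template coverage
minus an off-template penalty,

    s(e) = |A ∩ P_e| / |P_e| − β · |A \ P_e| / max(|A|, 1),

with `A` the AUs active at or above τ_active = 1 (FACS trace level) and
β = 0.5; below s_min = 0.5 (or with no active non-blink AU) the face is
neutral.

**Intensity.** Over the coded emotion's prototype AUs: mean of all relevant
AUs, mean of active (non-zero) AUs — the headline index — and the maximum
AU intensity.

**Agreement panel.** Per image, over the 17-AU comparison set, with machine
values binned to 0–5 (round half away from zero): percent agreement,
Cohen's κ (observed marginals), Gwet's AC1 (full 6-category scale),
ordinal Krippendorff's α (coincidence matrix, ordinal metric), and
ICC(3,1) (two-way mean squares; consistency by default, on the unbinned
machine values). Undefined indices (e.g. both raters constant) propagate
as `NA`, never as 0.

**Inference.** One-way ANCOVAs of per-participant accuracy (0/100) on BP
group, controlling for age, gender, and education, with partial
η² = df₁F/(df₁F + df₂) and Bonferroni subset letters; Pearson chi-square
for gender composition; one-way ANOVA recomputable from printed (n, mean,
SD) summaries; partial correlations of SBP/DBP with accuracy; and a priori
sample size from the noncentral F distribution
(power = P(F′(k−1, N−k−c, λ = f²N) > F_crit)).

## Worked example

```r
library(facedamp)

study <- generate_study(synth_config(seed = 7))   # 74 participants, 518 images
run   <- run_pipeline(study$participants, study$human, study$machine)

run$accuracy$table[, c("emotion", "normotensive", "prehypertensive",
                       "hypertensive_stage1", "statistic", "partial_eta2",
                       "letters")]
#>     emotion normotensive prehypertensive hypertensive_stage1 statistic partial_eta2 letters
#> 1 happiness         97.0            95.2                  95   0.00926     0.000272   a/a/a
#> 2   sadness         81.8            47.6                  20   5.93        0.149      b/ab/a
#> 3      fear         54.5            19.0                   5   6.08        0.152      b/a/a
#> 4     anger         69.7            47.6                  45   0.000194    0.0000057  a/a/a
#> 5  surprise         90.9            57.1                  10  21.3         0.386      c/b/a
#> 6   disgust         57.6            52.4                  55   0.131       0.00383    a/a/a
#> 7   neutral        100.0           100.0                 100   0           0          a/a/a
```

Accuracy percentages per BP group sit beside the ANCOVA F (`statistic`,
df 2 and 68 here), its partial η², and subset letters (groups sharing a
letter do not differ at α = .05 after Bonferroni correction): under this
seed's generative truth, sadness, fear and surprise are dampened with
rising BP while happiness is preserved — visible both in the group means
and in the letters.

```r
run$agreement[run$agreement$emotion == "sadness",
              c("bp_group", "n", "percent_agreement_mean", "kappa_mean",
                "ac1_mean", "alpha_mean", "icc_mean")]
#>              bp_group  n percent_agreement_mean kappa_mean ac1_mean alpha_mean icc_mean
#> 1        normotensive 27                   87.1      0.584    0.863      0.792    0.845
#> 2     prehypertensive 10                   85.3      0.536    0.843      0.734    0.769
#> 3 hypertensive_stage1  4                   88.2      0.547    0.876      0.635    0.606
```

`n` counts retained trials (accurate poses only), so it shrinks with BP —
itself a dampening signature. Raw percent agreement stays high while κ is
markedly lower: the prevalence of zero-intensity AUs depresses
chance-corrected agreement (the kappa paradox), which the panel makes
visible by reporting κ and the prevalence-robust AC1 side by side:

```r
h <- c(rep(0, 15), 1, 0); m <- c(rep(0, 16), 1)   # one trace AU each, mismatched
percent_agreement(h, m)   #> 88.2
cohens_kappa(h, m)        #> -0.063
gwets_ac1(h, m)           #> 0.88
benchmark_agreement(0.62, "ac1")  #> "acceptable"
```

Sample-size planning for the group ANCOVA:

```r
required_n_ancova(f = 0.50, alpha = 0.05, power = 0.95,
                  k_groups = 3, n_covariates = 3)
#> [1] 66
```

`plot_group_accuracy()`, `plot_agreement_indices()`,
`plot_intensity_profile()` and `autoplot()` on an ANCOVA fit give ggplot
views of each result table.

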