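---
title: "Methods: measuring expression dampening under elevated blood pressure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: measuring expression dampening under elevated blood pressure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(facedamp)
```

## The measurement problem

Cardiovascular emotional dampening (CED) describes blunted emotional
responsiveness in people with elevated resting blood pressure. facedamp
operationalises the *production* side of that hypothesis: participants pose
the six basic emotions plus neutral; each photograph is coded at the
Action-Unit (AU) level by a certified FACS coder (integer intensities 0–5,
the A–E scale) and by an automated detector emitting continuous 0–5
estimates for 17 AUs. The analysis asks whether accuracy and intensity of
the posed expressions fall as blood pressure rises, and how far the two
coders agree.

This vignette documents the model choices, the tunable parameters, the
synthetic-data generator that stands in for non-shareable photographs, and
the numerical decisions — including the points where the design was
genuinely open and we had to pick.

## Blood-pressure stratification

Four readings per day over two days; the first reading of each day is
discarded (automated monitors read high on the first inflation) and the six
remaining readings averaged. JNC-7 categories apply to the means:
normotensive requires *both* SBP < 120 and DBP < 80; prehypertension and
stage-1 hypertension are "and/or" bands (120–139 / 80–89 and 140–159 /
90–99 mmHg). Two decisions:

* **Higher stage dominates.** The and/or clauses overlap (e.g. SBP 135 with
  DBP 92); the stage-1 test is applied before the prehypertension test.
* **Out-of-range flagging.** A mean at stage-2 level (SBP ≥ 160 or DBP ≥
  100) is flagged `out_of_range` rather than forced into stage 1, because
  the study design recruits only up to stage 1. The out-of-range test is
  applied immediately after the normotensive test; this keeps the category
  monotone in both pressures (raising a pressure can never lower the
  category), which the literal "check stage 1 first" ordering would violate
  for, say, SBP 165 / DBP 80.

## Prototype classification and accuracy

Only the happiness prototype (AU6+AU12+AU25) is fixed by convention in the
source methodology; the remaining defaults are EMFACS-style sets
(sadness {1,4,15}; fear {1,2,4,5,20,26}; anger {4,5,7,23}; surprise
{1,2,5,26}; disgust {9,15,16}), overridable from a plain-text file via
`read_prototype_table()`.

How a human coder resolves a blended AU pattern into one label is not
formalised anywhere; the package's scoring rule is a deterministic,
auditable stand-in, not a reconstruction of coder judgement:

* an AU is *active* at intensity ≥ τ_active = 1, the FACS trace level —
  any trace counts as present;
* score = coverage of the prototype minus β · (share of active AUs that are
  off-template), β = 0.5. The rule reduces to exact match on clean
  prototypes (score 1 iff all and only the prototype AUs are active) and is
  bounded in [−β, 1];
* neutral is returned when no AU except AU45 is active (a blink is not an
  expression) or when the best score is below s_min = 0.5;
* ties break by higher mean intensity over the tied prototypes' AUs, then
  by a fixed emotion order, so classification is total and deterministic.

A trial is *accurate* when the coded label equals the intended emotion, and
only accurate trials enter the intensity and agreement analyses (the
retention rule). This is conservative: it shrinks cell sizes in the
elevated-BP groups — visibly so in the `n` column of the agreement table —
which is itself part of the dampening phenomenon.

## Intensity indices

Three summaries over the coded emotion's prototype AUs: `mean_all` (all
relevant AUs), `mean_active` (non-zero AUs only; the headline index, since
zero simply means the AU was not recruited), and `max_au`. For neutral
there is no prototype; the indices are computed over the full AU set.
`mean_all ≤ mean_active ≤ max_au` whenever anything is active.

## The agreement panel

Five indices are reported side by side because each fails differently:

| index | scale handling | chance model |
|---|---|---|
| percent agreement | binned machine (0–5) | none |
| Cohen's κ | binned | observed marginals per rater |
| Gwet's AC1 | binned | mean marginals over the full Q = 6 scale |
| Krippendorff's α (ordinal) | binned | coincidence matrix, ordinal metric |
| ICC(3,1) | unbinned machine by default | two-way mean squares |

Machine values are binned by rounding half away from zero and clamping to
[0, 5]; the categorical indices are undefined on continuous input, while
the ICC is not, so it uses the raw values (a `bin_icc` switch exists).
AC1's chance term deliberately uses all six scale categories, not just
observed ones — that is its canonical definition and the source of its
prevalence robustness; κ uses observed marginals, its canonical form.
ICC(3,1) is canonically a *consistency* coefficient, though it is sometimes
described as absolute agreement in a fixed-effects model; both variants are
implemented (`icc_variant`), consistency being the pipeline default, and
the absolute variant penalising a constant shift between raters.

Undefined values — both raters constant (κ, AC1), no expected disagreement
(α), no between-unit variance (ICC) — propagate as `NA`, are excluded from
group means, and are counted per cell in the run log. Treating them as 0
would bias group means downward exactly in the sparse cells where the
question is most delicate.

The comparison AU set defaults to the intersection of the AUs coded by both
raters — in practice the 17-AU intensity set of the automated coder's
output dialect, since the human codes all 45 AUs. The per-cell SDs of the
agreement table are across participants (trials), not across AUs.

### The kappa paradox

When most AUs are inactive for both raters, percent agreement is high by
construction while κ's chance term approaches 1, so κ collapses or turns
negative even with only one or two mismatched trace activations. The panel
is designed to expose this: `simulate_sparse_codings()` generates the
regime directly — trace-level activations (intensity 1, activation
probability 0.1 across 17 AUs) rated by a strongly attenuating machine
(gain 0.4, additive noise SD 0.35, dropout scale 0.9). These settings were
fixed analytically: with that transform the probability that the machine
reproduces a human trace as a binned 1 is ≈ 0.26, giving an expected
per-trial κ around 0.25 while expected percent agreement stays ≈ 92% and
AC1 ≈ 0.9. The acceptance suite verifies exactly this separation over
1,000 simulated codings.

## Group-level inference

* **ANCOVA.** Per-participant accuracy enters as 0/100 (reproducing the
  percentage scale of group accuracy tables; the original coding is not
  stated anywhere, so this is a package choice), modelled as
  `accuracy ~ group + age + gender + education` with no interactions —
  classic ANCOVA, so Type II and III group tests coincide. Gender enters
  as a 0/1 indicator. The group F compares full and covariates-only
  residual sums of squares with df (k−1, N−k−c); partial η² =
  df₁F/(df₁F + df₂). Adjusted means are predictions at the covariate
  sample means. Saturated cells (e.g. an emotion every participant poses
  accurately) have no residual variance; the group F is then reported as 0
  (nothing left to explain) rather than undefined, with pairwise
  comparisons returning p = 1.
* **Bonferroni subsets.** Pairwise adjusted-mean contrasts with p
  multiplied by the number of pairs (capped at 1); letters chain maximal
  runs of groups, ordered by adjusted mean, whose pairwise adjusted p ≥ α.
* **Partial correlations.** SBP and DBP against per-emotion accuracy,
  residualising both on age, gender and education; df = n − 2 − k,
  two-tailed p (correlations are reported signed).
* **Summary-statistics ANOVA.** `anova_from_summaries()` recovers the
  exact one-way F from printed (n, mean, SD) triples — an algebraic
  identity with the raw-data ANOVA, tested as such — so published
  demographic tables can be re-verified without raw data.
* **Power.** `required_n_ancova()` iterates N upward on the noncentral-F
  power function (λ = f²N). At f = .50, α = .05, power = .95, 3 groups and
  3 covariates the smallest adequate N is 66. A companion sample size of 38
  sometimes quoted for partial correlations under the same parameters is
  not reproduced here: it depends on an unstated choice of test family
  (exact bivariate normal vs regression coefficient, tails), so the
  package exposes only the ANCOVA routine.

## The synthetic-data generator

`generate_study()` emits the three input payloads (participants, human
coding, machine coding) plus a ground-truth sidecar. It emulates:

* three JNC-7 groups of 33/21/20 by default, with latent target pressures
  drawn uniformly inside per-group windows (chosen to sit ≥ 2 mmHg inside
  the category bounds and to land near the reported group means), integer
  readings with SD 1.5 mmHg noise, and a +6 mmHg first-reading elevation
  so the discard rule does real work; readings are resampled until the
  six-reading mean classifies into the intended group, making the BP
  stage exactly recoverable;
* demographics matching the study population (group age means ≈ 24/30/40,
  gender imbalance across groups, education ≈ 16 years) so the covariates
  are realistically confounded with group;
* a logistic accuracy model in *continuous* SBP (not group index), so both
  the categorical ANCOVA and the continuous partial-correlation analyses
  have coherent ground truth. Default intercepts/slopes were chosen to
  qualitatively reproduce the published ordering of group accuracies
  (happiness high and flat; sadness, fear, surprise steeply dampened;
  anger, disgust mildly so) — not their exact values, which no
  parameterisation is given for;
* intensity dampening of 0.25 intensity units per group step (SD 0.8),
  clamped to 1–5 on the correct path (FACS presence implies at least
  trace);
* incorrect trials split evenly between a sub-threshold partial prototype
  (a strict subset small enough that the intended emotion's score stays
  below s_min) and a confusable emotion's full prototype
  (sad↔fear, anger↔disgust, surprise→fear, happiness→surprise); either
  way the coded label cannot equal the intended emotion, so the latent
  correctness draw is exactly what the pipeline recovers;
* sparse off-template noise: AUs belonging to *no* prototype activate
  independently (p = 0.05) at intensity 1–2. Restricting noise to
  non-prototype AUs guarantees — provably, since off-template activity
  penalises every competitor at least as much as the intended emotion —
  that correct-path productions always classify as intended;
* a machine rater applying gain 0.75, additive noise SD 0.35, and a miss
  probability 0.5·exp(−h) that targets low-intensity AUs, reproducing the
  observed directions: machine intensities below human intensities, and
  agreement falling where expressions weaken. 2% of images fail detection
  outright (`success = 0`), exercising the exclusion path.

What the generator does **not** model: image formation (there are no
pixels anywhere in this package), temporal dynamics, coder drift or
fatigue, and failed *neutral* poses — synthetic neutral faces are
near-zero vectors, so synthetic neutral accuracy is essentially 100%,
higher than real studies report. Passing tests therefore demonstrate that
the pipeline recovers structure a real study assumes, not that the
generator reproduces every marginal of real data.

## Problem sizes and numerical choices

The validation suite uses problem sizes chosen to make each property
statistically decisive while staying desk-scale: 1,000 random small
instances for the oracle equivalence of the agreement indices (tolerance
1e-10 against independent brute-force implementations); 1,000 trials for
the kappa-paradox regime; 200 replicates of a 300-participant study for
parameter recovery (dampening slope 0.9 logit/10 mmHg on sadness, anger
and disgust; zero on the rest), requiring the significant-negative
partial-correlation pattern in ≥ 95% of replicates and a null happiness
association in ≥ 90%; and 1,000 null-model studies of 74 participants for
the ANCOVA type-I error, required to land in [0.03, 0.07] at α = .05.
Ties in classification are compared with tolerance 1e-12; ICC and κ
denominators below 1e-12–1e-14 are treated as undefined.

## Known limitations

* The match-score rule is a stand-in for expert judgement; real coders
  integrate wrinkle patterns and asymmetries no AU-vector rule sees.
* Binning machine intensities loses information for κ/AC1/α; the ICC on
  raw values partially compensates.
* Bonferroni is conservative for three groups; subset letters inherit
  that conservatism.
* No bootstrap confidence intervals for agreement indices, no >2-rater
  generalisations, no weighted-κ family, and no curvilinear BP models —
  the inverted-U hypothesis for BP and emotion remains untested here.
* With very small retained cells (a handful of accurate trials), the
  agreement means are unstable; the run log's per-cell undefined counts
  should be consulted before interpreting them.
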