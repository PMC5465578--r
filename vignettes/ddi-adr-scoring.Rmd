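---
title: "Scoring synergistic DDI-induced adverse drug reactions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring synergistic DDI-induced adverse drug reactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddisyn)
```

## The problem

Co-administered drugs can trigger adverse reactions that neither drug
causes alone, or aggravate a reaction one of them causes mildly. Such
synergistic DDI-induced ADRs surface in pharmacovigilance reports only
after drugs reach the market, because clinical trials rarely test drug
combinations. `ddisyn` implements a mechanism-motivated scoring method
for them: if an ADR requires simultaneous modulation of several proteins,
a pair of drugs that *between them* cover the required interactions can
induce the ADR even when neither drug covers them alone.

Two scenarios motivate the score. In the first, a *new* effect appears:
the ADR needs proteins α and β modulated at once, drug *i* hits only α
and drug *j* only β, so only the combination satisfies the requirement.
In the second, an *existing* effect is enhanced: drug *j* already causes
a mild reaction through protein ζ, and co-administering a drug that hits
α aggravates it beyond what drug *j* achieves alone. Two drugs with
identical interaction profiles can never synergise — their combination
adds no interaction either lacks.

## Model and assumptions

**Profiles.** A drug is a binary vector over (protein, category)
features, four categories per protein: binding, inhibition, activation,
catalysis. The representation assumes drug action on the organism is
mediated by protein interactions; ADRs driven by non-protein targets
(DNA intercalation, membrane partitioning) are invisible to it. A pair's
profile is the bitwise OR of its constituents. This deliberately
collapses complexities such as site competition or non-additive
molecular effects: the pair simply interacts with the union of the two
drugs' protein sets.

**Weights.** For an ADR with `m` positive pairs among `n` training
pairs, the naive per-feature probability that the feature accompanies
the ADR is `n_a/n_b` (positive pairs carrying the feature over all pairs
carrying it). With few carriers this overestimates wildly — one carrier
that happens to be positive reads as certainty — so `laplacian_weights()`
adds `K = n/m` virtual carriers at the baseline rate `m/n`:

$$w_\alpha = \log\frac{n_a(\alpha) + 1}{n_b(\alpha) + n/m} - \log\frac{m}{n}.$$

As `n_b → 0` the corrected estimate approaches the baseline and the
weight approaches 0; features entirely absent from training get weight
exactly 0, so prediction-time profiles with unseen features are handled
gracefully. `K` is used as the exact real number `n/m`, never rounded.
Fitting is pure counting — no iterative optimisation — so the number of
features is effectively unlimited and retraining is exactly
reproducible.

**Scores.** Additive: `S = Σ g_α w_α`. The synergy score of a pair is
`DDI = S(pair) − max(S(drug_i), S(drug_j))` and a pair is called positive
when `DDI > 0` (strictly: equality means the combination added nothing).
By inclusion–exclusion `S(pair) = S(i) + S(j) − S(shared)`, a useful
identity for testing.

**Training unit.** Models are fitted on *pair* profiles: `n` is the
number of training pairs, and feature counts are over pair profiles. The
same pair-trained weights then score single-drug profiles, which puts
`S(drug)` and `S(pair)` on one scale — required for the subtraction in
the DDI score to be meaningful. The alternative (training single-drug
weights from single-drug labels) would need a second label source and a
scale alignment; we document it as a road not taken.

**Log base.** Natural log. Any base rescales all weights by one positive
constant, leaving threshold-0 classification, rankings and AUC unchanged
(a property the test suite asserts), so the choice is presentational.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `min_confidence` | 0.40 | inclusive lower bound on combined interaction confidence ("medium"); records *below* 0.40 are removed, the boundary itself is kept |
| categories | B, I, A, C | interaction types encoded; everything else dropped |
| `min_positives` | 50 | ADRs with fewer positive pairs are not modelled — below this the fitted models hover near chance |
| `threshold` | 0 | decision threshold on the raw DDI score; 0 is the natural choice implied by the synergy definition |
| calibration grid | 0, 10, …, 90 | normalised-score thresholds searched for PPV targets; configurable to finer grids |
| `k` | 10 | cross-validation folds, positives and baseline stratified independently; each fold is held out exactly once |

Multiple interaction records of the same category for one
chemical–protein edge collapse to a single set bit: the encoding asks
whether *any* retained record of that category exists.

## Normalisation and degenerate cases

Scores are normalised to `100 · DDI / model_max`, where `model_max` is
the maximum DDI score over the model's training pair universe, stored in
the model artifact. Prediction-time scores can exceed 100 and are
reported uncapped with an `above_training_max` flag. A model whose
`model_max` is not positive cannot rank anything above its training
maximum; normalisation then signals an error rather than silently
clipping. PPV at a threshold where nothing is predicted positive is
reported as missing — never 0, never 100% — and a PPV target no grid
threshold reaches is reported unreachable.

AUC uses the rank (Mann–Whitney) formulation with midranks for ties, the
standard convention. In the robustness designs, "half of the baseline
samples" and "half of the test positives" round down; the remainder
stays in the test set.

## Seeding

One master seed drives everything. Sub-seeds are derived
deterministically per fold and per (fraction, repeat) cell, so any
single repeat is reproducible in isolation. In the robustness
experiment the sub-seed deliberately does **not** depend on the model
type: types I, II and III share the same base train/test draw and differ
only in the noise planted afterwards, so with a noise count of zero
types II and III reproduce type I exactly — the designs are controlled
comparisons, not three independent simulations.

## The synthetic generator

`generate_world()` emulates the *structure* of the real inputs — a
drug × (protein × category) incidence matrix and a positive
(pair, ADR) label table — with known ground truth:

1. Background bits are drawn i.i.d. at `background_density`.
2. Each rule's feature columns are cleared, then injected into disjoint
   carrier groups. For a new-effect rule the required features are split
   across two groups, so no drug carries them all; labels are then
   assigned by rule satisfaction on the OR-combined pair profile, with
   pairs that a single constituent already satisfies excluded. For an
   enhancement rule, solo-feature carriers are labelled alone with a
   small probability (`solo_rate`) and with certainty when paired with
   an enhancer carrier.
3. Optional bystander columns — noisy copies of causal columns —
   emulate correlated off-target interactions, spreading the fitted
   signal over many features.
4. Label noise: a fraction of true positives is removed (false
   negatives) and false positives are sampled uniformly from the
   unlabelled pair universe, disjoint from the remaining positives.

What it does *not* emulate: the heavy-tailed degree distributions of
real interaction databases, correlated reporting biases in
pharmacovigilance data, pharmacological similarity structure among
drugs, or dose effects. Passing tests on these worlds therefore
demonstrate that the estimator recovers planted structure under
controlled noise — not that real STITCH/TWOSIDES performance figures are
reproduced, which would require the source data.

## Problem sizes and study conditions

The benchmark worlds are sized for desk-scale, single-CPU runs:

* **Parameter recovery**: 200 drugs × 300 proteins (1,200 features),
  background density 0.05, one two-protein rule, carrier groups of 20%
  of drugs, no label noise. The planted features must carry the top-2
  positive weights and pooled 10-fold AUC must be high (≥ 0.95).
* **Robustness and calibration**: 80 drugs × 150 proteins with label
  noise of 25% planted false positives and 10% removed true positives —
  chosen once as a plausible pharmacovigilance noise level, since
  pair–event associations from disproportionality analyses carry a
  substantial false-discovery burden and under-reporting is endemic.
  The 3 types × 5 fractions × 50 repeats grid runs in well under a
  minute.

With noise present, AUC rises with the number of training positives,
planted false negatives barely move it (the baseline class is so much
larger that a few mislabelled positives dilute nothing), while planted
false positives — equal in number to the true positives — visibly hurt
at small positive counts and wash out as positives grow. These are the
qualitative signatures the evaluation module is designed to expose, and
the acceptance suite asserts them.

## Known limitations

* Pairwise combinations only; no three-drug interactions.
* No dose, regimen, timing or patient covariates.
* Identifiers are opaque: no chemistry perception or structural
  similarity.
* The baseline class is presumed-negative, not true-negative; the
  method's tolerance of that contamination is an empirical property
  demonstrated on synthetic noise, not a guarantee.
* Scores are ranking devices calibrated via PPV targets; they are not
  probabilities.
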