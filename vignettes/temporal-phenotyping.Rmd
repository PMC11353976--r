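---
title: "Temporal phenotyping of outpatient EHRs: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal phenotyping of outpatient EHRs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tempheno)
```

This vignette is the package's own account of the science it implements: the
models and their assumptions, what the synthetic-data generator does and does
not emulate, the numerical choices, and the design decisions that were
genuinely open. It states no empirical result that the test suite and
`scripts/acceptance.R` do not themselves compute.

## The problem

A first acute myocardial infarction (AMI) typically arrives in patients with
no recorded cardiac history, out of the hospital. Outpatient EHRs hold years
of labs, vitals, diagnoses and prescriptions for such patients, but the data
are irregular: encounters happen at arbitrary times, most variables are
unmeasured at most visits, and diagnoses are only observed when a patient
shows up. The package's pipeline turns this record into three feature
representations of increasing temporal content — latest values, five-year
summary statistics, and temporal computational phenotypes from a
patient × time × feature tensor — and asks which representation best
predicts an AMI within a six-month horizon, using only models whose
decisions can be inspected.

## Anchor-relative time

All timing is expressed as *days before an anchor*: the AMI date for cases,
the last encounter for controls. This avoids calendar arithmetic entirely
and makes the five-year observation window a half-open partition into ten
183-day bins, with bin 9 adjacent to the anchor. An event exactly 183 days
before the anchor falls in bin 8 — intervals are `(older, newer]`. The
choice of 183 days (rather than 182.625) makes the ten bins cover 1830 days
against a 1825-day window; the oldest bin is slightly truncated, which
affects nothing downstream because events are generated and filtered within
the window.

## The tensor model

For labs and vitals, the last value of each variable per bin is discretized
into quintile levels 1–5 with edges fit on the *training* measurements only;
an empty patient–bin–variable cell is 0. Zero therefore means
"missing in this bin", deliberately distinct from level 1: non-negative
factorization treats absence as low intensity, which matches zero-filling
and keeps the tensor non-negative. Quintile edges with duplicates are
collapsed, so a variable with few unique values gets fewer levels — the
degeneracy one actually observes in real lab data is reproduced rather than
hidden. For diagnoses and medications the tensor is binary: diagnoses are
carried forward across encounter-free bins (a chronic condition does not
vanish between visits) and then zero-filled; prescriptions flag only the
bins they overlap, with no carry-forward.

The non-negative CP (PARAFAC) decomposition approximates the tensor as a sum
of rank-one components `λ_r a_r ∘ b_r ∘ c_r` with all factors non-negative.
Each component is read as a phenotype: `c_r` says which features co-occur,
`b_r` when, `a_r` in whom. The solver is hierarchical alternating least
squares (HALS): column-wise closed-form updates floored at `1e-12` (so no
column can silently die; a column whose norm still collapses below `1e-10`
is re-seeded from uniform noise with a message). The objective is
non-increasing across sweeps by construction; the error is tracked through
Gram matrices, whose floating-point cancellation puts a noise floor of about
`sqrt(.Machine$double.eps)` on the reported relative error — relevant only
when the fit is essentially exact. Iteration stops at a relative improvement
below `tol` (default `1e-8`) or `max_iter` (200). After fitting, all scale
is absorbed into `λ` and the factor columns are normalized to unit length;
patient *memberships* are `a_r λ_r`, so a membership of `m` means the
patient's slice contains `m` copies of the unit rank-one pattern.

Held-out patients are scored by fixing `B`, `C` and `λ` and solving a
non-negative least squares problem per patient against the Khatri–Rao basis
— phenotypes never change after training, which is what makes train/test
evaluation honest. Rank selection fits replicate decompositions per rank,
trains a reference random forest on memberships, and reports the metric
curve with a maximum-curvature elbow *suggestion*; the final rank is a
config choice, not an automatic decision, because the elbow of these curves
is genuinely a judgment call.

Patient memberships in a phenotype report are rescaled to [0, 1] by the
column maximum. Per-column ℓ2 normalization was the alternative; the max
convention keeps "1 = the most expressed patient", which reads better in
reports.

## The synthetic cohort: what it emulates, and what it does not

The generator defines the study conditions used throughout the tests. Its
defaults are fixed once: 667 cases with 2:1 matched controls (≈2000
patients), five years of encounters at 8 per patient-year (floored at three
visits, mirroring a minimum-visit inclusion rule), 12 lab features with 30%
missingness per encounter and Gaussian noise of SD 0.5 against a signal
scale of ~1, 15 diagnosis and 8 medication features, a planted rank-4
structure, and an outcome whose log-odds load +1.5 on the first phenotype's
membership with the intercept solved so expected prevalence equals 1/3.
Patient loadings are Gamma(2, 2) (non-negative, right-skewed, mean 1);
temporal profiles are Gaussian bumps whose centers sit away from the anchor
for most components, so the planted signal is genuinely *historical* and a
183-day "latest value" window cannot see most of it — that asymmetry is what
the pipeline's central comparison (phenotype features vs latest values) is
designed to detect. Binary events use a logistic link on the same low-rank
intensity, keeping the binary tensor approximately low-rank. Diagnoses are
only recorded in bins containing an encounter; prescriptions are recorded
regardless, since their intervals do not require a visit.

Matching is greedy and nearest-first: cases in ascending id, exact on sex,
±2 years age, ±2 frailty points, ties by smaller age gap, then smaller
frailty gap, then id. Greedy matching is deterministic and auditable; it is
a repo convention, not a claim about how any particular study matched.
Cases that cannot receive a full set of controls are excluded. The candidate
pool is oversampled (×1.7 plus a constant headroom) so small test cohorts
can still fill their sets. Frailty is an additive score over distinct
3-character diagnosis categories using a *synthetic* weight table shipped in
`inst/extdata/`; any real weight catalogue with columns `code`/`weight`
plugs in unchanged, as does a real ICD-9→10 conversion table.

What the generator does **not** emulate: realistic disease progression or
code semantics, correlated measurement panels, informed presence (sicker
patients visiting more), calendar effects, or multi-site heterogeneity.
Passing tests therefore demonstrate that the *machinery* recovers planted
structure and planted effects under EHR-like sparsity and matching — not
that any clinical conclusion transfers to real data.

## Preprocessing rules

Cleaning drops unparsable numerics and values outside configured plausible
ranges, and converts Celsius temperatures (values ≤ 45, a threshold at which
the two scales cannot overlap for body temperature) to Fahrenheit.
Digit-leading diagnosis codes are treated as ICD-9 and mapped through a
two-column table; unmapped ICD-9 codes are dropped rather than passed
through, since a mixed vocabulary would corrupt the 3-character roll-up.
Chapter-Z codes are removed. Roll-up adds the 3-character category for every
deeper code at the same timestamp and is idempotent; deeper intermediate
levels are not generated. The missingness filter keeps a continuous
variable iff strictly more than 60% of *training* patients have a
measurement; the prevalence filter drops a binary variable iff its training
prevalence is strictly below 1% in cases *and* in controls. Both boundaries
are strict because the rules are worded as "more than"/"less than". All
filters are fit on train, frozen, and applied to both splits; re-running the
composed pipeline on its own output is a no-op, which the tests assert.

One wording tension is left explicit rather than resolved: "latest values"
can be read with or without a six-month recency window. The package exposes
`recency_window` (default 183 days) on `latest_values()` so either reading
is available.

## The fuzzy-rule network

The TGFNN encodes each continuous variable (min–max scaled from training
statistics) into memberships of *low*, *medium*, *high* via Gaussian
functions with trainable centers and widths, initialized at the training
quartiles with widths of half the inter-quartile gap (floored at 0.05).
Binary variables pass through as the concept pair (absent, present). Per
rule, a softmax attention selects concepts within each variable; variable
importance weights (softplus-reparameterized, hence non-negative) act as
exponents, so weight 0 contributes neutrally; the T-norm
`(1 − t)·product + t·minimum` aggregates variables into a rule strength.
Inference aggregates rule-importance-weighted strengths per class with the
T-conorm `(1 − s)·sum + s·maximum` — the max end is the tropical (max-plus)
operation — adds a per-class bias, and applies softmax. The convex
combination was chosen over a power-mean bridge for its exact endpoints,
monotonicity, and simple gradients; `t` and `s` are trainable in [0, 1]
through a logistic reparameterization.

The per-class bias deserves a note: without it, softmax over purely
non-negative aggregates cannot center the decision boundary, and training
reliably converges to inverted "negative-class rules" that rank well but
neither threshold nor read correctly. The bias restores a default class
(initialized toward "negative unless a rule fires"), which is also what
makes extracted rules describe the *positive* class.

Training is full-batch Adam on class-weighted cross-entropy with manually
derived gradients (checked against finite differences in the test suite),
small weight decay on the rule-module parameters, and early stopping on a
held-out fraction's F1 (best checkpoint kept). Membership values are floored
at `1e-6` so logarithms stay finite; gradients are masked at the clamps.

Rule extraction prunes rules below 0.1 relative importance (relative to the
largest positive-class rule weight; the share-of-total is reported
separately as `rule_contribution`) and, within a rule, ranks variables by
*effect weight*: the importance weight times the variable's mean attended
negative-log-membership over the training data. A concept whose Gaussian
has "squished" out of range acts as always-true; its raw weight receives no
gradient and can sit anywhere, but its effect weight is correctly ~0. Such
squashing is permitted — it is how the network dynamically simplifies three
concepts to two — and the report simply reflects it.

## Evaluation machinery

Class weights are `N/(2·N_c)`; models without weight support (gradient
boosting here) instead train on a seeded 1:1 downsample of the majority
class. Hyperparameter search samples random combinations and scores mean F1
over three stratified folds; evaluation uses five stratified folds, each
fold's model scored on its training folds, its validation fold, and the
fixed test set — means and SDs over the five instances, with no refit on
the full training set. Folds are stratified throughout because the matched
2:1 imbalance makes unstratified folds fragile. AUROC is tie-corrected rank
concordance; AUPRC is the step integral of the precision–recall curve; both
are tested against brute-force pair/step oracles to `1e-9`. Platt scaling
fits `1/(1 + exp(A·s + B))` by logistic regression (exactly the stated
log-loss minimization). Reliability uses ten equal-width bins with empty
bins omitted. The Friedman test uses tie-corrected within-block ranks, with
all-pairs Nemenyi p-values from the studentized range at the Bonferroni
default α = 0.01; blocks can be folds or feature sets depending on the
question, so the function simply takes a blocks × treatments matrix.
Kendall tau-b (tie-corrected) compares importance rankings across models or
replicates; a model-agnostic permutation importance (mean AUROC drop over
seeded column shuffles) is provided for models without native importances
and as a common currency across them.

## Problem sizes and numerical tolerances in the shipped checks

The test suite and acceptance script run entirely on synthetic data at desk
scale, chosen as the smallest sizes at which each property is a meaningful
statistical statement rather than noise: planted-rank recovery on a
300 × 10 × 40 tensor at amplitude SNR 10 (congruence against the generating
factors, and relative error compared with an independent unconstrained ALS
reference); noiseless exactness at `1e-6`; projection self-consistency at
`1e-3`; the phenotype-vs-latest comparison on ten independent ~2000-patient
cohorts with a one-sided sign test; two-rule recovery for the TGFNN on 800
samples; metric oracles at `1e-9`. For the calibration reliability check the
simulation is sized at 10,000 samples because with ten bins the 3σ binomial
bound on a per-bin gap is ~0.045 at that size — at 2,000 samples a 0.05 gap
criterion would be testing sampling noise, not calibration. The Platt-fit
log-loss is still checked at 2,000 samples against a dense grid-search
oracle.

## Known limitations

* The generator's encounter process is homogeneous Poisson; real visit
  patterns cluster around illness, which induces informed-presence bias the
  pipeline never sees.
* Greedy matching is order-dependent by design; optimal matching would
  retain more cases near the tolerance boundary.
* HALS is a local optimizer: on noisy tensors different seeds can reach
  different local minima. The tests pin seed-stability only on noiseless,
  exactly representable fixtures.
* The TGFNN's extracted rules are faithful to the fitted network, not to
  the data-generating process; on collinear features the network may
  express a planted rule through a correlated proxy.
* mRMR computes relevance once (not per step) and uses the common
  quotient combining rule; both are conventions where the method family
  genuinely varies.
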