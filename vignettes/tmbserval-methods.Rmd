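---
title: "Multiple-instance calibration learning for multidimensional TMB: models and methods"
author: "TMBserval authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiple-instance calibration learning for multidimensional TMB}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TMBserval)
```

## The problem

Tumor mutation burden (TMB) is usually reported as a single count of
non-synonymous somatic mutations, treating every mutation identically.  But
mutation classes differ in immunogenic weight — indel-derived neoantigens,
for instance, are more immunogenic per event than SNV-derived ones — so a
one-dimensional count discards signal that matters for predicting benefit
from immune checkpoint inhibitors (ICI).  TMBserval represents each patient
by a burden *vector* counted per mutation class, by default

$$\mathbf{x} = (\mathrm{SNV}, \mathrm{INS}, \mathrm{DEL})^\top \in
  \mathbb{R}^d, \qquad d = 3,$$

and asks how such vectors map to *subgroup-level* treatment prognosis.
Clinical decision criteria are formulated for patient groups, not
individuals, so supervision is attached to subgroups: the cohort of $N$
patients is partitioned into $M$ bags $G_m = \{x_{m1}, \dots, x_{mn_m}\}$,
$\sum_m n_m = N$, each carrying one prognosis label $y_m$.  This is the
multiple-instance learning (MIL) setting, with patients as instances and
subgroups as bags.

## The model

A small fully connected network $f: \mathbb{R}^d \to (0,1)^{k}$ (tanh
hidden layers, logistic output) produces per-patient outputs
$o_{mi} = f(x_{mi})$.  A bag-level aggregate
$\hat o_m = \mathrm{agg}(o_{m1}, \dots, o_{mn_m})$ is formed with one of
four subgroup efficacy metrics — median, maximum, minimum, mean — chosen to
match the clinical criterion in force (e.g. a trial judged on median
survival uses the median metric).  Training minimises a loss between
$\hat o_m$ and $y_m$ by full-batch gradient descent, backpropagating
through the aggregation: the mean spreads the gradient uniformly over
members, extreme metrics route it to the selecting member(s) (ties
averaged), and the even-count median splits it 0.5/0.5 between the central
pair.

### Labels

Two labeling schemes are supported.

* **Category labels** (`assign_category_label()`): an expert-style rule
  labels a bag favorable (1) when its responder proportion reaches a
  threshold (default 0.5) *and* its median progression-free survival
  exceeds 183 days (the conventional 6-month horizon); a three-class
  variant grades partial satisfaction.  Because such labeling is
  subjective, every rule parameter is explicit configuration.
* **Probabilistic labels** (`probabilistic_label()`): an objective
  two-component label $y_m = [p_R, p_T]$.  $p_R$ aggregates patient
  response values (with the mean metric it is exactly the bag's objective
  response rate), and $p_T$ aggregates per-patient probabilities
  $S_i(t_0)$ of surviving beyond the horizon $t_0 = 183$ days, estimated by
  a Cox proportional-hazards fit of time-to-event on the burden features
  (`estimate_pT()`, via the survival package, product-limit baseline).
  Both components are probabilities, which puts the two endpoints on a
  common scale — days-scale survival times would otherwise dominate any
  distance between labels.

### Losses

For category labels the **calibration loss**

$$E = \sum_{m=1}^{M} \frac{(y_m - \hat o_m)^2}{\hat o_m}
      + \frac{(y_m - \hat o_m)^2}{1 - \hat o_m}$$

is a Pearson-style discrepancy.  Its link to a standard goodness-of-fit
statistic is exact, not merely analogous: with mean aggregation, labels
taken as group event proportions, and each term weighted by the group size
$n_m$, the expression *is* the Hosmer–Lemeshow statistic (tested to 1e-9
relative agreement against the independently coded `hosmer_lemeshow()`).
The printed, unweighted form is the training default;
`weight_by_bag_size = TRUE` selects the exactly-HL variant.  Minimising
the calibration loss therefore optimises the model's calibration — the
agreement between predicted probabilities and observed frequencies — not
just its accuracy.

For probabilistic labels the **distance loss** $E = \sum_m
\mathrm{dist}(\hat o_m, y_m)$ supports three distances: squared Euclidean
$(y_1-y_2)(y_1-y_2)^\top$ (the default; a `sqrt_form` flag gives the metric
form), Mahalanobis $(y_1-y_2) V^{-1} (y_1-y_2)^\top$ with $V$ the
covariance between the response and survival endpoints (reducing to
Euclidean at $V = I$), and Minkowski $(\sum_i |\Delta_i|^p)^{1/p}$.  The
quadratic (no square root) forms are the training default because that is
how the distance expressions are defined here; both forms are tested.  MSE
and cross-entropy are implemented as comparison baselines.

Vector labels are aggregated componentwise.  A scalar aggregate of
per-patient distances-to-origin cannot be compared against a two-component
label in the distance loss, so componentwise aggregation is the only
dimensionally consistent choice; it is used throughout.

## The synthetic cohort generator

`simulate_cohort()` encodes the package's default study design at the
burden-vector level: 660 patients in five subgroups of sizes
90/212/64/202/92 with target labels (0.223, 0.246), (0.326, 0.397),
(0.461, 0.558), (0.654, 0.733), (0.908, 0.922).  Per subgroup it draws:

* **Features**: negative-binomial counts (dispersion 8) with
  subgroup-specific mean vectors rising from (30, 6, 5) to (110, 22, 18),
  times multiplicative lognormal measurement noise (sd 0.1).  This
  stands in for a read-level simulation pipeline (spike-in mutations
  re-called by a somatic caller) with direct draws that preserve the statistical
  structure the learner consumes: overdispersed class counts, monotone
  burden–benefit dependence, measurement error.
* **Response**: Bernoulli with logistic probability
  $\mathrm{logit}^{-1}(a_m + \beta^\top z_i)$, slopes
  $\beta = (0.6, 0.3, 0.3)$ on standardized features.  The latent
  probability is retained in the ground-truth table.
* **Survival**: exponential-baseline proportional hazards
  $h_i = \lambda_0 \exp(b_m + \gamma^\top z_i)$, $\lambda_0 = \ln 2 / 180$
  per day, $\gamma = (-0.4, -0.2, -0.2)$ (higher burden, lower hazard),
  with independent exponential censoring calibrated to a 20% censored
  fraction.

The per-subgroup intercepts $a_m, b_m$ are found by monotone root-finding
(`uniroot`) so that the subgroup *mean latent* response probability and
mean latent $P(T > t_0)$ equal the target labels exactly — the generator's
subgroup endpoint probabilities are its labels by construction.  Realized
binary draws then scatter binomially around those targets; at the printed
sizes the smallest subgroup ($n = 64$) has a binomial standard error near
0.06, so realized fractions should be judged against that scale, not
against the exact targets.  The slopes above are presets of this
package, chosen once to give a monotone but non-uniform burden-benefit
dependence, and documented as such.

What the generator does *not* emulate: sequencing reads, caller-specific
error profiles, inter-patient covariate shift, competing risks, or
non-proportional hazards.  Passing tests on these cohorts therefore
demonstrate correctness of the learning machinery under a well-specified
generative model, not clinical performance on real data.

## Training and evaluation protocol

* **Descent**: plain full-batch gradient descent (optional classical
  momentum, off by default), stopping at loss tolerance
  $\delta = 10^{-3}$ or `max_epochs = 5000`.  The bag-level loss gradient
  is clipped componentwise at 10 before backpropagation: the calibration
  loss's denominators grow like $1/\hat o^2$ near the boundary and a
  single unclipped step can otherwise eject the weights from the basin.
  Outputs are clipped to $[\varepsilon, 1-\varepsilon]$,
  $\varepsilon = 10^{-7}$, before divisions and logarithms.
* **Architecture**: one hidden layer of 16 units by default — 98
  parameters at $d = 3$, small enough for cohorts of a few hundred
  patients, expressive enough for non-uniform burden–benefit surfaces.
  `hidden = integer(0)` degenerates exactly to logistic regression.
* **Cross-validation** (`kfold_cv()`): folds are drawn *within* bags, so
  every fold sees every bag with about $1/k$ of its members.  With only
  five bags, splitting whole bags would leave folds without usable
  supervision; within-bag splitting keeps the bag labels defined on every
  fold.  The feature scaler is refit on each fold's training split only.
* **Learner comparison** (`compare_learners()`): four learners predicting
  patient response probability are trained on identical splits and judged
  by the Hosmer–Lemeshow test at $g = 10$ and $g = 20$ groups (df 8
  and 18).  Each loss is trained on the supervision its domain admits:
  calibration and MSE on bag response proportions (mean aggregation), CEL
  on binary category bag labels (cross-entropy requires labels in
  $\{0,1\}$), and a probability-calibrated SVM (e1071) instance-level on
  binary responses.  Gentler settings (learning rate 0.01, 600 epochs) are
  the default here because prolonged descent degrades instance-level
  calibration while still satisfying the bag constraint.
* **Learning curves** (`learning_curve()`): training subsets of increasing
  size with bag proportions preserved, each fit evaluated on a fixed
  held-out split, averaged over repeated splits.

The test suite runs these protocols at the default 660-patient cohort with
five seeds for the stochastic directional checks (label recovery within
±0.05, probabilistic-vs-category cross-validation ordering,
calibration-vs-CEL goodness-of-fit ordering, learning-curve convergence),
and at scaled-down cohorts (scale 0.2–0.4) for unit-level checks.
Training runs use 150–3000 epochs depending on how converged the check
needs the model to be; the acceptance script states its sizes alongside
each reported quantity.

## Numerical choices and edge cases

* Even-count medians are the midpoint of the central pair everywhere
  (aggregation, labels, gradients).
* Mahalanobis $V$ must be symmetric positive definite, checked by
  eigendecomposition; a near-singular $V$ (condition number beyond 1e10)
  is ridge-regularized with a warning, an indefinite one is an error
  naming the offending eigenvalue.
* Zero-variance feature dimensions are centered but not scaled, with a
  warning.
* A rank-deficient design in `estimate_pT()` triggers a collinearity
  warning and a ridge-penalized Cox refit; an all-censored cohort is an
  error.
* `estimate_pT()` uses the product-limit baseline (`stype = 1`), so a
  cohort whose members all fail before $t_0$ gets survival exactly 0.
* Variant filters read "more than 4 reads" strictly ($> 4$) and "2% VAF"
  inclusively ($\geq 0.02$); the two evidence clauses are disjunctive as
  stated, with a `conjunctive` flag for sensitivity analysis.  A missing
  population frequency is treated as 0 (novel variant), so only annotated
  common polymorphisms are excluded.  Indel alleles are classified as
  given, without left-alignment.

## Known limitations

* Bag supervision with a handful of bags means the network can satisfy
  the bag-level constraints while distributing instance outputs in more
  than one way; instance-level interpretations of a bag-trained model
  should be made with the calibration diagnostics in hand.
* The category-label rule is a deliberately simple stand-in for expert
  judgment; its thresholds are configuration, not recommendations.
* The generator's measurement-noise model (multiplicative lognormal on
  counts) is a coarse emulation of caller behaviour.
* Proportional hazards and independent censoring are assumed throughout;
  competing risks and time-varying covariates are out of scope.
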