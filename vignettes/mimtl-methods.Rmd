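---
title: "Multi-instance metric transfer learning: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-instance metric transfer learning: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mimtl)
```

## The problem

Genome-wide protein function annotation can be cast as multi-instance
multi-label (MIML) learning: a protein is a *bag* of instance vectors (one
per structural domain, e.g. 216-dimensional conjoint-triad frequencies),
and its Gene Ontology terms are a *label set*. A bag is positive for a
class iff at least one instance realizes that class's concept.

Annotated proteins (the source domain, SD) and the proteins one wants to
annotate (the target domain, TD) rarely come from the same distribution —
a covariate shift: the bag distribution changes, the labeling rule does
not. A classifier trained on SD alone then optimizes the wrong expected
loss. This package implements a transfer pipeline that

1. estimates **bag importance weights** $\omega(X) = P'(X)/P(X)$ (the
   TD-over-SD bag density ratio) by least-squares density-ratio fitting
   with a multi-instance set-kernel basis,
2. learns a **per-class Mahalanobis metric** $D(u,v) =
   (u-v)^\top A^\top A (u-v)$ from the reweighted bags, and
3. predicts labels with one of two base learners using the learned
   metrics: **citation-kNN** voting, or a **k-medoid bag embedding** fed
   to an RBF max-margin classifier.

## Importance weights

With $\psi_j(X)$ the normalized set kernel between bag $X$ and basis bag
$j$ (basis bags are a random subset of TD bags), the weights are modeled
as $\omega(X) = \sum_j \alpha_j \psi_j(X)$, $\alpha \ge 0$, and fitted by
minimizing $\tfrac12\alpha^\top B\alpha - b^\top\alpha$ with
$B = \frac1{n_{src}}\sum_{SD}\psi\psi^\top + \text{ridge}\cdot I$ and
$b = \frac1{n_{tgt}}\sum_{TD}\psi$ — the least-squares fit of the ratio.
The non-negative quadratic program is solved by projected gradient with
backtracking (zero start, deterministic, KKT-checked at exit).

Choices the source text leaves open, and how they are resolved:

* **Kernel variant.** The set kernel is the summed instance RBF,
  normalized so $k(X,X)=1$; normalization removes bag-size scale effects.
  The unnormalized sum is available (`normalize = FALSE`).
* **Kernel width.** `gamma = NULL` uses the median heuristic
  $\gamma = 1/\mathrm{median}^2$ on pairwise bag-mean distances over the
  pooled domains.
* **Conditioning.** `ridge = 1e-6` keeps $B$ positive definite.
* **Normalization of $\omega$.** Off by default: rescaling to unit mean
  silently rescales the $\lambda/\beta$ trade-off in the metric objective,
  so it is an explicit flag (`normalize_omega`).

## Per-class metric learning

For each class $k$ (one-vs-rest), the constrained program asks that every
instance stay within a radius $\delta_S$ of its own bag center
(compactness) and that bags with different class-$k$ labels stay at least
$\delta_D > \delta_S$ apart (separation), both softened by slack
variables and both weighted: within constraints by the bag's $\omega_i$,
between constraints by $\omega_i\omega_j$ (for independent draws the
expected pairwise loss factorizes into the product of the marginal
ratios). Labeled TD bags, when present, join with weight exactly 1;
without them the source-only formulation is used unchanged.

The penalty form optimized is
$$f = \|A\|_F^2 + \lambda\sum w\,\xi + \beta\sum w\,\zeta +
\sigma\Big[\sum \max(0, D(x,c)-\delta_S-\xi)^2 +
\sum \max(0, \delta_D-\zeta-D(\bar X_i,\bar X_j))^2 +
\sum\max(0,-\xi)^2 + \sum\max(0,-\zeta)^2\Big].$$

Design choices made where the design was genuinely open:

* **Regularizer** $r(A)=\|A\|_F^2$: smooth, coercive, and its gradient
  $2A$ matches the published derivative structure.
* **Penalty form**: one-sided quadratic penalties — the standard smooth
  penalty-function conversion, differentiable everywhere as the gradient
  formulas require.
* **Slack granularity**: one $\xi$ per (bag, instance) within constraint,
  one $\zeta$ per between pair.
* **Parameterization by $A$** keeps $M = A^\top A$ positive semidefinite
  at every iterate with no projection step.
* **Initialization** $A^0 = I$: the first iterate is the Euclidean
  baseline.
* **Optimization**: alternating per-block gradient updates ($A$, then
  $\xi$, then $\zeta$), each block with its own adaptive backtracking
  multiplier (halve until non-increase, double after acceptance). The
  blocks are scaled very differently — the $A$-gradient is typically
  three orders of magnitude larger than the slack gradients — and a
  shared step stalls the slacks and prevents the $|f_t - f_{t-1}| <
  \varepsilon$ stopping rule from engaging. The objective trace is
  non-increasing by construction.
* **Defaults**: $\lambda=\beta=1$ (the published configuration);
  $\delta_S$/$\delta_D$ default to the median within-bag
  instance-to-center squared distance and the median between-class bag
  distance at $A=I$ (clamped so $\delta_S<\delta_D$); $\sigma = 10$,
  fixed — a $\times 10$ continuation schedule is behind
  `sigma_continuation`; $\varepsilon = 10^{-5}$; `max_pairs = 5000` caps
  the $O(n^2)$ between pairs by seeded uniform down-sampling (a
  tractability device, not part of the model).

Centering: all training-visible instances (SD plus labeled TD; a flag
restricts to SD) define a grand-mean centering transform that is applied
unchanged to test bags — test statistics never leak into preprocessing.

## Prediction heads

**Citation-kNN** (`knn_head`): references are the $r$ training bags
nearest to the test bag under the class metric; citers are training bags
that rank the test bag within their own $c$ nearest neighbors (ties rank
the test bag last — pessimistic and deterministic). References and citers
vote as a multiset; ties predict negative, the conservative choice under
the ~1% positive rates typical of GO-term data. $r=3$, $c=5$ by default;
neither value is published.

**Medoid embedding + SVM** (`fit_svm_head`): per class,
$k = \max(1, \text{round}(0.4\,n_{train}))$ medoid *bags* are found by
seeded alternating k-medoids under the class metric, every bag becomes
the $k$-vector of its distances to the medoids, and a soft-margin RBF
SVM (cost 1, kernel coefficient 0.2 — the published LIBSVM settings) is
trained on the embeddings. Two points deserve emphasis:

* *Bags, not instances, are clustered.* The source text says "cluster all
  of the instances" but defines the embedding coordinate as the distance
  between the *j*-th bag and the *i*-th medoid, and the base method it
  degenerates to clusters bags; bag medoids are the only self-consistent
  reading.
* *Embedding scaling.* Embedding coordinates are min-max scaled to
  $[0,1]$ on training statistics before the kernel (test embeddings reuse
  the training scale). The 0.2 kernel coefficient presumes unit-scale
  features, as with the frequency features it was tuned on; on raw
  squared-distance embeddings (scale $\sim$ tens) the RBF Gram matrix
  collapses to the identity and the classifier degenerates to a constant.
  This is the standard `svm-scale` preprocessing.

No SVM library is bundled or assumed: the dual C-SVC problem is solved by
a compact deterministic SMO (maximal-violating-pair working-set
selection), adequate for the few hundred bags per class this pipeline
trains on. Decision values map to $[0,1]$ confidences by the logistic
squashing; the ranking metrics are invariant to this monotone map.

## The synthetic world

`generate_shifted_miml()` emulates the statistical shape of the organism
benchmarks: bag sizes $1+\text{Poisson}(\text{mean}-1)$ with mean 3.13,
hundreds of classes at ~1% positive rate (per-instance concept
probability $1-(1-\text{label\_rate})^{1/\text{mean}}$), instance
dimension 216 by default. Instances mix a background Gaussian with
per-class Gaussian concepts; a bag is positive for class $k$ iff at least
one instance realized concept $k$, so generated labels are exactly
consistent with the MIL assumption.

The covariate shift is **per bag**: on the coordinates where
`shift_vector` is nonzero, each bag draws a latent center
$t \sim N(\mu_{dom}, \tau^2)$ shared by its instances, with
$\mu_{dom} = 0$ in SD and $\delta$ in TD, and instances scatter around
$t$ so that the marginal instance spread stays `background_spread`
($\tau = s_b/\sqrt2$ by default — variance split evenly between and
within bags). Concept structure lives on the remaining coordinates and is
identical across domains. Consequences:

* The bag density ratio is exact and closed-form — integrating the latent
  center out of the conditional instance product gives
  $\log\omega(X) = \sum_j \delta_j(\bar x_j - \delta_j/2)\,/\,
  (\tau^2 + s^2/n_i)$ — linear in the bag mean over the shifted
  coordinates, monotone along the shift, ratio $\equiv 1$ at zero shift.
* An earlier design drew instances fully independently (the bag density a
  pure product). Its ratio carries an $e^{-n_i\|\delta\|^2/2}$ bag-size
  factor that bounded set-kernel features provably cannot represent: an
  oracle non-negative regression of the *true* ratio onto the kernel
  basis capped at Spearman $\approx 0.3$, making the ratio-recovery
  check unattainable *for any estimator in the model class*. The bag-level
  design is also the more faithful reading of "per-bag covariate shift".
* A consequence worth knowing: bag-level effects create directions that
  are compact within bags and spread between bags yet carry no label
  signal. The metric objective (within-bag compactness plus between-class
  separation, with no same-class attraction term) rewards *amplifying*
  such directions. On this synthetic family the learned metric therefore
  improves its own between/within criterion and helps citation-kNN, but
  can degrade the medoid-embedding head relative to the Euclidean
  baseline — an honest limitation of the method in worlds with strong
  bag-identity variance, documented rather than tuned away.

What a green test on this generator does *not* establish: realistic
conjoint-triad feature marginals, GO term co-occurrence or hierarchy
structure, or instance-level domain shift.

The two published splitting protocols are reproduced:
`split_by_feature_median()` (source = bags with above-median mean feature
value; the exact published two-clause membership condition is lost in the
source, so the deterministic $\ge$-median rule that reproduces the
published 50/50 domain sizes is used, ties by stable index order) and
`split_random_clusters()` (2-means on bag means, one cluster chosen as
source uniformly under the seed).

## Evaluation

`ranking_loss`, `coverage`, `set_metrics` implement the four headline
measures plus set-precision (computed for diagnostics; it is excluded
from headline reporting because the extreme class imbalance makes
all-negative predictors look precise). The published metric formulas are
not recoverable from the source, so the canonical MIML definitions are
used with the *pessimistic* tie conventions — ties count as misordered in
ranking loss; coverage assigns tied labels the worst rank — so reported
scores never flatter the method. F1 is the harmonic mean of the
*averaged* precision and recall. `friedman_nemenyi()` computes average
ranks (ties averaged), the Friedman chi-square, and the Nemenyi critical
distance $q_\alpha\sqrt{m(m+1)/(6N)}$ with
$q_\alpha = \texttt{qtukey}(1-\alpha, m, \infty)/\sqrt2$.

`benchmark_run()` repeats generate/split → fit → predict → score over a
seed list for any subset of `mimtl_svm`, `mimtl_knn`,
`euclidean_svm_baseline` ($\omega\equiv1$, $A=I$ — a MIMLSVM-like
pipeline) and `unweighted_metric` ($A$ learned, $\omega\equiv1$), and is
fully reproducible from the seeds.

## Numerical notes and degenerate inputs

* Gradients of the penalty objective are exact everywhere (the one-sided
  quadratic is $C^1$); finite-difference agreement is tested to 1e-5.
* `fit_bag_weights` errors on non-PSD input beyond an 1e-8 relative
  eigenvalue tolerance; `alpha = 0` is returned when $b \le 0$ (all
  constraints active).
* Classes with no positive training bag are skipped with a warning;
  single-label classes get a constant predictor; empty/full label sets
  are skipped by ranking loss (error if nothing remains) and contribute 0
  to coverage.
* k-medoids ties (assignment and medoid update) break to the lowest bag
  index; the iteration stops when the medoid set is stable.
* All stochastic steps (generation, basis subsampling, pair
  down-sampling, medoid initialization, cluster splits) consume explicit
  integer seeds; CLI outputs are byte-reproducible given `--seed`.

## Known limitations

* Instance-level weights (as in instance-and-bag weighting schemes) are
  out of scope; only bag weights are implemented.
* No low-rank, diagonal or kernelized metric variants.
* The LAMDA archive adapter is documentation-only: the archive is a
  MATLAB binary, and no `.mat` reader is assumed; `?read_miml_table`
  documents the plain-text interchange format a converter should target.
* Hausdorff bag distances and probability calibration are out of scope.
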