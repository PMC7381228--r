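---
title: "Combining partially overlapping relationship matrices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Combining partially overlapping relationship matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(covcomb)
```

## The problem

Breeding programs and genebanks accumulate genotypic and phenotypic data
across many independent experiments.  Each experiment characterizes
relatedness only for its own genotypes — a marker panel here, a pedigree
there, a set of phenotypic trials elsewhere — so what is available in
practice is a collection of relationship matrices
$G_{a_1}, \dots, G_{a_m}$ over partially overlapping genotype subsets
$a_1, \dots, a_m$ with union $K$ ($|K| = n$).  Genomic prediction, and any
other analysis that needs a single kernel over all genotypes, requires one
combined matrix $\Sigma$ over $K$, including the blocks that no experiment
observed.

## The model and the estimator

`covcomb` treats each observed kernel as a draw from a Wishart
distribution whose scale is the corresponding block of the combined
matrix:

$$G_a \sim \mathcal{W}(\nu, \Psi_a), \qquad
  \mathbb{E}[G_a] = \nu \Psi_a = \Sigma_a .$$

The degrees of freedom $\nu$ play the role of the (effective) number of
features — markers, transcripts, trials — behind each kernel.  Writing
$b = K \setminus a$ for the genotypes a sample does not cover, the EM
iteration completes every sample by its conditional expectation given the
observed block and averages the completions:

$$\Psi^{(t+1)} = \frac{1}{\nu m} \sum_{a}
  P_a \begin{bmatrix}
    G_a & G_a B_{b|a}' \\
    B_{b|a} G_a & \nu \Psi^{(t)}_{b|a} + B_{b|a} G_a B_{b|a}'
  \end{bmatrix} P_a' ,$$

with the regression coefficients and conditional covariance of the
unobserved genotypes on the observed ones,

$$B_{b|a} = \Psi_{ba}^{(t)} \left(\Psi_a^{(t)}\right)^{-1}, \qquad
  \Psi_{b|a}^{(t)} = \Psi_b^{(t)} -
  \Psi_{ba}^{(t)} \left(\Psi_a^{(t)}\right)^{-1} \Psi_{ab}^{(t)} .$$

The permutation matrices $P_a$ align each completed sample to a common
genotype order; `covcomb` realizes them as integer index maps, which is
mathematically identical and avoids $O(n^2)$ multiplications.  The final
estimate converts back to the relationship scale as
$\Sigma^{(T)} = \nu \Psi^{(T)}$.

Three consequences of this construction, each verified by the test suite:

* **$\nu$-invariance.**  Written on the $\Sigma$ scale the update contains
  no $\nu$: both $B_{b|a}$ and $\nu\Psi_{b|a}$ are functions of $\Sigma$
  alone.  The estimate is therefore independent of $\nu$ (which only
  scales the likelihood), and `combine_em` initializes on the $\Sigma$
  scale so that this invariance is exact in floating point.
* **Monotone likelihood.**  The iteration is an exact EM for the Wishart
  model (the conditional expectation of the unobserved blocks of a
  Wishart draw given its observed block is precisely the bracketed
  matrix), so the observed-data log-likelihood never decreases.
* **H-matrix equivalence.**  When the initial value is a full
  relationship matrix $A$ (say pedigree-based) and a single genomic
  kernel $G$ nested in $A$ is supplied, one iteration lands on the
  single-step H-matrix
  ($H_{22} = G$, $H_{12} = A_{12}A_{22}^{-1}G$,
  $H_{11} = A_{11} + A_{12}A_{22}^{-1}(G - A_{22})A_{22}^{-1}A_{21}$)
  and the algorithm has converged.  The EM estimator generalizes
  single-step blending to any number of, possibly non-nested, kernels.

### Weighted samples

A reliability weight $w_a \in [0,1]$ per sample replaces $G_a$ by the
convex blend $w_a G_a + (1 - w_a)\,\nu\Psi_a^{(t)}$ before completion.
At $w_a = 1$ the kernel is used as observed; at $w_a = 0$ it carries no
information and the estimate stays at the prior for that block.

## Parameters that matter

* `nu` — Wishart degrees of freedom.  Defaults to the mean `n_features`
  recorded on the samples, or 1000 when unrecorded.  It does not move the
  estimate; it only scales the reported log-likelihood (and would enter
  any sampling-variance statement).  It must exceed $|a| - 1$ for a
  sample's density to exist; smaller samples are skipped in the
  likelihood trace with a warning but still drive the estimate.
* `init` — the prior guess of $\Sigma$, identity by default
  (uninformative).  With few samples the estimate of never-observed
  blocks is visibly shrunk toward the init, so when good prior
  information exists (e.g. a pedigree A-matrix) supplying it is worth
  doing; the shrinkage fades as the number of samples grows.  When a full
  init matrix is supplied, its labels define the genotype set, which is
  how genotypes absent from every sample (the H-matrix use case) remain
  in the estimate.  With the identity init, the genotype set is the union
  of the sample labels: a genotype in no sample would be pure prior.
* `tol`, `max_iter` — convergence is declared when the relative Frobenius
  change of $\Psi$ drops below `tol` (default `1e-6`, `max_iter = 200`).
  Convergence is geometric with a rate controlled by the fraction of the
  matrix that is unobserved; disjoint or barely-overlapping designs
  converge slowly, and the experiment harnesses therefore accept
  `tol = 1e-5`, where the evaluation metrics have long plateaued.
* `jitter` — blocks are inverted via Cholesky solves; the default adds no
  ridge (keeping the iteration an exact EM, which is what makes the
  closed-form H-matrix comparison hold to 1e-10) and escalates a relative
  ridge from 1e-10 only if a factorization fails.  A fixed ridge can be
  requested for deliberately rank-deficient kernels.

Combining correlation matrices works unchanged (a correlation matrix is a
covariance matrix with unit diagonal); the combined output is *not*
re-standardized by default, since the blend of correlation blocks is a
covariance matrix whose diagonal may drift from 1 — apply
`cov2cor_kernel()` to the result when a correlation matrix is wanted.

## Kernels

`grm_vanraden()` builds the marker kernel as
$G = ZZ' / \left(2\sum_j p_j(1-p_j)\right)$ with $Z$ the dosage matrix
centered at twice the per-marker allele frequencies (method 1 with
observed frequencies — the field default).  Missing dosages are
mean-imputed per marker before centering and monomorphic markers are
dropped.  Frequencies are estimated per panel; in the combine-versus-
impute experiment each sub-panel is centered by its own frequencies, as
separate experiments would be in practice.  `amatrix_tabular()` builds
the pedigree numerator relationship matrix by the diploid tabular method;
the autotetraploid extension is out of scope.  `ensure_psd()` clips
negative eigenvalues for kernels that arrive indefinite from rounding or
file drift; it is offered, not forced.

## Prediction

`reml_spectral()` fits the standard single-kernel G-BLUP mixed model
(intercept-only fixed effects) by eigendecomposition of the kernel and a
1-D profiled REML optimization of the variance ratio — robust and exact
for this model class.  `multikernel_reml()` fits one variance component
per kernel by average-information REML with EM fallback steps: plain
EM-REML is monotone but linearly convergent, too slow to match the
spectral fit to 1e-6; the AI step restores fast convergence near the
optimum and the EM step guarantees progress elsewhere.  Negative
components are floored at effectively zero.  `gblup_predict()` predicts
unphenotyped genotypes by the conditional mean
$K_{21}K_{11}^{-1}\hat{g}$.  Accuracy is always the Pearson correlation
between GEBVs and observed values, and the two cross-validation
harnesses mirror the two standard scenarios: random folds
(`cv_random_folds`) and leave-one-dataset-out
(`cv_leave_dataset_out`).  On dataset-structured populations the random
folds can exploit within-dataset relatives while the leave-dataset-out
scenario cannot, so the first accuracy is systematically higher — the
gap is a measure of how much harder across-population prediction is.

## What the generators emulate — and what they do not

The synthetic module generates every input the analyses need:

* `simulate_markers()` — unstructured biallelic panels in Hardy-Weinberg
  equilibrium with uniform allele frequencies, independent loci.
* `simulate_pedigree_genedrop()` — random-mating pedigrees with Mendelian
  gene drop at independent loci, so the realized relationships fluctuate
  around the tabular A-matrix exactly as theory predicts; this provides
  the independent oracle for `amatrix_tabular()` and the related
  populations used in prediction tests.
* `sample_wishart_partials()` — partial kernels drawn exactly from the
  model (`stats::rWishart`, Bartlett decomposition), the clean setting
  for parameter-recovery experiments.
* `make_overlap_design()` — chained subset designs with controlled
  overlap, wrapping cyclically so that large sample counts remain
  feasible while distant genotype pairs stay unobserved.

Independent loci mean no linkage disequilibrium; the generators produce
no genotyping error, no population-specific allele frequencies and no
selection.  None of these affect the properties asserted here (the
estimator consumes relationship matrices, not markers), but passing
tests on these generators say nothing about, e.g., how a GRM built from
low-quality markers degrades the combined estimate.

## Experiment designs and problem sizes

Two harnesses reproduce the validation designs at desk scale:

* `run_anchor_experiment()` — two disjoint sets of pedigree relatives
  (their A-matrices share no information) are anchored by one genomic
  kernel built on a genotyped subsample, half from each set.  The
  combined estimate of the cross-pedigree relationships is scored against
  the full-pedigree A-matrix on entries observed in no kernel.  Accuracy
  rises with the number genotyped; defaults use pedigrees of 100 with
  10–40 genotyped per pedigree and 2,000 markers.
* `run_combine_vs_impute()` — a full marker panel is the ground truth
  (default 300 genotypes × 5,000 markers); sub-panels of 100 genotypes ×
  500 markers are drawn, and the combined kernel is compared against the
  route that imputes the union dosage matrix (`soft_impute()`, rank 50,
  no soft threshold — settings fixed once; the completed-entry metrics
  are insensitive to them in this range) and then builds a GRM.
  Combining is the more accurate route, and its error falls as panels
  accumulate, while never-observed relationships start out shrunk toward
  the init and recover as samples grow.

The test suite runs these designs with 10–20 replicates and the
recovery study at $n = 50$ with up to 40 partial samples; the
acceptance script reruns them at the same sizes with about 10
replicates.  These sizes keep every Monte-Carlo comparison comfortably
significant for the monotone trends asserted, while a full run of suite
plus script completes on a single CPU in well under an hour.

## Numerical choices and degenerate inputs

* Matrix files are symmetrized on read as $(M + M')/2$ with a warning
  past relative asymmetry 1e-6; label matching is exact and
  case-sensitive everywhere (a silent fuzzy merge is worse than a miss).
* Unknown parents may be written `0`, `NA` or empty; pedigrees are
  topologically sorted on construction and cycles are reported with the
  offending individuals.
* A constant phenotype vector yields a zero fit (no variance to
  partition) rather than an optimizer failure; a kernel proportional to
  the identity raises an identifiability error, since genetic and
  residual variance cannot be separated.
* `combine_em` symmetrizes the iterate every step; with PSD inputs and a
  PD init the estimate stays PSD in practice (asserted empirically on
  random instances, not claimed as a theorem — indefinite *input*
  kernels are the user's to repair, e.g. with `ensure_psd()`).

## Known limitations

* Sampling variances / asymptotic standard errors of the combined
  estimate are not provided, and $\nu$ is not estimated by maximum
  likelihood; a large $\nu$ on the feature-count scale is assumed.
* Features themselves are never imputed: the package combines
  relationships.  When inference about individual markers is the goal,
  a feature-level method is the right tool.
* The missingness mechanism is assumed ignorable (subsets not chosen as
  a function of the unobserved relationships).
* Estimates of never-observed blocks inherit the init when samples are
  few; with `init = "identity"` they are shrunk toward zero
  off-diagonals, which is visible in the experiment reports as a bias
  that fades with the number of samples.
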