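---
title: "Methods: feature-based prediction of temperature-sensitive mutations"
author: "tsmut"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: feature-based prediction of temperature-sensitive mutations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tsmut)
```

## Overview

`tsmut` predicts whether a single amino-acid substitution produces a
temperature-sensitive (TS) phenotype — wild-type activity at a permissive
temperature, reduced activity at a restrictive temperature. The method has
three stages:

1. **Feature extraction.** Each mutation is described by site-level
   descriptors and by aggregates over three residue neighborhoods
   (sequence window, Euclidean sphere, Delaunay-topological).
2. **Classification.** A logistic regression with inverse-class observation
   weights, on a feature subset selected by the Lasso via Least Angle
   Regression (LARS), refitted unpenalized on the selected subset.
3. **Evaluation.** Five measures (ACC, MCC, KL, DD, AUC) under stratified
   ten-fold or leave-one-protein-out cross-validation.

This vignette records the modelling assumptions, the tunable parameters and
their defaults, the numerical choices, and what the synthetic-data module
does and does not emulate.

## Neighborhood definitions

For a mutation site $i$ (0-based internal index along one chain):

* **Sequence**: residues $j$ with $|j-i| \le w$, default $w = 11$ residues.
  The default follows the cutoff scan protocol (single 20-D count feature,
  AUC versus cutoff), which plateaus around 11 for sequence windows.
* **Euclidean**: residues with $\lVert C\alpha_j - C\alpha_i\rVert \le r$,
  default $r = 13$ Å, boundary inclusive. The scan rises to a plateau near
  13 Å.
* **Topological**: residues sharing a Delaunay tetrahedron with $i$,
  additionally capped at the same radius $r = 13$ Å so results are
  comparable with the Euclidean set. By construction the topological
  neighborhood is a subset of the Euclidean one at equal radius, and its
  size is markedly more stable in $r$ (tetrahedra cluster four nearest
  neighbors without any absolute cutoff).

The site itself is never a member of its own neighborhood (`includeSite`
in `featureConfig()` flips this, default off). Each tetrahedron is
classified by how its four sorted vertices partition into maximal runs of
consecutive chain positions: $\{4\}$ = I, $\{3,1\}$ = II, $\{2,2\}$ = III,
$\{2,1,1\}$ = IV, $\{1,1,1,1\}$ = V. Only the partition classes matter
downstream (counts per class at the mutation site); the Roman numerals are
a fixed labelling of the five possible partitions.

## Delaunay tessellation

The tessellation of the Cα point set is computed by incremental
Bowyer–Watson insertion with a single ghost vertex representing the hull.
Numerical policies:

* **Degeneracy of the input**: fewer than 4 points, or a point set whose
  centered coordinate matrix is numerically rank-deficient (third singular
  value below $10^{-9}$ of the first) is rejected as degenerate
  (collinear/coplanar).
* **Cospherical ties**: before insertion the coordinates receive a
  deterministic jitter (fixed internal seed, relative magnitude $10^{-8}$
  of the bounding box). This acts as a reproducible symbolic-perturbation
  stand-in: ties are broken the same way on every run and on every
  machine. The same jitter helper is applied to the brute-force
  empty-circumsphere oracle in the test suite so the two are compared on
  identical inputs.
* **Predicates**: the in-sphere test is evaluated as a 4×4 determinant
  (expansion along the squared-norm column) multiplied by the sign of the
  orientation determinant, in double precision; with the jitter applied,
  near-zero predicate values do not arise for realistic point sets.

The test suite verifies exact agreement with an $O(n^5)$ brute-force
enumeration of empty circumspheres for hundreds of random point sets
(n ≤ 12), plus invariance under rigid motion and the subset/monotonicity
properties.

## Feature registry

`featureRegistryNames()` fixes a stable order of 164 features: 50 site
features followed by sequence- (37), Euclidean- (38), and topological-
neighborhood (41) blocks. The count differs from older feature catalogues
because conservation is computed at both subfamily and superfamily levels
wherever an alignment is supplied, while features that require external
tools (positional HMM conservation, disorder predictors, ΔΔG programs,
ligand-site databases) are represented as annotation pass-throughs: they
are masked unless the user supplies the annotation, never silently
approximated.

Notable conventions:

* 20-D count vectors are in fixed alphabetical one-letter order and always
  sum to the neighborhood size.
* Exactly one of the nine class-substitution indicators
  (non-polar/polar/charged × same) is 1 per mutation. The three-class
  grouping puts {D,E,K,R,H} in the charged class; the numeric charge
  feature treats His as 0 at pH 7.
* Hydrophobicity defaults to the Kyte–Doolittle scale; volumes are
  Zamyatnin residue volumes; both are configurable.
* The Grantham distance matrix is computed from Grantham's composition,
  polarity and volume properties with the mean-100 normalization,
  reproducing the published integer table (e.g. L–I = 5, C–W = 215).
* "Unusual residues" is a configurable indicator set, default {G, P, C}
  (glycine's flexibility, proline's backbone constraint, cysteine's
  disulfide potential). The default is a documented guess, not a
  reconstruction.
* "Buriedness" is emitted both ways: as $1 - \overline{\mathrm{RSA}}$ and
  as the count of members with RSA at or below the buried threshold
  (default 0.05, inclusive, configurable).
* Mutant-side structural features are approximated from the wild-type
  structure: mutant SASA equals wild-type SASA, mutant RSA renormalizes
  the wild-type area by the mutant residue type's maximum ASA. No mutant
  side-chain modelling is attempted; this is a documented approximation.
* Missing values are explicit: masked cells are `NA` plus a logical mask;
  imputation happens only inside model fitting (weighted training means,
  reused at test time).

## Solvent accessibility

Shrake–Rupley numerical SASA with 960 deterministic sphere points per atom
(generalized spiral; no RNG), probe radius 1.4 Å, van der Waals radii by
element (C 1.70, N 1.55, O 1.52, S 1.80, default 1.80 Å). RSA divides each
residue's area by a bundled maximum-ASA table (theoretical values of Tien
et al.); which normalization table legacy accessibility programs used is
not knowable from their outputs, so the table is a configuration constant,
not a fidelity claim. Two consequences worth knowing:

* An isolated residue can have RSA above 1 (it exposes more area than the
  in-chain maximum that defines the table). The test suite asserts
  RSA ≥ 1 for a free residue rather than RSA ≈ 1.
* With a fixed sphere-point grid, SASA is exactly invariant under
  translation but only quadrature-accurate under rotation (about 1–2 %
  relative at 960 points); the tests use a tolerance consistent with the
  point count.

## Conservation

Column entropy $H = -\sum_a p_a \log_2 p_a$ over the 20 amino acids, gaps
excluded from counts (a 21-symbol mode is available); relative entropy
$\mathrm{RE} = \sum_a p_a \log_2 (p_a/q_a)$ against a background $q$ that
defaults to the alignment's pooled composition with a one-count
pseudocount per amino acid (keeping $q$ strictly positive). All-gap
columns are masked. No sequence weighting or column pseudocounts are
applied to $p$: the entropy estimator is the plug-in estimator, a
deliberate simplicity choice given that the original estimator is
unspecified. With the pooled background, entropy and relative entropy are
strongly anti-correlated on alignments containing conserved columns, which
the tests verify on synthetic alignments.

Structure positions map to alignment columns by globally aligning the
chain sequence to the ungapped first alignment row; more than 5 %
mismatches among aligned positions is a hard error rather than a warning,
since a mis-mapped alignment silently corrupts every conservation feature.

## The classifier

**Weights.** With $n_1$ TS and $n_0$ neutral examples, observations get
weights $n/(2n_1)$ and $n/(2n_0)$: total weight $n$, equal class mass — a
50-50 effective mixture. Consequence (tested): the weighted intercept
equals the intercept of the balanced-population parametrization, shifted
by the realized log class ratio.

**Selection.** LARS with the Lasso modification runs on the weighted
squared-error surrogate: rows scaled by $\sqrt{w_i}$, features
standardized by weighted mean and (population) SD, response centered. The
standardization is required for scale-free selection and is a documented
decision. The path records every add/drop; the selection point is chosen
by 5-fold cross-validated deviance of the downstream weighted logistic
refit over path prefixes (the null model is a candidate), with ties going
to the smaller set; `lassoSteps` forces a fixed number of steps instead.

**Refit.** The selected subset is refitted by damped IRLS (Newton with
step-halving) to a gradient tolerance of $10^{-8}$ relative to the total
weight. Zero-variance features are dropped with a warning. If the
optimizer fails to converge or the linear predictor diverges
(|η| > 30 — numerically saturated probabilities, the signature of
separation), the fit is repeated with a ridge of $10^{-6}$ on the
standardized slopes and a warning. Coefficients are reported on the
original feature scale.

The LARS implementation is verified against the Lasso KKT conditions at
every breakpoint, against the soft-thresholding closed form on orthogonal
designs, against weighted least squares at the unconstrained end of the
path, and against the entry order of an independent coordinate-descent
Lasso (glmnet) — the cross-checks live in the test suite, never in the
implementation.

## Evaluation

With threshold $t = 0.5$ (inclusive: $p \ge t$ predicts TS):
ACC $=(TP+TN)/N$; MCC with the convention that a zero factor in the
denominator yields 0; KL divergence between predicted and observed class
distributions in bits. Threshold-free: AUC as the Mann–Whitney statistic
with ties counted one half (the trapezoidal ROC integral agrees to
machine precision), and DD — the posterior range $[0,1]$ is split into ten
equal intervals, TS and neutral predictions are histogrammed and
normalized, empty bins are smoothed with $\varepsilon = 10^{-10}$, and the
KL formula is applied across bins. DD is zero exactly when the two binned
distributions coincide. An `empirical` option bins the observed
probability range instead; $[0,1]$ is the default because posterior
probabilities have a natural scale.

Cross-validation is stratified by label; out-of-fold predictions are
pooled and scored once (a per-fold-averaged alternative would change the
variance of the estimate; pooling is the package's choice and is exposed
in the report's per-fold table). Within every training fold the entire
two-stage pipeline — imputation, selection, refit — is re-run from
scratch. Leave-one-protein-out holds out all mutations of one protein and
emits one report per protein. Measure concordance across per-feature
classifiers uses Pearson correlation plus mutual information on 10
equal-width bins per measure (the binning mirrors DD's spirit; the bin
count is configurable).

## Synthetic data: what it does and does not emulate

`generateStructure()` grows a self-avoiding random walk with consecutive
Cα–Cα distances of 3.8 ± 0.01 Å, all non-consecutive pairs at least 4.0 Å
apart, and an inward bias proportional to the distance beyond a target
globule radius $3.3\,n^{1/3}$ Å (compactness 0.55 by default — radius of
gyration ≈ 11 Å at n = 100, in the range of small globular proteins).
Schematic backbone atoms (N, C, O) and a pseudo side-chain atom (CB,
absent for Gly) support the SASA, thermal-factor and interaction-count
machinery. B-factors couple to burial (buried residues more rigid:
mean 25 Å², SD 8 Å², coupling 0.8) with side-chain values slightly above
residue values. The generator emulates *geometry and statistics*, not
physics: no secondary structure, no rotamers, no energetics, no real
fold. Consequently, passing tests demonstrate correctness of the
computational pipeline and recoverability of known signal — not predictive
accuracy on real proteins, which depends on real mutagenesis corpora.

`generateAlignment()` makes the structure's sequence the first row (column
map = identity), draws a configurable fraction of columns conserved
(consensus repeated with probability 0.9 by default), leaves the rest
near-uniform, and sprinkles gaps at rate 0.02. Real alignments have
phylogenetic correlation between rows; synthetic rows are independent, so
conservation estimates are cleaner than reality.

`generateLabeledMutations()` samples substitutions uniformly, computes
features through the real pipeline, and draws labels from
$\mathrm{Bernoulli}(\mathrm{logistic}(\beta_0 + \beta^\top z))$ where $z$
are (by default) cohort-standardized features, keeping the logit range
controlled independently of feature units. Truth parameters, seed and
probabilities are stored with the cohort; calibration of the sampled
labels against the stored probabilities is tested at n = 10,000.

## Problem sizes and determinism

The test suite and the acceptance script use synthetic systems of 60–100
residues with cohorts of 250–400 mutations (5,000–10,000 for parameter
recovery and calibration), ten-fold cross-validation, and 200 random point
sets for the geometry oracle — sizes chosen so the full suite completes in
well under two minutes per module while keeping every statistical
assertion comfortably powered. Every random step (chain growth, alignment
sampling, label draws, fold assignment, tie-break jitter) is governed by
an explicit seed, and generators restore the caller's RNG state, so
identical configurations give byte-identical outputs.

## Known limitations

* Mutant structural features come from the wild-type structure
  (renormalized RSA); substitutions whose effect hinges on side-chain
  rearrangement are under-described.
* Positional-HMM conservation, predicted disorder, computed ΔΔG and
  database-derived ligand sites enter only as user-supplied annotations.
* Hydrogen-bond and salt-bridge counts use simple geometric criteria
  (N···O ≤ 3.5 Å; side-chain N⁺···O⁻ ≤ 4.0 Å between basic and acidic
  residues) without angles or hydrogen placement.
* The per-protein chain model covers one chain; inter-chain contacts in
  oligomers are invisible.
* Probabilities are logistic-calibrated on the training mixture; no
  post-hoc calibration is applied.
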