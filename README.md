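# tsmut

Prediction of temperature-sensitive (TS) mutations from sequence and
structure neighborhood features.

## The problem

TS mutants — protein variants that work at a permissive temperature
(25–30 °C) and lose function at a restrictive temperature (37 °C) — are a
classic tool for probing gene function *in vivo*, but only a few percent of
random single amino-acid substitutions produce one. `tsmut` implements a
statistical route to them: describe each candidate substitution by a large
registry of sequence and structure features, fit a classifier on known
TS/neutral mutations, and rank new substitutions by their posterior
probability of being TS.

The package is aimed at structural bioinformaticians and at groups doing
targeted mutagenesis who want a ranked list of candidate TS substitutions
for a protein with a known structure.

## The model

Each mutation is described at the **site** and in three kinds of
**neighborhood** of the mutated residue:

* *sequence* neighborhood — residues within ±11 positions along the chain;
* *Euclidean* neighborhood — residues whose Cα lies within a 13 Å sphere;
* *topological* neighborhood — residues that share a Delaunay tetrahedron
  (hence a Delaunay edge) with the site, capped at the same radius. The
  Delaunay tessellation of the Cα point set defines clusters of four
  nearest neighbors without an absolute distance cutoff, which makes this
  neighborhood notably robust to the choice of radius.

Features include column entropy and relative entropy of superfamily and
subfamily alignments, hydrophobicity/volume/charge and Grantham distance,
amino-acid class substitution indicators, Shrake–Rupley solvent
accessibility and relative accessibility, raw and normalized thermal
factors, 20-dimensional residue-count vectors per neighborhood, hydrogen
bond and salt-bridge counts, Delaunay tetrahedron counts by
backbone-connectivity class (I–V), and annotation-driven features
(secondary structure, disorder, functional-site distances, precomputed
ΔΔG), with an explicit missing-value mask throughout.

The classifier is a logistic regression

    P(TS | x) = 1 / (1 + exp(−(β₀ + Σᵢ βᵢ xᵢ)))

with TS and neutral examples weighted inversely to their class counts (a
50–50 effective mixture), and a parsimonious feature subset chosen by the
Lasso via Least Angle Regression on the weighted squared-error problem,
followed by a plain weighted logistic refit on the selected subset.
Performance is measured with five statistics — ACC, MCC, Kullback–Leibler
divergence, distribution distance (DD), and ROC AUC — under stratified
ten-fold or leave-one-protein-out cross-validation.

A synthetic-data module generates compact Cα traces (3.8 Å virtual bonds),
alignments with controlled column conservation, and mutation cohorts
labeled from a known logistic truth model, so the whole pipeline is
exercisable and calibratable without external downloads.

## Worked example

```r
library(tsmut)

spec   <- syntheticSpec(nResidues = 100, seed = 42)
s      <- generateStructure(spec)
aln    <- generateAlignment(spec, s)
tess   <- delaunayTessellation(s)
print(tess)
#> Tessellation: 531 tetrahedra; 660 edges
#>   I  II III  IV   V
#>  27  85  70 257  92

topologicalNeighborhood(s, tess, site = 50, radius = 13)
#> Neighborhood [topological] site=50 cutoff=13: 17 members

truth  <- c(euc_n_residues = 1.0, top_ent_sub = -1.2, rsa_wt = -0.8)
cohort <- generateLabeledMutations(s, aln, truth, truthBeta0 = -0.5,
                                   n = 400, seed = 43)
model  <- fitTSModel(cohort$features, featureSet = "all", lassoSteps = 12)
print(model)
#> FittedModel: 9 features, intercept 5.923
#>    top_ent_sub        rsa_mut         rsa_wt b_residue_norm    top_count_N ...

report <- crossValidate(cohort$features, k = 10, featureSet = "all",
                        lassoSteps = 12, seed = 1)
print(report)
#> EvaluationReport (threshold 0.5):
#>    ACC    MCC     KL     DD    AUC
#> 0.7750 0.5429 0.0012 1.3236 0.8156
```

The tessellation summary counts Delaunay tetrahedra by how their four
vertices group into runs of consecutive chain positions (class I = four
consecutive residues … class V = four mutually non-consecutive residues).
The cross-validated report says the recovered model separates TS from
neutral mutations with AUC 0.82 on this synthetic cohort whose labels were
drawn from a truth model weighted on neighborhood size, topological
conservation, and site burial; DD ≈ 1.3 means the predicted TS and neutral
probability histograms are well separated.

A command-line interface wrapping the same functions ships in
`inst/cli/tsmut.R`, with subcommands `simulate`, `featurize`, `fit`,
`predict`, `evaluate`, `scan-cutoffs`, and `concordance`.

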