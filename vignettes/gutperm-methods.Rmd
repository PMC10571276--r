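---
title: "Methods: gut-permanence characterization and prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gut-permanence characterization and prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models, conventions and
numerical choices. Nothing here states an empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## The permanence label and its assumptions

The package works with four compound populations: metabolites detected only
in the gut (Gut), detected in both gut and serum (Gut/Serum), detected only
in serum (Serum), and orally administered, systemically acting small-molecule
drugs (DrugBank). Two operational assumptions turn these into a binary
endpoint:

1. Detection in serum is taken as evidence of gut-wall crossing — except for
   the four fatty-lipid (FL) chemical classes (glycerolipids,
   glycerophospholipids, fatty acyls, sphingolipids), which are hydrolyzed by
   lumenal lipases before absorption and resynthesized beyond the gut wall;
   their serum presence reflects de novo synthesis, so FL members of
   Gut/Serum are reassigned to Gut (`reassign_fl()`).
2. After that reassignment, **Lingerer** (the positive class) = Gut-FL ∪
   Gut-noFL and **Traverser** = DrugBank ∪ updated Gut/Serum. Serum-only
   molecules keep no permanence label and never enter the model.

Both assumptions are approximations: a low-but-nonzero-bioavailability
molecule can appear in serum by chance, and serum detection can reflect
synthesis in that compartment even outside the FL classes. The labels
inherit this noise; the label-noise knob of the synthetic generator exists
precisely to probe sensitivity to it.

## Chemistry backend and conventions

All structure handling goes through OpenBabel (ChemmineR/ChemmineOB, plus
the `obabel` CLI for SMARTS matching, whose in-process binding is unusable
in the installed ChemmineOB build). Conventions that matter downstream:

* **Normalization** (`normalize_structures()`): keep the largest connected
  fragment, neutralize charges where chemically valid, emit canonical
  SMILES. Idempotent by construction. Limitations: the largest fragment is
  chosen by atom count (a pathological salt whose counterion is the largest
  fragment would be mis-stripped), formal charges that survive
  neutralization (e.g. quaternary ammonium) are not tracked in the
  implicit-hydrogen model, and no tautomer canonicalization is attempted.
  Stereochemistry is retained by default; `keep_stereo = FALSE` strips
  tetrahedral and double-bond markers before canonicalization.
* **Descriptors**: MW, logP and TPSA come from OpenBabel; `hba`/`hbd` are
  Lipinski-style N/O counts (N+O atoms; N/O atoms bearing ≥ 1 H, with
  implicit hydrogens from standard valences on the kekulized graph); `rb`
  counts non-ring single bonds between non-terminal heavy atoms, excluding
  amide C–N; `nring` is the circuit rank (SSSR count); `naring` counts SSSR
  rings whose atoms are all aromatic, where per-atom aromaticity is read
  from OpenBabel's canonical SMILES (lowercase atoms) — OpenBabel preserves
  SMILES atom order when writing molfiles, which the package relies on;
  `fsp3` is the fraction of carbons with no double/triple bond (0 for
  carbon-free molecules).
* **QED** is implemented in-package from the published desirability-function
  parameterization (asymmetric double sigmoids over MW, ALOGP, HBA, HBD,
  PSA, ROTB, AROM, ALERTS; weighted geometric mean). The structural-alert
  term uses a reduced, package-curated set of 19 classical reactive/
  promiscuous-motif SMARTS (nitro, aldehyde, acyl halide, anhydride,
  epoxide, aziridine, Michael acceptor, alkyl halide, thiol, hydrazine,
  azide, isocyanate, azo, quaternary nitrogen, peroxide, sulfonyl halide,
  disulfide, long aliphatic chain), not the full published alert catalogue.
  QED values are therefore valid [0, 1] drug-likeness scores with the
  standard qualitative behaviour (long-chain lipids near 0, lead-like
  heterocycles near 0.5–0.8) but are not bit-identical to other toolkits.
* **Scaffolds** (`murcko_scaffold()`): the 2-core of the heavy-atom graph
  (iterative removal of degree-≤1 atoms leaves rings plus linkers), plus
  atoms attached to that core by a bond of order ≥ 2 (retaining exocyclic
  carbonyls), canonicalized through OpenBabel. Ringless molecules have no
  scaffold. Scaffold statistics weight ring counts and aromatic/hetero
  fractions by *unique scaffold*, not by molecule; a heteroaromatic ring
  counts toward both fractions. With a single unique scaffold the SDs are
  `NA`.
* **Fingerprints** (`path_fingerprint()`): every linear path of 0–7 bonds is
  written as an element/bond-order string (aromatic ring bonds labelled
  `a`, read in the lexicographically smaller direction) and hashed
  (31-ary rolling hash) onto 2048 bits. Deterministic, and 0-bond paths
  make even single-atom molecules produce a nonzero fingerprint; two empty
  fingerprints have Tanimoto 0 by convention. The fingerprint is
  self-consistent but intentionally not bit-compatible with any other
  toolkit; it is used only inside the package (similarity profiles, Butina
  splits).

## Ionization classes

A molecule carries an ionized acidic group iff its strongest-acidic pKa is
strictly below the environment pH, and an ionized basic group iff its
strongest-basic pKa is strictly above it; the four classes follow the truth
table (acid, basic, zwitterion, neutral). Decisions: missing pKa ⇒ the group
is absent (the classification consumes the two database-reported pKa fields
and never predicts pKa from structure); boundary equality ⇒ absent (strict
inequalities); implausible database pKa values are used as reported, with no
outlier filtering. The shipped pH presets are duodenum 6.0, caecum 6.4,
jejunum/descending colon 7.0, ileum/sigmoid/rectum 7.4 (default 7.4).
Class membership is binary; no fraction-ionized/microspecies computation.

## Statistical battery

* `cles()` is computed by the rank-sum identity, which reproduces exact pair
  enumeration including the half-weight tie convention.
* `kruskal_conover()`: omnibus from base R's tie-corrected Kruskal–Wallis;
  the Conover post hoc uses pooled tie-corrected ranks, the pooled variance
  S² = (Σr² − N(N+1)²/4)/(N−1), the chi-square-adjusted factor
  (N−1−H)/(N−k), and two-sided t tests on N−k degrees of freedom, with a
  configurable multiplicity correction (Bonferroni default). Note that on
  very small samples the chi-square omnibus approximation is coarse: for
  {1,1,1} vs {9,9,9} vs {9,9,9.1} the omnibus p is 0.030, even though the
  separation looks extreme.
* `mannwhitney_bh()` runs one two-sided Wilcoxon rank-sum test per
  (chemical class × property) cell, restricted to classes present in both
  groups, and applies Benjamini–Hochberg **jointly across all tested
  cells** (a single pooled family, the more conservative of the plausible
  pooling choices); direction comes from CLES vs 0.5.
* `contingency_posthoc()` computes margin-based expected counts, adjusted
  residuals (O−E)/√(E(1−rowfrac)(1−colfrac)), and a cell p-value from the
  two-sided exact Fisher test of the 2×2 collapse of the cell against the
  rest of its row and column. The exact-cell-test literature admits
  variants; the collapse-plus-Fisher reading is implemented, with the
  direction always taken from the residual sign, and the correction family
  sized as the full R×C cell count of the analyzed table. Cells on a zero
  margin are untestable (`NA`). For 2×2 tables every squared adjusted
  residual equals the Pearson chi-square — used as an oracle in the tests.
* Evaluation metrics use the zero-division → 0 convention for
  precision/recall/F1 (matching standard ML reporting); AUROC is `NA` for
  one-class scopes and AUPRC is average precision (step-wise integral with
  tied scores grouped). The *standardized* row is the plain mean of the FL
  and noFL rows and propagates `NA`.

## The Super Learner

The 31 predictors are the 10 descriptors, 4 ionization-class dummies and 17
chemical-class dummies. The class vocabulary has 18 labels (17 named +
"Other"); "Other" is the dropped reference level so that the total is 31.
All columns are standardized with training-set center/scale (zero-variance
columns are centered, not scaled); test data always reuse the training
parameters. Unseen class labels map to the all-zero reference block with a
warning.

Protocol: records are split into 8 chemical-class-stratified folds (per
class, fold sizes differ by ≤ 1; the external-test fold is fold 1 under the
seeded shuffle). On the remaining data, each of the nine base learners is
run in 7-fold CV to produce out-of-fold positive-class probabilities — the
n × 9 meta-feature matrix — on which an unpenalized logistic meta-model is
fitted; the base learners are then refit on the complete training data.
Prediction feeds the refit base learners' probabilities to the meta-model;
a probability of exactly 0.5 classifies as Lingerer.

Base-learner hyperparameters are library defaults under a fixed seed
(SVM with RBF kernel and probability outputs, `scale = FALSE` since the
features arrive standardized; kNN with k = 5; random forest and extra trees
with 300 trees; AdaBoost as SAMME over 50 depth-1 stumps with weighted-vote
probabilities, error clamped to [1e-10, 1−1e-10]; bagging as 10 bootstrap
trees). AdaBoost and bagging are implemented in-package; the others come
from their standard R packages. Meta-features are probabilities, not hard
labels, so the stack yields AUROC/AUPRC directly; they are not
re-standardized.

The alternative structure-disjoint split uses Butina sphere-exclusion
clustering at Tanimoto 0.8 on the path fingerprints (molecules ranked by
neighbour count, deterministic tie-break by index) and moves whole clusters
to the test side, in seeded order, until the test fraction (default 1/8) is
reached; a single all-encompassing cluster is an error suggesting a higher
threshold.

## The synthetic benchmark

The generator emulates the statistical structure the analysis assumes, not
any real database's frequencies:

* **FL stratum** — closed template grammar over triacylglycerols,
  1,3-diacylglycerols, wax esters, N-methyl fatty amides and glycerol
  phosphotriesters/phosphodiesters with random acyl chain lengths (default
  range 10–20 carbons; template families enforce larger minima — e.g. 17
  for wax esters — so every member sits inside the designed envelope:
  mw > 500, logp > 5, rb > 10, nring 0, hbd ≤ 1, fsp3 > 0.8). Chemical
  class follows the template family (glycerolipids dominate at 68%);
  the ionization mix is neutral with a ~15% acid minority carried by free
  phosphodiesters (pKa ≈ 2.5). Free short fatty acids are deliberately
  excluded: they fall outside the envelope and would not represent the
  long-chain population the stratum emulates.
* **noFL stratum** — short di-/hydroxy-/amino-acids, polyols, sugar-like
  molecules, simple benzenoids, small heterocycles, organosulfur acids;
  acid/zwitterion-enriched pKa sampling with essentially no bases. Designed
  to defeat the reversed rules (small, low-logp Lingerers).
* **Traverser stratum** — aromatic/heterocyclic ring-plus-substituent
  grammar (benzenes, pyridines, biphenyls, indoles, quinolines, benzamides,
  aryl amines/acids, a nucleoside template); neutral/basic-enriched pKa
  sampling.

pKa values are drawn from per-stratum truncated normals because the real
analysis consumes database-reported pKa, which the benchmark must emulate,
not predict. The **separation** knob controls the fraction of cross-grammar
template draws between the noFL and Traverser strata (descriptors derive
from structures, so a pure numeric offset is not possible): separation 1
keeps the pools disjoint, 0 mixes them fully. **label_noise** flips only
permanence labels (recorded per record in the truth table), never
structures or descriptors. All generators are deterministic under a fixed
seed, and every emitted SMILES is already a canonical parent, so
normalization is a no-op on generated libraries.

What passing tests on this benchmark do *not* show: real gut metabolomes
have heavier class imbalance, annotation errors in class labels and pKa,
structural diversity far beyond six FL templates, and label noise that is
correlated with chemistry (borderline-bioavailability compounds) rather
than independent flips. Results on the benchmark demonstrate correctness of
the machinery and qualitative behaviour, not field performance.

## Problem sizes and numerical choices

The shipped tests run the modeling benchmark at 1200 molecules (400 per
stratum) over three seeds with the full 8-fold/7-fold protocol, and the
statistical oracles at a few hundred replicates; these sizes make every
distributional check stable while keeping a complete run in minutes on one
CPU. The permutation-null check permutes labels across the whole benchmark
(training and external alike) — permuting only training labels leaves the
external AUROC dominated by chance alignment between stratum-level
prediction offsets and the true labels, which is not the no-signal property
being asserted. Ties: CLES counts ties as 1/2; the classification threshold
0.5 maps to the positive class; Butina tie-breaks are by molecule index;
fold assignment tie-breaks by the seeded shuffle. Degenerate inputs are
contracts, not crashes: empty scaffold sets yield `NA` summary fields,
one-class evaluation scopes yield `NA` AUROC, zero-margin contingency cells
are untestable, and molecules whose descriptor evaluation fails yield
all-`NA` rows with a warning.
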