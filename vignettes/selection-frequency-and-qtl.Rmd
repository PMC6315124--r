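---
title: "Gene selection frequency and QTL mapping in BIL populations: methods"
author: "bilfreqsel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene selection frequency and QTL mapping in BIL populations: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bilfreqsel)
```

This vignette is the package's own account of what it computes, which
knobs matter, and where the boundaries of the approach lie. It states no
empirical result that the test suite and `scripts/acceptance.R` do not
themselves compute.

## 1. The setting

A backcross inbred line (BIL) panel is derived from a donor x recipient
cross: one or more backcrosses to the recipient followed by several
generations of selfing. Each line is mostly homozygous — recipient
(`OU`) or donor (`AR`) at each marker — with residual heterozygosity
(`HET`). The data are: a genetic map (12 chromosomes, 124 markers by
default), a line x marker genotype table, a shoot-weight trait (mean of
three biological replicates per line), and an FPKM expression matrix for
a small subset of lines plus the two parents (22 samples by default,
one replicate each).

Two questions are asked of these data:

1. **Which transcripts track the trait?** Answered by the
   selection-frequency screen (section 3).
2. **Which genomic regions control the trait, and a focal gene's
   expression?** Answered by composite interval mapping with permutation
   thresholds (section 4).

## 2. The synthetic data generator

Every stage is developed and calibrated against simulated data with
planted ground truth, because the screen's operating characteristics
(null behaviour, recovery power, threshold calibration) can only be
verified when the truth is known.

**Genotypes.** Meiosis is simulated marker-to-marker: crossovers in
adjacent intervals are independent Bernoulli events with probability
equal to the Kosambi inverse of the interval's map distance, and
chromosomes assort independently. Crossover interference beyond the
Kosambi marginal is deliberately not modelled: the map function used to
generate recombination is exactly the one used downstream to convert
distances back, which makes the pseudomarker imputation testable against
an enumeration oracle. The default pedigree is one backcross plus five
selfing generations (BC1F6-like) for 104 lines. The pedigree of real BIL
panels is often not stated precisely; this default is an explicit,
recorded assumption, and it reproduces the analytic expectations the
tests check: donor-allele dosage 0.25 after one backcross, heterozygous
fraction 0.5 x (1/2)^t after t selfings (about 1.6% at t = 5).

**Trait.** Per line, shoot weight (mg) is baseline + sum of additive QTL
effects (dosage coding OU = -1, HET = 0, AR = +1, so positive effects
mean the donor allele raises the trait) + a polygenic term proportional
to genome-wide mean dosage + Gaussian noise. The default truth plants
four QTL on chromosomes 3, 6, 7 and 10 with effects 0.21, -0.28, 0.21
and 0.20 mg, and sizes the polygenic coefficient so the two parents sit
at 2.91 and 5.11 mg — the parental contrast typical of donor/recipient
pairs used for seedling-vigour mapping. Noise is scaled to a requested
single-replicate heritability (default 0.6 for the BIL population); the
trait used downstream is the mean of `n_replicates = 3` replicates,
mirroring the usual field design. One simplification: the same simulated
shoot-weight vector stands in for both "fresh" and "dry" weight; the
fresh/dry distinction of real studies is not modelled.

**Expression.** FPKM is log-normal on the log2 scale:
`log2 FPKM = mu_g + a_g * dosage(eQTL) + c_g * z(trait) + noise`, with
gene baselines `mu_g ~ N(log2 5, 3)` (wide, heavy-tailed FPKM),
residual SD 0.5 log2 units, 20 causal genes with couplings +/-1.2 (which
yields trait correlations around |r| = 0.9 at n = 22), a focal gene with
trans-eQTL on chromosomes 1 and 7 (effects -0.17 and -0.25 log2 units),
and 10% near-zero genes (mean FPKM below 0.01) to exercise the filter.
What the generator does **not** emulate: read-level sampling noise,
gene–gene correlation structure (co-expression modules), batch effects,
and length/GC biases of FPKM estimation. Passing tests therefore
demonstrate correctness of the statistical machinery and calibration
under a clean generative model, not robustness to every artefact of real
RNA-Seq.

**qPCR.** The focal gene's per-line copy numbers follow the same planted
model (negative trait coupling -0.5 log2 units per trait SD by default),
pushed through a true standard curve (slope -3.4, intercept 38) with
biological (0.3 log2) and technical (0.15 Cq) noise, three biological x
three technical replicates. A noise-free 10-fold dilution series is
emitted so the fitted curve recovers the generating one exactly.

Reproducibility: a master seed spawns a named RNG substream per
component and per trial/permutation index (`rng_substream()`), so
results are independent of execution order and identical across reruns.

## 3. The selection-frequency screen

**Preprocessing.** Genes are kept when their arithmetic mean FPKM across
*all* samples is **strictly** greater than 0.01; retained values are
transformed to `log2(FPKM + 0.01)`. Two pinned readings of an
under-specified recipe: the mean is over all samples (not a subset), and
the threshold comparison is strict. The filter uses raw FPKM; the
transform comes second.

**Per-trial model.** Each of `n_trials` (default 10,000) trials draws
`floor(0.10 x G)` genes without replacement, standardises the subset's
expression within the trial (selection is then invariant to gene scale),
centres the trait, and fits the LASSO path

$$\min_\beta \; \tfrac{1}{2n}\lVert y - X\beta\rVert^2 + \lambda\lVert\beta\rVert_1$$

from `lambda_max = max_j |x_j' y| / n` down a geometric grid of 100
values to `1e-3 x lambda_max`. The trial's explanatory set is the active
set at the largest lambda whose size reaches K = 8, truncated to the 8
largest |beta| if the size jumps past 8 between grid points.

Why pin K = 8? The published workflow reports exactly eight non-zero
coefficients per trial but not the penalty rule that produced them. The
package's default makes that behaviour reproducible by construction
("fixed_size"); a 5-fold cross-validated penalty ("cv") is available for
sensitivity analysis, under which the per-trial model size varies. With
n = 22 samples, K is capped at n - 1.

**The statistic.** Selection frequency = selected count / total trials —
the literal definition, with total trials in the denominator. A gene's
frequency is therefore bounded by its appearance fraction (about the
subset fraction, 0.10): even a perfectly predictive gene cannot exceed
it. The conditional rate selected/appearances is reported as a secondary
column. Genes with frequency strictly above 0.01 are reported with
Pearson r and two-sided p against the trait, sorted by descending
frequency (ties by gene id). No multiple-testing correction is applied
to those p-values — deliberately, matching the source workflow; the
screening statistic is the frequency, and the p-values are annotation.

**Numerical choices.** The path solver is cyclic coordinate descent with
naive residual updates, warm starts, an active-set strategy and a
vectorised KKT screen over all coordinates (with n = 22 and thousands of
columns, residual updates are cheaper than Gram-matrix caching and
numerically identical). Convergence: maximum absolute coefficient change
below 1e-10 per sweep — tighter than the 1e-7 sometimes quoted for
pathwise solvers, because near-collinear subsets otherwise leave
coefficient errors above the 1e-6 oracle-agreement bar; returned
solutions satisfy the subgradient conditions accordingly, verified in
the tests against an
independent proximal-gradient solver (1e-6 agreement) and against a
reference LASSO implementation at matched penalties. Zero-variance genes
inside a subset are dropped from that trial (still counted as
appearances); a constant trait or fewer than three samples is an error.

## 4. QTL and eQTL mapping

**Model.** Regression-based (Haley–Knott style) composite interval
mapping rather than full mixture-likelihood EM: for mostly homozygous
inbred lines the two are near-identical, and the regression form is
orders of magnitude faster — which matters because thresholds come from
permutation. At each grid position (1 cM step, marker positions always
included):

- the expected additive dosage is imputed from the flanking marker
  genotypes under a two-state recipient/donor chain whose switch
  probability over distance d is the Kosambi inverse r(d). Heterozygous
  calls code 0 at their own marker but are non-informative as flanks
  (the haploid chain has no heterozygous state); missing calls are
  imputed from the nearest informative flanks, with single-flank decay
  `s(1 - 2r)` at chromosome ends and dosage 0 when a line has no
  informative marker on a chromosome;
- LOD = (n/2) log10(RSS_reduced/RSS_full), where the full model is
  intercept + dosage + cofactors and the reduced model omits the dosage.
  Cofactors within 10 cM of the test position (same chromosome) are
  excluded from both local models. RSS_full is floored at 1e-12 x TSS so
  LOD stays finite; positions whose residualised dosage has negligible
  variance report LOD 0. The additive effect is the dosage coefficient;
  R^2(%) = 100 (RSS_reduced - RSS_full)/TSS.

**Cofactors.** Forward–backward stepwise selection on observed marker
dosages (entry p 0.05, exit p 0.10, at most 5 cofactors), deterministic
with ties broken by map order; collinear candidates are skipped. These
control-parameter defaults follow the QTL-Cartographer Model-6
tradition; the source workflow does not state its values, so mapped
positions and LODs of any particular real dataset are not exact
reproduction targets.

**Threshold.** The genome-wide max LOD is recorded for each of 1000
trait permutations (type-7 empirical 95th percentile = the threshold).
When a cofactor rule is supplied, cofactors are re-selected inside every
permutation so the threshold pays for model selection; this is
configurable off for speed, and the no-cofactor (simple interval
mapping) case is computed in a single vectorised cross-product. The
acceptance suite verifies calibration: over 100 null datasets the
fraction whose max LOD exceeds their own threshold matches the nominal
5% within binomial error.

**Calls.** One QTL per contiguous supra-threshold region per chromosome,
at the region's LOD peak (ties to the smaller position), reported with
the nearest map marker, additive effect and R^2 at the peak. eQTL
scanning is literally the same code path with a per-line expression
trait — here, the mean of three biological replicates of log2 qPCR copy
number.

**qPCR quantification.** Copies/ul of the standard =
concentration x N_A / (length x 650 g/mol per bp) — 650 is the standard
dsDNA convention, used because source protocols rarely print the exact
molecular weight. Technical replicates are averaged on the Cq scale
before inversion through the curve (common practice; inverting first
would exponentiate the technical noise), then log2 and the
biological-replicate mean.

## 5. Problem sizes used in the tests

The shipped test-and-calibration suite uses scaled-down but structurally
faithful designs, chosen as the package's own verification budget:

- threshold calibration: 100 null datasets x 100 permutations
  (104 lines, 124 markers, simple interval mapping);
- selection-frequency recovery: 20 seeds x 500 trials on a
  1000-gene universe at n = 22, planted couplings giving |r| about 0.9;
  success = planted median frequency above the null 95th percentile;
- QTL recovery: 50 simulations of a single QTL at single-replicate
  heritability 0.2 (a moderate effect; with the mean of three replicates
  the mapping-scale heritability is about 0.43), success = a call within
  10 cM of the truth;
- solver validation: 100 random small instances against the
  proximal-gradient oracle at 1e-6.

Full-scale settings (10,000 trials, 1000 permutations) are the defaults
of the exported functions; the scaled settings live only in the tests.

## 6. Known limitations

- The generator's independence assumptions (no interference, no
  co-expression structure, Gaussian log-expression noise) make the
  calibration results a best case; real data will be messier.
- De novo linkage-map construction and marker ordering are out of scope:
  the map is taken as given.
- No multiple-QTL model fitting or epistasis scanning; CIM with a single
  tested position at a time.
- The fixed-size penalty rule reproduces a reported behaviour rather
  than optimising prediction; use the CV rule to check sensitivity.
- Correlation p-values in reports are uncorrected for multiplicity by
  design; treat them as annotation, not inference.
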