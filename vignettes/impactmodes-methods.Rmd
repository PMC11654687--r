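---
title: "Methods: from allele dosages to impact modes"
author: "impactmodes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from allele dosages to impact modes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Complex behavioural traits such as dyslexia are highly polygenic: thousands
of common variants each shift the liability a little, and a polygenic score
(PGS) — the weighted sum of a person's allele dosages, with weights taken
from an independent discovery GWAS — summarizes that disposition in one
number. Regressing a brain measure on the PGS at every voxel (local volume
from Jacobian determinants of a nonlinear registration) or fixel (apparent
fiber density of a specific fiber population within a voxel) maps *where*
genetic disposition relates to brain structure. But a single score is
agnostic to heterogeneity: different disposing loci may act on different
circuits. The impact-mode analysis addresses this by building one
brain-wide t-map per disposing variant and decomposing the variant x
element t-matrix with spatial independent component analysis (ICA) into a
small number of spatially independent components — *impact modes* — each a
brain map tied to a distinctive set of variants through its mixing weights.

`impactmodes` implements this whole chain — variant QC, relatedness
pruning, LD clumping, clumping-and-thresholding PGS with IDP-based
optimization, mass-univariate GLM, max-statistic permutation inference,
and the ICA decomposition — together with a synthetic-data generator that
plants a known modes-by-loadings structure, so every stage can be
validated against ground truth.

# The synthetic generator

Real imaging-genetics cohorts at this scale are access-restricted, so the
package treats the generator (`simConfig()`, `genGenotypes()`,
`genCovariates()`, `genTruth()`, `genMaps()`, `genSumstats()`,
`genKinship()`) as first-class, tested code. What it emulates:

* **Genotypes.** Hard-call dosages (0/1/2) from two simulated haplotypes.
  LD is block-structured: within a block of `ldBlockSize` variants, each
  variant copies its left neighbour's haplotype allele with flip
  probability $(1-\rho)/2$, giving dosage correlation $\rho^{d}$ at
  in-block distance $d$ and *no* LD across block boundaries. This is
  deliberately not a coalescent model: the analytic $r^2$ makes clumping
  behaviour checkable exactly. One minor-allele frequency per block is
  drawn uniformly from `mafRange`; when $\rho < 1$ the realized
  frequencies of later in-block variants drift toward 0.5, an accepted
  artefact of the copy-with-flip construction. Variants sit at a fixed
  10-kb spacing (so the default 500-kb clump window spans ~50 variants),
  filled block-wise across up to 22 chromosomes.
* **Covariates.** Age uniform on 45–82 years, sex, age$^2$, age x sex,
  age$^2$ x sex, ten standard-normal ancestry-PC stand-ins, three imaging-
  site dummies and a preprocessing-batch flag — the standard confound set
  for population-cohort brain MRI.
* **Planted truth.** $K$ spatial modes occupy disjoint contiguous
  stretches of the element list; support values are smoothed Gaussian
  noise, centred to sum to zero (disjoint supports are then *exactly*
  uncorrelated) and scaled to unit SD. Variant loadings are sparse
  Gaussian (`loadingSparsity` of variants per mode). The variant x element
  effect matrix is exactly `loadings %*% modes`, i.e. rank $K$.
* **Brain maps.** `1 + centredDosage %*% (effectScale * effectMaps) +
  covariate shift + N(0, noiseSd^2)`. Dosages are centred per variant so
  the baseline of 1.0 (a neutral Jacobian determinant) is MAF-independent.
  Covariate effects are global — the same shift at every element — which
  mimics head-size-like nuisance variation. Voxel maps live on a 16x16x16
  grid under an ellipsoidal mask by default; fixels are a flat element
  list with unit direction vectors.
* **Discovery GWAS.** An independent cohort from the same genotype model;
  liability is `centredDosage %*% causalWeights + N(0,1)` and each variant
  gets a marginal OLS beta, SE and two-sided p. Variants that load on a
  planted brain mode also receive a liability weight (plus a 5% random
  background): in the study design being emulated, the trait-disposing
  variants *are* the ones whose brain effects the decomposition should
  find, and without this coupling the clumped top-GWAS variants would
  carry no planted structure.
* **Kinship.** Related pairs with coefficients in {0.25, 0.125, 0.0625}
  plus sub-threshold distractor pairs.

Everything is a pure function of `(config, seed)`; each generator derives
a child seed from the master seed and a stage label (`childSeed()`), so a
single stage can be re-run bit-identically.

**What the generator does not emulate:** realistic human LD panels,
population stratification beyond Gaussian PC stand-ins, genotyping error,
MRI physics, registration error, or spatially correlated map noise.
Passing tests therefore demonstrate the *statistical machinery* is
correct and calibrated, not that effect sizes found in real cohorts will
match.

## Default conditions and free parameters

| parameter | default | meaning |
|---|---|---|
| `nSubjects` / `nVariants` | 500 / 200 | desk-scale target sample |
| `mafRange` | 0.05–0.5 | common variants (QC floor is 0.01) |
| `ldBlockSize`, `ldDecay` | 5, 0.8 | moderate block LD |
| `nModes` | 3 | planted components |
| `modeSparsity` | 0.05 | active elements per mode |
| `loadingSparsity` | 0.10 | variants loading per mode |
| `effectScale` | 0.02 | per-allele effect on a baseline-1.0 map |
| `noiseSd` | 0.05 | map noise (a few % of baseline, Jacobian-like) |
| `causalSd` | 0.15 | liability-weight scale |

No external reference fixes the per-variant effect scale on regional
volume; `effectScale` is an explicit free parameter of the simulation (a
few per cent of baseline per allele, detectable at n in the hundreds), not
an empirical claim.

# Genetics stage

* **QC** (`qcFilter()`): keep variants with empirical MAF >= 0.01,
  imputation info > 0.7, and Hardy–Weinberg p > 1e-7. HWE uses the Pearson
  1-df chi-square on hard-called dosages — the common choice for GWAS QC at
  thousands of samples; an exact test is out of scope. A fixed allele makes
  the test degenerate and returns p = 1.
* **Relatedness pruning** (`pruneRelatedness()`): on the graph of pairs
  with kinship >= 0.044, recursively delete the maximum-degree individual
  until no edge remains. The tie-break (lexicographically largest id) is a
  package convention chosen for determinism.
* **Clumping** (`clumpVariants()`): greedy index selection by ascending p
  among variants with p < 0.01, removing same-chromosome neighbours within
  +-500 kb at r^2 >= 0.1, with LD measured in the target genotypes (no
  external reference panel). Ties on p break by smaller position, then id,
  making the output independent of input row order.
* **PGS** (`computePGS()`, `pgsGrid()`, `optimizePGS()`): weighted dosage
  sums with allele alignment (dosage flipped to `2 - d` when the weight's
  effect allele is the other allele); mismatching alleles are skipped with
  a warning and missing dosages are mean-imputed per variant
  (deterministic, standard). The score family is clumping + p-value
  thresholding with GWAS betas as weights — a transparent stand-in for
  shrinkage-model scoring (elastic-net/Bayesian PGS internals are out of
  scope), optimized the same way: each candidate is regressed against
  every imaging-derived phenotype (principal-component IDPs from
  `idpExtract()`) with covariate adjustment, and the candidate with the
  largest max |t| wins.

# Association stage

`fitGLM()` fits, per element, OLS of the element value on
`[predictor | design]` by residualizing both sides on the design
(Frisch–Waugh); the resulting t equals the full-design OLS t to numerical
precision, and the per-element effect size is reported as partial
$r^2 = t^2/(t^2 + \nu)$ with $\nu$ the residual df. Elements with zero
residual variance get t = 0 and are counted. `variantTMaps()` vectorizes
this across variants, orienting each dosage to the disposing allele when
summary statistics are supplied, and flags monomorphic variants as NA
rows.

`permutationFWE()` controls family-wise error with the max-statistic
distribution: values and predictor are residualized on the nuisance
design; each permutation shuffles the residualized predictor,
re-residualizes it on the design (the Freedman–Lane-style scheme that
stays calibrated under nuisance covariates), recomputes every element's t
and records the maximum of the chosen tail statistic (|t| by default; a
`tail` flag exposes signed contrasts). The corrected p is
`(1 + #{maxima >= observed}) / (nPerm + 1)` — the +1 convention includes
the unpermuted statistic and guarantees validity. No cluster enhancement
of any kind is applied. Under a global-null simulation the family-wise
rejection rate at alpha = 0.05 sits within Monte-Carlo error of 0.05
(see `tests/testthat/test-acceptance.R` and `scripts/acceptance.R`).

# Impact-mode decomposition

`decomposeModes()` treats the variant x element t-matrix $X$ as mixtures
of $K$ spatial sources: $X \approx A S$ with $A$ (variants x K) the mixing
matrix and $S$ (K x elements) independent over elements. Two deliberate
numerical choices:

1. **No mean removal, no variance normalization.** Row means and scales of
   a t-matrix are meaningful signal, so whitening is performed on the raw
   matrix within its rank-$K$ principal subspace:
   $Z = \sqrt{E}\,V_K^\top$ from the SVD $X = U D V^\top$, which has
   identity second moment over elements.
2. **Fixed-point ICA** with the logcosh contrast and symmetric
   decorrelation, tolerance 1e-6 on the unmixing rotation, up to 1000
   iterations, and up to 5 restarts from fresh random rotations on
   non-convergence (an error, with diagnostics, after that). The
   decomposition is stochastic only through the seeded initial rotation,
   which is recorded in the result.

Because $W$ is orthogonal on whitened coordinates, the mixing matrix is
recovered in closed form as $A = U_K D_K W^\top / \sqrt{E}$, and
$A S$ equals the rank-$K$ projection of $X$ exactly — the package's
reconstruction invariant. Conventions: each source is oriented so its
spatial skewness is positive (tie: the largest-|z| element is positive),
modes are ordered by decreasing rank-1 contribution, reported maps are
z-scored over elements, and `modeWeights()` standardizes each mixing
column over variants (mean 0, population SD 1) — the "mode weight
z-score" used to rank variants within a mode. How such weight z-scores
should be standardized is not externally fixed; within-mode
standardization across variants is this package's definition.

`varianceExplained()` uses a zero-matrix baseline (again: no mean
removal), so "variance explained" is the fraction of squared Frobenius
norm reproduced by $A S$; per-mode fractions are the rank-1 terms
$\|a_k s_k^\top\|_F^2 / \|X\|_F^2$, whose cross-terms vanish up to the
decorrelation of the whitened sources. A column-mean baseline can be
obtained by centring the input beforehand.

For volumetric data, `normalizeJacobians()` divides each subject's map by
its mean over the mask before t-maps enter the decomposition, removing
global-volume signal so the rotation is driven by local effects; whether
to decompose head-size-adjusted t-maps instead is exposed as a pipeline
flag (`headSizeAdjust`), defaulting to unadjusted.

`matchModes()` supports validation: greedy maximum-|correlation|
assignment of recovered to planted maps with per-pair spatial |r|,
loading |r| and sign alignment.

# Pipeline and reproducibility

`runPipeline()` chains simulate → QC → prune → clump → PGS → GLM →
permutation FWE → modes → report, writing every artifact in plain-text
formats (TSV; NIfTI for voxel maps) plus a JSON manifest carrying the
package version, the serialized configuration and its checksum, and every
derived seed. `writeRunConfig()` serializes each parameter with `deparse`,
so the round-trip is exact including doubles. Reruns with the same
configuration are bit-identical, including the ICA given its recorded
seed. `runReport()` reassembles the QC attrition, clump counts, PGS–IDP
grid, top FWE elements and top-|z| variants per mode from the run
directory alone.

# Validation problem sizes

The shipped checks use desk-scale problem sizes chosen to give decisive
Monte-Carlo bounds while keeping the suite quick: 100 random fixtures for
the GLM-vs-OLS oracle (agreement to 1e-8); 500 replicate global-null
datasets (100 subjects x 200 elements, 200 permutations) for FWE
calibration within 0.05 +- 0.03; 10 replicates of K = 5 modes x 500
variants x 2000 elements at high SNR for mode recovery (mean spatial
|r| >= 0.95, loading |r| >= 0.90); 1000 random triples for the HWE oracle;
exhaustive greedy-oracle comparison on fixtures of <= 20 variants for
clumping; 50 replicate discovery simulations (n = 10,000) for the
clumping-and-thresholding score, where fixed-magnitude causal weights make
the sparse threshold's variant set known by construction and it must be
selected in >= 90% of replicates; and 20 end-to-end runs whose
FWE-significant elements must fall inside the planted supports in >= 90%
of seeds. The discovery-scan dominance example runs at 25 replicates with
the same >= 95% dominance rate.

# Known limitations

* The PGS family is clumping + thresholding only; shrinkage models
  (elastic-net, Bayesian continuous-shrinkage) are out of scope, as are
  LD reference panels, VCF/BGEN parsing and exact HWE tests.
* ICA is plain fixed-point ICA with user-set $K$; probabilistic ICA,
  automatic model-order selection and dual-regression back-projection are
  out of scope.
* No spatial statistics beyond the element-wise max statistic: no cluster
  enhancement, no smoothing, no reduced-resolution permutation tricks.
* Map noise is iid over elements; real registration residuals are
  spatially correlated, which would widen the max-statistic null. The
  permutation scheme remains valid under such correlation, but simulated
  power is not transferable.
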