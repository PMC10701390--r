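---
title: "Methods: sparse testing designs and multi-kernel genomic prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sparse testing designs and multi-kernel genomic prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(sparsegp)
```

This vignette is the package's own account of the science it
implements: the generative model behind the simulator, the two
training-set selection strategies, the multi-kernel Gibbs sampler, the
evaluation conventions, and the numerical and design choices that were
genuinely open. It states no empirical result that the test suite does
not itself compute.

## 1. The phenotype model

All machinery is organized around the nested family of mixed models for
a RIL `i` (in family `k`) observed in environment `j`:

$$y_{ij} = \mu + E_j + L_i + F_k + g_i + gE_{ij} + FE_{kj} + \epsilon_{ij}$$

* `E_j ~ N(0, σ²_E)` — environment main effect (year-location).
* `L_i ~ N(0, σ²_L)` — RIL identity ("line") effect: non-genomic
  repeatable line variation.
* `F_k ~ N(0, σ²_F)` — family main effect, shared by all RILs of one
  bi-parental cross.
* `g ~ N(0, G σ²_g)` — genomic effect, `G = XX′/p` with `X` the
  centered, column-standardized dosage matrix. Standardization uses the
  divisor-n variance so that `trace(G) = n` exactly.
* `gE ~ N(0, (Z_g G Z_g′) ∘ (Z_E Z_E′) σ²_{gE})` — reaction-norm G×E
  interaction: genomic covariance masked (Hadamard product) to pairs of
  records in the same environment.
* `FE ~ N(0, (Z_F Z_F′) ∘ (Z_E Z_E′) σ²_{FE})` — family-by-environment
  interaction.

M1 drops `F, FE, gE`; M2 drops `F, FE`; M3 is the full model. The three
models are nested so that comparing their predictive abilities isolates
the value of the G×E and family×E terms.

## 2. What the simulator emulates — and what it does not

No public simulator accompanies the study design this package targets,
so the generative model is fixed at the most complex model fitted (M3,
with independent Gaussian components): data generated this way exercise
every term of every model. Concretely:

* **Founders.** One hub haplotype is drawn at allele frequency 0.5 per
  marker; each founder copies the hub with an independent per-marker
  allele flip at its ancestry group's divergence probability. This is
  the simplest mechanism that reproduces the elite < diverse < exotic
  (G1 < G2 < G3) diversity ordering. Defaults 0.10 / 0.20 / 0.35 were
  chosen once as plausible SNP-sharing levels between an elite hub and
  elite, diverse and exotic-introduction founders.
* **RIL descent.** Each RIL is, per chromosome, a two-state (hub /
  founder) Markov-chain mosaic with switch probability `recomb_prob`
  between adjacent markers, doubled into a fully homozygous genotype.
  This Haldane-like, no-interference shortcut replaces explicit
  multi-generation selfing; it produces realistic block-wise LD at desk
  scale but not map-distance calibration (cM), crossover interference,
  residual heterozygosity, or selection during inbreeding. Default
  `recomb_prob = 0.01` with ~205 markers per chromosome gives on the
  order of two segment switches per chromosome, the right order of
  magnitude for a RIL genome.
* **Phenotypes.** `g = Xβ` with `β_m ~ N(0, σ²_g/p)` and `gE` from
  independent environment-specific marker-effect deviations
  `β_{mj} ~ N(0, σ²_{gE}/p)`, so both terms have the configured marginal
  variance by construction. `L`, `F`, `FE`, `ε` are i.i.d. Gaussian.
  The distribution of `L_i` is not pinned down by the study the package
  follows; i.i.d. `N(0, σ²_L)` is assumed and `σ²_L` is exposed like
  every other component.

**Default variance components** (kg ha⁻¹)², chosen once to mimic a
soybean yield trial with grand mean μ = 3,560 kg ha⁻¹ and roughly half
the within-environment variance genetic: `E = 202500` (environment SD
450 — year-location swings dominate), `L = 30625`, `F = 40000`,
`g = 75625`, `gE = 50625`, `FE = 40000`, `resid = 122500` (plot-error SD
350). Nonzero `gE` and `FE` are deliberate: they are the terms whose
value the M1/M2/M3 comparison measures.

A green test on synthetic data therefore establishes that the pipeline
is internally correct (allocation arithmetic, kernel algebra, sampler
calibration, scoring); it does not establish field performance on real
SoyNAM data, which has selection history, non-Gaussian residuals and
map structure the generator does not emulate.

## 3. Selection method S1: the NO/O composition grid

`allocate_base()` randomly partitions the panel into `J` disjoint
per-environment training sets (195 per environment at the 1,755 × 9
reference scale) and freezes each environment's prediction set as its
complement (1,560). `derive_composition()` then

1. reduces each environment to `n_per_env` RILs by masking from the end
   of the environment's random assignment order — masking is therefore
   *nested*: the size-s design is contained in the size-(s+10) design;
2. repeats `n_overlap / group_size` redistribution steps: mask
   `group_size` further NO-RILs per environment, pool them, and promote
   `group_size` randomly drawn pooled RILs to O-RILs observed in every
   environment.

Per-environment training size stays at `n_per_env` throughout; the
number of *unique* RILs falls as O-RILs replace NO-RILs. The reference
grid `composition_grid()` spans sizes 195..95 by 10 with compositions
down to 5 NO-RILs: 20 compositions in the largest row, 10 in the
smallest, 165 cells.

**Prediction sets are frozen at the base allocation.** The open
question is what to do when a masked RIL is promoted to O-RIL: it now
appears in 8 of 9 frozen prediction sets while being observed
everywhere. The package never scores an observed cell:
`evaluated_prediction()` returns the frozen set minus the current
O-RILs. This is the only rule consistent with a constant advertised
testing-set size and with never evaluating a trained-on cell; the
evaluated count per environment shrinks by at most `n_overlap`, and the
accounting object reports exact counts rather than hiding the
difference.

**Cost model.** Plot-count arithmetic at a configurable `$15` per
yield plot: a full 1,755 × 9 grid costs $236,925; the 1,755-plot sparse
design saves $210,600; the 855-plot design saves $224,100. These exact
figures are asserted in the acceptance tests.

## 4. Selection method S2: E(S²) exchange algorithm

For a selected submatrix `X₀` (columns standardized **once** on the
full candidate set — subsamples are never re-standardized), the
criterion is `trace((X₀′X₀)²)`, evaluated through the Gram identity
`trace((X′X)²) = trace((XX′)²)` on the small n × n side. The classical
off-diagonal-only form (sum of squared off-diagonal entries of
`S = X₀′X₀`) differs by the sum of squared diagonal entries; both are
implemented (`variant = "offdiag"`), the trace form is the default
because it is the form the search is defined against. Lower values mean
nearer-orthogonal marker columns, i.e. more diverse samples.

The search is greedy steepest descent/ascent: each iteration evaluates
**every** (selected, pool) exchange — 195 × 1,560 = 304,200 at reference
scale — and applies the single best one; it stops when no exchange
improves. Because swapping one row changes one row/column of the Gram
matrix, each candidate swap is an O(1) delta on cached cross-products,
and a full iteration is one vectorized outer sum. Ties are broken by the
lowest (selected-position, pool-position) pair for determinism; strict
improvement is required beyond a relative tolerance of 1e-9 so
termination is guaranteed (the criterion is bounded). Equivalence of the
fast update with from-scratch recomputation, and of the Gram shortcut
with the explicit p × p similarity matrix, are tested properties.

Published iteration counts and final criterion values for this
algorithm depend on the actual genotype matrix and starting split, so
the package asserts only direction (max-diversity runs decrease the
criterion, min-diversity runs increase it) and mechanics.

## 5. The Gibbs sampler

The sampler is a conventional Bayesian multi-kernel (RKHS) Gaussian
model: `y = μ1 + Σ_t b_t + e`, `b_t ~ N(0, σ²_t K_t)`,
`e ~ N(0, σ²I)`.

* **Eigenbasis sampling.** Each `K_t = U_t D_t U_t′`; writing
  `b_t = U_t γ_t` makes the coordinates of `γ_t` conditionally
  independent (eigenvectors are orthonormal), so a block update is two
  matrix-vector products. Eigenvalues below `1e-10 ×` the largest are
  dropped; a diagonal jitter of `1e-8 × mean(diag)` is added once if a
  structure fails PSD, and a structure that still fails raises an error.
* **Grid shortcut.** The record index is always the complete
  RIL × environment grid (missing cells predicted by design), in
  environment-major order. Every model structure is then a Kronecker
  product — e.g. `GE = I_J ⊗ G`, `L = (11′/J) ⊗ I_n · J` — so all six
  eigendecompositions are assembled analytically from `eigen(G)` and a
  per-family block, never from the N × N matrix. The analytic
  decompositions are verified against the explicit kernels in the tests.
* **Missing cells** are data-augmented: their residual is redrawn from
  `N(0, σ²)` each iteration, which leaves the parameter posterior
  identical to omitting them from the likelihood while keeping the
  complete-grid algebra.
* **Priors.** Scaled-inverse-chi-square with `df0 = 5` on every
  variance; scales set so each random term's prior mode captures an
  equal share of 50% of the observed phenotypic variance and the
  residual mode the remaining 50%. These are conventional weakly
  informative defaults; all are configurable, and any subset of
  variances can be held fixed (`fixed_variances`), which is how the
  closed-form GBLUP oracle test is run: with fixed variances the
  posterior mean of the genetic effect must equal
  `σ²_g K (σ²_g K + σ²I)⁻¹(y − μ̂)` up to Monte-Carlo error.
* **Defaults** `n_iter = 6000, burn_in = 1000, thin = 5` are
  conservative for full runs; the test suite and the desk-scale
  experiment use shorter chains (typically 1500/500) because posterior
  *means of predictions* stabilize much faster than variance-component
  tails. This is a runtime choice, documented here, not a claim about
  convergence of all posterior summaries.
* **Predictions** are posterior means of the linear predictor
  `μ + Σ_t b_t[cell]` — never-observed RILs get `L̂` shrunk to zero with
  genomic information entering through `G` (and family information
  through `F`/`FE` in M3).

## 6. Evaluation conventions

Predictive ability is the within-environment Pearson correlation
between predicted and true values over the evaluated prediction set,
then averaged: environments first, replicates reported separately
(matching the "mean over replicates of the across-environment average"
convention). Undefined correlations (constant vectors, empty strata)
are flagged `undefined`, excluded from means, and counted — the
reference material is silent on this, so exclusion-with-logging was
chosen over failing or zero-filling. Post-stratification by ancestry
group (and optionally family) recomputes correlations within the
stratum's members per environment. `env_pair_correlations()` gives the
J(J−1)/2 between-environment phenotype correlations (36 at J = 9) used
to describe environment stability of a selected sample.

## 7. Experiment orchestration and reproducibility

`run_experiment()` runs replicate × grid-cell × model, rebuilding the
population per replicate for synthetic inputs (replicate = fresh
simulation) and only re-randomizing the allocation for user data
(replicate = new random calibration set, as in the motivating design).
Kernels and their eigendecompositions are built once per replicate from
the M3 superset and subset per model. Every stage seed derives from one
master seed via `derive_seed(master, stage, counter)` (a fixed
documented affine-mod scheme), so any stage can be reproduced in
isolation; provenance JSON (seeds, config, package version) accompanies
every CLI output. Failed fits are caught, logged as flagged rows, and
do not abort the run.

## 8. Known limitations

* The simulator's recombination model is not calibrated to a genetic
  map, and founders are unrelated to each other beyond hub sharing.
* Variance-component recovery at small numbers of levels (few
  environments or families) is limited by information, not by the
  sampler: `L`/`g`/`F` are partially confounded when family blocks
  dominate `G`. The acceptance test uses a 400-record instance chosen
  so every component has enough levels for a 30% check to be
  meaningful, and compares against realized (drawn) component variances.
* Full-scale fits (15,795 records) are supported but long-running in a
  single process; the package's tested envelope is desk scale
  (≤ ~2,000 records), with larger runs flagged as a compute decision.
* No REML/frequentist path, pedigree matrices, dominance/epistasis
  kernels, environmental covariates, spatial field models, or
  significance testing between compositions.
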