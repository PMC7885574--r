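---
title: "Measuring genetic connectedness: models, statistics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring genetic connectedness: models, statistics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connekt)
```

## The model

All statistics in this package derive from the standard animal model

$$\mathbf{y} = \mathbf{X}\mathbf{b} + \mathbf{Z}\mathbf{u} + \boldsymbol{\varepsilon},
\qquad \mathbf{u} \sim N(\mathbf{0}, \mathbf{K}\sigma^2_u),
\qquad \boldsymbol\varepsilon \sim N(\mathbf{0}, \mathbf{I}\sigma^2_e),$$

where the fixed effects $\mathbf{b}$ always include the management-unit
effect, $\mathbf{u}$ are additive genetic values, and $\mathbf{K}$ is a
relationship matrix — the pedigree-based numerator matrix $\mathbf{A}$
(tabular method, `build_A()`) or a genomic matrix $\mathbf{G}$
(VanRaden's first method, `build_G()`). Variance components are treated
as known: the user supplies $(\sigma^2_u, \sigma^2_e)$ or a
heritability, in which case the phenotypic variance is normalized to 1.
No variance-component estimation is attempted.

Henderson's mixed model equations have coefficient matrix

$$\mathbf{C} = \begin{bmatrix}\mathbf{X}'\mathbf{X} & \mathbf{X}'\mathbf{Z}\\
\mathbf{Z}'\mathbf{X} & \mathbf{Z}'\mathbf{Z} + \mathbf{K}^{-1}\lambda\end{bmatrix},
\qquad \lambda = \sigma^2_e/\sigma^2_u,$$

whose inverse blocks $\mathbf{C}^{11}$ and $\mathbf{C}^{22}$ give the
sampling variance of the fixed-effect estimates,
$\mathrm{Var}(\hat{\mathbf{b}}) = \mathbf{C}^{11}\sigma^2_e$, and the
prediction error (co)variance of the genetic values,
$\mathrm{PEV}(\mathbf{u}) = \mathrm{Var}(\hat{\mathbf{u}} - \mathbf{u})
= \mathbf{C}^{22}\sigma^2_e$. PEV is also the posterior variance of
$\mathbf{u}$ given the data, and equals
$(\mathbf{Z}'\mathbf{M}\mathbf{Z} + \mathbf{K}^{-1}\lambda)^{-1}\sigma^2_e$
with $\mathbf{M} = \mathbf{I} - \mathbf{X}(\mathbf{X}'\mathbf{X})^-\mathbf{X}'$
the fixed-effect absorption projector. `pev()` exposes both routes
(`method = "blocks"` and `method = "absorption"`); the test suite
asserts their agreement to 1e-8, which exercises the entire MME
assembly twice through independent algebra.

## Connectedness statistics

Two units are *connected* when differences between their estimated unit
means (or their members' breeding values) are predicted precisely.

**PEV-derived metrics.** For individuals $i, j$:
$\mathrm{PEVD}_{ij} = \mathrm{PEV}_{ii} + \mathrm{PEV}_{jj} - 2\,\mathrm{PEC}_{ij}$;
$\mathrm{CD}_{ij} = 1 - \mathrm{PEVD}_{ij} / \{\sigma^2_u (K_{ii} + K_{jj} - 2K_{ij})\}$;
$r_{ij} = \mathrm{PEC}_{ij}/\sqrt{\mathrm{PEV}_{ii}\mathrm{PEV}_{jj}}$.
Each is summarized at the unit level three ways:

* **GrpAve** — apply the pairwise formula to within/between-unit *block
  means* of PEV (and of $\mathbf{K}$ for CD);
* **IdAve** — average the pairwise statistic over all cross-unit pairs
  (for CD, the printed form is a *ratio of sums* — numerator and
  denominator averaged separately — not the mean of pairwise CDs; the
  two differ measurably and the ratio-of-sums algebra is implemented,
  because it is the form the statistic's published display reduces to);
* **Contrast** — the quadratic form $\mathbf{x}'\,\mathrm{PEV}\,\mathbf{x}$
  (and $\mathbf{x}'\mathbf{K}\mathbf{x}$) for a zero-sum contrast
  $\mathbf{x}$; the unit-pair contrast has entries $1/n_{i'}$,
  $-1/n_{j'}$, 0.

**VE-derived metrics.** The variance of estimated unit effects,
$\mathrm{VE}_0 = $ unit block of $\mathrm{Var}(\hat{\mathbf{b}})$,
approximates the mean PEV over units. Exact corrections:

* $\mathrm{VE}_1 = \mathrm{Var}(\hat{\mathbf{b}}) - \sigma^2_e(\mathbf{X}'\mathbf{X})^{-1}$
  when unit is the only fixed effect — the subtracted term is diagonal
  with entries $\sigma^2_e/n_i$, so off-diagonal entries pass through
  unchanged;
* $\mathrm{VE}_2$ adds, for models with further fixed effects, the
  terms that map the variance of the other effect estimates
  ($\mathrm{Var}(\hat{\mathbf{b}}_2)$) and both cross-covariance blocks
  back onto the unit scale through
  $(\mathbf{X}_1'\mathbf{X}_1)^{-1}\mathbf{X}_1'\mathbf{X}_2$. With two
  or more extra effects, all non-unit columns form one concatenated
  $\mathbf{X}_2$ block.

Under the block-mean convention below, $\mathrm{VE}_1$ and
$\mathrm{VE}_2$ equal the block means of PEV *exactly* (machine
precision; asserted at 1e-8 in the tests). VED, CDVED and CR then plug
$\mathrm{VE}_c$ into the PEVD, CD and r group-average formulas, so the
corrected single-step statistics reproduce the two-step PEV statistics
while only ever inverting for the fixed-effect block — the practical
appeal when units are few and individuals are many.

The **overall** statistic is the unweighted mean of the strictly
off-diagonal upper-triangle unit-pair entries; weighting pairs by unit
size is deliberately not done (no published convention prescribes it),
and the diagonal never contributes.

## The block-mean convention

Group-average summaries need "mean PEV within a unit". This package
averages over **all** $n_i^2$ elements of a within-unit block,
*including the diagonal*. Consequences:

* $\mathrm{VE}_1 = \overline{\mathrm{PEV}}$ becomes an exact identity,
  not an approximation;
* GrpAve and Contrast summaries coincide identically for PEVD and CD,
  because the unit-pair contrast's quadratic form expands to exactly
  the diagonal-inclusive block means.

Whether published group averages include the diagonal is not stated
anywhere authoritative, so the alternative (off-diagonal-only within-unit
means) is available via `include_diagonal = FALSE` in
`pev_blockmean()`, `pevd_grpave()`, `cd_grpave()`, `r_grpave()` and
`cdved()`; under that option the two identities above hold only
approximately.

## Numerical choices

* **Inversion.** $\mathbf{C}$ and $\mathbf{K}$ are inverted by Cholesky
  factorization with the full inverse formed explicitly — appropriate
  for the package's target sizes (up to a few thousand equations; a
  warning is emitted above 10,000). No sparse or iterative solvers.
* **Singular $\mathbf{K}$.** If the factorization fails (duplicated
  genotypes, clones), a ridge $\varepsilon\mathbf{I}$ with
  $\varepsilon = 10^{-8}$ is added once, with a warning, and the
  applied $\varepsilon$ is recorded on the result. Blending a genomic
  matrix with the pedigree matrix is *not* done — it changes the model
  rather than fixing the numerics.
* **Identifiability.** Unit effects are one-hot coded with no
  intercept, so every unit-effect variance is directly available (VE
  metrics need them); every additional categorical effect is
  reference-coded (first level dropped). A rank check on the assembled
  $\mathbf{X}$ rejects confounded designs and names the aliased
  columns. The absorption projector uses a symmetric pseudo-inverse of
  $\mathbf{X}'\mathbf{X}$, while the VE formulas require full column
  rank after the constraint — the single point where a generalized and
  a true inverse are deliberately distinguished.
* **Degenerate denominators.** CD-family and r-family statistics are
  undefined when the prior contrast variance (or a VE/PEV diagonal)
  falls below $10^{-10}$: affected pairs are reported as `NA` with a
  warning, never as 0, since a silent zero would fabricate
  disconnection where the statistic is actually meaningless
  (genetically identical groups).
* **One record per individual.** Repeated records (permanent
  environment models) are rejected with a clear message. Individuals
  present in $\mathbf{K}$ without phenotypes keep all-zero columns in
  $\mathbf{Z}$, so their (prior-dominated) PEV is still defined —
  standard BLUP prediction of non-phenotyped animals.

## The simulator

`make_example()` emulates the multi-generation cattle population used
throughout the documentation: 2,500 individuals in five non-overlapping
generations (500 founders, then 500 offspring per generation by random
mating), 10,000 biallelic markers evenly spaced on 29 chromosome pairs
of 100 cM with Haldane recombination and founder frequencies uniform on
(0.1, 0.9), units formed by k-medoids (PAM) on the dissimilarity
$1 - \mathbf{K}/\max(\mathbf{K})$ (the alternative
$\max(\mathbf{K}) - \mathbf{K}$ is available; PAM is deterministic
given the dissimilarity, and units are assigned to all individuals
regardless of generation), and a phenotype with heritability 0.6 and a
sex covariate of one phenotypic standard deviation, sexes alternating
at birth. Breeding values are drawn directly from
$N(\mathbf{0}, \mathbf{K}\sigma^2_u)$ — the model the statistics
assume — rather than from explicitly simulated QTL; marker genotypes
are therefore linked to the pedigree but not causally to the
phenotype. The simulator also deliberately omits selection, overlapping
generations, genotyping error and allele-frequency ascertainment.
Passing tests on these data show the statistics behave correctly under
the assumed model; they cannot show robustness to selection or to
model misspecification in real populations.

All randomness flows from the single integer seed in `sim_config()`;
a fixed configuration reproduces its output bit for bit.

## Behaviour worth knowing about

* **CD is not monotone in linkage.** Adding across-unit sire links
  first raises CD (prediction improves), but past the point where the
  units become genetically similar, CD falls again — by design: its
  denominator, the prior contrast variance, shrinks toward zero for
  near-identical groups. PEVD and r respond monotonically over the
  same designs. The design-response tests therefore operate in the
  sparse-linkage regime (up to a third of one unit's offspring sired
  across units).
* **The perfect-knowledge limit of CD is a within-unit property.** With
  one record per individual, an across-unit breeding-value difference
  is partially confounded with the unit fixed-effect difference, so its
  PEVD does not vanish even as $\lambda \to 0$; within a unit it does,
  and CD $\to 1$ there.
* **Monte-Carlo agreement.** Simulating phenotype replicates and
  solving the MME reproduces PEV as the empirical variance of
  $\hat{u}_i - u_i$; with 2,000 replicates the per-individual variance
  estimates carry a sampling error of about 3% (relative SE
  $\sqrt{2/n}$), so the mean relative deviation settles near 2% while
  the maximum across 40 individuals is typically 6–9%. Deterministic
  correctness is instead pinned down by the dense-inverse and
  absorption-route oracles.

## Scales used in the tests

The test suite and the acceptance script work at desk scale — systems
of 24–60 phenotyped individuals for the algebraic identities (which
hold at machine precision regardless of size), 2,000 replicates for the
Monte-Carlo posterior check, 20,000 replicate loci for the
gene-dropping check of the tabular $\mathbf{A}$ (sampling error well
under the 0.02 assertion), and one full-size simulator run for the
reference dimensions. These sizes were chosen so the whole suite
completes in well under a minute while leaving every assertion's
tolerance dominated by the property under test, not by the problem
size.

## Limitations

Single-trait models only; no maternal or permanent-environment
effects; no REML/Bayesian variance estimation; no single-step
$\mathbf{H}$ matrix or non-additive relationship matrices; no
reference-set optimization (the package measures connectedness, it
does not search designs). Dense linear algebra bounds practical size
to a few thousand individuals.
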