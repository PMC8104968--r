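---
title: "Models and methods behind molequeen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind molequeen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`molequeen` reimplements, as one tested pipeline, the statistical machinery
used to study what happens to the skeleton and its gene regulation when a
female Damaraland mole-rat becomes the breeding "queen" of her colony:
kinship-aware differential expression in cultured bone cells, cell-type
deconvolution with mediation analysis, topological classification of bone
shape, cross-sectional bone mechanics with a relative failure-risk model,
and morphometric growth and fecundity models. Every stage can be driven by
the package's own synthetic-data generators, which carry known ground
truth, so the statistical behavior of the whole pipeline is testable
without animal data.

## The expression mixed model

The central model treats the log2 expression of one gene across bone-cell
cultures as

$$ y_i = \mu + d_i\beta_1 + b_i\beta_2
   + q_i\,\beta_3\,I(b_i = \mathrm{long}) + q_i\,\beta_4\,I(b_i = \mathrm{LV})
   + s_i\,\beta_5\,I(b_i = \mathrm{long}) + s_i\,\beta_6\,I(b_i = \mathrm{LV})
   + (Zu)_i + \varepsilon_i $$

with $u \sim \mathrm{MVN}(0, \sigma_u^2 K)$ and
$\varepsilon \sim \mathrm{MVN}(0, \sigma_e^2 I)$. Here $d$ is days in
culture, $b$ bone type (long bone vs. lumbar vertebra, LV), $q$ breeding
status, $s$ estradiol treatment, $Z$ the incidence matrix mapping samples
to animals, and $K$ the genetic relatedness matrix. The contrasts of
interest are $\beta_3$ and $\beta_4$ (status within each bone type) and
$\beta_5,\beta_6$ (estradiol within each bone type).

REML estimation exploits the single-kernel structure: one
eigendecomposition of $ZKZ'$ is shared by all genes, after which the REML
criterion is one-dimensional in the variance ratio
$\delta = \sigma_e^2/\sigma_u^2$. `fit_lmm_matrix()` profiles $\delta$ on a
100-point log10 grid spanning $10^{-5}$ to $10^{5}$ and refines each
gene's optimum by golden-section search between the flanking grid points
(default tolerance $10^{-4}$ on $\log_{10}\delta$); the fixed effects then
come from GLS at the optimum. Wald t statistics use
$\mathrm{df} = n - \mathrm{rank}(X)$; the convention is a documented
choice, as is the boundary treatment ($\delta$ at the top of the grid is
reported as $\sigma_u^2 = 0$). The engine reproduces `lme4::lmer` REML
fits to about five decimal places on random-intercept data and collapses
exactly to OLS when the random effect vanishes; both facts are asserted in
the test suite.

### Nuisance covariates: in the model, not regressed out first

Two nuisance covariates accompany the design: the proportion of uniquely
mapped reads (library-preparation efficiency) and natal colony (littermate
sets and processing batches). An obvious two-stage approach — per-gene OLS
residualization on these covariates, then the mixed model — turns out to
distort inference: natal colony aligns with the blocks of $K$ (littermates
are both kin and colony-mates), and OLS demeaning of those groups changes
the residual covariance away from the $\sigma_u^2 ZKZ' + \sigma_e^2 I$
form the mixed model assumes. Under null simulations this inflates small
p-values badly enough that a Kolmogorov–Smirnov test against uniformity
fails at 2000 genes. `run_de()` therefore folds the nuisance covariates
into the fixed-effect design of the mixed model itself, which restores
calibration (verified across seeds in the acceptance tests). A standalone
`residualize()` is still exported for the two-stage workflow, with this
caveat documented. Nuisance columns that become collinear with the design
(e.g., a permuted status that is constant within colonies) are dropped by
QR pivoting; core design columns are protected.

### Permutation-based empirical FDR

Significance is controlled by an empirical false discovery rate: the
variable of interest is permuted, the whole per-gene fit is repeated, and
for any threshold $t$ the FDR estimate is the mean number of permuted
p-values at or below $t$ per permutation divided by the observed count at
or below $t$; per-gene q-values are the monotonized minimum over
thresholds at or above the gene's p. Breeding status is permuted **across
animals**, never across samples: the two bone types cultured from one
animal are not exchangeable under the null, and sample-level shuffling
would break the repeated-measures structure. Estradiol, which is assigned
at the sample level, is permuted within animals. Each variable of interest
gets its own permutation set.

Voom-style precision weights are computed and reported by
`log_cpm_voom()` but are deliberately not fed into the mixed model; the
modeled pipeline's mixed-model stage accepted no observation weights, and
keeping the default path weight-free preserves that behavior while the
weights remain available for diagnostics.

The expressed-gene filter keeps genes with TPM ≥ 2 in at least
`ceiling(0.25 * n)` samples; the ceiling convention for "at least 25%" is
a documented, configurable choice (at n = 47 it requires 12 samples).

## Relatedness from SNP genotypes

`filter_snps()` applies, in a fixed logged order: biallelic, minor allele
frequency ≥ 0.1 (inclusive), at most 2 missing calls, exact Hardy–Weinberg
p > 0.05 (full enumeration conditional on allele counts), optional
depth/quality thresholds when those fields exist, then greedy left-to-right
10 kb thinning (a SNP is kept when it lies at least `thin_bp` from the
last kept SNP; ties in position resolve by input order). The relatedness
estimator is the allele-frequency-weighted form whose off-diagonals are
$\frac{1}{N}\sum_i (x_{ij} - 2p_i)(x_{ik} - 2p_i)/(2p_i(1-p_i))$ with the
matching diagonal correction; missing dosages are imputed to the per-SNP
mean first (a deliberate simplification — the modeled workflow used
haplotype phasing, which is out of scope here). Because allele frequencies
are estimated from the sample itself, the estimator centers unrelated
pairs slightly below zero and full sibs slightly below 0.5 in small
family-structured samples; the pedigree simulations in the tests show sib
means within 0.05 of 0.5 at 6000 SNPs and clean separation of sib from
non-sib pairs, which is the property the downstream model needs.

## Cell composition and mediation

Deconvolution regresses each sample's (quantile-normalized) expression
profile on a purified-population signature matrix by nonnegative least
squares and renormalizes the coefficients to the simplex. This is an
explicit approximation to ν-support-vector-regression deconvolution: NNLS
shares its nonnegativity and linear-mixture assumptions, needs no tuning
parameters, and recovers mixing proportions within 0.05 mean absolute
error at 5% noise in simulation; the `solver` argument accepts any
replacement. Composition is summarized by centered PCA with a
deterministic sign convention (largest-magnitude loading positive).

The mediation analysis asks how much of the breeding-status effect on a
gene travels through composition PC1: the indirect effect is the
difference between the status coefficient without and with the mediator,
both fitted by the same kinship mixed model (the kinship term is retained
in both, consistent with the surrounding workflow). Uncertainty comes from
a cluster bootstrap that resamples **animals** with replacement — samples
from one animal are never split across bootstrap draws; the resampling
unit was not otherwise specified, and the animal is the natural
exchangeable unit. The 95% interval is the percentile interval, and an
indirect effect is called significant when it excludes zero. Bootstrap
replicates with constant status are redrawn and counted. In linear
settings the difference-of-coefficients estimate agrees with the
product-of-paths form, which the tests assert.

## Bone shape: Euler characteristic transform

A mesh's ECT records, for each direction $\nu$ on the sphere and height
$t$, the Euler characteristic $\chi_\nu(t) = V - E + F$ of the sublevel
complex (vertices with projection ≤ t plus the edges and faces whose
vertices are all included). Directions are the vertices of a subdivided
icosahedron ($10 \cdot 4^{\mathrm{level}} + 2$; level 2 gives 162) — the
construction is the package's choice of an approximately uniform
spherical point set. Heights are `n_heights` evenly spaced values per
direction spanning the **pooled** projection range of the whole data set,
so features are comparable across meshes (per-mesh ranges are available
as an option). The smooth variant (SECT) integrates the mean-centered
curve cumulatively by trapezoids. With 162 directions and 100 heights the
flattened feature vector has length 16,200. Meshes are assumed
pre-aligned; `pca_align_mesh()` is provided as a crude convenience and is
clearly not equivalent to proper joint surface alignment. A
per-direction-variable evaluation count (as used for femora in the
modeled study, averaging 71) has no stated generating rule and is not
reproduced; fixed counts are used instead.

Classification is leave-one-out with a linear soft-margin SVM. To balance
unequal class sizes the minority class (queens) carries a per-class
misclassification weight of $10^5$ against 1 — the weighted side is a
documented choice, since a bare "1:100,000" ratio does not name it. Tied
decision values predict the heavier-weighted class, deterministically.
The permutation p-value uses the add-one estimator
$p = (1 + \#\{\mathrm{perm} \ge \mathrm{obs}\})/(1 + n_{\mathrm{perm}})$,
so p is never zero and its floor at 100 permutations is 1/101.

## Cross-sections, failure risk, thickness deciles

`section_geometry()` works on binary rasters: cortical area is foreground
pixel count times pixel area; total (periosteal) area additionally counts
enclosed holes, identified by flood filling from the image border (any
pixel unreachable from the border is enclosed); second moments accumulate
per pixel about the centroid with the $a^4/12$ pixel self-moment, and
principal moments come from the 2×2 area-moment tensor
($J = I_{xx} + I_{yy}$ is rotation invariant). Annulus closed forms are
recovered within 2–3% at radii of tens of pixels.

Failure risk is modeled without any measured failure loads: a linear
calibration of maximum load on cortical area, fitted to a rodent data set
(synthetic stand-in here, tuned so the expected $R^2 \approx 0.88$ at
n = 81 — slope 30 N/mm², intercept 2 N, residual sd 6.5 N over a
0.5–2.5 mm² CA range), is extrapolated to the study animals, predictions
are rescaled so the nonbreeder median equals 1, and the predicted
relative load is treated as the failure-time axis of a Cox model with no
censoring (every bone "fails" at its load, so the partial likelihood
compares whole load distributions; Efron tie handling, the common modern
default). Lower load means earlier failure, so a group with thinner
cortex gets a hazard ratio above one. A Schoenfeld-residual diagnostic
and Kaplan–Meier curves are attached to every fit. The headline hazard
ratios of the motivating study require the real femora; the synthetic
pipeline checks direction and calibration, not those values.

Cortical thickness profiles are trimmed to the central 80% of the axial
extent — the trim is half-open, $[0.1, 0.9)$, so a point at exactly 10%
is retained — and re-partitioned into 10 equal axial bins whose means
feed per-decile mixed models (status + offspring count, random intercept
per littermate pair, identity kinship over pairs through the same REML
engine; unpaired animals become singleton groups with a warning).

## Morphometric and fecundity models

Longitudinal vertebral growth is modeled as LV5 length on time, status
and their interaction with a random animal intercept, fitted within a
stated post-pairing interval (the queen-specific lengthening concentrates
in the first interval). Litter size is modeled on maternal body length
and a first-litter flag with a random maternal intercept; pup mass adds
litter size and a second random intercept per litter, fitted by direct
REML over two variance ratios (`reml_multikernel()`, Nelder–Mead on the
log scale), which collapses to the single-kernel fit when the litter
variance is zero. Growth-plate fusion and chondrocyte-column density are
ordinary least squares on offspring count and age. All single-kernel fits
route through the same REML core as the expression model, so a fix there
propagates everywhere; coefficients rescale exactly under unit changes.

## What the generators emulate — and what they do not

The synthetic module generates: family pedigrees with Mendelian SNP
transmission (founder frequencies uniform over a stated MAF range);
negative-binomial counts whose log-mean follows the expression model
exactly, with per-gene dispersions drawn log-normal
($\mu = -1.5, \sigma = 0.5$ on the log scale, a plausible bulk RNA-seq
range), log-normal library sizes, and an animal-level random effect drawn
from the supplied kinship; elongated-vs-round icosphere meshes
(subdivision level 3, 642 vertices, so 162-direction featurization is
nondegenerate; default elongation 1.3 with vertex jitter sd 0.02);
annular cross-sections in which queens' endosteal radius grows
0.02 mm per pup at fixed periosteal radius (marrow expansion, the
pattern seen in parous queens); a linear max-load calibration set; and
longitudinal LV5, litter, and growth-plate tables with stated effect
sizes (interaction 0.08 mm/month in the first interval only; litter-size
slope 0.35 pups/cm; fusion slope 0.05 per pup). Offspring counts are
Poisson(3) capped at 12. Every generator is a pure function of
(parameters, seed).

What they do **not** emulate: aligned real bone geometry (icospheres are
a caricature of vertebrae), annotation artifacts, batch structure beyond
a colony label, sequencing-depth–dependent dispersion trends, mesh
decimation or registration error, or μCT segmentation noise. Passing
tests therefore demonstrate that the statistical machinery is correct and
calibrated under its stated assumptions — not that those assumptions hold
in any particular real data set.

## Numerical choices and problem sizes

Degenerate inputs are handled explicitly: empty sections, all-zero
samples, monomorphic SNPs, rank-deficient designs and zero-variance
calibrations raise errors naming the offender; empty decile bins and
all-zero NNLS coefficient vectors warn and return missing/uniform values.
The kinship eigendecomposition clips eigenvalues at zero and rejects
matrices below $-10^{-8}$ relative. Interval arithmetic is 0-based
half-open internally; the promoter window around a TSS is closed at both
ends, so a motif hit at exactly TSS + 2000 bp counts.

The test and acceptance suites run the statistics at deliberately modest
problem sizes chosen by the package — e.g., 2000 genes for calibration
checks, 200 replicates at 200 genes with 12 permutations for the
empirical-FDR check, 80 null simulations with 120 bootstrap draws for
mediation coverage, 24 animals for growth-model recovery, and a reduced
end-to-end configuration for the bit-identity check — sizes at which the
asserted properties (uniformity, coverage, recovery within three standard
errors) are stable across seeds. The pipeline's `default_config()` uses
similarly desk-scale sizes and finishes in minutes on one CPU.

## Known limitations

* The per-gene t reference with $n - \mathrm{rank}(X)$ df ignores
  variance-component uncertainty; the permutation FDR absorbs residual
  miscalibration, and the paired KS checks bound it under the null.
* The NNLS deconvolution is a stand-in for ν-SVR deconvolution and will
  differ on real signature matrices with collinear cell types.
* The cluster bootstrap treats resampled animals as independent clusters
  while reusing the kinship submatrix; with strongly related duplicated
  animals the interval is mildly conservative.
* Mesh alignment is out of scope; unaligned meshes are accepted silently
  because alignment is the caller's contract.
* The relatedness estimator inherits in-sample allele-frequency bias in
  small family-structured cohorts, as quantified in the tests.
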