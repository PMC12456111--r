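---
title: "Landscape genomics with adaptscape: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Landscape genomics with adaptscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adaptscape)
```

adaptscape implements a complete landscape-genomics workflow for biallelic
SNPs sampled across populations of a non-model species: from a filtered
genotype matrix to the neutral/outlier partition, isolation by distance and
environment, variance partitioning, genotype–environment association (GEA),
gradient-forest turnover modelling, and spatial genomic-vulnerability
surfaces under future climates. This vignette explains the models behind
each stage, the tunable parameters, and what the synthetic-landscape
generator does and does not emulate.

## The study design the package assumes

All analyses take population-level data: a `genotype_matrix` of diploid
dosages (0/1/2, `NA` for missing) with a population label per individual,
per-population coordinates (decimal degrees, WGS84), and a per-population
environmental table. The reference design — mirrored by the synthetic
generator's defaults — is 27 populations of 2–17 diploid individuals spread
over a heterogeneous landscape in three genetic groups, with 19 bioclimatic
and 5 soil variables, and future climate rasters for low- and high-emission
scenarios.

## SNP filtering

`filter_snps()` applies, in order: one SNP per RAD locus (the first by
position within each `chrom` tag, to limit linkage), presence (genotyped in
at least 85% of individuals *and* at least 19 populations), global minor
allele frequency at least 0.05, and observed heterozygote fraction at most
0.5 (a guard against collapsed paralogs). Each rule's removal count is
logged. The order matters for the counts, not the surviving set.

## Diversity and differentiation

Per-population expected heterozygosity uses the unbiased gene diversity
$H_E = 2p(1-p)\,n/(n-1)$ with $n$ the sampled alleles at the site. For an
SNP site this equals the per-variant-site nucleotide diversity, so `pi` and
`he` coincide in `diversity()` — with SNP-matrix input, per-base $\pi$ over
all sites is not computable, and the reported value is the mean over
variant sites (monomorphic-within-population sites contribute zero).
$F_{IS} = 1 - \bar H_O/\bar H_E$.

Differentiation is Weir & Cockerham's (1984) $\theta$, computed from the
per-locus variance components $a$ (among populations), $b$ (among
individuals within populations) and $c$ (within individuals), and combined
over loci as a ratio of sums $\sum_l a_l / \sum_l (a_l+b_l+c_l)$ — the
standard, stable choice for RAD data (averaging per-locus ratios is noisier
at small sample sizes). Loci untyped in one member of a pair are skipped
for that pair only.

`genotype_pca()` uses the GCTA-style GRM convention: dosages centred by
$2\hat p$ and scaled by $\sqrt{2\hat p(1-\hat p)}$, missing values
mean-imputed per locus (equivalent to zero after centring), and an
eigen-decomposition of the individual covariance. The first three
population-mean scores serve as neutral-structure proxies downstream.

## The neutral/outlier partition

Two $F_{ST}$-outlier scans are implemented, and a locus is declared an
outlier only when *every* configured scan flags it — the conservative
intersection rule. An externally produced flag file (for example a Bayesian
F-model run made outside the package) can join the intersection via
`partition_outliers(external = ...)`; a reversible-jump MCMC scan is
deliberately not reimplemented, since its role in the rule is one vote.

* `pc_scan()` regresses each locus's scaled dosages on the first $K$
  genotype PCs, converts the $K$ coefficients to z-scores, and measures a
  robust Mahalanobis distance per locus. Distances are rescaled by the
  genomic inflation factor (median distance over the $\chi^2_K$ median) and
  referred to $\chi^2_K$; flags are BH q-values below $\alpha$. The robust
  scatter uses a deterministic iteratively trimmed estimator (recompute
  mean/covariance from points inside the 95% $\chi^2$ envelope): unlike
  subsample-based robust estimators, it is reproducible and invariant to
  locus order, which the tests rely on.
* `fdist_scan()` rebuilds the classical $F_{ST}$-vs-heterozygosity
  envelope with a parametric Balding–Nichols island-model null instead of
  coalescent simulation: ancestral frequencies uniform on (0.01, 0.99),
  population frequencies Beta-distributed with $F$ set to the trimmed mean
  of the observed per-locus $\theta$ ("neutral mean F_ST"), binomial
  sampling at the observed per-population median allele counts. Observed
  loci get an upper-tail p within their expected-heterozygosity bin (20
  equal-width bins on [0, 0.5], widened adaptively until at least 100 null
  draws). A locus is flagged when its p sits in the top-1% tail *and* its
  BH q is below $\alpha$; both criteria are also reported separately, since
  the conjunction is one reading of combining a "top 1%" rule with an FDR
  rule. The default null size is $10^6$ draws; analyses in the package's
  own tests and acceptance script use $10^5$–$2\times 10^5$, which the
  Monte-Carlo stability check shows is already flag-stable at these locus
  counts.

## Space: distances, dbMEMs, Mantel tests

Geographic distances are haversine great-circle distances on a sphere of
radius 6371.0088 km. Moran eigenvector maps use the distance-based
construction: truncate the distance matrix at the longest
minimum-spanning-tree edge, replace larger distances by four times the
truncation, double-centre and eigen-decompose (via `vegan::pcnm`), keep
positive-eigenvalue vectors, and retain those with significant positive
Moran's I under a 999-permutation test. On a regular transect the first
eigenvector is a one-node sine wave — the broadest-scale pattern the basis
can express — not a strictly monotone trend; the tests assert that
structural fact. All significant vectors are reported; a config cap allows
reproducing workflows that fix the count (e.g. exactly three).

Mantel tests (`mantel_test()`, wrapping `vegan::mantel`) correlate
lower-triangle entries with a one-sided upper-tail permutation p,
$p = (1 + \#\{r^\ast \ge r\})/(n_{perm}+1)$ — IBD and IBE are directional
hypotheses. The genetic distance defaults to raw pairwise $\theta$;
$\theta/(1-\theta)$ linearisation is a switch. Environmental distance is
Euclidean on the first two PCs of the z-scored variables.

## Variance partitioning

`variance_partition()` runs the full RDA of the population × locus
allele-frequency matrix on all predictors and the three partial RDAs in
which each set (environment, geography = retained MEMs, structure = first
three genetic PCs) is conditioned on the other two. The headline numbers
are Ezekiel-adjusted $R^2$ (vegan's convention); small negative conditional
fractions are legitimate and reported as-is. The confounded remainder is
the full fraction minus the three conditional ones. The response is
population-level allele frequencies rather than individual dosages because
the predictors are per-population; an individual-level mode would simply
pass a dosage matrix.

## Genotype–environment association

`lfmm_scan()` is a ridge latent-factor linear mixed model, one scan per
environmental variable: alternate (a) latent factors $U, V$ from a rank-$K$
truncated SVD of $Y - x b^\top$ and (b) per-locus effects $b$ from ridge
regression of $Y - UV^\top$ on $x$, to convergence. Final inference refits
each locus by OLS on $(x, U)$, calibrates the z-scores by the genomic
inflation factor, and applies BH per variable (each variable is scanned
independently). With $K = 0$ the scan reduces exactly to per-locus simple
regression — a tested identity. The solver is deterministic; the default
$K = 3$ matches the three-group structure the design assumes.

`rda_loading_scan()` flags loci whose RDA loadings sit more than 3 SD from
the mean on one or more constrained axes (inclusive at the boundary). By
default **all** constrained axes are scanned. This is a deliberate design
choice: with strong neutral structure, the first axes are dominated by
group-level gradients, and loci tied to a single climate variable load on
later axes; restricting to the first three axes systematically misses them.
The number of axes remains an argument for narrower conventions.

Core candidates are the intersection of LFMM hits (q < 0.05 for at least
one variable) and RDA hits, annotated with their associated variables;
`gea_by_group()` repeats the scans within each genetic group. When scans
are run to measure recovery of known (simulated) adaptive loci, they are
applied to the filtered locus set *without* first removing $F_{ST}$
outliers — the partition would remove precisely the strongest planted
clines, conflating two different questions.

## Gradient-forest turnover

`fit_gradient_forest()` fits one random-forest regression per locus of its
population allele frequencies on the predictors — 500 trees per SNP by
default, `mtry = ceiling(p/3)`, bootstrap over populations, all seeded. The
forest is a compact Rcpp implementation written for this package because
the turnover functions need what off-the-shelf forests do not expose: every
split's predictor, split value and impurity improvement, plus out-of-bag
permutation importance. Loci with positive OOB $R^2$ are retained;
predictor importance is the mean over retained loci of (per-locus
importance share × locus $R^2$). Split improvements are binned along each
predictor (201 bins over the observed range), normalised so the area equals
the predictor's weighted importance, and cumulated into the turnover
function $F_p$. Density standardisation of split improvements is omitted:
the offsets depend on relative turnover shape, and the unstandardised form
is simpler and directly testable (conservation: total turnover equals total
weighted importance). Outside the training range $F_p$ is clamped, not
extrapolated — extrapolated turnover is undefined by the method, so
$F_p(\min) = 0$ and $F_p(\max)$ equals the predictor's importance.

`prune_variables()` removes multicollinearity before the final models:
while any pair exceeds $|r| > 0.75$, the pair's lower-importance member is
dropped. In the default pipeline a ranking forest is fitted first on a
seeded subsample of loci (500 by default) to supply the importances, and
the final turnover model is fitted on a seeded subsample of neutral loci
(1,000 by default) plus all core candidates — problem sizes chosen so the
complete pipeline runs in minutes while leaving importance rankings and
turnover shapes stable.

## Offsets, RGB composites, RONA

`transform_env()` maps every raster cell into "genetic composition" space
by applying each predictor's $F_p$. The offsets are then:

* **local** — Euclidean distance between a cell's current and future
  compositions;
* **forward** — minimum distance from a cell's current composition to the
  future composition of any cell within a migration radius (50, 100, 200,
  500 km or unlimited; the cell itself included, so forward ≤ local and
  larger radii can only shrink it — both identities are tested cellwise);
* **reverse** — minimum distance from a cell's future composition to any
  cell's current composition: is anyone alive today preadapted to that
  future?

The forward/reverse minimisation searches all grid cells, not only sampled
populations, because compositions are predicted for every cell. The RGB
composite min–max scales local/forward/reverse to [0, 255] (R/G/B), keeping
the scaling bounds so offsets can be recovered up to quantisation.

`rona()` (risk of non-adaptedness) regresses each associated core locus's
frequencies on its variable, keeps slopes with p < 0.05, and averages
$|a\,v_{fut} + b - p_{obs}|$ across loci with regression-$R^2$ weights (the
cited workflows say only "weighted means"; $R^2$ weighting is the common
practice, and uniform weighting is a switch). By default a locus
contributes only to the variables it is associated with. RONA and local
offset generally agree in ranking populations, but not tightly: recursive
partitioning concentrates turnover mid-range even for linear clines, making
$F_p$ S-shaped while RONA is linear in the environmental shift — the
agreement is reported as a sanity check, not asserted as a theorem.

## The synthetic landscape generator

`simulate_dataset()` produces a complete, fully seeded dataset:

* **Environment** — each bioclim layer is a linear gradient in a random
  direction plus a low-frequency sinusoid plus white noise (defaults:
  gradient range 10, sinusoid amplitude 4, noise SD 0.5 on a 20×50
  one-degree grid). The sinusoid amplitude is deliberately substantial:
  with nearly pure gradients every layer is a linear function of
  (lon, lat), the 19-layer set is effectively rank two, and correlation
  pruning would collapse it to two or three survivors — real climate
  surfaces are far from that degenerate, and with these defaults pruning
  retains about ten of 24 variables, as typical published sets do. Soil
  layers are independent smoothed random fields. The future stack is the
  current one plus a per-variable shift (half a spatial SD by default)
  modulated north–south; soils do not change.
* **Neutral loci** — hierarchical Balding–Nichols: ancestral frequency
  uniform on (0.05, 0.95), group frequencies Beta-distributed at
  $F_{between} = 0.25$, population frequencies Beta at $F_{within} = 0.10$
  within their group, genotypes Binomial(2, p), 5% uniform missingness.
  The three groups occupy distinct spatial clusters, which by itself
  produces strong realised isolation by distance (Mantel r ≈ 0.6–0.7) and
  pairwise $\theta$ spanning roughly 0.1–0.5 — in the range reported for
  strongly structured understory herbs. An optional Gaussian-copula
  spatial correlation of within-group frequencies (`ibd_range_km`) adds
  locus-level IBD while preserving the Balding–Nichols marginals; it is
  off by default because spatially autocorrelated neutral loci manufacture
  chance environmental clines and are not part of the base model.
* **Adaptive loci** — logistic clines
  $p = \mathrm{logis}(\alpha + \beta z)$ in a standardised driver variable,
  with $|\beta|$ uniform on [1, 2] and random sign. Drivers default to the
  five mutually least-correlated bioclim layers: distinct selective
  pressures act along distinct climate axes, and a driver that is a
  near-duplicate of several other layers is both unrealistic and
  undetectable after pruning. The truth table (locus, driver, α, β) is
  returned for recovery experiments.

What the generator does *not* emulate: linkage disequilibrium along
chromosomes (loci are exchangeable), selection dynamics through time,
demographic size changes, sequencing-error or depth-dependent missingness
patterns, and polygenic architectures (each adaptive locus responds to one
driver). Passing tests therefore demonstrate that the estimators and scans
behave correctly under the generative models they assume — not that any
particular real dataset satisfies those assumptions.

## Numerical and testing choices

Tests and the acceptance script run the pipeline at reduced problem sizes —
3,000 neutral + 30 adaptive loci, a 1,000-cell grid, $10^5$–$2\times10^5$
fdist null draws, 500-tree forests on 500–800-locus subsamples — chosen as
the package's own desk-scale defaults; every estimator is additionally
pinned to brute-force oracles on tiny instances at $10^{-10}$ tolerance.
Seeds control every stochastic step (beta/binomial sampling, permutation
tests, forest bootstraps via R's RNG inside the C++ code), so identical
seeds give bit-identical outputs. Degenerate inputs are handled
deliberately: constant environmental variables are dropped with a warning,
aliased RDA predictors pruned with a warning naming them, duplicate
coordinates refuse MEM construction rather than silently jittering, empty
filter results raise an error advising threshold review, and a perfect RDA
fit reports the permutation floor rather than an undefined F-statistic.

## Known limitations

GeoTIFF rasters are not read or written — the grid format is the ESRI
ASCII grid, which is plain text and round-trips exactly; convert GeoTIFFs
externally. The fdist-style scan's parametric null assumes an island model
and will be miscalibrated under strong hierarchical structure (the
intersection rule mitigates, and the PC scan models structure directly).
RONA inherits the limits of locus-wise linear regression. Forward/reverse
offsets scale quadratically in grid cells; the default grids keep this in
the hundreds of milliseconds, but continental 30-arc-second grids need
tiling or coarsening first.
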