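---
title: "Methods: habitat age and microsatellite genetic structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: habitat age and microsatellite genetic structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agenet)
```

## The scientific question

Forest herb populations in fragmented agricultural landscapes occupy patches
of very different habitat ages (decades to centuries).  Population genetic
theory predicts that young, recently founded populations carry the signature
of founder effects and post-founding drift — lower diversity, higher
differentiation — while old populations have had time to accumulate
diversity and genetic exchange.  `agenet` implements the full analysis chain
needed to test this on co-dominant microsatellite data: per-population
diversity, three complementary pairwise differentiation measures, a
population-graph layer, spatial covariables, and a mixed-model regression
layer that relates all of these to habitat age while controlling for
population size and spatial connectivity.

Because the interesting contrasts are *within* a landscape, populations are
organized into replicate landscape windows (5 × 5 km in the emulated study
design); all pairwise quantities are computed within windows only.

## Data model and quality control

Genotypes enter as one row per sampled individual with two allele columns
per locus (fragment lengths), in either a tabular CSV dialect or GenePop.
All missing-value spellings are normalized to one internal sentinel at parse
time, and a locus is either fully observed or fully missing for a sample —
half-calls are rejected.  Tetraploid taxa scored with two allele calls per
locus are handled exactly as coded; no dosage inference is attempted, since
every downstream estimator here operates on the two-column coding.

Three filters mirror standard microsatellite QC for clonal herbs:

1. samples failing at more than one locus are removed;
2. repeated multi-locus genotypes (MLGs) within a population are collapsed
   to one genet (putative clones); repeats in *different* populations are
   never collapsed;
3. populations with fewer than four MLGs are dropped — too small for the
   among-population covariance estimation of the graph layer.

Whether two MLGs with different missingness patterns are "repeated" is not
decidable from the data alone.  The default is conservative: they must agree
at every mutually observed locus *and* have the same missingness pattern;
`wildcard_missing = TRUE` relaxes this so a missing locus matches anything.
With genotyping failure rates of a few percent the two rules rarely differ,
but the conservative default never merges distinct genets that merely share
their observed loci.

## Diversity statistics

Per population: observed heterozygosity `Ho` (locus-wise fraction of
heterozygous genotypes, unweighted mean over loci), unbiased expected
heterozygosity `He` (Nei's gene diversity with the small-sample factor
2N/(2N−1), N = observed genotypes at the locus), the inbreeding coefficient
`F = 1 − Ho/He` (undefined, not zero, when He = 0), and rarefied allelic
richness

$$A_r = \sum_a \left[1 - \binom{N_g - N_a}{g}\Big/\binom{N_g}{g}\right],$$

the hypergeometric expectation of the number of distinct alleles in a
standardized subsample of $g$ gene copies.  The rarefaction depth is given
in individuals (matching how field sample sizes are reported — the default
depths are 18/16/16 individuals for the three emulated species panels) and
mapped internally to $g = 2 \times$ depth gene copies.  At loci with fewer
observed copies than $g$ the value is computed at the observed depth and the
locus is flagged, rather than dropping the population: the emulated design
deliberately keeps very small populations and rarefies to the *mean*, not
the minimum, sample size.  Locus averaging is unweighted throughout.

## Pairwise differentiation

Within each window, for every population pair:

* **DPS** — one minus the mean over loci of the summed minimum shared allele
  frequencies, computed from population frequency profiles.  (An
  individual-pair averaging variant exists in the literature; the
  frequency-based form is used because every other statistic here is also
  frequency-based.)
* **G″ST** — the standardized, small-sample-corrected heterozygosity-based
  measure for k = 2 demes,
  $G''_{ST} = k(\hat H_T - \hat H_S)/[(k\hat H_T - \hat H_S)(1 - \hat H_S)]$,
  with $\hat H_S, \hat H_T$ the Nei–Chesser sample-size-corrected
  heterozygosities using the harmonic-mean sample size.  Heterozygosities
  are averaged across loci before the ratio (ratio of averages), the
  convention of the standard implementations; per-locus ratio averaging is
  available as an option.  Negative finite-sample estimates are retained —
  truncating them at zero would bias the regression layer.  Note that the
  small-sample correction means two finite samples with *identical*
  frequency profiles do not return exactly 0 (the uncorrected estimator
  does; it is exposed via `correction = "none"`); the corrected estimator is
  unbiased over sampling replicates instead.
* **cGD** — conditional genetic distance through the population graph
  (below); only defined for pairs, and only modelled for pairs directly
  connected by a retained edge, because the pairwise age covariates carry no
  information about intermediate populations on a multi-edge path.

## The population graph layer

Individuals are encoded as allele-dosage vectors (0/0.5/1 per allele column,
one column per distinct allele in the window).  Missing loci are imputed
with the within-population mean dosage — this leaves population centroids,
which drive everything downstream, unchanged, and is the package's
documented mechanism for tolerating missing genotypes in the graph machinery
(the classic implementations require complete data).  A locus missing for an
entire population falls back to the window mean with a warning.

Squared Euclidean distances among population centroids are double-centered,
`C = −½ H D² H`, to give the among-population covariance.  `C` always has
the constant vector in its null space (a property of centering), so the
Gaussian-graphical-model precision matrix is computed on the orthogonal
complement of that structural direction; any *additional* near-null
direction signals duplicate populations and raises an error pointing at the
ridge option.  Each edge's partial correlation $r_{ij}$ gives its edge
exclusion deviance $EED = -n\,\ln(1 - r_{ij}^2)$, compared against
$\chi^2_1$ at the pruning level (0.05 by default, configurable); `n` is the
number of genotyped individuals in the window after filtering.  Edges whose
removal does not significantly worsen the fit carry no unique covariance
information and are pruned.  Retained edges are weighted by the
covariance-derived distance $d_{ij} = \sqrt{C_{ii} + C_{jj} - 2C_{ij}}$
(equal to the centroid distance), which is a proper metric for shortest
paths.

From the pruned graph: **cGD** is the Dijkstra shortest-path length (pairs
in different components are missing, not infinite); **NHc**, normalized
harmonic centrality, standardizes all pairwise graph distances by the
minimum positive distance (so they lie in [1, ∞)) and averages their
inverses over the *n* node slots (division by n follows the definition used
for cross-graph comparability; n−1 is available as an option); and
**DIFF_GEN_GEO** is, per retained edge, the edge's share of total cGD minus
its share of total straight-line geographic distance — positive edges are
genetically farther apart than geography suggests.  The shares are taken
over retained edges only, and they sum to zero by construction.

## Spatial covariables

Hanski's incidence-function connectivity
$C_i = \sum_{j \ne i} A_j^{b} e^{-\alpha d_{ij}}$ with $b = 0.5$ and
$1/\alpha$ calibrated per species as the mean nearest-neighbour distance
within windows, averaged across windows.  Distances are Euclidean between
population reference points in projected metres; when only point locations
are available this stands in for edge-to-edge patch distance, and the same
distance definition is reused for the pairwise `GEO_DIST` covariate for
internal consistency.  Census size enters the connectivity sum untransformed
(the size exponent b already damps it).

## The regression layer

All quantitative variables are Box-Cox transformed (profile-likelihood
lambda on a [−3, 3] grid at 0.01 steps, with a `1 − min` shift when values
are non-positive) and standardized to mean 0, SD 1.  Standardization
grouping follows the logic of the emulated design: measures with
species-specific absolute scales (diversity, differentiation, population
size, connectivity) are standardized per species so effect sizes are
comparable across species; variables on a shared scale (habitat age,
geographic distance) are standardized globally so between-species contrasts
remain meaningful.

Diversity and NHc are modelled with random-intercept LMMs (lme4, ML — not
REML, because AICc selection compares fixed-effect structures), with
landscape window and forest patch nested in window as random factors
(window only for the node- and pair-level graph models).  A grouping factor
with as many levels as observations is confounded with the residual and is
dropped with a message — this happens for the patch term in single-species
runs where nearly every population has its own patch.  Coefficient p-values
use Satterthwaite degrees of freedom.

Pairwise responses use **MLPE** (maximum-likelihood population effects)
models, which account for the non-independence of pairs sharing a
population.  The implementation parameterizes the structure through node
effects: an observation on pair (i, j) carries $u_i + u_j$ with
$\mathrm{Var}(u) = \sigma_a^2$, plus a window intercept and residual.  Pairs
sharing exactly one population then have correlation
$\rho = \sigma_a^2 / (2\sigma_a^2 + \sigma_e^2) \in (0, 0.5)$ — exactly the
Clarke et al. correlated-pair structure with its usual bound on rho.  The
likelihood is maximized over the three log-variances with the fixed effects
profiled out by GLS, exploiting the block-diagonal (per-window) covariance;
coefficient p-values use the normal approximation on the GLS standard
errors.

Model selection enumerates **all subsets** of the optional fixed terms that
respect marginality (an interaction never enters without its lower-order
relatives), always keeps the retained terms (species identity), fits every
candidate by ML on identical data, and picks the lowest AICc
(`AIC + 2k(k+1)/(n−k−1)`), breaking ties toward fewer parameters.
Candidates that fail to converge are excluded and logged in the selection
table.  Generalized variance-inflation factors (determinant-ratio
definition, reported as GVIF^(1/2df)) flag collinearity; the conventional
concern threshold is 4 on the squared scale.  Marginal and conditional
R² use the variance-partition definitions; for MLPE fits the window and
node-effect variances are assigned to the conditional component.
Significance is reported at the conventional field levels ((*) p ≤ .1,
* p ≤ .05, ** p ≤ .01), and species-specific slopes from interaction terms
are compared pairwise at α = .05 without multiplicity correction, with
compact letters marking groups.

## The synthetic landscape generator

The generator exists so every stage is testable without any field data, and
its defaults are the emulated study conditions: 6 windows of 5 × 5 km,
10 populations per window at least 200 m apart, habitat ages spanning
18–338 years (log-uniform with both endpoints always present, since the
field sampling deliberately covered the full age range), a 10-year
generation time (age of first flowering), 6–9 loci, ~20 sampled individuals
per population, ~2% missing genotypes, ~10% clonal duplicates, and census
size log-linearly coupled to age (mirroring the empirical size-age
correlation).  Ages are spatially clustered within windows (old forest
cores vs. afforestation fringes) so that age, size and neighbourhood
connectivity covary positively, as they do in the field data the design
emulates — without spatial clustering of age, incidence-function
connectivity would be independent of a population's own attributes.

Genetics are simulated **forward in time** per window: a coalescent would
be awkward with staggered founding times and age-dependent sizes, and the
problem is small enough for frequency-based Wright–Fisher simulation.  The
oldest populations are initialized by binomial sampling from a window-level
ancestral pool (symmetric Dirichlet over a stepwise allele ladder, a
mutation-drift-equilibrium stand-in); younger populations are founded at
their age in generations by a configurable number of diploid founders drawn
from extant populations weighted by a distance kernel; every generation
applies doubly stochastic distance-kernel migration (symmetric, so
metapopulation allele frequencies are conserved in expectation), stepwise
mutation (±1 repeat unit, reflecting ladder boundaries), and multinomial
drift at 2Ne gene copies, with Ne a clamped linear map of census size.
Present-day samples are drawn under Hardy–Weinberg, then missingness and
within-population clonal duplicates (full-row copies) are injected.

What the generator does *not* emulate: linkage, null alleles and scoring
error, selection, tetraploid inheritance, pollinator-specific dispersal
kernels, and realistic patch geometry (populations are points, not
polygons).  Passing tests therefore demonstrate correctness of the
estimators and the direction of the founder/drift/gene-flow mechanisms, not
that field data will show any particular effect size.  Two systematic
consequences are worth knowing: attribute collinearity (size–connectivity)
is weaker in simulated landscapes than in the field data the design
emulates, and the sign of the pairwise age effect on DPS can legitimately
differ from the field result — in the simulator young populations resemble
their source populations (recent founding from neighbours), whereas in
century-scale field systems young populations are often *more*
differentiated.

## Numerical choices and known limitations

* Problem sizes in the shipped tests and the acceptance script are
  desk-scale by design: 200-replicate coverage checks and 1000-replicate
  type-I checks for the parametric model layer, windows of 4–10 populations
  for the graph layer, full 6-window 3-species runs for the end-to-end
  pipeline.
* The EED pruning level defaults to 0.05; with ~10 populations per window
  the test has modest power and retained topologies are sparse.  `alpha → 1`
  reproduces the saturated graph.
* Rarefaction uses `lchoose` so large copy counts do not overflow.
* With mostly-singleton forest patches, the patch-in-window variance is
  weakly identified; the placebo simulation shows no systematic age trend
  (mean standardized slope ≈ 0) but Wald p-values on pipeline responses can
  be mildly anticonservative in that regime.  The parametric calibration of
  the model layer itself is clean (type-I ≈ 0.05).
* Box-Cox lambda is chosen per variable on the pooled data before grouped
  standardization; transform records (lambda, shift, grouping) are kept.
* The MLPE rho is bounded in (0, 0.5) by the node-effect parameterization;
  pairwise data generated with negative shared-population correlation would
  hit the boundary at 0.

## A worked miniature

```{r mini, eval = FALSE}
cfg <- scenario_config("age_gradient", seed = 7, n_windows = 3,
                       pops_per_window = 8)
sim <- simulate_dataset(cfg)
run <- run_all(list(herb = list(table = sim$table, attrs = sim$attrs)),
               rarefaction_depths = 16)
report_tables(run)
```

The `founder_effect` scenario (2-founder colonizations) depresses allelic
richness in young populations relative to the 20-founder default; the
`null` scenario (all founding times equal, size decoupled from age) is the
placebo against which any spurious age trend would show; `paper_scale` is
the default emulated design.
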