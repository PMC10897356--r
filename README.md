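# agenet

Does habitat age leave a detectable imprint on the genetic structure of
spatially isolated plant populations?  `agenet` is an R package for
landscape geneticists working with co-dominant microsatellite data from
populations of known habitat age — typically forest herbs in fragmented
agricultural landscapes, where patches range from recent afforestation to
centuries-old forest remnants.  It implements the complete analysis chain
from raw allele tables to age-effect regression tables, plus a forward-time
simulator so that every stage can be exercised and validated without field
data.

## What it computes

**Per population** (after QC filtering: samples failing at >1 locus removed,
repeated multi-locus genotypes collapsed as clones within populations,
populations with <4 genets dropped):

- rarefied allelic richness
  `Ar = Σ_a [1 − C(N_g − N_a, g) / C(N_g, g)]` (hypergeometric expectation
  at a standardized subsample of g gene copies),
- observed heterozygosity `Ho`, unbiased expected heterozygosity
  `He = 2N/(2N−1) · (1 − Σ p²)`, and the inbreeding coefficient
  `F = 1 − Ho/He`.

**Per within-window population pair**: the standardized differentiation
`G″ST = k(Ĥ_T − Ĥ_S) / [(kĤ_T − Ĥ_S)(1 − Ĥ_S)]` (Nei–Chesser-corrected,
harmonic-mean sample size), the shared-allele distance
`DPS = 1 − (1/L) Σ_loci Σ_a min(p_i, p_j)`, and the conditional genetic
distance `cGD` — the shortest path through a population graph whose edges
are pruned by edge-exclusion deviance `EED = −n ln(1 − r²)` against χ²(1),
where r is the pair's partial correlation in the among-population covariance
(missing genotypes are handled by mean-dosage imputation at the encoding
step).  Graph nodes also get normalized harmonic centrality `NHc`, and
retained edges get `DIFF_GEN_GEO`, the edge's share of total genetic
distance minus its share of total geographic distance.

**Spatial covariables**: Hanski incidence-function connectivity
`C_i = Σ_j A_j^b e^(−α d_ij)` with b = 0.5 and 1/α calibrated from mean
nearest-neighbour distances.

**Regression layer**: Box-Cox transforms, per-species or global
standardization, random-intercept LMMs (window, patch-in-window) for
diversity and centrality, maximum-likelihood population effects (MLPE)
models for pairwise responses (pairs sharing a population are correlated
with ρ = σ²_pop/(2σ²_pop + σ²_e)), all-subsets AICc model selection with
retained terms and marginality, generalized VIF, and coefficient tables
with per-species slopes and compact-letter slope comparisons.

## A worked example

Three synthetic species (6/9/6-locus marker panels) on shared landscapes,
with a strong age gradient injected (young populations founded by two
diploids, low migration):

```r
library(agenet)
mk <- function(seed, n_loci) simulate_dataset(scenario_config("age_gradient",
  seed = seed, n_windows = 3, pops_per_window = 8, n_loci = n_loci))
sims <- list(herb_a = mk(11, 6), herb_b = mk(12, 9), herb_c = mk(13, 6))
datasets <- lapply(sims, function(s) list(table = s$table, attrs = s$attrs))
run <- run_all(datasets, rarefaction_depths = 16)
run
#> agenet_run: 3 species, 72 populations, 252 population pairs
round(run$one_over_alpha, 1)      # calibrated dispersal scale, metres
#> herb_a herb_b herb_c
#> 1275.0  920.4  903.4
aggregate(cbind(Ar, Ho, He) ~ SPECIES, run$diversity, function(x) round(mean(x), 2))
#>   SPECIES   Ar   Ho   He
#> 1  herb_a 2.81 0.45 0.46
#> 2  herb_b 2.93 0.48 0.49
#> 3  herb_c 2.67 0.44 0.44
```

The selected models (all-subsets AICc) come back as a coefficient table in
the layout of standard age-effect reporting — one centered row when a
predictor acts equally across species, three rows with compact letters when
it interacts with species identity:

```r
tab <- report_tables(run)
tab[tab$response %in% c("Ho", "DPS"), ]
#> response variable species estimate    se       p stars letters  R2m  R2c
#>       Ho  POP_AGE     all     0.65 0.087 1.6e-10    **          0.44 0.45
#>      DPS AGE_BASE  herb_a     0.19 0.089 3.5e-02     *       b  0.24 0.43
#>      DPS AGE_BASE  herb_b     0.16 0.095 9.9e-02   (*)       b  0.24 0.43
#>      DPS AGE_BASE  herb_c    -0.12 0.094 2.2e-01  n.s.      a   0.24 0.43
#>      DPS GEO_DIST  herb_a     0.59 0.093 2.0e-10    **       b  0.24 0.43
#>      DPS GEO_DIST  herb_b     0.55 0.099 2.0e-08    **      ab  0.24 0.43
#>      DPS GEO_DIST  herb_c     0.33 0.083 5.6e-05    **      a   0.24 0.43
```

Read: observed heterozygosity rises with habitat age (standardized slope
0.65) identically across species — the injected founder/drift signal — and
pairwise differentiation (DPS) increases with geographic distance in all
three species, more steeply in `herb_a` and `herb_b` (letters mark slopes
that differ at α = .05).  `run_all(..., outdir = "out/")` additionally
writes every table as CSV, each window's population graph as GraphML, the
selection traces as JSON and a run manifest.

A thin command-line wrapper for the simulator and the full pipeline lives
at `inst/scripts/agenet-run.R`.

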