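#' Observed heterozygosity of a population
#'
#' Per locus, the fraction of observed (non-missing) genotypes carrying two
#' distinct alleles; the population value is the unweighted mean across loci
#' with at least one observed genotype.
#'
#' @param table a filtered `genotype_table`.
#' @param population_id population to score.
#' @return numeric Ho in \[0, 1\].
#' @export
observed_heterozygosity <- function(table, population_id) {
  idx <- which(table$meta$population_id == population_id)
  if (!length(idx)) stop("unknown population: ", population_id)
  per_locus <- rep(NA_real_, length(table$loci))
  for (j in seq_along(table$loci)) {
    g <- table$alleles[idx, locus_cols(table, j), drop = FALSE]
    obs <- !is.na(g[, 1])
    if (any(obs)) per_locus[j] <- mean(g[obs, 1] != g[obs, 2])
  }
  if (all(is.na(per_locus)))
    stop("no observed genotypes at any locus for population ", population_id)
  mean(per_locus, na.rm = TRUE)
}

#' Unbiased expected heterozygosity of a population
#'
#' Nei's gene diversity with the small-sample correction
#' \eqn{uHe = 2N/(2N-1) (1 - \sum_a p_a^2)} per locus, where N is the number
#' of observed genotypes at that locus; averaged (unweighted) over loci with
#' data.  Loci without observed genotypes are skipped.
#'
#' @inheritParams observed_heterozygosity
#' @return numeric He.
#' @export
unbiased_expected_heterozygosity <- function(table, population_id) {
  freqs <- allele_frequencies(table, population_id)
  n_copies <- attr(freqs, "n_copies")
  per_locus <- rep(NA_real_, length(freqs))
  for (j in seq_along(freqs)) {
    if (n_copies[j] == 0L) next
    N <- n_copies[j] / table$ploidy      # observed genotypes at this locus
    p <- freqs[[j]]
    per_locus[j] <- (2 * N / (2 * N - 1)) * (1 - sum(p^2))
  }
  if (all(is.na(per_locus)))
    stop("no observed genotypes at any locus for population ", population_id)
  mean(per_locus, na.rm = TRUE)
}

#' Inbreeding coefficient F = 1 - Ho/He
#'
#' @param Ho observed heterozygosity.
#' @param He unbiased expected heterozygosity.
#' @return F, or `NA` when He = 0 (F is undefined for a monomorphic
#'   population, not zero).
#' @export
inbreeding_coefficient <- function(Ho, He) {
  if (any(c(Ho, He) < 0, na.rm = TRUE)) stop("Ho and He must be non-negative")
  ifelse(He > 0, 1 - Ho / He, NA_real_)
}

#' Rarefied allelic richness of a population
#'
#' Hypergeometric expectation of the number of distinct alleles in a
#' standardized subsample of g = 2 * `depth_individuals` gene copies:
#' \deqn{Ar = \sum_a [1 - C(N_g - N_a, g) / C(N_g, g)]}
#' with \eqn{N_g} the observed gene copies at the locus and \eqn{N_a} the
#' copies of allele a; averaged over loci.  Rarefaction depth is given in
#' individuals, matching how field sample sizes are reported; the gene-copy
#' mapping g = 2 * depth is applied internally.  At loci with fewer observed
#' copies than g, Ar is computed at min(g, N_g) and the locus is flagged in
#' the `shallow_loci` attribute rather than the population being dropped.
#'
#' @inheritParams observed_heterozygosity
#' @param depth_individuals rarefaction depth in individuals (>= 1).
#' @return numeric Ar (>= 1 for any locus with data); attribute
#'   `shallow_loci` lists loci where N_g < g.
#' @export
rarefied_allelic_richness <- function(table, population_id, depth_individuals) {
  if (depth_individuals < 1) stop("rarefaction depth must be >= 1 individual")
  g_target <- 2L * as.integer(depth_individuals)
  freqs <- allele_frequencies(table, population_id)
  n_copies <- attr(freqs, "n_copies")
  per_locus <- rep(NA_real_, length(freqs))
  shallow <- character(0)
  for (j in seq_along(freqs)) {
    Ng <- n_copies[j]
    if (Ng == 0L) next
    g <- min(g_target, Ng)
    if (Ng < g_target) shallow <- c(shallow, names(freqs)[j])
    counts <- round(freqs[[j]] * Ng)
    per_locus[j] <- rarefy_locus(counts, g)
  }
  if (all(is.na(per_locus)))
    stop("no observed genotypes at any locus for population ", population_id)
  out <- mean(per_locus, na.rm = TRUE)
  attr(out, "shallow_loci") <- shallow
  out
}

# expected distinct alleles among g copies drawn without replacement from
# allele copy counts; lchoose keeps large N stable
rarefy_locus <- function(counts, g) {
  Ng <- sum(counts)
  sum(1 - exp(lchoose(Ng - counts, g) - lchoose(Ng, g)))
}

#' Per-population diversity table
#'
#' Computes Ar (at the given rarefaction depth), Ho, He and F for every
#' population in the table.
#'
#' @param table a filtered `genotype_table`.
#' @param depth_individuals rarefaction depth in individuals; either a single
#'   value or a named vector keyed by population id.
#' @return data.frame with columns `population_id`, `window_id`, `patch_id`,
#'   `n_mlg`, `rarefaction_depth`, `Ar`, `Ho`, `He`, `F`.
#' @export
diversity_table <- function(table, depth_individuals) {
  pops <- populations(table)
  depth <- if (length(depth_individuals) == 1L)
    stats::setNames(rep(depth_individuals, length(pops)), pops) else depth_individuals
  rows <- lapply(pops, function(p) {
    idx <- which(table$meta$population_id == p)
    Ho <- observed_heterozygosity(table, p)
    He <- unbiased_expected_heterozygosity(table, p)
    data.frame(population_id = p,
               window_id = table$meta$window_id[idx[1]],
               patch_id = table$meta$patch_id[idx[1]],
               n_mlg = length(idx),
               rarefaction_depth = unname(depth[p]),
               Ar = as.numeric(rarefied_allelic_richness(table, p, depth[p])),
               Ho = Ho, He = He,
               F = inbreeding_coefficient(Ho, He),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
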