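#' Shared-allele distance DPS between two populations
#'
#' \eqn{D_{PS} = 1 - (1/L) \sum_{loci} \sum_a \min(p_{ia}, p_{ja})}, computed
#' from population allele frequencies over the L loci usable (observed) in
#' both populations.
#'
#' @param freqs_i,freqs_j frequency lists from [allele_frequencies()].
#' @return numeric DPS in \[0, 1\].
#' @export
pairwise_dps <- function(freqs_i, freqs_j) {
  loci <- intersect(names(freqs_i), names(freqs_j))
  usable <- loci[vapply(loci, function(l)
    length(freqs_i[[l]]) > 0 && length(freqs_j[[l]]) > 0, logical(1))]
  if (!length(usable))
    stop("no locus with observed data in both populations")
  shared <- vapply(usable, function(l) {
    alleles <- union(names(freqs_i[[l]]), names(freqs_j[[l]]))
    pi <- freqs_i[[l]][alleles]; pi[is.na(pi)] <- 0
    pj <- freqs_j[[l]][alleles]; pj[is.na(pj)] <- 0
    sum(pmin(pi, pj))
  }, numeric(1))
  1 - mean(shared)
}

#' Standardized differentiation G''ST between two populations
#'
#' Meirmans & Hedrick's small-sample standardized measure for k = 2 demes:
#' \deqn{G''_{ST} = k(\hat H_T - \hat H_S) /
#'                  [(k \hat H_T - \hat H_S)(1 - \hat H_S)]}
#' where \eqn{\hat H_S}, \eqn{\hat H_T} are the Nei & Chesser (1983)
#' sample-size-corrected within-deme and total heterozygosities with the
#' harmonic-mean sample size, and heterozygosities are averaged across loci
#' before the ratio is taken (ratio of averages; per-locus ratio averaging is
#' available via `combine = "locus"`).  With `correction = "none"` the raw
#' (uncorrected) HS/HT are used, for which identical frequency profiles give
#' exactly 0.  Negative finite-sample estimates are retained, not truncated.
#'
#' @param table a filtered `genotype_table`.
#' @param pop_i,pop_j population ids.
#' @param correction `"nei_chesser"` (default) or `"none"`.
#' @param combine `"ratio_of_averages"` (default) or `"locus"`.
#' @return numeric G''ST (typically in \[0, 1\], small negative values
#'   possible from sampling); `NA` when the estimator is degenerate
#'   (\eqn{\hat H_S = 1}).
#' @export
pairwise_g2st <- function(table, pop_i, pop_j,
                          correction = c("nei_chesser", "none"),
                          combine = c("ratio_of_averages", "locus")) {
  correction <- match.arg(correction)
  combine <- match.arg(combine)
  comps <- g2st_locus_components(table, pop_i, pop_j, correction)
  if (!nrow(comps)) stop("no locus with observed data in both populations")
  if (combine == "ratio_of_averages") {
    g2st_from_h(mean(comps$Hs), mean(comps$Ht))
  } else {
    mean(mapply(g2st_from_h, comps$Hs, comps$Ht), na.rm = TRUE)
  }
}

g2st_from_h <- function(Hs, Ht, k = 2) {
  if (1 - Hs < .Machine$double.eps) return(NA_real_)  # degenerate: Hs = 1
  if (abs(k * Ht - Hs) < .Machine$double.eps && abs(Ht - Hs) < .Machine$double.eps)
    return(0)                                          # 0/0: no diversity at all
  k * (Ht - Hs) / ((k * Ht - Hs) * (1 - Hs))
}

# per-locus corrected (or raw) within/total heterozygosities for two demes
g2st_locus_components <- function(table, pop_i, pop_j, correction) {
  fi <- allele_frequencies(table, pop_i)
  fj <- allele_frequencies(table, pop_j)
  ni <- attr(fi, "n_copies") / table$ploidy   # observed genotypes per locus
  nj <- attr(fj, "n_copies") / table$ploidy
  idx_i <- which(table$meta$population_id == pop_i)
  idx_j <- which(table$meta$population_id == pop_j)
  rows <- list()
  for (l in seq_along(table$loci)) {
    if (ni[l] == 0 || nj[l] == 0) next
    alleles <- union(names(fi[[l]]), names(fj[[l]]))
    pi <- fi[[l]][alleles]; pi[is.na(pi)] <- 0
    pj <- fj[[l]][alleles]; pj[is.na(pj)] <- 0
    Hs_raw <- 1 - mean(c(sum(pi^2), sum(pj^2)))
    pbar <- (pi + pj) / 2
    Ht_raw <- 1 - sum(pbar^2)
    if (correction == "none") {
      rows[[length(rows) + 1L]] <- data.frame(locus = table$loci[l],
                                              Hs = Hs_raw, Ht = Ht_raw)
      next
    }
    nh <- 2 / (1 / ni[l] + 1 / nj[l])         # harmonic mean sample size
    Ho <- mean(c(locus_ho(table, idx_i, l), locus_ho(table, idx_j, l)))
    Hs <- (nh / (nh - 1)) * (Hs_raw - Ho / (2 * nh))
    Ht <- Ht_raw + Hs / (2 * nh) - Ho / (2 * 2 * nh)
    rows[[length(rows) + 1L]] <- data.frame(locus = table$loci[l], Hs = Hs, Ht = Ht)
  }
  if (!length(rows)) return(data.frame(locus = character(0), Hs = numeric(0),
                                       Ht = numeric(0)))
  do.call(rbind, rows)
}

locus_ho <- function(table, idx, j) {
  g <- table$alleles[idx, locus_cols(table, j), drop = FALSE]
  obs <- !is.na(g[, 1])
  if (!any(obs)) return(NA_real_)
  mean(g[obs, 1] != g[obs, 2])
}

#' Within-window pairwise differentiation table
#'
#' Builds the long-format pairwise table for every within-window population
#' pair: G''ST, DPS, geographic distance and the two pairwise age predictors
#' AGE_BASE (age of the younger population: genetic exchange can only start
#' once the younger member exists) and AGE_DIFF (absolute age difference).
#' Conditional genetic distance and the graph-edge flag are appended later by
#' [add_graph_columns()].
#'
#' @param table a filtered `genotype_table`.
#' @param attrs population attribute data.frame with columns
#'   `population_id`, `window_id`, `age`, `x`, `y`.
#' @return data.frame keyed by (`window_id`, `pop_i`, `pop_j`) with columns
#'   `G2ST`, `DPS`, `GEO_DIST`, `AGE_BASE`, `AGE_DIFF`, `cGD` (NA),
#'   `is_graph_edge` (NA).
#' @export
differentiation_table <- function(table, attrs) {
  rows <- list()
  for (w in unique(table$meta$window_id)) {
    pops <- unique(table$meta$population_id[table$meta$window_id == w])
    if (length(pops) < 2L) next
    freqs <- lapply(stats::setNames(pops, pops),
                    function(p) allele_frequencies(table, p))
    a <- attrs[match(pops, attrs$population_id), ]
    for (i in seq_along(pops)[-length(pops)]) {
      for (j in (i + 1L):length(pops)) {
        rows[[length(rows) + 1L]] <- data.frame(
          window_id = w, pop_i = pops[i], pop_j = pops[j],
          G2ST = pairwise_g2st(table, pops[i], pops[j]),
          DPS = pairwise_dps(freqs[[i]], freqs[[j]]),
          GEO_DIST = sqrt((a$x[i] - a$x[j])^2 + (a$y[i] - a$y[j])^2),
          AGE_BASE = min(a$age[i], a$age[j]),
          AGE_DIFF = abs(a$age[i] - a$age[j]),
          cGD = NA_real_, is_graph_edge = NA,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
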