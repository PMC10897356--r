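# Hand-built genotype tables and independent brute-force oracles used across
# the suite.  Oracles are deliberately naive (enumeration, scalar loops) and
# share no code with the package implementation.

make_table <- function(pop, alleles, window = "W1", loci = NULL,
                       sample_id = NULL, patch = NULL) {
  n <- length(pop)
  if (is.null(loci)) loci <- paste0("L", seq_len(ncol(alleles) / 2))
  meta <- data.frame(
    sample_id = if (is.null(sample_id)) paste0("s", seq_len(n)) else sample_id,
    population_id = pop,
    window_id = if (length(window) == 1L) rep(window, n) else window,
    stringsAsFactors = FALSE)
  if (!is.null(patch)) meta$patch_id <- patch
  genotype_table(meta, alleles, loci)
}

# expected distinct alleles in a subsample of g copies: exhaustive average
# over all C(N, g) subsets
rarefy_oracle <- function(counts, g) {
  copies <- rep(seq_along(counts), counts)
  subsets <- utils::combn(length(copies), g)
  mean(apply(subsets, 2, function(s) length(unique(copies[s]))))
}

# shortest path by exhaustive enumeration of all simple paths
shortest_path_oracle <- function(edges, from, to) {
  nodes <- unique(c(edges$from, edges$to, from, to))
  best <- Inf
  recurse <- function(at, visited, len) {
    if (at == to) { best <<- min(best, len); return(invisible()) }
    for (k in seq_len(nrow(edges))) {
      nxt <- if (edges$from[k] == at) edges$to[k]
             else if (edges$to[k] == at) edges$from[k] else NA
      if (!is.na(nxt) && !(nxt %in% visited))
        recurse(nxt, c(visited, nxt), len + edges$weight[k])
    }
  }
  recurse(from, from, 0)
  if (is.infinite(best)) NA_real_ else best
}

# random genotype table: n_pop populations, n individuals each, no missing
random_table <- function(n_pop = 4, n = 8, n_loci = 3, n_alleles = 4,
                         window = "W1") {
  rows <- n_pop * n
  alleles <- matrix(sample(100 + 2 * seq_len(n_alleles), rows * 2 * n_loci,
                           replace = TRUE), rows, 2 * n_loci)
  make_table(rep(paste0("P", seq_len(n_pop)), each = n), alleles,
             window = window)
}

# G''ST oracle: literal transcription of the two-deme estimator, scalar
# arithmetic on explicit genotype lists (list of c(a1, a2) per individual)
g2st_oracle <- function(geno_i, geno_j) {
  n_loci <- length(geno_i[[1]]) / 2
  Hs_l <- Ht_l <- numeric(n_loci)
  for (l in seq_len(n_loci)) {
    gi <- t(sapply(geno_i, function(g) g[(2 * l - 1):(2 * l)]))
    gj <- t(sapply(geno_j, function(g) g[(2 * l - 1):(2 * l)]))
    gi <- gi[!is.na(gi[, 1]), , drop = FALSE]
    gj <- gj[!is.na(gj[, 1]), , drop = FALSE]
    ni <- nrow(gi); nj <- nrow(gj)
    all_a <- sort(unique(c(gi, gj)))
    pi <- sapply(all_a, function(a) sum(gi == a) / (2 * ni))
    pj <- sapply(all_a, function(a) sum(gj == a) / (2 * nj))
    Ho <- (mean(gi[, 1] != gi[, 2]) + mean(gj[, 1] != gj[, 2])) / 2
    nh <- 2 / (1 / ni + 1 / nj)
    Hs_raw <- 1 - (sum(pi^2) + sum(pj^2)) / 2
    Hs <- nh / (nh - 1) * (Hs_raw - Ho / (2 * nh))
    pbar <- (pi + pj) / 2
    # k = 2 demes: Ht = Ht_raw + Hs/(k*nh) - Ho/(2*k*nh)
    Ht <- (1 - sum(pbar^2)) + Hs / (2 * nh) - Ho / (4 * nh)
    Hs_l[l] <- Hs; Ht_l[l] <- Ht
  }
  Hs <- mean(Hs_l); Ht <- mean(Ht_l)
  2 * (Ht - Hs) / ((2 * Ht - Hs) * (1 - Hs))
}
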