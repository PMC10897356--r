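#' Encode individuals as allele-dosage vectors
#'
#' Each individual in a landscape window becomes a numeric vector with one
#' column per distinct allele observed in the window (per locus), holding the
#' allele's dosage in that individual: 0, 0.5 or 1 (each gene copy
#' contributes 0.5).  Missing loci are imputed with the within-population
#' mean dosage for that locus, which leaves the population centroid — the
#' quantity that drives the among-population covariance — unchanged; this is
#' how the graph machinery tolerates missing genotypes.  If a locus is
#' missing for an entire population it is imputed with the window-wide mean,
#' with a warning.
#'
#' @param table a filtered `genotype_table`.
#' @param window window id.
#' @return numeric matrix, rows = individuals (rownames = sample ids),
#'   columns = `<locus>:<allele>`; attribute `population` gives each row's
#'   population id.
#' @export
encode_individuals <- function(table, window) {
  idx <- which(table$meta$window_id == window)
  if (!length(idx)) stop("no samples in window ", window)
  pops <- table$meta$population_id[idx]
  blocks <- list()
  for (j in seq_along(table$loci)) {
    g <- table$alleles[idx, locus_cols(table, j), drop = FALSE]
    alleles <- sort(unique(as.vector(g[!is.na(g)])))
    if (!length(alleles)) next
    m <- matrix(0, length(idx), length(alleles),
                dimnames = list(NULL, paste0(table$loci[j], ":", alleles)))
    for (k in seq_along(alleles)) {
      m[, k] <- 0.5 * ((!is.na(g[, 1]) & g[, 1] == alleles[k]) +
                       (!is.na(g[, 2]) & g[, 2] == alleles[k]))
    }
    miss <- is.na(g[, 1])
    if (any(miss)) {
      for (p in unique(pops[miss])) {
        p_rows <- pops == p
        donor <- p_rows & !miss
        if (any(donor)) {
          fill <- colMeans(m[donor, , drop = FALSE])
        } else {
          warning("locus '", table$loci[j], "' missing for all of population ",
                  p, "; imputed with window-wide mean")
          fill <- colMeans(m[!miss, , drop = FALSE])
        }
        m[p_rows & miss, ] <- rep(fill, each = sum(p_rows & miss))
      }
    }
    blocks[[length(blocks) + 1L]] <- m
  }
  out <- do.call(cbind, blocks)
  rownames(out) <- table$meta$sample_id[idx]
  attr(out, "population") <- pops
  out
}

#' Among-population genetic covariance
#'
#' Squared Euclidean distances among population centroid vectors are
#' double-centered (\eqn{C = -\frac12 H D^2 H}, H the centering matrix) to
#' give the among-population covariance matrix.  By construction C has the
#' constant vector in its null space (the centering direction); the pruning
#' step inverts C on the orthogonal complement.  Populations with identical
#' centroids make C rank-deficient beyond that structural direction; pass a
#' small `ridge` to regularize (added to the diagonal, with a warning).
#'
#' @param encoded matrix from [encode_individuals()].
#' @param ridge optional non-negative ridge added to diag(C).
#' @return covariance matrix with population ids as dimnames.
#' @export
population_covariance <- function(encoded, ridge = 0) {
  pops <- attr(encoded, "population")
  ids <- unique(pops)
  if (length(ids) < 3L) stop("need >= 3 populations in the window")
  centroids <- t(vapply(ids, function(p)
    colMeans(encoded[pops == p, , drop = FALSE]), numeric(ncol(encoded))))
  D2 <- as.matrix(stats::dist(centroids))^2
  n <- nrow(D2)
  H <- diag(n) - matrix(1 / n, n, n)
  C <- -0.5 * H %*% D2 %*% H
  if (ridge > 0) {
    warning("ridge ", ridge, " added to the covariance diagonal")
    C <- C + diag(ridge, n)
  }
  dimnames(C) <- list(ids, ids)
  C
}

# invert C on the complement of its structural (centering) null direction;
# error if additional near-null directions exist (duplicate populations)
precision_matrix <- function(C, tol = 1e-9) {
  e <- eigen((C + t(C)) / 2, symmetric = TRUE)
  scale <- max(abs(e$values))
  null_idx <- which(abs(e$values) < tol * scale)
  if (length(null_idx) > 1L)
    stop("covariance matrix is rank-deficient beyond the centering direction ",
         "(duplicate populations?); rebuild with population_covariance(..., ridge = )")
  keep <- setdiff(seq_along(e$values), null_idx)
  e$vectors[, keep, drop = FALSE] %*%
    diag(1 / e$values[keep], length(keep)) %*%
    t(e$vectors[, keep, drop = FALSE])
}

#' Prune a saturated population graph by edge-exclusion deviance
#'
#' Treats the among-population covariance as a Gaussian graphical model:
#' the precision matrix gives partial correlations
#' \eqn{r_{ij} = -\Omega_{ij}/\sqrt{\Omega_{ii}\Omega_{jj}}}, and each edge's
#' exclusion deviance \eqn{EED_{ij} = -n \log(1 - r_{ij}^2)} is compared with
#' the \eqn{\chi^2_1} quantile at `alpha`.  Edges whose removal does not
#' significantly worsen the model fit carry no unique information about the
#' covariance structure and are pruned.  Retained edges are weighted by the
#' covariance-derived genetic distance
#' \eqn{d_{ij} = \sqrt{C_{ii} + C_{jj} - 2 C_{ij}}}.
#'
#' @param C covariance matrix from [population_covariance()] (or any
#'   symmetric positive (semi)definite matrix with dimnames).
#' @param n_individuals sample size n entering the deviance (total
#'   individuals in the window after filtering).
#' @param alpha pruning significance level (default 0.05).
#' @return a `population_graph`: list with `nodes`, `edges` (data.frame
#'   `from`, `to`, `weight`, `eed`, `partial_r`), the `igraph` object, and a
#'   `report` (class `graph_build_report`) with saturated/retained counts and
#'   every edge's EED decision.
#' @export
prune_edges <- function(C, n_individuals, alpha = 0.05) {
  if (is.null(dimnames(C))) dimnames(C) <- list(seq_len(nrow(C)), seq_len(nrow(C)))
  ids <- rownames(C)
  n_pop <- nrow(C)
  Omega <- if (n_pop == 2L) NULL else precision_matrix(C)
  crit <- stats::qchisq(1 - alpha, df = 1)
  rows <- list()
  for (i in seq_len(n_pop - 1L)) {
    for (j in (i + 1L):n_pop) {
      if (is.null(Omega)) {
        # 2 nodes: no conditioning set, EED tests the simple correlation
        r <- C[1, 2] / sqrt(C[1, 1] * C[2, 2])
      } else {
        r <- -Omega[i, j] / sqrt(Omega[i, i] * Omega[j, j])
      }
      r <- max(min(r, 1 - 1e-12), -1 + 1e-12)
      eed <- -n_individuals * log(1 - r^2)
      rows[[length(rows) + 1L]] <- data.frame(
        from = ids[i], to = ids[j], partial_r = r, eed = eed,
        weight = sqrt(C[i, i] + C[j, j] - 2 * C[i, j]),
        retained = eed > crit, stringsAsFactors = FALSE)
    }
  }
  all_edges <- do.call(rbind, rows)
  edges <- all_edges[all_edges$retained, c("from", "to", "weight", "eed", "partial_r")]
  rownames(edges) <- NULL
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = ids))
  report <- structure(list(n_edges_saturated = nrow(all_edges),
                           n_edges_retained = nrow(edges),
                           pruning_alpha = alpha,
                           edge_tests = all_edges),
                      class = "graph_build_report")
  structure(list(nodes = ids, edges = edges, igraph = g, report = report),
            class = "population_graph")
}

#' @method print population_graph
#' @export
print.population_graph <- function(x, ...) {
  cat("population_graph:", length(x$nodes), "nodes,", nrow(x$edges),
      "of", x$report$n_edges_saturated, "edges retained (alpha =",
      x$report$pruning_alpha, ")\n")
  invisible(x)
}

#' Build a population graph for one window
#'
#' Convenience wrapper: encode, covariance, prune.
#'
#' @inheritParams encode_individuals
#' @param alpha pruning significance level.
#' @param ridge optional covariance ridge.
#' @return a `population_graph`.
#' @export
build_population_graph <- function(table, window, alpha = 0.05, ridge = 0) {
  enc <- encode_individuals(table, window)
  C <- population_covariance(enc, ridge = ridge)
  prune_edges(C, n_individuals = nrow(enc), alpha = alpha)
}

#' Conditional genetic distance through the population graph
#'
#' Shortest-path (Dijkstra) sum of edge weights between two populations.
#' Pairs in different graph components get `NA` (their conditional genetic
#' distance is undefined, not infinite-as-a-number).
#'
#' @param graph a `population_graph`.
#' @param pop_i,pop_j node ids.
#' @return numeric cGD, or `NA` if unreachable.
#' @export
conditional_genetic_distance <- function(graph, pop_i, pop_j) {
  if (!all(c(pop_i, pop_j) %in% graph$nodes))
    stop("unknown node: ", paste(setdiff(c(pop_i, pop_j), graph$nodes), collapse = ", "))
  d <- igraph::distances(graph$igraph, v = pop_i, to = pop_j, weights = NULL,
                         algorithm = "dijkstra")[1, 1]
  if (is.infinite(d)) NA_real_ else d
}

# full cGD matrix (NA for unreachable pairs)
cgd_matrix <- function(graph) {
  d <- igraph::distances(graph$igraph, weights = NULL, algorithm = "dijkstra")
  d[is.infinite(d)] <- NA_real_
  d[graph$nodes, graph$nodes, drop = FALSE]
}

#' Normalized harmonic centrality
#'
#' Pairwise conditional genetic distances are standardized by the minimum
#' positive distance in the graph (so they lie in \[1, Inf)), and each node's
#' centrality is \eqn{NHc(i) = (1/n) \sum_{j \ne i} 1/\tilde d(i,j)}, with
#' unreachable nodes contributing 0.  Division by the node count n makes
#' centralities comparable among graphs of different size; values near zero
#' mark highly isolated populations.
#'
#' @param graph a `population_graph`.
#' @param divide_by `"n"` (default, node count) or `"n_minus_1"`.
#' @return named numeric vector of NHc per node.
#' @export
normalized_harmonic_centrality <- function(graph, divide_by = c("n", "n_minus_1")) {
  divide_by <- match.arg(divide_by)
  n <- length(graph$nodes)
  if (n == 1L) return(stats::setNames(0, graph$nodes))
  d <- cgd_matrix(graph)
  pos <- d[upper.tri(d)]
  pos <- pos[!is.na(pos) & pos > 0]
  if (length(pos)) d <- d / min(pos)
  inv <- 1 / d
  inv[is.na(inv)] <- 0
  diag(inv) <- 0
  denom <- if (divide_by == "n") n else n - 1L
  rowSums(inv) / denom
}

#' Genetic-versus-geographic edge imbalance (DIFF_GEN_GEO)
#'
#' For each retained edge, the edge's share of total conditional genetic
#' distance minus its share of total geographic distance,
#' \eqn{DIFF_i = cGD_i/\sum cGD - geo_i/\sum geo}, sums taken over retained
#' edges only.  Positive values flag pairs genetically farther apart than
#' their geography would suggest; the values sum to zero over the graph.
#'
#' @param graph a `population_graph`.
#' @param attrs population attribute data.frame with `population_id`, `x`,
#'   `y` covering all nodes.
#' @return data.frame `from`, `to`, `cGD`, `geo`, `DIFF_GEN_GEO`.
#' @export
diff_gen_geo <- function(graph, attrs) {
  e <- graph$edges
  if (!nrow(e)) stop("graph has no retained edges")
  miss <- setdiff(unique(c(e$from, e$to)), attrs$population_id)
  if (length(miss)) stop("coordinates missing for node(s): ",
                         paste(miss, collapse = ", "))
  xi <- attrs$x[match(e$from, attrs$population_id)]
  yi <- attrs$y[match(e$from, attrs$population_id)]
  xj <- attrs$x[match(e$to, attrs$population_id)]
  yj <- attrs$y[match(e$to, attrs$population_id)]
  geo <- sqrt((xi - xj)^2 + (yi - yj)^2)
  if (sum(e$weight) <= 0 || sum(geo) <= 0)
    stop("zero total distance over retained edges")
  data.frame(from = e$from, to = e$to, cGD = e$weight, geo = geo,
             DIFF_GEN_GEO = e$weight / sum(e$weight) - geo / sum(geo),
             stringsAsFactors = FALSE)
}

#' Attach graph-derived columns to a pairwise table
#'
#' Fills `cGD` (shortest-path distance) and `is_graph_edge` for every pair
#' in one window's rows of a [differentiation_table()].
#'
#' @param pairs pairwise data.frame (rows of one or more windows).
#' @param graphs named list of `population_graph` objects keyed by window id.
#' @return `pairs` with `cGD` and `is_graph_edge` filled.
#' @export
add_graph_columns <- function(pairs, graphs) {
  for (k in seq_len(nrow(pairs))) {
    g <- graphs[[pairs$window_id[k]]]
    if (is.null(g)) next
    if (!all(c(pairs$pop_i[k], pairs$pop_j[k]) %in% g$nodes)) next
    pairs$cGD[k] <- conditional_genetic_distance(g, pairs$pop_i[k], pairs$pop_j[k])
    pairs$is_graph_edge[k] <- any((g$edges$from == pairs$pop_i[k] & g$edges$to == pairs$pop_j[k]) |
                                  (g$edges$from == pairs$pop_j[k] & g$edges$to == pairs$pop_i[k]))
  }
  pairs
}

#' Serialize a population graph
#'
#' GraphML (via igraph) with node attributes (NHc plus any supplied
#' attribute columns) and edge attributes (weight, EED); or an edge-list
#' CSV.
#'
#' @param graph a `population_graph`.
#' @param path output file.
#' @param format `"graphml"` or `"edgelist"`.
#' @param attrs optional population attribute data.frame; `age` and `size`
#'   are attached to nodes when present.
#' @return `path`, invisibly.
#' @export
write_population_graph <- function(graph, path, format = c("graphml", "edgelist"),
                                   attrs = NULL) {
  format <- match.arg(format)
  if (format == "edgelist") {
    utils::write.csv(graph$edges, path, row.names = FALSE)
    return(invisible(path))
  }
  g <- graph$igraph
  nhc <- normalized_harmonic_centrality(graph)
  g <- igraph::set_vertex_attr(g, "NHc", value = as.numeric(nhc[igraph::V(g)$name]))
  if (!is.null(attrs)) {
    m <- match(igraph::V(g)$name, attrs$population_id)
    if ("age" %in% names(attrs))
      g <- igraph::set_vertex_attr(g, "age", value = attrs$age[m])
    if ("size" %in% names(attrs))
      g <- igraph::set_vertex_attr(g, "size", value = attrs$size[m])
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
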