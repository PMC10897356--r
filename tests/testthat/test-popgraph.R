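test_that("dosage encoding is 0/0.5/1 and imputes missing with the population mean", {
  al <- matrix(c(100L, 102L,     # heterozygote -> (0.5, 0.5)
                 100L, 100L,     # homozygote  -> (1, 0)
                 NA,   NA), 3, 2, byrow = TRUE)
  tab <- make_table(rep("P1", 3), al)
  enc <- encode_individuals(tab, "W1")
  expect_equal(unname(enc[1, ]), c(0.5, 0.5))
  expect_equal(unname(enc[2, ]), c(1, 0))
  expect_equal(unname(enc[3, ]), c(0.75, 0.25))  # mean of the observed rows
  expect_equal(colnames(enc), c("L1:100", "L1:102"))
})

test_that("encoding with no missing data is unaffected by the imputation path", {
  set.seed(14)
  tab <- random_table(n_pop = 4, n = 6)
  enc <- encode_individuals(tab, "W1")
  expect_false(anyNA(enc))
  expect_equal(unname(rowSums(enc)), rep(length(tab$loci), n_samples(tab)))
  # covariance from complete data equals covariance after a no-op imputation
  expect_equal(population_covariance(enc), population_covariance(enc))
})

test_that("population covariance matches brute-force double-centering", {
  set.seed(15)
  tab <- random_table(n_pop = 4, n = 6)
  enc <- encode_individuals(tab, "W1")
  C <- population_covariance(enc)
  pops <- attr(enc, "population")
  mu <- t(sapply(unique(pops), function(p) colMeans(enc[pops == p, , drop = FALSE])))
  D2 <- outer(1:4, 1:4, Vectorize(function(i, j) sum((mu[i, ] - mu[j, ])^2)))
  H <- diag(4) - 1 / 4
  expect_equal(unname(C), unname(-0.5 * H %*% D2 %*% H), tolerance = 1e-12)
  # three equidistant populations: equal diagonal, equal off-diagonal
  mu3 <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
  D2e <- as.matrix(dist(mu3))^2
  H3 <- diag(3) - 1 / 3
  Ce <- -0.5 * H3 %*% D2e %*% H3
  expect_equal(diag(Ce), rep(diag(Ce)[1], 3))
  off <- Ce[upper.tri(Ce)]
  expect_equal(off, rep(off[1], 3))
})

test_that("edge-exclusion pruning removes conditionally independent pairs", {
  # chain precision A-B-C: A and C conditionally independent given B
  Omega <- rbind(c(2, -0.9, 0), c(-0.9, 2, -0.9), c(0, -0.9, 2))
  C <- solve(Omega)
  dimnames(C) <- list(c("A", "B", "C"), c("A", "B", "C"))
  g <- prune_edges(C, n_individuals = 60)
  keys <- paste(g$edges$from, g$edges$to)
  expect_true(all(c("A B", "B C") %in% keys))
  expect_false("A C" %in% keys)
  expect_equal(g$report$n_edges_saturated, 3)
  # zero partial correlation -> EED 0 -> pruned
  ac <- g$report$edge_tests
  expect_lt(ac$eed[ac$from == "A" & ac$to == "C"], 1e-6)
  # 4-node chain recovered from its covariance
  O4 <- diag(2, 4); O4[cbind(1:3, 2:4)] <- -0.9; O4[cbind(2:4, 1:3)] <- -0.9
  C4 <- solve(O4); dimnames(C4) <- list(LETTERS[1:4], LETTERS[1:4])
  g4 <- prune_edges(C4, n_individuals = 100)
  expect_equal(sort(paste(g4$edges$from, g4$edges$to)), c("A B", "B C", "C D"))
})

test_that("two-node graphs test the simple correlation and alpha -> 1 keeps all edges", {
  C2 <- rbind(c(1, 0.8), c(0.8, 1)); dimnames(C2) <- list(c("A", "B"), c("A", "B"))
  g2 <- prune_edges(C2, n_individuals = 20)
  expect_equal(nrow(g2$edges), 1)
  expect_equal(g2$edges$partial_r, 0.8)
  # saturated limit: every edge retained and cGD <= direct distance
  set.seed(16)
  tab <- random_table(n_pop = 5, n = 8)
  g <- build_population_graph(tab, "W1", alpha = 0.999999)
  expect_equal(nrow(g$edges), choose(5, 2))
  for (k in seq_len(nrow(g$edges)))
    expect_lte(conditional_genetic_distance(g, g$edges$from[k], g$edges$to[k]),
               g$edges$weight[k] + 1e-12)
})

test_that("cGD is the shortest path and matches exhaustive enumeration", {
  mk_graph <- function(edges, nodes) {
    ig <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                        vertices = data.frame(name = nodes))
    structure(list(nodes = nodes, edges = edges, igraph = ig,
                   report = list(n_edges_saturated = nrow(edges),
                                 pruning_alpha = NA)),
              class = "population_graph")
  }
  toy <- mk_graph(data.frame(from = c("A", "B", "A"), to = c("B", "C", "C"),
                             weight = c(2, 3, 6)), c("A", "B", "C"))
  expect_equal(conditional_genetic_distance(toy, "A", "C"), 5)
  expect_equal(conditional_genetic_distance(toy, "A", "B"), 2)
  expect_error(conditional_genetic_distance(toy, "A", "Z"), "unknown node")
  # random graphs up to 9 nodes vs brute-force path enumeration
  set.seed(17)
  for (rep in 1:6) {
    n <- sample(5:9, 1)
    nodes <- LETTERS[1:n]
    all_pairs <- t(utils::combn(nodes, 2))
    keep <- runif(nrow(all_pairs)) < 0.45
    if (!any(keep)) keep[1] <- TRUE
    edges <- data.frame(from = all_pairs[keep, 1], to = all_pairs[keep, 2],
                        weight = round(runif(sum(keep), 0.5, 5), 2),
                        stringsAsFactors = FALSE)
    g <- mk_graph(edges, nodes)
    for (q in 1:5) {
      pr <- sample(nodes, 2)
      expect_equal(conditional_genetic_distance(g, pr[1], pr[2]),
                   shortest_path_oracle(edges, pr[1], pr[2]))
    }
  }
})

test_that("normalized harmonic centrality matches hand computations", {
  mk_graph <- function(edges, nodes) {
    ig <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                        vertices = data.frame(name = nodes))
    structure(list(nodes = nodes, edges = edges, igraph = ig,
                   report = list()), class = "population_graph")
  }
  # equal-weight triangle: standardized distances all 1 -> NHc = 2/3 each
  tri <- mk_graph(data.frame(from = c("A", "B", "A"), to = c("B", "C", "C"),
                             weight = c(1, 1, 1)), c("A", "B", "C"))
  expect_equal(unname(normalized_harmonic_centrality(tri)), rep(2 / 3, 3))
  # path A-B-C equal weights: NHc(B) = 2/3, ends 1/2
  path <- mk_graph(data.frame(from = c("A", "B"), to = c("B", "C"),
                              weight = c(4, 4)), c("A", "B", "C"))
  nhc <- normalized_harmonic_centrality(path)
  expect_equal(unname(nhc[c("A", "B", "C")]), c(1 / 2, 2 / 3, 1 / 2))
  # isolated node contributes/receives zero
  iso <- mk_graph(data.frame(from = "A", to = "B", weight = c(2)),
                  c("A", "B", "Z"))
  expect_equal(unname(normalized_harmonic_centrality(iso)["Z"]), 0)
  # n vs n-1 normalization option
  expect_equal(unname(normalized_harmonic_centrality(path, "n_minus_1")["B"]), 1)
})

test_that("DIFF_GEN_GEO is the difference of distance shares and sums to zero", {
  mk_graph <- function(edges, nodes) {
    ig <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                        vertices = data.frame(name = nodes))
    structure(list(nodes = nodes, edges = edges, igraph = ig,
                   report = list()), class = "population_graph")
  }
  g <- mk_graph(data.frame(from = c("A", "B"), to = c("B", "C"),
                           weight = c(2, 2)), c("A", "B", "C"))
  attrs <- data.frame(population_id = c("A", "B", "C"),
                      x = c(0, 1, 1), y = c(0, 0, 3))
  d <- diff_gen_geo(g, attrs)      # geo = (1, 3), cGD = (2, 2)
  expect_equal(d$DIFF_GEN_GEO, c(0.25, -0.25))
  expect_equal(sum(d$DIFF_GEN_GEO), 0)
  # equal shares everywhere -> all zero
  attrs2 <- data.frame(population_id = c("A", "B", "C"),
                       x = c(0, 1, 2), y = c(0, 0, 0))
  expect_equal(diff_gen_geo(g, attrs2)$DIFF_GEN_GEO, c(0, 0))
  # property: the sum is zero on random graphs
  set.seed(18)
  tab <- random_table(n_pop = 5, n = 8)
  gg <- build_population_graph(tab, "W1", alpha = 0.5)
  attrs3 <- data.frame(population_id = gg$nodes,
                       x = runif(5, 0, 5000), y = runif(5, 0, 5000))
  expect_equal(sum(diff_gen_geo(gg, attrs3)$DIFF_GEN_GEO), 0, tolerance = 1e-12)
})

test_that("duplicate populations are caught and the ridge option recovers", {
  set.seed(19)
  tab <- random_table(n_pop = 3, n = 6)
  # append an exact copy of P1 as P4
  idx <- which(tab$meta$population_id == "P1")
  meta2 <- rbind(tab$meta, transform(tab$meta[idx, ],
                                     population_id = "P4",
                                     sample_id = paste0("dup", seq_along(idx))))
  tab2 <- genotype_table(meta2, rbind(tab$alleles, tab$alleles[idx, ]), tab$loci)
  enc <- encode_individuals(tab2, "W1")
  C <- population_covariance(enc)
  expect_error(prune_edges(C, 24), "rank-deficient")
  expect_warning(Cr <- population_covariance(enc, ridge = 1e-4), "ridge")
  expect_s3_class(prune_edges(Cr, 24), "population_graph")
})

test_that("graphs serialize to GraphML and edge-list CSV", {
  set.seed(20)
  tab <- random_table(n_pop = 4, n = 8)
  g <- build_population_graph(tab, "W1", alpha = 0.9)
  gml <- tempfile(fileext = ".graphml")
  write_population_graph(g, gml,
                         attrs = data.frame(population_id = g$nodes,
                                            age = c(10, 20, 30, 40),
                                            size = c(5, 6, 7, 8)))
  reread <- igraph::read_graph(gml, format = "graphml")
  expect_equal(sort(igraph::V(reread)$name), sort(g$nodes))
  expect_equal(igraph::ecount(reread), nrow(g$edges))
  csv <- tempfile(fileext = ".csv")
  write_population_graph(g, csv, format = "edgelist")
  expect_equal(nrow(utils::read.csv(csv)), nrow(g$edges))
})
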