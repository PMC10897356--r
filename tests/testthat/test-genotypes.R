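test_that("tabular and GenePop dialects parse to the same table, with missing normalized", {
  csv <- tempfile(fileext = ".csv")
  writeLines(c("sample_id,window,population,patch,L1_a,L1_b,L2_a,L2_b",
               "s1,W1,P1,F1,100,102,110,110",
               "s2,W1,P1,F1,0,0,110,112"), csv)
  tab <- read_allele_table(csv)
  expect_equal(length(tab$loci), 2)
  expect_equal(sum(is.na(tab$alleles)), 2)        # one fully-missing locus call
  expect_true(is.na(tab$alleles[2, 1]) && is.na(tab$alleles[2, 2]))

  gen <- tempfile(fileext = ".gen")
  writeLines(c("toy", "L1", "L2", "POP",
               "W1:P1_s1 , 100102 110110",
               "W1:P1_s2 , 000000 110112"), gen)
  tab2 <- read_allele_table(gen)
  expect_equal(tab2$meta$sample_id, tab$meta$sample_id)
  expect_equal(tab2$meta$population_id, tab$meta$population_id)
  expect_equal(unname(tab2$alleles), unname(tab$alleles))
})

test_that("parse-time validation rejects malformed input", {
  csv <- tempfile(fileext = ".csv")
  writeLines(c("sample_id,window,population,L1_a,L1_b",
               "s1,W1,P1,100,102", "s1,W1,P1,100,102"), csv)
  expect_error(read_allele_table(csv), "duplicate sample_id")
  # half-called genotypes are rejected, naming the sample
  expect_error(make_table(c("P1"), matrix(c(100L, NA), 1, 2)), "half-called")
  expect_error(read_allele_table(tempfile(), format = "tabular"), "not found")
})

test_that("missingness filter drops >=2 missing loci and keeps 0 or 1", {
  al <- matrix(100L, 3, 12)                        # 6 loci
  al[2, 1:2] <- NA                                 # one missing locus: keep
  al[3, 1:4] <- NA                                 # two missing loci: drop
  tab <- make_table(rep("P1", 3), al)
  res <- filter_by_missingness(tab)
  expect_equal(res$table$meta$sample_id, c("s1", "s2"))
  expect_equal(res$report$n_dropped_missingness, 1)
  # fully observed table passes untouched
  full <- make_table(rep("P1", 3), matrix(100L, 3, 12))
  expect_equal(n_samples(filter_by_missingness(full)$table), 3)
})

test_that("clone collapsing works within, never across, populations", {
  al <- matrix(c(100L, 102L, 110L, 112L), 6, 4, byrow = TRUE)
  tab <- make_table(c("P1", "P1", "P1", "P2", "P2", "P2"), al)
  # P1: 3 identical MLGs -> 1 kept; P2 identical to P1's MLG but kept separately
  al2 <- al; al2[5, 1] <- 104L; al2[6, 1] <- 106L
  tab <- make_table(c("P1", "P1", "P1", "P2", "P2", "P2"), al2)
  res <- collapse_clones(tab)
  expect_equal(res$report$n_clones_removed, 2)
  expect_true(all(c("P1", "P2") %in% populations(res$table)))
  # identical MLG in two different populations: both retained
  both <- make_table(c("P1", "P2"), matrix(c(100L, 102L), 2, 2, byrow = TRUE))
  expect_equal(n_samples(collapse_clones(both)$table), 2)
  # all-unique population is untouched
  uniq <- make_table(rep("P1", 3),
                     matrix(c(100L, 100L, 102L, 102L, 104L, 104L), 3, 2, byrow = TRUE))
  expect_equal(n_samples(collapse_clones(uniq)$table), 3)
})

test_that("differing missingness patterns block clone matching unless wildcarded", {
  al <- matrix(c(100L, 102L, 110L, 112L,
                 100L, 102L, NA,   NA), 2, 4, byrow = TRUE)
  tab <- make_table(c("P1", "P1"), al)
  expect_equal(n_samples(collapse_clones(tab)$table), 2)
  expect_equal(n_samples(collapse_clones(tab, wildcard_missing = TRUE)$table), 1)
})

test_that("small populations are dropped at the <4 MLG boundary", {
  al <- matrix(sample.int(20, 7 * 4 * 2, replace = TRUE) + 99L, 7, 8)
  tab <- make_table(c(rep("P1", 4), rep("P2", 3)), al)
  res <- drop_small_populations(tab)
  expect_equal(populations(res$table), "P1")       # 4 kept, 3 dropped
  expect_equal(res$report$populations_dropped, "P2")
  expect_equal(populations(drop_small_populations(tab, min_mlg = 1)$table),
               c("P1", "P2"))
  expect_error(drop_small_populations(tab, min_mlg = 100), "empty study")
})

test_that("filter chain is idempotent and conserves sample counts", {
  set.seed(11)
  tab <- random_table(n_pop = 5, n = 10)
  tab$alleles[sample(length(tab$alleles), 40)] <- NA
  # re-impose the whole-locus missingness contract
  for (j in seq_along(tab$loci)) {
    cols <- (j - 1) * 2 + 1:2
    na <- is.na(tab$alleles[, cols[1]]) | is.na(tab$alleles[, cols[2]])
    tab$alleles[na, cols] <- NA
  }
  tab <- genotype_table(tab$meta, tab$alleles, tab$loci)
  once <- apply_qc_filters(tab)
  twice <- apply_qc_filters(once$table)
  expect_equal(twice$table$meta, once$table$meta)
  expect_equal(twice$table$alleles, once$table$alleles)
  r <- once$reports
  expect_equal(r$missingness$n_in - r$missingness$n_dropped_missingness,
               r$missingness$n_out)
  expect_equal(r$clones$n_in - r$clones$n_clones_removed, r$clones$n_out)
})

test_that("allele frequencies count observed gene copies only and sum to 1", {
  al <- matrix(c(100L, 100L, 110L, 112L,
                 100L, 102L, NA,   NA), 2, 4, byrow = TRUE)
  tab <- make_table(c("P1", "P1"), al)
  f <- allele_frequencies(tab, "P1")
  expect_equal(unname(f$L1[c("100", "102")]), c(0.75, 0.25))
  expect_equal(unname(attr(f, "n_copies")), c(4L, 2L))     # missing-aware denominator
  expect_equal(sum(f$L2), 1)
  expect_error(allele_frequencies(tab, "nope"), "unknown population")
  # monomorphic locus: single frequency 1
  mono <- make_table("P1", matrix(c(100L, 100L), 1, 2))
  expect_equal(unname(allele_frequencies(mono, "P1")$L1), 1)
  # property: per-locus sums are 1 wherever copies were observed
  set.seed(4)
  rt <- random_table()
  for (p in populations(rt)) {
    fr <- allele_frequencies(rt, p)
    expect_true(all(abs(vapply(fr, sum, numeric(1)) - 1) < 1e-12))
  }
})
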