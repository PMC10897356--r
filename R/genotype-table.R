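#' Construct a genotype table
#'
#' The canonical container for per-individual microsatellite genotypes.
#' Each sample belongs to exactly one population inside one landscape window;
#' each locus holds `ploidy` allele slots per sample (two for diploid-coded
#' data, which is also how tetraploid taxa are scored in practice when the
#' marker panel is read as co-dominant two-allele calls).  A locus is either
#' fully observed or fully missing for a sample: half-called genotypes are
#' rejected at construction.
#'
#' @param meta data.frame with columns `sample_id`, `population_id`,
#'   `window_id` and optionally `patch_id`.
#' @param alleles integer matrix, one row per sample and `ploidy` columns per
#'   locus named `<locus>.1`, `<locus>.2`, ...  Missing calls are `NA`
#'   (the single internal missing sentinel; dialect spellings such as "0",
#'   blank or "NA" are normalized by [read_allele_table()]).
#' @param loci character vector of locus names, in column order.
#' @param ploidy allele slots per locus per sample (default 2).
#'
#' @return An object of class `genotype_table`: a list with elements `meta`,
#'   `alleles`, `loci`, `ploidy`.
#' @export
genotype_table <- function(meta, alleles, loci, ploidy = 2L) {
  stopifnot(is.data.frame(meta), is.matrix(alleles))
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  required <- c("sample_id", "population_id", "window_id")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols))
    stop("meta lacks required column(s): ", paste(missing_cols, collapse = ", "))
  if (!"patch_id" %in% names(meta)) meta$patch_id <- meta$population_id
  if (anyDuplicated(meta$sample_id))
    stop("duplicate sample_id: ",
         paste(unique(meta$sample_id[duplicated(meta$sample_id)]), collapse = ", "))
  if (nrow(meta) != nrow(alleles))
    stop("meta and alleles disagree on sample count")
  loci <- as.character(loci)
  expected_cols <- as.vector(t(outer(loci, seq_len(ploidy),
                                     function(l, k) paste0(l, ".", k))))
  if (ncol(alleles) != length(expected_cols))
    stop("alleles must have ploidy * n_loci = ", length(expected_cols), " columns")
  colnames(alleles) <- expected_cols
  storage.mode(alleles) <- "integer"
  bad <- which(!is.na(alleles) & alleles <= 0L)
  if (length(bad))
    stop("allele values must be positive integers (fragment lengths) or NA")
  # a locus must be fully observed or fully missing per sample
  for (j in seq_along(loci)) {
    block <- alleles[, (j - 1L) * ploidy + seq_len(ploidy), drop = FALSE]
    n_na <- rowSums(is.na(block))
    half <- which(n_na > 0L & n_na < ploidy)
    if (length(half))
      stop("half-called genotype at locus '", loci[j], "' for sample(s): ",
           paste(meta$sample_id[half], collapse = ", "))
  }
  structure(list(meta = meta, alleles = alleles, loci = loci,
                 ploidy = as.integer(ploidy)),
            class = "genotype_table")
}

#' @method print genotype_table
#' @export
print.genotype_table <- function(x, ...) {
  cat("genotype_table:", nrow(x$meta), "samples,", length(x$loci), "loci,",
      length(unique(x$meta$population_id)), "populations,",
      length(unique(x$meta$window_id)), "windows\n")
  miss <- mean(is.na(x$alleles))
  cat(sprintf("  missing allele calls: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' Number of samples in a genotype table
#' @param table a `genotype_table`.
#' @return integer sample count.
#' @export
n_samples <- function(table) nrow(table$meta)

#' Populations present in a genotype table
#' @param table a `genotype_table`.
#' @return character vector of population ids.
#' @export
populations <- function(table) unique(table$meta$population_id)

#' Subset a genotype table by sample index
#' @keywords internal
subset_samples <- function(table, idx) {
  genotype_table(table$meta[idx, , drop = FALSE],
                 table$alleles[idx, , drop = FALSE],
                 table$loci, table$ploidy)
}

# columns of the allele matrix belonging to locus j
locus_cols <- function(table, j) (j - 1L) * table$ploidy + seq_len(table$ploidy)

# per-sample count of missing loci
missing_loci_per_sample <- function(table) {
  p <- table$ploidy
  miss <- is.na(table$alleles)
  sapply(seq_along(table$loci), function(j) miss[, (j - 1L) * p + 1L])
}

#' Allele frequencies within one population
#'
#' Frequencies are computed over observed gene copies only: a sample missing
#' at a locus contributes nothing to that locus's denominator.  Loci with no
#' observed copies in the population come back as empty numeric vectors and
#' are reported in the `zero_copy_loci` attribute.
#'
#' @param table a `genotype_table`.
#' @param population_id population to tabulate.
#' @return named list (one element per locus) of named frequency vectors;
#'   names are allele values as characters.  Attribute `n_copies` gives the
#'   observed gene-copy count per locus; attribute `zero_copy_loci` flags loci
#'   with no data.
#' @export
allele_frequencies <- function(table, population_id) {
  idx <- which(table$meta$population_id == population_id)
  if (!length(idx)) stop("unknown population: ", population_id)
  out <- vector("list", length(table$loci))
  names(out) <- table$loci
  n_copies <- integer(length(table$loci))
  names(n_copies) <- table$loci
  for (j in seq_along(table$loci)) {
    a <- as.vector(table$alleles[idx, locus_cols(table, j), drop = FALSE])
    a <- a[!is.na(a)]
    n_copies[j] <- length(a)
    if (length(a)) {
      tab <- table(a)
      out[[j]] <- as.numeric(tab) / length(a)
      names(out[[j]]) <- names(tab)
    } else {
      out[[j]] <- numeric(0)
    }
  }
  attr(out, "n_copies") <- n_copies
  attr(out, "zero_copy_loci") <- table$loci[n_copies == 0L]
  out
}
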