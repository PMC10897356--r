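#' Quality filters for genotype tables
#'
#' Three sequential filters mirror standard microsatellite QC for clonal
#' herbs: (1) drop samples whose genotyping failed at more than one locus;
#' (2) within each population, collapse repeated multi-locus genotypes (MLG)
#' to a single representative, treating them as clonal ramets of one genet;
#' (3) drop populations left with fewer than `min_mlg` genets, which are too
#' small for a reliable among-population covariance estimate.
#'
#' Each filter returns the filtered table together with a `filter_report`
#' recording what was removed; [apply_qc_filters()] chains all three.
#'
#' @name filters
NULL

new_filter_report <- function(step, n_in, n_out, n_dropped_missingness = 0L,
                              n_clones_removed = 0L,
                              populations_dropped = character(0),
                              mlg_counts = integer(0)) {
  structure(list(step = step, n_in = n_in, n_out = n_out,
                 n_dropped_missingness = n_dropped_missingness,
                 n_clones_removed = n_clones_removed,
                 populations_dropped = populations_dropped,
                 mlg_counts = mlg_counts),
            class = "filter_report")
}

#' @method print filter_report
#' @export
print.filter_report <- function(x, ...) {
  cat("filter_report [", x$step, "]: ", x$n_in, " -> ", x$n_out, " samples\n",
      sep = "")
  if (x$n_dropped_missingness) cat("  dropped for missingness:", x$n_dropped_missingness, "\n")
  if (x$n_clones_removed) cat("  clonal duplicates removed:", x$n_clones_removed, "\n")
  if (length(x$populations_dropped))
    cat("  populations dropped:", paste(x$populations_dropped, collapse = ", "), "\n")
  invisible(x)
}

#' @describeIn filters Remove samples missing at two or more loci (samples
#'   with zero or one failed locus are retained).
#' @param table a `genotype_table`.
#' @return list with elements `table` (filtered `genotype_table`) and
#'   `report` (a `filter_report`).
#' @export
filter_by_missingness <- function(table) {
  n_missing <- rowSums(missing_loci_per_sample(table))
  keep <- n_missing < 2L
  out <- subset_samples(table, which(keep))
  rep <- new_filter_report("missingness", n_samples(table), n_samples(out),
                           n_dropped_missingness = sum(!keep),
                           mlg_counts = table(out$meta$population_id))
  list(table = out, report = rep)
}

# MLG key per sample: allele values joined; NA spelled out so that two
# samples are "repeated" only if equal at every observed locus AND share the
# same missingness pattern (missing loci never match as wildcards)
mlg_key <- function(table) {
  apply(table$alleles, 1L, function(r) paste(ifelse(is.na(r), ".", r), collapse = "/"))
}

#' @describeIn filters Collapse repeated multi-locus genotypes within each
#'   population to one representative (the first occurrence).  Identical MLGs
#'   in different populations are never collapsed.  Two samples count as
#'   repeats only when equal at every mutually observed locus and with the
#'   same missingness pattern (`wildcard_missing = FALSE`, the conservative
#'   default); with `wildcard_missing = TRUE` a missing locus matches any
#'   genotype.
#' @param wildcard_missing logical; see above.
#' @export
collapse_clones <- function(table, wildcard_missing = FALSE) {
  keep <- rep(TRUE, n_samples(table))
  if (!wildcard_missing) {
    key <- paste(table$meta$population_id, mlg_key(table), sep = "\r")
    keep <- !duplicated(key)
  } else {
    for (p in populations(table)) {
      idx <- which(table$meta$population_id == p)
      for (a in seq_along(idx)) {
        if (!keep[idx[a]]) next
        for (b in seq_along(idx)) {
          if (b <= a || !keep[idx[b]]) next
          ra <- table$alleles[idx[a], ]; rb <- table$alleles[idx[b], ]
          obs <- !is.na(ra) & !is.na(rb)
          if (all(ra[obs] == rb[obs])) keep[idx[b]] <- FALSE
        }
      }
    }
  }
  out <- subset_samples(table, which(keep))
  rep <- new_filter_report("clones", n_samples(table), n_samples(out),
                           n_clones_removed = sum(!keep),
                           mlg_counts = table(out$meta$population_id))
  list(table = out, report = rep)
}

#' @describeIn filters Drop populations with fewer than `min_mlg` distinct
#'   multi-locus genotypes after clone collapsing.
#' @param min_mlg minimum MLG count for a population to be retained
#'   (default 4).
#' @export
drop_small_populations <- function(table, min_mlg = 4L) {
  counts <- table(table$meta$population_id)
  dropped <- names(counts)[counts < min_mlg]
  keep <- !(table$meta$population_id %in% dropped)
  if (!any(keep)) stop("all populations dropped: empty study")
  out <- subset_samples(table, which(keep))
  rep <- new_filter_report("small_populations", n_samples(table), n_samples(out),
                           populations_dropped = dropped,
                           mlg_counts = table(out$meta$population_id))
  list(table = out, report = rep)
}

#' @describeIn filters Run the full filter chain (missingness, clones, small
#'   populations) and return the table plus all three reports.
#' @export
apply_qc_filters <- function(table, min_mlg = 4L, wildcard_missing = FALSE) {
  f1 <- filter_by_missingness(table)
  f2 <- collapse_clones(f1$table, wildcard_missing = wildcard_missing)
  f3 <- drop_small_populations(f2$table, min_mlg = min_mlg)
  list(table = f3$table,
       reports = list(missingness = f1$report, clones = f2$report,
                      small_populations = f3$report))
}
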