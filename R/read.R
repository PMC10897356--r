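#' Read a microsatellite allele table
#'
#' Two dialects are accepted.  `"tabular"` is a comma- or tab-separated file
#' with columns `sample_id`, `window`, `population`, optionally `patch`, then
#' two allele columns per locus named `<locus>_a` / `<locus>_b` (or
#' `<locus>.1` / `<locus>.2`).  `"genepop"` is the classic GenePop layout:
#' title line, locus names (one per line or comma-separated), `POP` blocks,
#' and per-sample lines `id , 092104 088088 ...` in 4- or 6-digit coding.
#' All missing-genotype spellings (blank, `0`, `NA`, `000000`, `0000`) are
#' normalized to the single internal `NA` sentinel at parse time so that no
#' downstream computation ever branches on dialect.
#'
#' GenePop carries no window/patch columns; populations parsed from `POP`
#' blocks are named after their first sample (GenePop convention) or
#' `pop_<k>`, and all are assigned to window `"W1"` unless the population id
#' embeds `window:population` with a `:` separator.
#'
#' @param path file to read.
#' @param format `"auto"` (sniffed), `"tabular"` or `"genepop"`.
#' @return a validated [genotype_table()].
#' @export
read_allele_table <- function(path, format = c("auto", "tabular", "genepop")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    head_lines <- readLines(path, n = 50L, warn = FALSE)
    format <- if (any(toupper(trimws(head_lines)) == "POP")) "genepop" else "tabular"
  }
  switch(format,
         tabular = read_allele_tabular(path),
         genepop = read_allele_genepop(path),
         stop("unknown format: ", format))
}

normalize_allele <- function(x) {
  x <- trimws(as.character(x))
  x[x %in% c("", "0", "00", "000", "NA", "na", "N/A", "?")] <- NA_character_
  suppressWarnings(out <- as.integer(x))
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad)) stop("non-numeric allele value: ", x[bad[1]])
  out[!is.na(out) & out == 0L] <- NA_integer_
  out
}

read_allele_tabular <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE,
                          strip.white = TRUE, blank.lines.skip = TRUE)
  names(df) <- trimws(names(df))
  id_col  <- grep("^sample_?id$", names(df), ignore.case = TRUE, value = TRUE)
  win_col <- grep("^window(_id)?$", names(df), ignore.case = TRUE, value = TRUE)
  pop_col <- grep("^population(_id)?$|^pop$", names(df), ignore.case = TRUE, value = TRUE)
  pat_col <- grep("^patch(_id)?$", names(df), ignore.case = TRUE, value = TRUE)
  if (!length(id_col) || !length(win_col) || !length(pop_col))
    stop("tabular allele file must have sample_id, window and population columns")
  allele_cols <- setdiff(names(df), c(id_col, win_col, pop_col, pat_col))
  # allele columns come in pairs <locus>_a/<locus>_b or <locus>.1/<locus>.2
  stem <- sub("(_[ab]|\\.[12])$", "", allele_cols)
  loci <- unique(stem)
  for (l in loci) {
    if (sum(stem == l) != 2L)
      stop("locus '", l, "' does not have exactly two allele columns")
  }
  n <- nrow(df)
  alleles <- matrix(NA_integer_, n, 2L * length(loci))
  for (j in seq_along(loci)) {
    cols <- allele_cols[stem == loci[j]]
    for (k in 1:2) {
      v <- tryCatch(normalize_allele(df[[cols[k]]]),
                    error = function(e) stop("parse error in column '", cols[k],
                                             "': ", conditionMessage(e)))
      alleles[, (j - 1L) * 2L + k] <- v
    }
  }
  # normalize half-missing to fully missing?  No: reject, naming the row.
  meta <- data.frame(sample_id = df[[id_col[1]]],
                     population_id = df[[pop_col[1]]],
                     window_id = df[[win_col[1]]],
                     stringsAsFactors = FALSE)
  if (length(pat_col)) meta$patch_id <- df[[pat_col[1]]]
  genotype_table(meta, alleles, loci)
}

read_allele_genepop <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 3L) stop("malformed GenePop file: too few lines")
  pop_idx <- which(toupper(trimws(lines)) == "POP")
  if (!length(pop_idx)) stop("malformed GenePop file: no POP line")
  header <- lines[2:(pop_idx[1] - 1L)]
  loci <- trimws(unlist(strsplit(header, ",")))
  loci <- loci[nzchar(loci)]
  n_loci <- length(loci)
  meta_list <- list(); allele_list <- list()
  pop_idx <- c(pop_idx, length(lines) + 1L)
  for (b in seq_len(length(pop_idx) - 1L)) {
    block <- lines[(pop_idx[b] + 1L):(pop_idx[b + 1L] - 1L)]
    if (!length(block)) next
    pop_name <- NULL
    for (ln in block) {
      parts <- strsplit(ln, ",")[[1]]
      if (length(parts) < 2L)
        stop("malformed GenePop sample line (no comma): '", ln, "'")
      sid <- trimws(parts[1])
      geno <- strsplit(trimws(paste(parts[-1], collapse = " ")), "[ \t]+")[[1]]
      geno <- geno[nzchar(geno)]
      if (length(geno) != n_loci)
        stop("GenePop line for sample '", sid, "' has ", length(geno),
             " genotypes, expected ", n_loci)
      width <- nchar(geno[1])
      if (!width %in% c(4L, 6L))
        stop("GenePop genotype '", geno[1], "' is neither 4- nor 6-digit")
      half <- width %/% 2L
      a1 <- normalize_allele(substr(geno, 1L, half))
      a2 <- normalize_allele(substr(geno, half + 1L, width))
      parsed <- sid_population_name(sid, b)
      if (is.null(pop_name)) pop_name <- parsed
      row <- integer(2L * n_loci)
      row[seq(1L, by = 2L, length.out = n_loci)] <- a1
      row[seq(2L, by = 2L, length.out = n_loci)] <- a2
      meta_list[[length(meta_list) + 1L]] <-
        data.frame(sample_id = parsed$sample, population_id = pop_name$pop,
                   window_id = pop_name$window, stringsAsFactors = FALSE)
      allele_list[[length(allele_list) + 1L]] <- row
    }
  }
  meta <- do.call(rbind, meta_list)
  alleles <- do.call(rbind, allele_list)
  # a half-present pair (one slot 0) becomes fully missing: GenePop codes
  # missing genotypes as 0000/000000 as a unit, partial zeros are treated as
  # a failed call for the whole locus
  for (j in seq_len(ncol(alleles) / 2L)) {
    cols <- (j - 1L) * 2L + 1:2
    any_na <- is.na(alleles[, cols[1]]) | is.na(alleles[, cols[2]])
    alleles[any_na, cols] <- NA_integer_
  }
  genotype_table(meta, alleles, loci)
}

# GenePop block naming: "W2:P7_s01" style ids put sample s01 in window W2,
# population P7; otherwise population = pop_<k> in window W1
sid_population_name <- function(sid, k) {
  if (grepl(":", sid)) {
    parts <- strsplit(sid, ":")[[1]]
    pop <- sub("_.*$", "", parts[2])
    sample <- if (grepl("_", parts[2])) sub("^[^_]*_", "", parts[2]) else parts[2]
    list(window = parts[1], pop = pop, sample = sample)
  } else {
    list(window = "W1", pop = paste0("pop_", k), sample = sid)
  }
}

#' Write a genotype table as tabular CSV
#'
#' Serializes the canonical table in the exact dialect [read_allele_table()]
#' reads back (`<locus>_a`/`<locus>_b` columns, missing as empty fields).
#'
#' @param table a `genotype_table`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_allele_csv <- function(table, path) {
  df <- data.frame(sample_id = table$meta$sample_id,
                   window = table$meta$window_id,
                   population = table$meta$population_id,
                   patch = table$meta$patch_id,
                   stringsAsFactors = FALSE)
  for (j in seq_along(table$loci)) {
    cols <- locus_cols(table, j)
    df[[paste0(table$loci[j], "_a")]] <- table$alleles[, cols[1]]
    df[[paste0(table$loci[j], "_b")]] <- table$alleles[, cols[2]]
  }
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write a genotype table in GenePop 6-digit dialect
#'
#' Sample ids are emitted as `window:population_sampleid` so that the window
#' and population assignment round-trips through [read_allele_table()].
#'
#' @param table a `genotype_table`.
#' @param path output file.
#' @param title first line of the file.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(table, path, title = "agenet export") {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(title, con)
  writeLines(table$loci, con)
  key <- paste(table$meta$window_id, table$meta$population_id)
  for (k in unique(key)) {
    writeLines("POP", con)
    idx <- which(key == k)
    for (i in idx) {
      g <- character(length(table$loci))
      for (j in seq_along(table$loci)) {
        a <- table$alleles[i, locus_cols(table, j)]
        a[is.na(a)] <- 0L
        g[j] <- sprintf("%03d%03d", a[1], a[2])
      }
      sid <- paste0(table$meta$window_id[i], ":", table$meta$population_id[i],
                    "_", table$meta$sample_id[i])
      writeLines(paste0(sid, " , ", paste(g, collapse = " ")), con)
    }
  }
  invisible(path)
}
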