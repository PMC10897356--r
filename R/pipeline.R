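#' Run the full analysis pipeline
#'
#' Orchestrates, per species: QC filtering, per-population diversity,
#' spatial covariables (geographic distance, calibrated Hanski
#' connectivity), pairwise differentiation, per-window population graphs
#' (cGD, NHc, DIFF_GEN_GEO), and the regression layer (all-subsets AICc
#' selection of LMMs for diversity and NHc, MLPE models for the pairwise
#' measures and DIFF_GEN_GEO).  Optionally writes every table, graph and a
#' run manifest to `outdir`.
#'
#' @param datasets named list, one element per species, each a list with
#'   `table` (a `genotype_table`) and `attrs` (population attributes with
#'   `population_id`, `window_id`, `patch_id`, `age`, `size`, `x`, `y`).
#' @param rarefaction_depths named numeric vector of rarefaction depths
#'   (individuals) per species, recycled if length 1 (defaults to 18 for the
#'   first species and 16 otherwise, the study's per-species mean sample
#'   sizes).
#' @param b Hanski size exponent (default 0.5).
#' @param one_over_alpha `"calibrate"` (nearest-neighbour calibration per
#'   species) or a named numeric vector of distance scales in metres.
#' @param pruning_alpha population-graph pruning level (default 0.05).
#' @param min_mlg minimum MLG per population (default 4).
#' @param fit_models logical; run the regression layer (default TRUE).
#' @param outdir optional output directory.
#' @param seed seed recorded in the manifest (model fitting is
#'   deterministic).
#' @return list of class `agenet_run`: `diversity`, `pairs`, `nodes`
#'   (NHc + attributes), `edges` (DIFF_GEN_GEO), `graphs`, `filter_reports`,
#'   `one_over_alpha`, `models` (list of selection results), `manifest`.
#' @export
run_all <- function(datasets, rarefaction_depths = NULL, b = 0.5,
                    one_over_alpha = "calibrate", pruning_alpha = 0.05,
                    min_mlg = 4L, fit_models = TRUE, outdir = NULL, seed = 1L) {
  species <- names(datasets)
  if (is.null(species)) stop("datasets must be a named list (names = species)")
  if (is.null(rarefaction_depths))
    rarefaction_depths <- stats::setNames(
      c(18, rep(16, length(species) - 1L))[seq_along(species)], species)
  if (length(rarefaction_depths) == 1L)
    rarefaction_depths <- stats::setNames(rep(rarefaction_depths, length(species)),
                                          species)
  div_all <- list(); pair_all <- list(); node_all <- list(); edge_all <- list()
  graphs_all <- list(); reports <- list(); ooa <- c()
  for (sp in species) {
    stage <- "filtering"
    res <- tryCatch({
      qc <- apply_qc_filters(datasets[[sp]]$table, min_mlg = min_mlg)
      tab <- qc$table
      attrs <- datasets[[sp]]$attrs
      attrs <- attrs[attrs$population_id %in% populations(tab), , drop = FALSE]
      stage <- "landscape"
      sp_ooa <- if (identical(one_over_alpha, "calibrate"))
        calibrate_alpha(attrs) else unname(one_over_alpha[sp])
      attrs$SPA_CON <- unname(hanski_connectivity(attrs, sp_ooa, b)[attrs$population_id])
      stage <- "diversity"
      div <- diversity_table(tab, rarefaction_depths[sp])
      div <- merge(div, attrs[, c("population_id", "age", "size", "SPA_CON")],
                   by = "population_id")
      stage <- "differentiation"
      pairs <- differentiation_table(tab, attrs)
      stage <- "popgraph"
      graphs <- list(); nodes <- list(); edges <- list()
      for (w in unique(tab$meta$window_id)) {
        pops_w <- unique(tab$meta$population_id[tab$meta$window_id == w])
        if (length(pops_w) < 3L) {
          warning("window ", w, " has < 3 populations for species ", sp,
                  "; population graph skipped")
          next
        }
        g <- build_population_graph(tab, w, alpha = pruning_alpha)
        graphs[[w]] <- g
        nhc <- normalized_harmonic_centrality(g)
        nodes[[w]] <- data.frame(population_id = names(nhc), NHc = as.numeric(nhc),
                                 window_id = w, stringsAsFactors = FALSE)
        if (nrow(g$edges)) {
          e <- diff_gen_geo(g, attrs)
          e$window_id <- w
          edges[[w]] <- e
        }
      }
      pairs <- add_graph_columns(pairs, graphs)
      node_df <- do.call(rbind, nodes)
      node_df <- merge(node_df, attrs[, c("population_id", "patch_id", "age",
                                          "size", "SPA_CON")],
                       by = "population_id")
      edge_df <- if (length(edges)) do.call(rbind, edges) else NULL
      if (!is.null(edge_df)) {
        edge_df$AGE_BASE <- pmin(attrs$age[match(edge_df$from, attrs$population_id)],
                                 attrs$age[match(edge_df$to, attrs$population_id)])
        edge_df$AGE_DIFF <- abs(attrs$age[match(edge_df$from, attrs$population_id)] -
                                attrs$age[match(edge_df$to, attrs$population_id)])
      }
      list(div = div, pairs = pairs, nodes = node_df, edges = edge_df,
           graphs = graphs, reports = qc$reports, ooa = sp_ooa)
    }, error = function(e)
      stop("pipeline failed for species '", sp, "' at stage '", stage, "': ",
           conditionMessage(e), call. = FALSE))
    res$div$SPECIES <- sp; res$pairs$SPECIES <- sp; res$nodes$SPECIES <- sp
    if (!is.null(res$edges)) res$edges$SPECIES <- sp
    div_all[[sp]] <- res$div; pair_all[[sp]] <- res$pairs
    node_all[[sp]] <- res$nodes; edge_all[[sp]] <- res$edges
    graphs_all[[sp]] <- res$graphs; reports[[sp]] <- res$reports
    ooa[sp] <- res$ooa
  }
  out <- list(diversity = do.call(rbind, div_all),
              pairs = do.call(rbind, pair_all),
              nodes = do.call(rbind, node_all),
              edges = do.call(rbind, unname(edge_all[!vapply(edge_all, is.null,
                                                             logical(1))])),
              graphs = graphs_all, filter_reports = reports,
              one_over_alpha = ooa)
  rownames(out$diversity) <- rownames(out$pairs) <- NULL
  out$models <- if (fit_models) fit_all_models(out) else NULL
  out$manifest <- list(species = species, seed = seed, b = b,
                       rarefaction_depths = as.list(rarefaction_depths),
                       one_over_alpha = as.list(ooa),
                       pruning_alpha = pruning_alpha, min_mlg = min_mlg,
                       r_version = as.character(getRversion()),
                       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  class(out) <- "agenet_run"
  if (!is.null(outdir)) write_run_outputs(out, outdir)
  out
}

# Box-Cox + standardize the modelling variables with the grouping each one
# calls for: measures and the two size/connectivity covariables per species
# (their absolute scales are species-specific nuisance), ages and distances
# globally (shared origin across species)
prepare_diversity_data <- function(div) {
  multi <- length(unique(div$SPECIES)) > 1L
  d <- data.frame(window_id = div$window_id, patch_id = div$patch_id,
                  SPECIES = factor(div$SPECIES), stringsAsFactors = FALSE)
  grp <- if (multi) div$SPECIES else NULL
  d$POP_AGE <- transform_variable(div$age)$values
  d$POP_SIZE <- transform_variable(div$size, grp)$values
  d$SPA_CON <- transform_variable(div$SPA_CON, grp)$values
  for (y in c("Ar", "Ho", "He", "F"))
    d[[y]] <- tryCatch(transform_variable(div[[y]], grp)$values,
                       error = function(e) rep(NA_real_, nrow(div)))
  d
}

prepare_pairwise_data <- function(pairs) {
  multi <- length(unique(pairs$SPECIES)) > 1L
  d <- data.frame(window_id = pairs$window_id, pop_i = pairs$pop_i,
                  pop_j = pairs$pop_j, SPECIES = factor(pairs$SPECIES),
                  is_graph_edge = pairs$is_graph_edge, stringsAsFactors = FALSE)
  grp <- if (multi) pairs$SPECIES else NULL
  d$AGE_BASE <- transform_variable(pairs$AGE_BASE)$values
  d$AGE_DIFF <- transform_variable(pairs$AGE_DIFF)$values
  d$GEO_DIST <- transform_variable(pairs$GEO_DIST)$values
  for (y in c("G2ST", "DPS", "cGD")) {
    d[[y]] <- NA_real_
    ok <- !is.na(pairs[[y]])
    if (any(ok)) {
      grp_ok <- if (multi) pairs$SPECIES[ok] else NULL
      d[[y]][ok] <- transform_variable(pairs[[y]][ok], grp_ok)$values
    }
  }
  d
}

with_species <- function(terms, multi) {
  if (!multi) return(terms)
  c(terms, paste0(terms, ":SPECIES"))
}

fit_all_models <- function(run) {
  multi <- length(unique(run$diversity$SPECIES)) > 1L
  retained <- if (multi) "SPECIES" else character(0)
  models <- list()
  dd <- prepare_diversity_data(run$diversity)
  for (y in c("Ar", "He", "Ho", "F")) {
    dat <- dd[!is.na(dd[[y]]), , drop = FALSE]
    models[[y]] <- all_subsets_aicc(
      y, optional = with_species(c("POP_SIZE", "SPA_CON", "POP_AGE"), multi),
      retained = retained, data = dat, engine = "lmm")
  }
  pd <- prepare_pairwise_data(run$pairs)
  base_terms <- c("AGE_DIFF", "AGE_BASE", "AGE_DIFF:AGE_BASE", "GEO_DIST")
  for (y in c("G2ST", "DPS", "cGD")) {
    dat <- pd[!is.na(pd[[y]]), , drop = FALSE]
    if (y == "cGD") dat <- dat[dat$is_graph_edge %in% TRUE, , drop = FALSE]
    models[[y]] <- all_subsets_aicc(
      y, optional = with_species(base_terms, multi), retained = retained,
      data = dat, engine = "mlpe")
  }
  if (!is.null(run$nodes)) {
    nd <- data.frame(window_id = run$nodes$window_id,
                     SPECIES = factor(run$nodes$SPECIES))
    nd$POP_AGE <- transform_variable(run$nodes$age)$values
    grp <- if (multi) run$nodes$SPECIES else NULL
    nd$NHc <- transform_variable(run$nodes$NHc, grp)$values
    models$NHc <- all_subsets_aicc(
      "NHc", optional = with_species("POP_AGE", multi), retained = retained,
      data = nd, engine = "lmm", random = "window_id")
  }
  if (!is.null(run$edges) && nrow(run$edges) >= 10L) {
    ed <- data.frame(window_id = run$edges$window_id, pop_i = run$edges$from,
                     pop_j = run$edges$to, SPECIES = factor(run$edges$SPECIES))
    grp <- if (multi) run$edges$SPECIES else NULL
    ed$DIFF_GEN_GEO <- transform_variable(run$edges$DIFF_GEN_GEO, grp)$values
    ed$AGE_BASE <- transform_variable(run$edges$AGE_BASE)$values
    ed$AGE_DIFF <- transform_variable(run$edges$AGE_DIFF)$values
    opt <- c("AGE_DIFF", "AGE_BASE", "AGE_DIFF:AGE_BASE")
    if (multi) opt <- c(opt, paste0(opt, ":SPECIES"))
    models$DIFF_GEN_GEO <- all_subsets_aicc(
      "DIFF_GEN_GEO", optional = opt, retained = retained, data = ed,
      engine = "mlpe")
  }
  models
}

#' @method print agenet_run
#' @export
print.agenet_run <- function(x, ...) {
  cat("agenet_run:", length(x$manifest$species), "species,",
      nrow(x$diversity), "populations,", nrow(x$pairs), "population pairs\n")
  invisible(x)
}

write_run_outputs <- function(run, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(run$diversity, file.path(outdir, "diversity.csv"),
                   row.names = FALSE)
  utils::write.csv(run$pairs, file.path(outdir, "pairwise.csv"),
                   row.names = FALSE)
  if (!is.null(run$nodes))
    utils::write.csv(run$nodes, file.path(outdir, "nodes.csv"), row.names = FALSE)
  if (!is.null(run$edges))
    utils::write.csv(run$edges, file.path(outdir, "edges.csv"), row.names = FALSE)
  for (sp in names(run$graphs)) {
    for (w in names(run$graphs[[sp]])) {
      write_population_graph(run$graphs[[sp]][[w]],
                             file.path(outdir, paste0("graph_", sp, "_", w, ".graphml")))
    }
  }
  if (!is.null(run$models)) {
    sel <- lapply(run$models, function(m) m$table)
    jsonlite::write_json(sel, file.path(outdir, "selection_traces.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    utils::write.csv(report_tables(run), file.path(outdir, "coefficients.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(run$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}

# compact-letter display: species sharing a letter do not differ at alpha.
# Letters are the maximal cliques of the "not significantly different" graph,
# ordered by the mean estimate of their members.
slope_letters <- function(est, vc, alpha = 0.05) {
  k <- length(est)
  same <- matrix(TRUE, k, k)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    se <- sqrt(vc[i, i] + vc[j, j] - 2 * vc[i, j])
    z <- (est[i] - est[j]) / se
    same[i, j] <- same[j, i] <- 2 * stats::pnorm(-abs(z)) > alpha
  }
  g <- igraph::graph_from_adjacency_matrix(same, mode = "undirected",
                                           diag = FALSE)
  cliques <- igraph::max_cliques(g)
  cliques <- cliques[order(vapply(cliques, function(cl) mean(est[as.integer(cl)]),
                                  numeric(1)))]
  letters_out <- rep("", k)
  for (ci in seq_along(cliques))
    for (i in as.integer(cliques[[ci]]))
      letters_out[i] <- paste0(letters_out[i], letters[ci])
  letters_out
}

#' Format selected models as coefficient tables
#'
#' One row per (response, variable, species) in the layout of standard
#' age-effect reporting: when the final model keeps a variable's interaction
#' with species, per-species slopes are shown with compact letters marking
#' significant slope differences (pairwise contrasts at alpha = .05, no
#' multiplicity correction); otherwise a single coefficient row common to
#' all species.  Marginal and conditional R-squared close each response
#' block.
#'
#' @param run an `agenet_run` with fitted models.
#' @param model `"best"` (the AICc-selected model, default) or `"global"`
#'   (the full model with every optional term).
#' @return data.frame `response`, `variable`, `species`, `estimate`, `se`,
#'   `p`, `stars`, `letters`, `R2m`, `R2c`.
#' @export
report_tables <- function(run, model = c("best", "global")) {
  model <- match.arg(model)
  stopifnot(!is.null(run$models))
  species <- sort(unique(as.character(run$diversity$SPECIES)))
  rows <- list()
  for (resp in names(run$models)) {
    fit <- run$models[[resp]][[model]]
    if (is.null(fit)) next
    cf <- fit$coefficients
    vc <- fit$vcov
    vars <- setdiff(attr(stats::terms(fit$formula), "term.labels"), "SPECIES")
    vars <- vars[!grepl("(^|:)SPECIES(:|$)", vars)]
    for (v in vars) {
      int_terms <- cf$term[grepl(paste0("^", v, ":SPECIES"), cf$term) |
                           grepl(paste0("^SPECIES[^:]*:", v, "$"), cf$term)]
      main_idx <- match(v, cf$term)
      if (!length(int_terms)) {
        rows[[length(rows) + 1L]] <- data.frame(
          response = resp, variable = v, species = "all",
          estimate = cf$estimate[main_idx], se = cf$se[main_idx],
          p = cf$p[main_idx], stars = cf$stars[main_idx], letters = "",
          R2m = fit$R2m, R2c = fit$R2c, stringsAsFactors = FALSE)
      } else {
        # per-species slopes under treatment coding: reference slope is the
        # main effect; others add their interaction coefficient
        k <- length(species)
        est <- numeric(k); L <- matrix(0, k, nrow(cf))
        L[, main_idx] <- 1
        for (s in 2:k) {
          it <- int_terms[grepl(paste0("SPECIES", species[s]), int_terms)]
          if (length(it)) L[s, match(it[1], cf$term)] <- 1
        }
        est <- as.numeric(L %*% cf$estimate)
        vs <- L %*% vc %*% t(L)
        se <- sqrt(diag(vs))
        p <- 2 * stats::pnorm(-abs(est / se))
        lt <- slope_letters(est, vs)
        for (s in seq_len(k)) {
          rows[[length(rows) + 1L]] <- data.frame(
            response = resp, variable = v, species = species[s],
            estimate = est[s], se = se[s], p = p[s],
            stars = significance_stars(p[s]), letters = lt[s],
            R2m = fit$R2m, R2c = fit$R2c, stringsAsFactors = FALSE)
        }
      }
    }
    if (!length(vars)) {
      rows[[length(rows) + 1L]] <- data.frame(
        response = resp, variable = "(intercept only)", species = "all",
        estimate = NA_real_, se = NA_real_, p = NA_real_, stars = "",
        letters = "", R2m = fit$R2m, R2c = fit$R2c, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
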