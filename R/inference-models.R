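#' @title Mixed-model layer
#' @description Random-intercept LMMs (via lme4) and maximum-likelihood
#'   population effects (MLPE) models for pairwise distance data, both fitted
#'   by ML so that AICc comparisons across fixed-effect structures are valid,
#'   and both summarized as a common `model_fit` object.
#' @name models
NULL

aicc_from <- function(logLik, k, n) {
  aic <- -2 * logLik + 2 * k
  aic + 2 * k * (k + 1) / (n - k - 1)
}

new_model_fit <- function(engine, formula, coefficients, logLik, k, n,
                          varcomp, R2m, R2c, rho = NA_real_, object = NULL,
                          vcov = NULL) {
  structure(list(engine = engine, formula = formula,
                 coefficients = coefficients, logLik = logLik, k = k, n = n,
                 AICc = aicc_from(logLik, k, n), varcomp = varcomp,
                 R2m = R2m, R2c = R2c, rho = rho, object = object,
                 vcov = vcov),
            class = "model_fit")
}

#' @method print model_fit
#' @export
print.model_fit <- function(x, ...) {
  cat("model_fit [", x$engine, "] ", deparse(x$formula), "\n", sep = "")
  cat(sprintf("  n = %d, k = %d, AICc = %.2f, R2m = %.3f, R2c = %.3f\n",
              x$n, x$k, x$AICc, x$R2m, x$R2c))
  if (!is.na(x$rho)) cat(sprintf("  MLPE rho = %.3f\n", x$rho))
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' Significance codes at the conventional reporting levels
#' @param p numeric p-values.
#' @return character: `**` (p <= .01), `*` (p <= .05), `(*)` (p <= .1),
#'   `n.s.` otherwise.
#' @export
significance_stars <- function(p) {
  ifelse(is.na(p), "", ifelse(p <= .01, "**", ifelse(p <= .05, "*",
         ifelse(p <= .1, "(*)", "n.s."))))
}

#' Fit a random-intercept linear mixed model
#'
#' ML-fitted (not REML, since AICc model selection compares fixed-effect
#' structures).  Random intercepts default to landscape window and forest
#' patch nested in window.  Coefficient p-values use Satterthwaite degrees of
#' freedom (lmerTest).  Marginal and conditional R-squared follow the
#' variance-partition (Nakagawa-type) definitions.  Singular fits (a variance
#' component at the zero boundary) are kept at the boundary with a warning,
#' in which case the coefficients coincide with the simpler nested model.
#'
#' @param fixed fixed-effects formula, e.g. `Ho ~ (POP_SIZE + SPA_CON +
#'   POP_AGE) * SPECIES`.
#' @param data data.frame with the model variables plus the grouping columns.
#' @param random character vector of grouping columns; the first is the top
#'   level, subsequent ones are nested inside it (default
#'   `c("window_id", "patch_id")`).
#' @return a `model_fit`.
#' @export
fit_lmm <- function(fixed, data, random = c("window_id", "patch_id")) {
  rterms <- random[1]
  if (length(random) > 1L)
    rterms <- c(rterms, paste0(random[1], ":", random[[2]]))
  # a grouping factor with one observation per level is confounded with the
  # residual and cannot enter a random-intercept fit
  n_levels <- vapply(rterms, function(tm) {
    cols <- strsplit(tm, ":", fixed = TRUE)[[1]]
    nlevels(interaction(data[cols], drop = TRUE))
  }, integer(1))
  drop_terms <- n_levels >= nrow(data) | n_levels < 2L
  if (all(drop_terms)) stop("no usable random grouping factor")
  if (any(drop_terms)) {
    message("dropping random term(s) with as many levels as observations: ",
            paste(rterms[drop_terms], collapse = ", "))
    rterms <- rterms[!drop_terms]
  }
  fml <- stats::as.formula(paste(deparse1(fixed), "+",
                                 paste0("(1 | ", rterms, ")", collapse = " + ")))
  fit <- suppressMessages(lmerTest::lmer(fml, data = data, REML = FALSE))
  if (lme4::isSingular(fit))
    warning("singular fit: a random-effect variance is at the zero boundary")
  sm <- stats::coef(summary(fit))
  coefs <- data.frame(term = rownames(sm), estimate = sm[, "Estimate"],
                      se = sm[, "Std. Error"], p = sm[, "Pr(>|t|)"],
                      stringsAsFactors = FALSE, row.names = NULL)
  coefs$stars <- significance_stars(coefs$p)
  vc <- as.data.frame(lme4::VarCorr(fit))
  s2_rand <- sum(vc$vcov[vc$grp != "Residual"])
  s2_e <- vc$vcov[vc$grp == "Residual"]
  s2_f <- stats::var(as.numeric(stats::model.matrix(fit) %*% lme4::fixef(fit)))
  tot <- s2_f + s2_rand + s2_e
  ll <- as.numeric(stats::logLik(fit))
  k <- attr(stats::logLik(fit), "df")
  new_model_fit("lmm", fixed, coefs, ll, k, stats::nobs(fit),
                varcomp = stats::setNames(vc$vcov, vc$grp),
                R2m = s2_f / tot, R2c = (s2_f + s2_rand) / tot, object = fit,
                vcov = as.matrix(stats::vcov(fit)))
}

# ---- MLPE -------------------------------------------------------------------

#' Implied MLPE covariance matrix
#'
#' The MLPE structure is parameterized through node effects: a pairwise
#' observation on populations (i, j) carries u_i + u_j with
#' Var(u) = sigma_a^2, plus a window intercept (sigma_w^2) and residual
#' (sigma_e^2).  Two pairs in the same window sharing exactly one population
#' then have correlation \eqn{\rho = \sigma_a^2/(2\sigma_a^2 + \sigma_e^2)}
#' (bounded in (0, 0.5)), pairs sharing none only the window correlation —
#' the Clarke et al. correlated-pair structure.  This helper materializes the
#' full covariance matrix for inspection/testing.
#'
#' @param data data.frame with the pair columns and window column.
#' @param s2_w,s2_a,s2_e variance components.
#' @param pop_cols names of the two population-id columns.
#' @param window_col name of the window column.
#' @return covariance matrix (n x n).
#' @export
mlpe_implied_covariance <- function(data, s2_w, s2_a, s2_e,
                                    pop_cols = c("pop_i", "pop_j"),
                                    window_col = "window_id") {
  n <- nrow(data)
  pops <- sort(unique(c(data[[pop_cols[1]]], data[[pop_cols[2]]])))
  Z <- matrix(0, n, length(pops), dimnames = list(NULL, pops))
  Z[cbind(seq_len(n), match(data[[pop_cols[1]]], pops))] <- 1
  Z[cbind(seq_len(n), match(data[[pop_cols[2]]], pops))] <-
    Z[cbind(seq_len(n), match(data[[pop_cols[2]]], pops))] + 1
  W <- outer(data[[window_col]], data[[window_col]], "==") * 1
  s2_w * W + s2_a * (Z %*% t(Z)) + s2_e * diag(n)
}

#' Fit a maximum-likelihood population effects (MLPE) model
#'
#' For pairwise responses (differentiation between population pairs), where
#' observations sharing a population are not independent.  See
#' [mlpe_implied_covariance()] for the structure.  The likelihood is
#' maximized over the three log-variances with the window blocks exploited
#' (pairs in different windows are independent), the fixed effects profiled
#' out by GLS.  Populations appearing in fewer than two pairs are retained
#' but flagged (they carry no information on rho).
#'
#' @param fixed fixed-effects formula, e.g.
#'   `DPS ~ (AGE_DIFF * AGE_BASE + GEO_DIST) * SPECIES`.
#' @param data pairwise data.frame; must contain `pop_cols` and
#'   `window_col`.
#' @param pop_cols,window_col column names tagging each observation's two
#'   populations and its window.
#' @param with_window logical; include the window random intercept
#'   (default TRUE).
#' @return a `model_fit` with `rho` filled; element `varcomp` holds
#'   `sigma2_window`, `sigma2_pop`, `sigma2_resid`.
#' @export
fit_mlpe <- function(fixed, data, pop_cols = c("pop_i", "pop_j"),
                     window_col = "window_id", with_window = TRUE) {
  mf <- stats::model.frame(fixed, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(fixed, mf)
  n <- length(y)
  win <- as.character(data[[window_col]])
  pop_pair <- cbind(as.character(data[[pop_cols[1]]]),
                    as.character(data[[pop_cols[2]]]))
  pop_use <- table(c(pop_pair))
  lonely <- names(pop_use)[pop_use < 2]
  if (length(lonely))
    message(length(lonely), " population(s) appear in < 2 pairs (no information on rho)")
  blocks <- lapply(unique(win), function(w) {
    idx <- which(win == w)
    pops <- sort(unique(c(pop_pair[idx, ])))
    Z <- matrix(0, length(idx), length(pops))
    Z[cbind(seq_along(idx), match(pop_pair[idx, 1], pops))] <- 1
    ji <- cbind(seq_along(idx), match(pop_pair[idx, 2], pops))
    Z[ji] <- Z[ji] + 1
    list(idx = idx, ZZt = Z %*% t(Z))
  })
  v0 <- stats::var(y)
  profile <- function(theta) {
    s2 <- exp(theta)                      # (w, a, e) or (a, e)
    s2_w <- if (with_window) s2[1] else 0
    s2_a <- s2[length(s2) - 1L]
    s2_e <- s2[length(s2)]
    A <- matrix(0, ncol(X), ncol(X)); b <- numeric(ncol(X))
    logdet <- 0; quad_parts <- list()
    for (bl in blocks) {
      m <- length(bl$idx)
      V <- s2_a * bl$ZZt + diag(s2_e, m)
      if (with_window) V <- V + matrix(s2_w, m, m)
      ch <- tryCatch(chol(V), error = function(e) NULL)
      if (is.null(ch)) return(NULL)
      logdet <- logdet + 2 * sum(log(diag(ch)))
      Xi <- backsolve(ch, X[bl$idx, , drop = FALSE], transpose = TRUE)
      yi <- backsolve(ch, y[bl$idx], transpose = TRUE)
      A <- A + crossprod(Xi); b <- b + crossprod(Xi, yi)
      quad_parts[[length(quad_parts) + 1L]] <- list(Xi = Xi, yi = yi)
    }
    beta <- tryCatch(solve(A, b), error = function(e) NULL)
    if (is.null(beta)) return(NULL)
    quad <- sum(vapply(quad_parts, function(q)
      sum((q$yi - q$Xi %*% beta)^2), numeric(1)))
    ll <- -0.5 * (logdet + quad + n * log(2 * pi))
    list(ll = ll, beta = as.numeric(beta), A = A,
         s2 = c(window = s2_w, pop = s2_a, resid = s2_e))
  }
  nll <- function(theta) {
    pr <- profile(theta)
    if (is.null(pr)) return(1e10)
    -pr$ll
  }
  n_par <- if (with_window) 3L else 2L
  start <- log(rep(v0 / n_par, n_par))
  opt <- stats::optim(start, nll, method = "L-BFGS-B",
                      lower = log(v0 * 1e-8), upper = log(v0 * 1e4))
  pr <- profile(opt$par)
  se <- sqrt(diag(solve(pr$A)))
  z <- pr$beta / se
  coefs <- data.frame(term = colnames(X), estimate = pr$beta, se = se,
                      p = 2 * stats::pnorm(-abs(z)), stringsAsFactors = FALSE)
  coefs$stars <- significance_stars(coefs$p)
  s2 <- pr$s2
  rho <- s2["pop"] / (2 * s2["pop"] + s2["resid"])
  s2_f <- stats::var(as.numeric(X %*% pr$beta))
  tot <- s2_f + s2["window"] + 2 * s2["pop"] + s2["resid"]
  k <- ncol(X) + n_par
  new_model_fit("mlpe", fixed, coefs, pr$ll, k, n,
                varcomp = c(sigma2_window = unname(s2["window"]),
                            sigma2_pop = unname(s2["pop"]),
                            sigma2_resid = unname(s2["resid"])),
                R2m = unname(s2_f / tot),
                R2c = unname((s2_f + s2["window"] + 2 * s2["pop"]) / tot),
                rho = unname(rho), vcov = solve(pr$A))
}

# ---- all-subsets AICc selection --------------------------------------------

# marginality closure: every lower-order relative of each term that exists in
# the candidate pool must be present
respects_marginality <- function(terms_in, pool) {
  for (t in terms_in) {
    parts <- strsplit(t, ":", fixed = TRUE)[[1]]
    if (length(parts) == 1L) next
    for (k in seq_len(length(parts) - 1L)) {
      subs <- utils::combn(parts, k, simplify = FALSE)
      for (s in subs) {
        cand <- pool[vapply(pool, function(p) {
          pp <- strsplit(p, ":", fixed = TRUE)[[1]]
          length(pp) == length(s) && setequal(pp, s)
        }, logical(1))]
        if (length(cand) && !any(cand %in% terms_in)) return(FALSE)
      }
    }
  }
  TRUE
}

#' All-subsets model selection by AICc
#'
#' Enumerates every subset of the optional fixed-effect terms that respects
#' marginality (an interaction never enters without its lower-order
#' relatives) and always contains the retained terms; fits every candidate by
#' ML on identical data with the supplied engine; returns the fit with the
#' lowest AICc (ties broken by fewer parameters).  Candidates that fail to
#' converge are excluded and logged in the selection table.
#'
#' @param response response column name.
#' @param optional character vector of droppable terms (use `:` for
#'   interactions).
#' @param retained character vector of terms that can never be dropped
#'   (e.g. `"SPECIES"`); may be empty.
#' @param data model data.
#' @param engine `"lmm"` or `"mlpe"`.
#' @param ... passed to [fit_lmm()] or [fit_mlpe()].
#' @return list with `best` (a `model_fit`) and `table` (data.frame of all
#'   candidates: formula, k, AICc, converged).
#' @export
all_subsets_aicc <- function(response, optional, retained = character(0),
                             data, engine = c("lmm", "mlpe"), ...) {
  engine <- match.arg(engine)
  fit_fun <- switch(engine, lmm = fit_lmm, mlpe = fit_mlpe)
  pool <- c(optional, retained)
  subsets <- list()
  for (mask in 0:(2^length(optional) - 1)) {
    sel <- optional[bitwAnd(mask, 2^(seq_along(optional) - 1)) > 0]
    if (respects_marginality(c(sel, retained), pool))
      subsets[[length(subsets) + 1L]] <- sel
  }
  rows <- list(); fits <- list()
  for (s in subsets) {
    rhs <- c(retained, s)
    fml <- stats::as.formula(paste(response, "~",
                                   if (length(rhs)) paste(rhs, collapse = " + ") else "1"))
    fit <- tryCatch(suppressWarnings(fit_fun(fml, data, ...)),
                    error = function(e) NULL)
    ok <- !is.null(fit) && is.finite(fit$AICc)
    rows[[length(rows) + 1L]] <- data.frame(
      formula = paste(deparse1(fml), collapse = ""),
      k = if (ok) fit$k else NA_integer_,
      AICc = if (ok) fit$AICc else NA_real_,
      converged = ok, stringsAsFactors = FALSE)
    fits[length(fits) + 1L] <- list(fit)   # keep NULLs as placeholders
  }
  tab <- do.call(rbind, rows)
  ok_idx <- which(tab$converged)
  if (!length(ok_idx)) stop("no candidate model converged")
  best_idx <- ok_idx[order(tab$AICc[ok_idx], tab$k[ok_idx])][1]
  global_idx <- which(vapply(subsets, length, integer(1)) == length(optional))
  list(best = fits[[best_idx]],
       global = if (length(global_idx)) fits[[global_idx[1]]] else NULL,
       table = tab[order(tab$AICc), ])
}

# ---- generalized VIF --------------------------------------------------------

#' Generalized variance-inflation factors
#'
#' Fox & Monette determinant-ratio GVIF per model term, reported as
#' GVIF^(1/(2 df)) so that values are comparable across terms of different
#' dimension; the conventional concern threshold (on the squared scale) is
#' 4.0, i.e. GVIF^(1/(2 df)) = 2.
#'
#' @param fixed fixed-effects formula.
#' @param data model data.
#' @return data.frame `term`, `df`, `GVIF`, `GVIF_scaled`
#'   (= GVIF^(1/(2 df))).
#' @export
generalized_vif <- function(fixed, data) {
  mf <- stats::model.frame(fixed, data)
  X <- stats::model.matrix(fixed, mf)
  assign <- attr(X, "assign")
  labels <- attr(stats::terms(fixed), "term.labels")
  keep <- assign != 0
  X <- X[, keep, drop = FALSE]; assign <- assign[keep]
  if (qr(X)$rank < ncol(X)) {
    q <- qr(X)
    aliased <- colnames(X)[-q$pivot[seq_len(q$rank)]]
    stop("aliased columns in the design: ", paste(aliased, collapse = ", "))
  }
  if (length(unique(assign)) < 2L)
    stop("generalized VIF needs at least two terms")
  R <- stats::cor(X)
  detR <- det(R)
  rows <- lapply(unique(assign), function(a) {
    gi <- assign == a
    gvif <- det(R[gi, gi, drop = FALSE]) * det(R[!gi, !gi, drop = FALSE]) / detR
    data.frame(term = labels[a], df = sum(gi), GVIF = gvif,
               GVIF_scaled = gvif^(1 / (2 * sum(gi))), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
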