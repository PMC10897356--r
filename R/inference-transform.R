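#' Box-Cox transform with profile-likelihood lambda
#'
#' Enhances symmetry of a quantitative variable before modelling.  If the
#' minimum is <= 0 the values are first shifted by `1 - min` so all are
#' positive.  Lambda is chosen by profile log-likelihood on the grid
#' \[-3, 3\] in steps of 0.01 (via [MASS::boxcox()] on an intercept-only
#' model), and the transform is \eqn{y^{(\lambda)} = (y^\lambda - 1)/\lambda}
#' (log for lambda = 0).
#'
#' @param values numeric vector (no NAs).
#' @return list with `values` (transformed), `lambda`, `shift`.
#' @export
boxcox_transform <- function(values) {
  if (any(is.na(values))) stop("boxcox_transform: values contain NA")
  if (stats::sd(values) == 0) stop("boxcox_transform: constant input")
  shift <- if (min(values) <= 0) 1 - min(values) else 0
  y <- values + shift
  fit0 <- stats::lm(y ~ 1, data = data.frame(y = y), y = TRUE, qr = TRUE)
  bc <- MASS::boxcox(fit0, lambda = seq(-3, 3, 0.01), plotit = FALSE)
  lambda <- bc$x[which.max(bc$y)]
  out <- if (abs(lambda) < 1e-8) log(y) else (y^lambda - 1) / lambda
  list(values = out, lambda = lambda, shift = shift)
}

#' Standardize to mean 0, SD 1 within groups
#'
#' @param values numeric vector.
#' @param grouping factor-like of the same length, or `NULL` for global
#'   standardization.  The grouping choice (per species vs. global) is part
#'   of the analysis design: species-specific scales are removed where
#'   absolute differences among species are nuisance, while globally shared
#'   scales (e.g. habitat age from the same maps) are standardized jointly.
#' @return z-scores; attribute `grouping` records the grouping used.
#' @export
standardize_by <- function(values, grouping = NULL) {
  if (is.null(grouping)) grouping <- rep("all", length(values))
  grouping <- as.character(grouping)
  out <- numeric(length(values))
  for (g in unique(grouping)) {
    idx <- grouping == g
    s <- stats::sd(values[idx])
    if (is.na(s) || s == 0) stop("zero within-group SD in group '", g, "'")
    out[idx] <- (values[idx] - mean(values[idx])) / s
  }
  attr(out, "grouping") <- if (length(unique(grouping)) == 1L) "global" else "by_group"
  out
}

#' Box-Cox then standardize, recording the transform
#'
#' @inheritParams standardize_by
#' @return list `values`, `record` (variable-level `transform_record` with
#'   lambda, shift, grouping).
#' @keywords internal
transform_variable <- function(values, grouping = NULL) {
  bc <- boxcox_transform(values)
  z <- standardize_by(bc$values, grouping)
  list(values = as.numeric(z),
       record = list(lambda = bc$lambda, shift = bc$shift,
                     grouping = attr(z, "grouping")))
}
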