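test_that("Box-Cox picks sensible lambdas and shifts only when needed", {
  set.seed(101)
  v <- rlnorm(10000)
  b <- boxcox_transform(v)
  expect_lt(abs(b$lambda), 0.1)              # lognormal -> lambda near 0
  expect_equal(b$shift, 0)                   # strictly positive input
  # near lambda = 1 the transform is near-affine: symmetric input comes
  # through almost unchanged, and the transform is always monotone
  u <- runif(200, 1, 2)
  b1 <- boxcox_transform(u)
  expect_gt(cor(b1$values, u), 0.99)
  expect_equal(order(b1$values), order(u))
  # non-positive input is shifted by 1 - min
  w <- rnorm(100)
  bw <- boxcox_transform(w)
  expect_equal(bw$shift, 1 - min(w))
  expect_error(boxcox_transform(rep(2, 10)), "constant")
})

test_that("grouped standardization yields mean 0 / SD 1 per group", {
  set.seed(102)
  x <- c(rnorm(50, 10, 2), rnorm(50, 1000, 300))
  g <- rep(c("a", "b"), each = 50)
  z <- standardize_by(x, g)
  for (gr in c("a", "b")) {
    expect_equal(mean(z[g == gr]), 0, tolerance = 1e-12)
    expect_equal(sd(z[g == gr]), 1, tolerance = 1e-12)
  }
  # global standardization preserves between-group mean differences
  zg <- standardize_by(x, NULL)
  expect_gt(mean(zg[g == "b"]) - mean(zg[g == "a"]), 1)
  expect_error(standardize_by(c(1, 1, 2, 2), c("a", "a", "b", "b")), "zero within-group SD",
               fixed = TRUE)
})

sim_lmm_data <- function(n_win = 6, per_win = 60, beta = 0.3, sd_win = 0.5,
                         sd_e = 1) {
  win <- rep(paste0("W", seq_len(n_win)), each = per_win)
  u <- rnorm(n_win, 0, sd_win)
  x <- rnorm(n_win * per_win)
  y <- beta * x + u[as.integer(factor(win))] + rnorm(n_win * per_win, 0, sd_e)
  data.frame(y = y, x = x, window_id = win)
}

test_that("LMM with zero random variance matches ordinary least squares", {
  set.seed(103)
  d <- sim_lmm_data(sd_win = 0)
  fit <- suppressWarnings(fit_lmm(y ~ x, d, random = "window_id"))
  ols <- lm(y ~ x, d)
  expect_equal(fit$coefficients$estimate, unname(coef(ols)), tolerance = 1e-4)
  expect_gte(fit$R2c, fit$R2m - 1e-12)
})

test_that("LMM recovers an injected slope and reports finite AICc", {
  set.seed(104)
  d <- sim_lmm_data(beta = 0.3)
  fit <- fit_lmm(y ~ x, d, random = "window_id")
  b <- fit$coefficients[fit$coefficients$term == "x", ]
  expect_lt(abs(b$estimate - 0.3), 3 * b$se)
  expect_true(is.finite(fit$AICc))
  expect_gt(fit$AICc, -2 * fit$logLik)       # AICc exceeds the deviance
})

sim_mlpe_data <- function(n_win = 6, pops = 8, beta = 0.4, sd_pop = 0.5,
                          sd_win = 0.3, sd_e = 1) {
  rows <- list()
  for (w in paste0("W", seq_len(n_win))) {
    ids <- paste0(w, "P", seq_len(pops))
    u <- rnorm(pops, 0, sd_pop); uw <- rnorm(1, 0, sd_win)
    pr <- t(utils::combn(pops, 2))
    x <- rnorm(nrow(pr))
    y <- beta * x + u[pr[, 1]] + u[pr[, 2]] + uw + rnorm(nrow(pr), 0, sd_e)
    rows[[w]] <- data.frame(window_id = w, pop_i = ids[pr[, 1]],
                            pop_j = ids[pr[, 2]], x = x, y = y)
  }
  do.call(rbind, rows)
}

test_that("MLPE implied covariance matches a hand-built shared-population incidence", {
  d <- data.frame(window_id = "W1",
                  pop_i = c("A", "A", "A", "B", "B", "C"),
                  pop_j = c("B", "C", "D", "C", "E", "D"))
  V <- mlpe_implied_covariance(d, s2_w = 0.5, s2_a = 1, s2_e = 2)
  # diagonal: s2_w + 2 s2_a + s2_e
  expect_equal(unname(diag(V)), rep(4.5, 6))
  # rows 1 (A-B) and 2 (A-C) share population A: s2_w + s2_a
  expect_equal(V[1, 2], 1.5)
  # rows 3 (A-D) and 5 (B-E) share none: s2_w only
  expect_equal(V[3, 5], 0.5)
  # correlation between one-shared pairs net of window: rho = s2_a/(2 s2_a + s2_e)
  expect_equal((V[1, 2] - 0.5) / (V[1, 1] - 0.5), 1 / 4)
})

test_that("MLPE at rho = 0 equals the independent-errors fit", {
  set.seed(105)
  d <- sim_mlpe_data(sd_pop = 0, sd_win = 0)
  fit <- fit_mlpe(y ~ x, d, with_window = FALSE)
  ols <- lm(y ~ x, d)
  expect_equal(fit$coefficients$estimate, unname(coef(ols)), tolerance = 1e-3)
  expect_lt(fit$rho, 0.05)
  # likelihood continuity: the MLPE logLik at its optimum cannot fall below
  # the independent-errors ML logLik
  expect_gte(fit$logLik, as.numeric(logLik(ols)) - 0.01)
})

test_that("MLPE recovers node-effect structure: rho > 0 and beta unbiased", {
  set.seed(106)
  d <- sim_mlpe_data(beta = 0.4, sd_pop = 0.7)
  fit <- fit_mlpe(y ~ x, d)
  b <- fit$coefficients[fit$coefficients$term == "x", ]
  expect_lt(abs(b$estimate - 0.4), 3 * b$se)
  expect_gt(fit$rho, 0.1)
  expect_lt(fit$rho, 0.5)                   # structural upper bound
  expect_gte(fit$R2c, fit$R2m)
})

test_that("all-subsets selection respects marginality, ties and retained terms", {
  set.seed(107)
  d <- sim_lmm_data()
  d$x2 <- rnorm(nrow(d)); d$x3 <- rnorm(nrow(d))
  sel <- all_subsets_aicc("y", optional = c("x", "x2", "x3"), data = d,
                          engine = "lmm", random = "window_id")
  expect_lte(nrow(sel$table), 8)            # 2^3 candidates
  expect_true(all(grepl("y ~", sel$table$formula)))
  # the active predictor x survives selection
  expect_true("x" %in% attr(terms(sel$best$formula), "term.labels"))
  # refitting the selected model reproduces its AICc exactly
  refit <- fit_lmm(sel$best$formula, d, random = "window_id")
  expect_equal(refit$AICc, sel$best$AICc)
  # an interaction never enters without its main effects
  d$g <- factor(rep(c("u", "v"), length.out = nrow(d)))
  sel2 <- all_subsets_aicc("y", optional = c("x", "x:g"), retained = "g",
                           data = d, engine = "lmm", random = "window_id")
  for (f in sel2$table$formula) {
    tl <- attr(terms(as.formula(f)), "term.labels")
    if (any(grepl(":", tl))) expect_true(all(c("x", "g") %in% tl))
  }
})

test_that("selection keeps the active predictor in most replicates", {
  set.seed(108)
  hits <- 0; n_rep <- 100
  for (r in seq_len(n_rep)) {
    d <- sim_lmm_data(n_win = 6, per_win = 20, beta = 0.4)
    d$x2 <- rnorm(nrow(d)); d$x3 <- rnorm(nrow(d))
    sel <- tryCatch(suppressWarnings(
      all_subsets_aicc("y", optional = c("x", "x2", "x3"), data = d,
                       engine = "lmm", random = "window_id")),
      error = function(e) NULL)
    if (!is.null(sel) &&
        "x" %in% attr(terms(sel$best$formula), "term.labels")) hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.8)
})

test_that("generalized VIF matches closed forms and car::vif", {
  set.seed(109)
  n <- 500
  x1 <- rnorm(n); x2 <- rnorm(n)
  d <- data.frame(y = rnorm(n), x1 = x1, x2 = x2)
  v <- generalized_vif(y ~ x1 + x2, d)
  expect_equal(v$GVIF, c(1, 1), tolerance = 0.05)       # orthogonal predictors
  # two predictors with correlation r: GVIF = 1/(1 - r^2)
  x3 <- 0.9 * scale(x1) + sqrt(1 - 0.81) * rnorm(n)
  d$x3 <- as.numeric(x3)
  v2 <- generalized_vif(y ~ x1 + x3, d)
  r <- cor(d$x1, d$x3)
  expect_equal(v2$GVIF, rep(1 / (1 - r^2), 2), tolerance = 1e-6)
  expect_equal(v2$GVIF[1], 1 / (1 - 0.81), tolerance = 0.6)
  # duplicated predictor is aliased
  d$x1b <- d$x1
  expect_error(generalized_vif(y ~ x1 + x1b, d), "aliased")
  # cross-check against the established implementation on a factor model
  d$g <- factor(sample(letters[1:3], n, replace = TRUE))
  mine <- generalized_vif(y ~ x1 + x3 + g, d)
  ref <- car::vif(lm(y ~ x1 + x3 + g, d))
  expect_equal(mine$GVIF, unname(ref[, "GVIF"]), tolerance = 1e-6)
})
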