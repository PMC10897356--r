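#' Simulation configuration
#'
#' Defaults reproduce the study design the package targets: six 5 x 5 km
#' landscape windows, about ten populations per window, habitat ages spanning
#' 18-338 years with a generation time of 10 years (age of first flowering),
#' 6-9 microsatellite loci, about 20 sampled individuals per population with
#' missing genotypes and clonal duplicates, and census size positively
#' coupled to age.
#'
#' @param n_windows landscape windows (default 6).
#' @param window_size window side length in metres (default 5000).
#' @param pops_per_window populations per window (default 10).
#' @param age_range habitat age range in years (default c(18, 338)).
#' @param generation_time years per generation (default 10).
#' @param n_loci microsatellite loci (default 7; the study panels span 6-9).
#' @param allele_states size of the stepwise-mutation allele ladder
#'   (default 14 repeat states per locus).
#' @param ancestral_dirichlet concentration of the symmetric Dirichlet the
#'   ancestral allele frequencies are drawn from (default 0.4; smaller means
#'   fewer common alleles).
#' @param mutation_rate stepwise mutations per gene copy per generation
#'   (default 5e-4).
#' @param founder_count diploid founders per colonization event (default 10).
#' @param migration_rate maximum per-generation immigrant fraction
#'   (default 0.05); realized pairwise rates decay with distance.
#' @param kernel_scale migration/founder distance-kernel scale in metres
#'   (default 500).
#' @param size_coupling slope c of log(size) = a + c log(age) + noise
#'   (default 0.6; 0 decouples size from age).
#' @param size_log_mean,size_log_sd location/spread of log census size
#'   (defaults log(1500), 0.7).
#' @param missing_rate per sample-locus missing-genotype rate (default 0.02).
#' @param clone_rate fraction of samples replaced by within-population clonal
#'   duplicates (default 0.1).
#' @param sample_size individuals sampled per population (default 20).
#' @param ne_scale,ne_min,ne_max map census size to effective size:
#'   Ne = clamp(ne_scale * size, ne_min, ne_max) (defaults 0.05, 10, 150).
#' @param min_pop_spacing minimum distance between populations in metres
#'   (default 200).
#' @param age_spatial_corr strength (0-1) of spatial clustering of habitat
#'   age within a window (default 0.6); 0 places ages at random.
#' @param seed RNG seed; mandatory for reproducibility.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(n_windows = 6L, window_size = 5000,
                              pops_per_window = 10L, age_range = c(18, 338),
                              generation_time = 10, n_loci = 7L,
                              allele_states = 14L, ancestral_dirichlet = 0.4,
                              mutation_rate = 5e-4, founder_count = 10L,
                              migration_rate = 0.05, kernel_scale = 500,
                              size_coupling = 0.6, size_log_mean = log(1500),
                              size_log_sd = 0.7, missing_rate = 0.02,
                              clone_rate = 0.1, sample_size = 20L,
                              ne_scale = 0.05, ne_min = 10L, ne_max = 150L,
                              min_pop_spacing = 200, age_spatial_corr = 0.6,
                              seed) {
  if (missing(seed)) stop("simulation_config: seed is mandatory")
  cfg <- as.list(environment())
  stopifnot(cfg$missing_rate >= 0, cfg$missing_rate <= 1,
            cfg$clone_rate >= 0, cfg$clone_rate <= 1,
            cfg$migration_rate >= 0, cfg$migration_rate <= 1,
            cfg$mutation_rate >= 0, cfg$mutation_rate <= 1,
            diff(cfg$age_range) >= 0, cfg$age_range[1] > 0)
  structure(cfg, class = "simulation_config")
}

#' Named simulation scenarios
#'
#' `paper_scale` is the default study design; `null` is the placebo (all
#' ages equal, size decoupled from age: no statistic should show an age
#' trend); `founder_effect` founds young populations from 2 diploids;
#' `age_gradient` combines few founders with low migration so the age signal
#' in diversity is strong.
#'
#' @param name scenario name.
#' @param seed RNG seed.
#' @param ... overrides passed on to [simulation_config()].
#' @return a `simulation_config`.
#' @export
scenario_config <- function(name = c("paper_scale", "null", "founder_effect",
                                     "age_gradient"), seed, ...) {
  name <- match.arg(name)
  base <- switch(name,
    paper_scale = list(),
    null = list(age_range = c(100, 100), size_coupling = 0),
    founder_effect = list(founder_count = 2L),
    age_gradient = list(founder_count = 2L, migration_rate = 0.01,
                        size_coupling = 0.8))
  do.call(simulation_config, utils::modifyList(c(base, list(seed = seed)),
                                               list(...)))
}

#' Generate a synthetic landscape
#'
#' Uniform population coordinates inside each window with a minimum spacing,
#' ages sampled log-uniformly across the configured range (always including
#' both endpoints, mirroring the sampling criterion that the full age
#' spectrum be represented), census size log-linearly coupled to age, and
#' patch ids occasionally shared between populations >= 200 m apart.
#'
#' @param config a [simulation_config()].
#' @return list with `attrs` (data.frame `population_id`, `window_id`,
#'   `patch_id`, `age`, `size`, `x`, `y`) and `truth` (founding generations,
#'   coupling, seed echo).
#' @export
generate_landscape <- function(config) {
  set.seed(config$seed)
  rows <- list()
  for (w in seq_len(config$n_windows)) {
    n <- config$pops_per_window
    xy <- matrix(NA_real_, n, 2)
    for (i in seq_len(n)) {
      for (try in 1:200) {
        cand <- stats::runif(2, 0, config$window_size)
        if (i == 1L || all(sqrt(colSums((t(xy[seq_len(i - 1L), , drop = FALSE]) -
                                         cand)^2)) >= config$min_pop_spacing)) {
          xy[i, ] <- cand; break
        }
      }
      if (any(is.na(xy[i, ])))
        stop("could not place populations with the required spacing")
    }
    lo <- log(config$age_range[1]); hi <- log(config$age_range[2])
    if (hi > lo) {
      q <- (seq_len(n) - 1) / max(1, n - 1)              # cover the full range
      ages <- round(exp(lo + q * (hi - lo) +
                        stats::runif(n, -0.1, 0.1) * (hi - lo)))
      ages <- pmin(pmax(ages, config$age_range[1]), config$age_range[2])
      ages[which.min(ages)] <- config$age_range[1]
      ages[which.max(ages)] <- config$age_range[2]
    } else {
      ages <- rep(config$age_range[1], n)
    }
    # ages cluster in space (old forest cores vs. recent afforestation
    # fringes): assign the age set along a random spatial gradient with
    # noise, so age — and through it size — carries over into neighbourhood
    # connectivity
    dir <- stats::runif(1, 0, 2 * pi)
    grad <- xy[, 1] * cos(dir) + xy[, 2] * sin(dir)
    score <- config$age_spatial_corr * scale(grad) +
      (1 - config$age_spatial_corr) * stats::rnorm(n)
    ages <- sort(ages)[rank(score, ties.method = "first")]
    lsize <- config$size_log_mean +
      config$size_coupling * (log(ages) - mean(log(ages))) +
      stats::rnorm(n, 0, config$size_log_sd)
    patch <- paste0("W", w, "F", seq_len(n))
    for (i in seq_len(n)[-1]) {                           # some shared patches, >= 200 m apart
      d <- sqrt(sum((xy[i, ] - xy[i - 1L, ])^2))
      if (d >= 200 && d <= 1500 && stats::runif(1) < 0.2) patch[i] <- patch[i - 1L]
    }
    rows[[w]] <- data.frame(
      population_id = paste0("W", w, "P", seq_len(n)),
      window_id = paste0("W", w), patch_id = patch,
      age = ages, size = round(exp(lsize)), x = xy[, 1], y = xy[, 2],
      stringsAsFactors = FALSE)
  }
  attrs <- do.call(rbind, rows)
  truth <- list(founding_generation = stats::setNames(
                  pmax(1L, round(attrs$age / config$generation_time)),
                  attrs$population_id),
                size_coupling = config$size_coupling, seed = config$seed)
  list(attrs = attrs, truth = truth)
}

# symmetric (doubly stochastic) per-window migration matrix: off-diagonals
# proportional to exp(-d/kernel), scaled so the largest total immigration
# fraction equals migration_rate; symmetry conserves metapopulation allele
# frequencies in expectation
migration_matrix <- function(d, rate, kernel) {
  n <- nrow(d)
  W <- exp(-d / kernel); diag(W) <- 0
  W <- if (rate > 0 && max(rowSums(W)) > 0) W * (rate / max(rowSums(W)))
       else W * 0
  diag(W) <- 1 - rowSums(W)
  W
}

smm_shift <- function(p, mu) {
  if (mu == 0) return(p)
  K <- length(p)
  up <- c(0, p[-K]); down <- c(p[-1], 0)
  out <- (1 - mu) * p + (mu / 2) * (up + down)
  out[1] <- out[1] + (mu / 2) * p[1]          # reflecting ladder boundaries
  out[K] <- out[K] + (mu / 2) * p[K]
  out
}

#' Simulate microsatellite genotypes on a landscape
#'
#' Forward-in-time Wright-Fisher simulation per window: the oldest
#' populations are initialized by binomial sampling from a window-level
#' ancestral gene pool at mutation-drift-equilibrium-like frequencies
#' (symmetric Dirichlet over a stepwise allele ladder); each younger
#' population is founded at its age (in generations) by `founder_count`
#' diploids drawn from extant populations weighted by exp(-d/kernel);
#' thereafter generations apply distance-kernel migration, stepwise mutation
#' (one repeat unit up or down) and multinomial drift at 2 Ne gene copies.
#' At present, min(`sample_size`, Ne) individuals are sampled per population
#' under Hardy-Weinberg; missing genotypes and within-population clonal
#' duplicates are injected at the configured rates (clones copy the full
#' row, including its missingness pattern).
#'
#' @param attrs,truth from [generate_landscape()].
#' @param config the same [simulation_config()].
#' @return a [genotype_table()]; attribute `truth` carries the augmented
#'   truth record (migration matrices, ancestral frequencies).
#' @export
simulate_genotypes <- function(attrs, truth, config) {
  set.seed(config$seed + 1L)
  allele_sizes <- 100L + 2L * seq_len(config$allele_states)
  meta_rows <- list(); allele_rows <- list()
  truth$migration <- list()
  for (w in unique(attrs$window_id)) {
    a <- attrs[attrs$window_id == w, , drop = FALSE]
    n_pop <- nrow(a)
    Ne <- pmin(pmax(round(config$ne_scale * a$size), config$ne_min), config$ne_max)
    t_found <- pmax(1L, round(a$age / config$generation_time))
    d <- as.matrix(stats::dist(cbind(a$x, a$y)))
    M <- migration_matrix(d, config$migration_rate, config$kernel_scale)
    truth$migration[[w]] <- M
    K <- config$allele_states
    anc <- replicate(config$n_loci, {
      g <- stats::rgamma(K, shape = config$ancestral_dirichlet)
      g / sum(g)
    })                                                   # K x n_loci
    T0 <- max(t_found)
    # freq[[l]] is n_pop x K; NA rows = not yet founded
    freq <- lapply(seq_len(config$n_loci), function(l)
      matrix(NA_real_, n_pop, K))
    for (i in which(t_found == T0)) {
      for (l in seq_len(config$n_loci))
        freq[[l]][i, ] <- as.numeric(stats::rmultinom(1, 2 * Ne[i], anc[, l])) / (2 * Ne[i])
    }
    if (T0 >= 1) for (t in seq(T0 - 1L, 0L)) {
      extant <- which(t_found >= t + 1L)                 # exist at time t + 1
      for (l in seq_len(config$n_loci)) {
        P <- freq[[l]]
        if (length(extant) > 1L) {
          Ms <- M[extant, extant, drop = FALSE]
          diag(Ms) <- diag(Ms) + (1 - rowSums(Ms))       # renormalize to extant pops
          P[extant, ] <- Ms %*% P[extant, , drop = FALSE]
        }
        for (i in extant) {
          p <- smm_shift(P[i, ], config$mutation_rate)
          P[i, ] <- as.numeric(stats::rmultinom(1, 2 * Ne[i], p)) / (2 * Ne[i])
        }
        freq[[l]] <- P
      }
      newly <- which(t_found == t)                       # colonization events at time t
      for (i in newly) {
        sources <- extant
        wgt <- exp(-d[i, sources] / config$kernel_scale)
        if (sum(wgt) == 0) {                             # no reachable source: nearest pop
          warning("no reachable source for founding of ", a$population_id[i],
                  "; using nearest population")
          wgt <- as.numeric(seq_along(sources) == which.min(d[i, sources]))
        }
        src <- sources[sample.int(length(sources), config$founder_count,
                                  replace = TRUE, prob = wgt)]
        for (l in seq_len(config$n_loci)) {
          copies <- numeric(config$allele_states)
          for (s in src) {
            copies <- copies + as.numeric(stats::rmultinom(1, 2, freq[[l]][s, ]))
          }
          freq[[l]][i, ] <- copies / sum(copies)
        }
      }
    }
    # present-day sampling under HWE
    for (i in seq_len(n_pop)) {
      n_s <- min(config$sample_size, Ne[i])
      g <- matrix(NA_integer_, n_s, 2L * config$n_loci)
      for (l in seq_len(config$n_loci)) {
        p <- freq[[l]][i, ]
        copies <- matrix(sample.int(K, 2L * n_s, replace = TRUE, prob = p), n_s, 2L)
        g[, (l - 1L) * 2L + 1:2] <- allele_sizes[copies]
      }
      # missing genotypes (whole-locus failures)
      miss <- matrix(stats::runif(n_s * config$n_loci) < config$missing_rate,
                     n_s, config$n_loci)
      for (l in seq_len(config$n_loci)) g[miss[, l], (l - 1L) * 2L + 1:2] <- NA_integer_
      # clonal duplicates: copy full rows within the population
      n_clone <- floor(config$clone_rate * n_s)
      if (n_clone > 0 && n_s >= 2L) {
        victims <- sample.int(n_s, n_clone)
        for (v in victims) {
          donor <- sample(setdiff(seq_len(n_s), v), 1L)
          g[v, ] <- g[donor, ]
        }
      }
      meta_rows[[length(meta_rows) + 1L]] <- data.frame(
        sample_id = paste0(a$population_id[i], "_s", seq_len(n_s)),
        population_id = a$population_id[i], window_id = w,
        patch_id = a$patch_id[i], stringsAsFactors = FALSE)
      allele_rows[[length(allele_rows) + 1L]] <- g
    }
  }
  tab <- genotype_table(do.call(rbind, meta_rows), do.call(rbind, allele_rows),
                        loci = paste0("L", seq_len(config$n_loci)))
  attr(tab, "truth") <- truth
  tab
}

#' Simulate a full dataset (landscape + genotypes)
#'
#' @param config a [simulation_config()].
#' @return list `table` (genotype_table), `attrs`, `truth`.
#' @export
simulate_dataset <- function(config) {
  land <- generate_landscape(config)
  tab <- simulate_genotypes(land$attrs, land$truth, config)
  list(table = tab, attrs = land$attrs, truth = attr(tab, "truth"))
}

#' Write simulator output in the pipeline's input formats
#'
#' Emits the tabular allele CSV, the same genotypes as GenePop, the
#' population attribute CSV, the scenario configuration as YAML and the
#' truth record as JSON.
#'
#' @param table a `genotype_table`.
#' @param attrs population attribute data.frame.
#' @param path output directory (created if needed).
#' @param config optional `simulation_config` to serialize.
#' @param truth optional truth record to serialize.
#' @return named character vector of the files written.
#' @export
emit_fixture_files <- function(table, attrs, path, config = NULL, truth = NULL) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  files <- c(alleles_csv = file.path(path, "alleles.csv"),
             genepop = file.path(path, "alleles.gen"),
             attrs_csv = file.path(path, "populations.csv"))
  write_allele_csv(table, files["alleles_csv"])
  write_genepop(table, files["genepop"])
  utils::write.csv(attrs, files["attrs_csv"], row.names = FALSE)
  if (!is.null(config)) {
    files["config_yaml"] <- file.path(path, "scenario.yaml")
    yaml::write_yaml(unclass(config), files["config_yaml"])
  }
  if (!is.null(truth)) {
    files["truth_json"] <- file.path(path, "truth.json")
    truth$migration <- lapply(truth$migration, function(m) round(unclass(m), 6))
    jsonlite::write_json(truth, files["truth_json"], auto_unbox = TRUE,
                         digits = NA, force = TRUE)
  }
  files
}
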