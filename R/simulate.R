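# Synthetic AML-like cohort generator with known ground truth. Every
# downstream stage (screening, signature, stacking, final model, evaluation)
# is exercised against data from here, so the defaults emulate the cohort
# structure the pipeline targets: log2-scale expression with per-gene means
# in 5-12 and SDs well below 2.3, a 10-gene seed panel, blocks of genes
# rank-correlated with the panel, exponential-baseline Cox survival over a
# sparse causal subset plus clinical effects, independent censoring around
# 27%, and FAB/ELN2017 clinical covariates with MCAR missingness.

#' Default cuproptosis seed panel
#'
#' The 10 copper-death-related genes commonly used as the seed panel for
#' correlation screening.
#' @export
cuproptosis_seed_genes <- c("FDX1", "LIAS", "LIPT1", "DLD", "DLAT",
                            "PDHA1", "PDHB", "MTF1", "GLS", "CDKN2A")

.default_fab_probs <- c(M0 = 22, M1 = 113, M2 = 164, M3 = 26, M4 = 121,
                        M5 = 66, M6 = 22, M7 = 3) / 537
.default_fab_betas <- c(M0 = 0, M1 = 0, M2 = 0, M3 = -0.1, M4 = 0,
                        M5 = 0.1, M6 = 0.2, M7 = 0.3)

#' Configure a synthetic survival cohort
#'
#' Parameters define the ground-truth data-generating process: a latent
#' Gaussian factor per seed gene induces the rank-correlated gene block,
#' survival times follow a Cox model with exponential baseline over a sparse
#' causal gene subset plus clinical effects, and censoring times are
#' exponential with a rate calibrated to the target censoring fraction.
#'
#' @param n_samples,n_genes Cohort dimensions (`n_genes` counts non-seed
#'   genes; seed genes are added on top).
#' @param n_seed_genes Size of the seed panel (default 10).
#' @param n_correlated Genes constructed to rank-correlate with a seed gene
#'   (population Spearman about 0.5-0.8).
#' @param n_causal Genes with nonzero true log-hazard coefficients; drawn
#'   from the correlated block.
#' @param true_beta_range Magnitude bounds of causal coefficients; signs
#'   alternate.
#' @param baseline_hazard Exponential baseline rate per day, applied to the
#'   mean-centred linear predictor (default `log(2)/353`, i.e. a median
#'   survival near 353 days for an average-risk patient).
#' @param censoring_rate Target censored fraction in `[0, 1)`.
#' @param clinical_effects List with `age_beta` (log-hazard per year) and
#'   `fab_betas` (named per-category log-hazards).
#' @param missing_frac Fraction of clinical cells (age, fab, eln2017) set
#'   missing completely at random.
#' @param rng_seed Integer seed; identical seeds reproduce the cohort
#'   bit-for-bit.
#'
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_samples = 553, n_genes = 500, n_seed_genes = 10,
                       n_correlated = 100, n_causal = 5,
                       true_beta_range = c(0.3, 0.8),
                       baseline_hazard = log(2) / 353,
                       censoring_rate = 0.266,
                       clinical_effects = list(age_beta = 0.02,
                                               fab_betas = .default_fab_betas),
                       missing_frac = 0.03, rng_seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
              n_seed_genes = as.integer(n_seed_genes),
              n_correlated = as.integer(n_correlated),
              n_causal = as.integer(n_causal),
              true_beta_range = as.numeric(true_beta_range),
              baseline_hazard = baseline_hazard,
              censoring_rate = censoring_rate,
              clinical_effects = clinical_effects,
              missing_frac = missing_frac, rng_seed = as.integer(rng_seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  chk <- function(ok, what) {
    if (!ok) stop("invalid simulation config: ", what, call. = FALSE)
  }
  chk(cfg$n_samples >= 1, "n_samples must be positive")
  chk(cfg$n_genes >= 1, "n_genes must be positive")
  chk(cfg$n_seed_genes >= 1, "n_seed_genes must be positive")
  chk(cfg$n_correlated <= cfg$n_genes,
      "n_correlated must not exceed n_genes (the non-seed gene count)")
  chk(cfg$n_causal <= cfg$n_correlated,
      "n_causal must not exceed n_correlated")
  chk(length(cfg$true_beta_range) == 2 && all(cfg$true_beta_range > 0) &&
        cfg$true_beta_range[1] <= cfg$true_beta_range[2],
      "true_beta_range must be increasing positive magnitude bounds")
  chk(cfg$baseline_hazard > 0, "baseline_hazard must be positive")
  chk(cfg$censoring_rate >= 0 && cfg$censoring_rate < 1,
      "censoring_rate must lie in [0, 1)")
  chk(cfg$missing_frac >= 0 && cfg$missing_frac < 1,
      "missing_frac must lie in [0, 1)")
  chk(is.numeric(cfg$clinical_effects$age_beta),
      "clinical_effects$age_beta must be numeric")
  invisible(cfg)
}

#' Simulate an expression + survival cohort with known ground truth
#'
#' @param config A [sim_config()].
#' @return A list of class `"sim_cohort"` with elements
#'   * `expression`: genes x samples log2-scale matrix (seed genes included),
#'   * `outcome`: tibble `sample_id`, `time` (days), `event`,
#'   * `clinical`: tibble `sample_id`, `age`, `fab`, `eln2017`
#'     (with `NA` for missing cells),
#'   * `truth`: ground truth — `causal_genes`, `true_beta` (named),
#'     `true_lp` (the exact inner product of `true_beta` with causal-gene
#'     expression plus clinical effects), `seed_assignment`, `gene_ids`,
#'     `clinical_effects`, `censoring_rate_realized`.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_samples = 60, n_genes = 40,
#'                                      n_correlated = 10, n_causal = 2))
#' dim(cohort$expression)
#' @export
simulate_cohort <- function(config = sim_config()) {
  validate_sim_config(config)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()), add = TRUE)
  set.seed(config$rng_seed)

  n <- config$n_samples
  sample_ids <- sprintf("S%04d", seq_len(n))
  n_seed <- config$n_seed_genes
  seed_ids <- if (n_seed <= length(cuproptosis_seed_genes)) {
    cuproptosis_seed_genes[seq_len(n_seed)]
  } else {
    c(cuproptosis_seed_genes,
      sprintf("SEED%02d", seq_len(n_seed - length(cuproptosis_seed_genes))))
  }
  corr_ids <- sprintf("CORR%04d", seq_len(config$n_correlated))
  n_noise <- config$n_genes - config$n_correlated
  noise_ids <- if (n_noise > 0) sprintf("GENE%04d", seq_len(n_noise)) else
    character(0)
  gene_ids <- c(seed_ids, corr_ids, noise_ids)

  # per-gene location/scale in the plausible log2 range
  n_total <- length(gene_ids)
  mu <- stats::runif(n_total, 5, 12)
  sigma <- stats::runif(n_total, 0.3, 1.5)
  names(mu) <- names(sigma) <- gene_ids

  # latent factor per seed gene; seed gene expression is a pure read-out
  factors <- matrix(stats::rnorm(n_seed * n), n_seed, n)
  expr <- matrix(NA_real_, n_total, n,
                 dimnames = list(gene_ids, sample_ids))
  expr[seq_len(n_seed), ] <- mu[seq_len(n_seed)] +
    sigma[seq_len(n_seed)] * factors

  # correlated block: loading * factor + noise, Pearson loading 0.52-0.82
  # (population Spearman ~ 0.5-0.8 under bivariate normality)
  seed_assignment <- stats::setNames(
    sample(seq_len(n_seed), config$n_correlated, replace = TRUE), corr_ids)
  if (config$n_correlated > 0) {
    load <- stats::runif(config$n_correlated, 0.52, 0.82)
    eps <- matrix(stats::rnorm(config$n_correlated * n),
                  config$n_correlated, n)
    z <- load * factors[seed_assignment, , drop = FALSE] +
      sqrt(1 - load^2) * eps
    expr[corr_ids, ] <- mu[corr_ids] + sigma[corr_ids] * z
  }
  if (n_noise > 0) {
    expr[noise_ids, ] <- mu[noise_ids] + sigma[noise_ids] *
      matrix(stats::rnorm(n_noise * n), n_noise, n)
  }

  # causal genes and true coefficients (alternating signs)
  causal <- if (config$n_causal > 0) corr_ids[seq_len(config$n_causal)] else
    character(0)
  true_beta <- stats::setNames(numeric(length(causal)), causal)
  if (length(causal)) {
    mag <- stats::runif(length(causal), config$true_beta_range[1],
                        config$true_beta_range[2])
    true_beta[] <- mag * rep_len(c(1, -1), length(causal))
  }

  # clinical covariates
  age <- pmin(pmax(stats::rnorm(n, 54.9, 14.81), 18), 90)
  fab_levels <- names(.default_fab_probs)
  fab <- sample(fab_levels, n, replace = TRUE, prob = .default_fab_probs)
  eln_levels <- c("Favorable", "Intermediate", "Adverse")
  eln_base <- c(0.225, 0.566, 0.209)
  eln <- vapply(age, function(a) {
    w <- eln_base * c(exp(-0.03 * (a - 55)), 1, exp(0.03 * (a - 55)))
    sample(eln_levels, 1, prob = w / sum(w))
  }, character(1))

  fb <- config$clinical_effects$fab_betas
  fab_eff <- if (is.null(fb)) numeric(n) else {
    unname(fb[fab])
  }
  fab_eff[is.na(fab_eff)] <- 0
  clin_eff <- config$clinical_effects$age_beta * age + fab_eff

  # true linear predictor: exact inner product plus clinical effects
  true_lp <- if (length(causal)) {
    drop(crossprod(expr[causal, , drop = FALSE], true_beta)) + clin_eff
  } else clin_eff
  names(true_lp) <- sample_ids

  # survival: exponential baseline over the centred lp (the centring
  # constant is absorbed into the baseline; Cox-invariant)
  lp_c <- true_lp - mean(true_lp)
  hazard <- config$baseline_hazard * exp(lp_c)
  t_event <- stats::rexp(n, rate = hazard)

  # censoring rate calibrated in closed form: P(C < T_i) = r / (r + h_i)
  if (config$censoring_rate > 0) {
    target <- config$censoring_rate
    fr <- function(r) mean(r / (r + hazard)) - target
    r_cens <- stats::uniroot(fr, lower = 1e-12, upper = 1e6,
                             tol = 1e-12)$root
    t_cens <- stats::rexp(n, rate = r_cens)
  } else {
    t_cens <- rep(Inf, n)
  }
  time <- pmin(t_event, t_cens)
  event <- as.integer(t_event <= t_cens)

  clinical <- tibble::tibble(
    sample_id = sample_ids, age = age,
    fab = factor(fab, levels = fab_levels),
    eln2017 = factor(eln, levels = eln_levels)
  )
  if (config$missing_frac > 0) {
    for (col in c("age", "fab", "eln2017")) {
      holes <- stats::runif(n) < config$missing_frac
      clinical[[col]][holes] <- NA
    }
  }

  structure(list(
    expression = expr,
    outcome = tibble::tibble(sample_id = sample_ids, time = time,
                             event = event),
    clinical = clinical,
    truth = list(
      causal_genes = causal, true_beta = true_beta, true_lp = true_lp,
      seed_genes = seed_ids, seed_assignment = seed_assignment,
      gene_ids = gene_ids, clinical_effects = config$clinical_effects,
      baseline_hazard = config$baseline_hazard,
      censoring_rate_realized = mean(event == 0),
      submodel_informativeness = NULL
    ),
    config = config
  ), class = "sim_cohort")
}

#' Simulate "published" sub-model signatures of graded informativeness
#'
#' Stands in for externally published prognostic signatures entering the
#' stacking ensemble. Informativeness 1 reproduces the true causal signature
#' exactly; informativeness 0 is a disjoint random gene set with random
#' coefficients; intermediate values mix the two.
#'
#' @param truth The `truth` element of a [simulate_cohort()] result.
#' @param n_submodels Number of signatures (>= 1).
#' @param informativeness Numeric vector in `[0, 1]`, recycled to
#'   `n_submodels`.
#' @param rng_seed Integer seed.
#' @return A list of [gene_signature] objects, each with an
#'   `informativeness` attribute.
#' @export
simulate_submodel_signatures <- function(truth, n_submodels,
                                         informativeness,
                                         rng_seed = 1L) {
  if (n_submodels < 1) stop("n_submodels must be at least 1", call. = FALSE)
  informativeness <- rep(as.numeric(informativeness),
                         length.out = n_submodels)
  if (any(informativeness < 0 | informativeness > 1)) {
    stop("informativeness values must lie in [0, 1]", call. = FALSE)
  }
  causal <- truth$causal_genes
  k <- length(causal)
  if (k == 0) stop("ground truth has no causal genes", call. = FALSE)
  pool <- setdiff(truth$gene_ids, c(causal, truth$seed_genes))
  beta_sd <- stats::sd(truth$true_beta)
  if (!is.finite(beta_sd) || beta_sd == 0) beta_sd <- mean(abs(truth$true_beta))

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()), add = TRUE)
  set.seed(rng_seed)

  out <- vector("list", n_submodels)
  for (m in seq_len(n_submodels)) {
    a <- informativeness[m]
    n_true <- round(a * k)
    genes_true <- causal[seq_len(n_true)]
    n_rand <- k - n_true
    genes_rand <- sample(pool, n_rand)
    sig <- gene_signature(
      genes = c(genes_true, genes_rand),
      betas = c(unname(truth$true_beta[genes_true]),
                stats::rnorm(n_rand, 0, beta_sd)),
      provenance = sprintf("synthetic sub-model %d (informativeness %.2f)",
                           m, a)
    )
    attr(sig, "informativeness") <- a
    out[[m]] <- sig
  }
  out
}

#' Write a simulated cohort to the standard pipeline input files
#'
#' Produces `expression.tsv` (genes x samples), `clinical.tsv`
#' (`sample_id`, `time_days`, `event`, `age`, `fab`, `eln2017`) and
#' `ground_truth.json` under `dir`.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_expression(cohort$expression, file.path(dir, "expression.tsv"))
  clin <- dplyr::left_join(cohort$outcome, cohort$clinical, by = "sample_id")
  clin <- dplyr::rename(clin, time_days = "time")
  readr::write_tsv(clin, file.path(dir, "clinical.tsv"))
  truth <- cohort$truth
  truth$seed_assignment <- as.list(truth$seed_assignment)
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
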