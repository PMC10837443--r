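# Sparse Cox gene-signature construction: spike-and-slab lasso EM with
# CVPL-selected spike scale, stepwise AIC refinement, the linear risk score,
# and the proportional-hazards check.

#' Construct a gene signature
#'
#' An ordered gene list with Cox log-hazard coefficients. Zero coefficients
#' are dropped (a signature retains only active genes).
#'
#' @param genes Character vector of gene identifiers.
#' @param betas Numeric coefficients aligned to `genes`.
#' @param provenance Free-text origin of the signature.
#' @return An object of class `"gene_signature"`.
#' @export
gene_signature <- function(genes, betas, provenance = "unspecified") {
  if (length(genes) != length(betas)) {
    stop("genes and betas must have equal length", call. = FALSE)
  }
  if (anyDuplicated(genes)) stop("duplicate genes in signature",
                                 call. = FALSE)
  keep <- betas != 0
  genes <- genes[keep]; betas <- betas[keep]
  if (length(genes) < 1) stop("signature must retain at least one gene with ",
                              "a nonzero coefficient", call. = FALSE)
  structure(list(genes = as.character(genes), betas = as.numeric(betas),
                 provenance = provenance), class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat("Gene signature (", length(x$genes), " genes) — ", x$provenance,
      "\n", sep = "")
  print(tibble::tibble(gene = x$genes, coefficient = x$betas))
  invisible(x)
}

#' The packaged published 14-gene cuproptosis-related signature
#'
#' Loads the published 14-gene AML risk-score coefficients shipped with the
#' package (TSV under `extdata`).
#' @return A [gene_signature].
#' @examples
#' sig <- published_crg_signature()
#' risk_score(sig, diag(14) * 0 + diag(14) |>
#'   `dimnames<-`(list(sig$genes, paste0("P", 1:14))))
#' @export
published_crg_signature <- function() {
  path <- system.file("extdata", "crg14_signature.tsv",
                      package = "stacksurv", mustWork = TRUE)
  read_signature(path, provenance = "published 14-gene CRG signature")
}

# ---- spike-and-slab lasso ------------------------------------------------

# One EM fit at fixed spike scale s0. E-step: posterior slab probability of
# each coefficient under the double-exponential mixture; M-step: weighted-L1
# Cox fit with per-coefficient scale S_j = (1 - p_j) s0 + p_j s1, penalty
# 1/S_j on |beta_j|.
sslasso_em <- function(X, time, event, s0, s1, theta, beta_init = NULL,
                       tol = 1e-4, max_iter = 200, cd_tol = 1e-8,
                       cd_max_outer = 100) {
  p <- ncol(X)
  beta <- if (is.null(beta_init)) rep(0, p) else beta_init
  log_odds_prior <- log((1 - theta) / theta)
  converged <- FALSE
  fit <- NULL
  for (it in seq_len(max_iter)) {
    # E-step (in log space; DE(b; s) = exp(-|b|/s) / (2s))
    ld0 <- -log(2 * s0) - abs(beta) / s0
    ld1 <- -log(2 * s1) - abs(beta) / s1
    p_slab <- 1 / (1 + exp(log_odds_prior + ld0 - ld1))
    S <- (1 - p_slab) * s0 + p_slab * s1
    fit <- cox_lasso_cd(X, time, event, lambda = 1 / S, beta_init = beta,
                        tol = cd_tol, max_outer = cd_max_outer)
    delta <- max(abs(fit$beta - beta))
    beta <- unname(fit$beta)
    if (delta < tol) { converged <- TRUE; break }
  }
  list(beta = stats::setNames(beta, colnames(X)), loglik = fit$loglik,
       p_slab = p_slab, converged = converged, iterations = it)
}

# Event-stratified fold assignment used by the CVPL loop and the stacking
# module (exported there as make_folds with extra guarantees).
.stratified_folds <- function(event, K) {
  fold <- integer(length(event))
  for (g in list(which(event == 1), which(event == 0))) {
    if (length(g)) fold[g] <- sample(rep_len(seq_len(K), length(g)))
  }
  fold
}

#' Spike-and-slab lasso Cox variable selection
#'
#' EM coordinate-ascent over the penalized Cox partial likelihood with a
#' per-coefficient mixture double-exponential prior (narrow spike scale
#' `s0`, wide slab scale `s1`, prior inclusion probability `theta`). The
#' spike scale is chosen from `s0_grid` by maximizing the mean
#' cross-validated partial log-likelihood (CVPL, Verweij-van Houwelingen:
#' \eqn{\sum_k l(\hat\beta_{(-k)}; \mathrm{full}) -
#' l(\hat\beta_{(-k)}; \mathrm{full} \setminus k)}) over
#' `cv_replicates` repeats of `cv_folds` event-stratified folds.
#'
#' @param expr_subset Genes x samples matrix of candidate genes (>= 2).
#' @param outcome Survival outcome.
#' @param s0_grid Spike scales to scan (default 16 log-spaced values in
#'   `[0.005, s1]`).
#' @param s1 Slab scale (default 1).
#' @param theta Prior inclusion probability (default 0.5).
#' @param cv_folds,cv_replicates Cross-validation layout (defaults 10 / 10).
#' @param rng_seed Integer seed for fold assignment.
#' @param standardize If `TRUE`, z-score genes before fitting (coefficients
#'   are returned on the fitting scale).
#' @return A list of class `"sslasso_fit"`: `selected` (genes with nonzero
#'   coefficients at the chosen `s0`), `betas` (their coefficients),
#'   `best_s0`, `cvpl` (tibble `s0`, `cvpl`), `beta_full` (all
#'   coefficients), `converged`.
#' @export
sslasso_select <- function(expr_subset, outcome, s0_grid = NULL, s1 = 1,
                           theta = 0.5, cv_folds = 10, cv_replicates = 10,
                           rng_seed = 1L, standardize = FALSE) {
  stopifnot(is.matrix(expr_subset))
  if (nrow(expr_subset) < 2) {
    stop("at least 2 candidate genes required", call. = FALSE)
  }
  if (is.null(s0_grid)) {
    s0_grid <- exp(seq(log(0.005), log(s1), length.out = 16))
  }
  if (any(s0_grid > s1)) stop("every s0 must be <= s1", call. = FALSE)
  al <- align_samples(expr_subset, outcome)
  X <- t(al$expr)
  if (standardize) X <- scale(X)
  time <- al$time; event <- al$event
  s0_grid <- sort(s0_grid, decreasing = TRUE)   # warm-start dense -> sparse

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()), add = TRUE)
  set.seed(rng_seed)

  rs_full <- cox_risk_structure(time, event)
  cvpl_sum <- matrix(0, length(s0_grid), cv_replicates)
  if (length(s0_grid) > 1) for (r in seq_len(cv_replicates)) {
    fold <- .stratified_folds(event, cv_folds)
    for (k in seq_len(cv_folds)) {
      tr <- fold != k
      if (sum(event[tr]) == 0) next
      rs_tr <- cox_risk_structure(time[tr], event[tr])
      beta_ws <- NULL
      for (i in seq_along(s0_grid)) {
        # CV fits only rank s0 values; a looser inner tolerance suffices
        fit <- sslasso_em(X[tr, , drop = FALSE], time[tr], event[tr],
                          s0 = s0_grid[i], s1 = s1, theta = theta,
                          beta_init = beta_ws, tol = 1e-3,
                          cd_tol = 1e-5, cd_max_outer = 25)
        beta_ws <- unname(fit$beta)
        cvpl_sum[i, r] <- cvpl_sum[i, r] +
          cox_pl_loglik(X, fit$beta, rs_full) -
          cox_pl_loglik(X[tr, , drop = FALSE], fit$beta, rs_tr)
      }
    }
  }
  cvpl_mean <- rowMeans(cvpl_sum)
  best <- which.max(cvpl_mean)

  beta_ws <- NULL
  final <- NULL
  for (i in seq_len(best)) {    # warm-start path down to the chosen s0
    final <- sslasso_em(X, time, event, s0 = s0_grid[i], s1 = s1,
                        theta = theta, beta_init = beta_ws)
    beta_ws <- unname(final$beta)
  }
  if (!final$converged) {
    warning("spike-and-slab EM did not fully converge at the chosen s0; ",
            "best iterate returned", call. = FALSE)
  }
  sel <- names(final$beta)[final$beta != 0]
  structure(list(
    selected = sel, betas = final$beta[sel], best_s0 = s0_grid[best],
    cvpl = tibble::tibble(s0 = s0_grid, cvpl = cvpl_mean),
    beta_full = final$beta, converged = final$converged
  ), class = "sslasso_fit")
}

# ---- stepwise AIC --------------------------------------------------------

#' Bidirectional stepwise AIC refinement of a Cox gene model
#'
#' Starting from `start_genes`, repeatedly applies the single add/drop move
#' that most lowers `AIC = -2 loglik + 2k` of the unpenalized Cox fit, until
#' no move improves. Ties are broken toward the smaller model. Coefficients
#' of the returned signature come from the final unpenalized fit.
#'
#' @param expr_subset Genes x samples matrix holding at least the candidate
#'   pool.
#' @param outcome Survival outcome.
#' @param start_genes Starting gene set (>= 1); also the default add pool.
#' @param pool Optional candidate pool for additions (defaults to
#'   `start_genes`).
#' @return A [gene_signature] with attribute `aic`.
#' @export
stepwise_aic <- function(expr_subset, outcome, start_genes,
                         pool = start_genes) {
  if (length(start_genes) < 1) {
    stop("start_genes must contain at least one gene", call. = FALSE)
  }
  miss <- setdiff(union(start_genes, pool), rownames(expr_subset))
  if (length(miss)) stop("gene(s) absent from expression: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  al <- align_samples(expr_subset, outcome)
  oc <- data.frame(time = al$time, event = al$event)
  rs <- cox_risk_structure(al$time, al$event)
  null_ll <- cox_pl_loglik(matrix(0, length(al$time), 1), 0, rs)

  fit_aic <- function(genes) {
    if (length(genes) == 0) return(list(aic = -2 * null_ll, fit = NULL))
    fit <- tryCatch(
      suppressWarnings(fit_cox(t(al$expr[genes, , drop = FALSE]), oc)),
      error = function(e) NULL
    )
    if (is.null(fit)) return(NULL)
    list(aic = -2 * fit$loglik + 2 * length(genes), fit = fit)
  }

  current <- unique(start_genes)
  cur <- fit_aic(current)
  if (is.null(cur)) stop("initial Cox fit failed", call. = FALSE)
  repeat {
    moves <- c(
      lapply(current, function(g) list(set = setdiff(current, g), k = -1)),
      lapply(setdiff(pool, current),
             function(g) list(set = c(current, g), k = +1))
    )
    best_move <- NULL
    best_aic <- cur$aic - 1e-10
    for (mv in moves) {
      cand <- fit_aic(mv$set)
      if (is.null(cand)) {
        warning("Cox fit failed for a candidate move; move skipped",
                call. = FALSE)
        next
      }
      better <- cand$aic < best_aic - 1e-10 ||
        (abs(cand$aic - best_aic) <= 1e-10 && !is.null(best_move) &&
           length(mv$set) < length(best_move$set))
      if (better) { best_aic <- cand$aic; best_move <- mv; best_fit <- cand }
    }
    if (is.null(best_move)) break
    current <- best_move$set
    cur <- best_fit
  }
  if (length(current) == 0) {
    stop("stepwise selection eliminated every gene (null model preferred)",
         call. = FALSE)
  }
  sig <- gene_signature(current, unname(cur$fit$beta),
                        provenance = "stepwise AIC refinement")
  attr(sig, "aic") <- cur$aic
  sig
}

# ---- risk score ----------------------------------------------------------

#' Linear risk score of a gene signature
#'
#' The exact linear combination \eqn{\sum_i \beta_i \, Exp_i} per sample; no
#' standardization is applied.
#'
#' @param signature A [gene_signature].
#' @param expr Genes x samples expression matrix containing every signature
#'   gene.
#' @return Tibble `sample_id`, `score`.
#' @examples
#' sig <- published_crg_signature()
#' expr <- matrix(0, 14, 1, dimnames = list(sig$genes, "patient1"))
#' expr["ARPC5L", 1] <- 1
#' risk_score(sig, expr)   # 0.5170
#' @export
risk_score <- function(signature, expr) {
  stopifnot(inherits(signature, "gene_signature"), is.matrix(expr))
  miss <- setdiff(signature$genes, rownames(expr))
  if (length(miss)) {
    stop("signature gene(s) missing from expression: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  score <- drop(crossprod(expr[signature$genes, , drop = FALSE],
                          signature$betas))
  tibble::tibble(
    sample_id = colnames(expr) %||% paste0("sample", seq_len(ncol(expr))),
    score = unname(score)
  )
}

# ---- proportional hazards check -----------------------------------------

#' Test the proportional-hazards assumption
#'
#' Correlates scaled Schoenfeld residuals against Kaplan-Meier-transformed
#' event times (via [survival::cox.zph]); reports a per-covariate
#' chi-square (1 df each) and the global chi-square (df = number of
#' covariates). The check is advisory — nothing is dropped automatically.
#'
#' @param x Either a covariate matrix (samples x covariates) or a
#'   [gene_signature] (its genes become the covariates, taken from `expr`).
#' @param outcome Survival outcome.
#' @param expr Expression matrix, required when `x` is a signature.
#' @return A list of class `"ph_test"`: `per_covariate` tibble
#'   (`covariate`, `rho`, `chi2`, `p`), `global` tibble (`chi2`, `df`, `p`).
#' @export
ph_test <- function(x, outcome, expr = NULL) {
  if (inherits(x, "gene_signature")) {
    stopifnot(is.matrix(expr))
    al <- align_samples(expr, outcome)
    X <- t(al$expr[x$genes, , drop = FALSE])
    oc <- list(time = al$time, event = al$event)
  } else {
    X <- as.matrix(x)
    oc <- as_outcome(outcome)
  }
  if (sum(oc$event) < 2) stop("at least 2 events required", call. = FALSE)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  df <- data.frame(time = oc$time, event = oc$event, X, check.names = FALSE)
  fml <- stats::as.formula(paste(
    "survival::Surv(time, event) ~",
    paste(sprintf("`%s`", colnames(X)), collapse = " + ")))
  fit <- survival::coxph(fml, data = df, ties = "breslow")
  zph <- survival::cox.zph(fit, transform = "km")
  tab <- zph$table
  per <- tab[rownames(tab) != "GLOBAL", , drop = FALSE]
  rho <- vapply(seq_len(ncol(zph$y)), function(j) {
    suppressWarnings(stats::cor(zph$x, zph$y[, j]))
  }, numeric(1))
  structure(list(
    per_covariate = tibble::tibble(
      covariate = rownames(per), rho = rho,
      chi2 = per[, "chisq"], p = per[, "p"]
    ),
    global = tibble::tibble(chi2 = tab["GLOBAL", "chisq"],
                            df = tab["GLOBAL", "df"],
                            p = tab["GLOBAL", "p"])
  ), class = "ph_test")
}

#' @export
print.ph_test <- function(x, ...) {
  cat("Proportional-hazards check (scaled Schoenfeld residuals, KM time)\n")
  print(x$per_covariate)
  cat(sprintf("GLOBAL: chi2 = %.3f, df = %d, p = %.4g\n",
              x$global$chi2, as.integer(x$global$df), x$global$p))
  invisible(x)
}
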