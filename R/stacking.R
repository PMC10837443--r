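# Stacking of survival sub-models: out-of-fold linear predictors per
# sub-model, a non-negativity-constrained Cox meta-fit of the weights on the
# out-of-fold columns, and the weighted stacking linear predictor.

#' Event-stratified balanced cross-validation folds
#'
#' Partitions samples into `K` folds whose sizes differ by at most one,
#' stratified by event status, with every fold containing at least one
#' event (re-drawn up to 100 times if needed).
#'
#' @param outcome Survival outcome (needs `sample_id` or positional ids).
#' @param K Number of folds (default 10).
#' @param rng_seed Integer seed; assignment is deterministic under it.
#' @return Tibble `sample_id`, `fold` with attributes `K` and `rng_seed`.
#' @examples
#' oc <- tibble::tibble(sample_id = sprintf("S%03d", 1:550),
#'                      time = 1:550, event = rep(c(1, 0), 275))
#' table(make_folds(oc, K = 10)$fold)   # ten folds of 55
#' @export
make_folds <- function(outcome, K = 10, rng_seed = 1L) {
  oc <- as_outcome(outcome)
  n <- length(oc$time)
  if (K < 2) stop("K must be at least 2", call. = FALSE)
  if (n < K) stop("need at least K samples", call. = FALSE)
  ids <- oc$sample_id %||% sprintf("sample%04d", seq_len(n))

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()), add = TRUE)
  set.seed(rng_seed)

  for (attempt in seq_len(100)) {
    fold <- integer(n)
    ev <- sample(which(oc$event == 1))
    fold[ev] <- rep_len(sample(K), length(ev))
    cs <- sample(which(oc$event == 0))
    counts <- tabulate(fold[fold > 0], K)
    for (i in cs) {                       # fill smallest folds first
      k <- which(counts == min(counts))
      if (length(k) > 1) k <- sample(k, 1)
      fold[i] <- k
      counts[k] <- counts[k] + 1
    }
    sizes <- tabulate(fold, K)
    ev_per <- tabulate(fold[oc$event == 1], K)
    if (max(sizes) - min(sizes) <= 1 && all(ev_per >= 1)) {
      out <- tibble::tibble(sample_id = ids, fold = fold)
      attr(out, "K") <- as.integer(K)
      attr(out, "rng_seed") <- as.integer(rng_seed)
      return(out)
    }
  }
  stop("could not build K folds with at least one event each after 100 ",
       "attempts", call. = FALSE)
}

#' Declare a stacking sub-model
#'
#' A sub-model is either a `fixed_signature` (a published [gene_signature]
#' whose coefficients never change, so its out-of-fold linear predictor is
#' just its risk score) or a `refittable_signature` (a fitting recipe
#' `function(expr, outcome) -> gene_signature`, retrained per fold).
#'
#' @param id Sub-model identifier.
#' @param kind `"fixed_signature"` or `"refittable_signature"`.
#' @param definition A [gene_signature] (fixed) or a fitting function
#'   (refittable).
#' @return An object of class `"submodel_spec"`.
#' @export
submodel_spec <- function(id, kind = c("fixed_signature",
                                       "refittable_signature"),
                          definition) {
  kind <- match.arg(kind)
  if (kind == "fixed_signature" && !inherits(definition, "gene_signature")) {
    stop("a fixed_signature sub-model needs a gene_signature definition",
         call. = FALSE)
  }
  if (kind == "refittable_signature" && !is.function(definition)) {
    stop("a refittable_signature sub-model needs a fitting function",
         call. = FALSE)
  }
  structure(list(id = id, kind = kind, definition = definition),
            class = "submodel_spec")
}

#' Out-of-fold linear predictors of the stacking sub-models
#'
#' For each refittable sub-model, fits on nine of the ten folds (in general
#' K - 1) and evaluates the linear predictor on the held-out fold, so no
#' sample's value derives from a model trained on it. Fixed signatures are
#' evaluated directly (no fold dependence). A fold-level fit failure leaves
#' that fold's entries `NA` with a warning; such rows are excluded from the
#' meta-fit.
#'
#' @param submodels List of [submodel_spec] objects.
#' @param expr Genes x samples expression matrix.
#' @param outcome Survival outcome aligned to `expr`.
#' @param folds A [make_folds()] assignment.
#' @return Samples x sub-models numeric matrix (class `"oof_matrix"`) with
#'   sample ids as row names and sub-model ids as column names.
#' @export
oof_linear_predictors <- function(submodels, expr, outcome, folds) {
  stopifnot(is.list(submodels), all(vapply(submodels, inherits,
                                           logical(1), "submodel_spec")))
  al <- align_samples(expr, outcome)
  ids <- al$sample_id %||% colnames(al$expr) %||%
    sprintf("sample%04d", seq_len(ncol(al$expr)))
  fold <- folds$fold[match(ids, folds$sample_id)]
  if (any(is.na(fold))) stop("fold assignment does not cover every sample",
                             call. = FALSE)
  oc <- tibble::tibble(sample_id = ids, time = al$time, event = al$event)
  K <- attr(folds, "K") %||% max(fold)
  M <- length(submodels)
  lp <- matrix(NA_real_, length(ids), M,
               dimnames = list(ids, vapply(submodels, `[[`, "", "id")))
  for (m in seq_len(M)) {
    sm <- submodels[[m]]
    if (sm$kind == "fixed_signature") {
      lp[, m] <- risk_score(sm$definition, al$expr)$score
    } else {
      for (k in seq_len(K)) {
        test <- fold == k
        sig <- tryCatch(
          sm$definition(al$expr[, !test, drop = FALSE], oc[!test, ]),
          error = function(e) NULL
        )
        if (is.null(sig)) {
          warning("sub-model '", sm$id, "' failed in fold ", k,
                  "; entries left missing", call. = FALSE)
          next
        }
        lp[test, m] <- risk_score(sig, al$expr[, test, drop = FALSE])$score
      }
    }
  }
  structure(lp, class = c("oof_matrix", "matrix"), outcome = oc)
}

#' Deployment-time sub-model linear predictors
#'
#' Refits each refittable sub-model on the FULL training data (out-of-fold
#' values are only for fitting the weights) and evaluates every sub-model's
#' linear predictor on `expr`.
#'
#' @inheritParams oof_linear_predictors
#' @param outcome Training outcome for the refits (ignored for fixed
#'   signatures).
#' @return Samples x sub-models numeric matrix.
#' @export
full_linear_predictors <- function(submodels, expr, outcome = NULL) {
  M <- length(submodels)
  ids <- colnames(expr)
  lp <- matrix(NA_real_, ncol(expr), M,
               dimnames = list(ids, vapply(submodels, `[[`, "", "id")))
  for (m in seq_len(M)) {
    sm <- submodels[[m]]
    sig <- if (sm$kind == "fixed_signature") sm$definition else
      sm$definition(expr, outcome)
    lp[, m] <- risk_score(sig, expr)$score
  }
  lp
}

#' Construct a set of stacking weights
#'
#' @param w Named non-negative weights (names are sub-model ids).
#' @param normalized Whether `w` sums to 1 (checked when `TRUE`).
#' @return An object of class `"stacking_weights"`.
#' @examples
#' stacking_weights(c(crg = 0.68, mrna4 = 0.25, gene24 = 0.07))
#' @export
stacking_weights <- function(w, normalized = TRUE) {
  if (any(w < 0)) stop("stacking weights must be non-negative",
                       call. = FALSE)
  if (normalized && abs(sum(w) - 1) > 1e-9) {
    stop("normalized weights must sum to 1 (got ", sum(w), ")",
         call. = FALSE)
  }
  structure(list(
    submodel_ids = names(w) %||% paste0("submodel", seq_along(w)),
    w = unname(w), normalized = normalized
  ), class = "stacking_weights")
}

#' @export
print.stacking_weights <- function(x, ...) {
  cat("Stacking weights", if (x$normalized) "(normalized)" else "(raw)",
      "\n")
  print(tibble::tibble(submodel = x$submodel_ids, weight = x$w))
  invisible(x)
}

#' Fit non-negative stacking weights on out-of-fold linear predictors
#'
#' Maximizes the Breslow Cox partial likelihood of the outcome on the
#' out-of-fold sub-model columns subject to the box constraint
#' \eqn{w_m \ge 0}, by limited-memory quasi-Newton (L-BFGS-B) with the
#' analytic gradient. Weights start at `1/M`, are bounded in
#' `[0, 10 M]`, and convergence requires a projected-gradient infinity
#' norm below `pgtol`.
#'
#' @param oof An [oof_linear_predictors()] matrix (rows with missing
#'   entries are dropped from the fit), or any samples x sub-models matrix.
#' @param outcome Survival outcome; defaults to the outcome attached to
#'   `oof`.
#' @param normalize Rescale the weights to sum to 1 (default `TRUE`).
#' @param pgtol Projected-gradient tolerance (default 1e-6).
#' @return A [stacking_weights] object with extra fields `raw_w`,
#'   `loglik`, `converged`.
#' @export
fit_stacking_weights <- function(oof, outcome = attr(oof, "outcome"),
                                 normalize = TRUE, pgtol = 1e-6) {
  X <- unclass(oof)
  attr(X, "outcome") <- NULL
  stopifnot(is.matrix(X), ncol(X) >= 1)
  oc <- as_outcome(outcome)
  keep <- stats::complete.cases(X)
  if (!all(keep)) {
    X <- X[keep, , drop = FALSE]
    oc$time <- oc$time[keep]; oc$event <- oc$event[keep]
  }
  if (sum(oc$event) < 2) stop("at least 2 events required", call. = FALSE)
  M <- ncol(X)
  rs <- cox_risk_structure(oc$time, oc$event)
  negll <- function(w) -cox_pl_loglik(X, w, rs)
  neggr <- function(w) -cox_pl_deriv(X, w, rs)$grad
  opt <- stats::optim(rep(1 / M, M), fn = negll, gr = neggr,
                      method = "L-BFGS-B", lower = rep(0, M),
                      upper = rep(10 * M, M),
                      control = list(pgtol = pgtol, maxit = 500))
  if (opt$convergence != 0) {
    warning("stacking weight optimization did not report convergence (code ",
            opt$convergence, "); best iterate returned", call. = FALSE)
  }
  w <- opt$par
  if (all(w <= 1e-12)) {
    stop("all stacking weights are zero at the optimum; no sub-model ",
         "carries signal", call. = FALSE)
  }
  out_w <- if (normalize) w / sum(w) else w
  sw <- stacking_weights(stats::setNames(out_w, colnames(X)),
                         normalized = normalize)
  sw$raw_w <- w
  sw$loglik <- -opt$value
  sw$converged <- opt$convergence == 0
  sw
}

#' The stacking linear predictor
#'
#' Exact weighted sum \eqn{\sum_m w_m \, lp_m} per sample.
#'
#' @param weights A [stacking_weights] object.
#' @param lps Samples x sub-models matrix of linear predictors, or a single
#'   numeric vector of length M (one sample).
#' @return Numeric vector, one value per sample.
#' @examples
#' w <- stacking_weights(c(crg = 0.68, mrna4 = 0.25, gene24 = 0.07))
#' stacking_lp(w, c(1, 0, 0))   # 0.68
#' @export
stacking_lp <- function(weights, lps) {
  stopifnot(inherits(weights, "stacking_weights"))
  M <- length(weights$w)
  if (is.null(dim(lps))) {
    if (length(lps) != M) stop("lps length (", length(lps),
                               ") does not match the number of weights (",
                               M, ")", call. = FALSE)
    return(sum(weights$w * lps))
  }
  lps <- as.matrix(lps)
  if (ncol(lps) != M) stop("lps has ", ncol(lps), " columns but there are ",
                           M, " weights", call. = FALSE)
  if (!is.null(colnames(lps)) &&
      all(weights$submodel_ids %in% colnames(lps))) {
    lps <- lps[, weights$submodel_ids, drop = FALSE]
  }
  drop(lps %*% weights$w)
}
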