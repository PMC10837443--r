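# Seed-panel Spearman screen and per-gene univariate Cox screen.

#' Spearman rank-correlation screen against a seed gene panel
#'
#' Correlates every non-seed gene with each seed gene using Spearman rank
#' correlation on average ranks (ties mid-ranked). A gene passes if
#' `|Rs| > rs_threshold` and `P < p_threshold` against ANY seed gene; the
#' reported `best_seed_gene`/`rs`/`p_value` correspond to the seed gene with
#' the largest `|Rs|`. P-values come from the t-approximation
#' \eqn{t = Rs \sqrt{(n-2)/(1-Rs^2)}} with `n - 2` degrees of freedom,
#' two-sided.
#'
#' @param expr Genes x samples expression matrix.
#' @param seed_genes Character vector of seed panel gene identifiers; all
#'   must be present in `expr`.
#' @param rs_threshold Absolute-correlation threshold (default 0.4).
#' @param p_threshold P-value threshold (default 0.05).
#' @return A tibble with one row per non-seed gene: `gene_id`,
#'   `best_seed_gene`, `rs`, `p_value`, `passed`, `constant` (flag for
#'   zero-variance genes, reported as not passed).
#' @examples
#' cohort <- simulate_cohort(sim_config(n_samples = 80, n_genes = 30,
#'                                      n_correlated = 10, n_causal = 2))
#' scr <- spearman_screen(cohort$expression, cohort$truth$seed_genes)
#' table(scr$passed)
#' @export
spearman_screen <- function(expr, seed_genes = cuproptosis_seed_genes,
                            rs_threshold = 0.4, p_threshold = 0.05) {
  stopifnot(is.matrix(expr))
  if (!(rs_threshold >= 0 && rs_threshold < 1)) {
    stop("rs_threshold must lie in [0, 1)", call. = FALSE)
  }
  if (!(p_threshold > 0 && p_threshold <= 1)) {
    stop("p_threshold must lie in (0, 1]", call. = FALSE)
  }
  absent <- setdiff(seed_genes, rownames(expr))
  if (length(absent)) {
    stop("seed gene(s) absent from the expression matrix: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  n <- ncol(expr)
  if (n < 5) stop("at least 5 samples required", call. = FALSE)

  others <- setdiff(rownames(expr), seed_genes)
  ranks <- t(apply(expr[c(seed_genes, others), , drop = FALSE], 1, rank))
  const <- apply(expr[others, , drop = FALSE], 1,
                 function(x) diff(range(x)) == 0)
  # Pearson on mid-ranks = Spearman; constant rows yield NA via zero sd
  rs_mat <- suppressWarnings(
    stats::cor(t(ranks[others, , drop = FALSE]),
               t(ranks[seed_genes, , drop = FALSE]))
  )
  best_idx <- apply(abs(rs_mat), 1, function(r) {
    if (all(is.na(r))) NA_integer_ else which.max(r)
  })
  rs <- rs_mat[cbind(seq_along(others), best_idx)]
  tstat <- rs * sqrt((n - 2) / pmax(1 - rs^2, 0))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  p[is.infinite(tstat)] <- 0

  tibble::tibble(
    gene_id = others,
    best_seed_gene = ifelse(is.na(best_idx), NA_character_,
                            seed_genes[best_idx]),
    rs = rs, p_value = p,
    passed = !is.na(rs) & abs(rs) > rs_threshold & p < p_threshold,
    constant = unname(const)
  )
}

#' Univariate Cox screen over all genes
#'
#' Fits one Cox model per gene on the raw log-expression (standardization is
#' optional and off by default, so hazard ratios are per unit
#' log-expression). Per-gene failures (e.g. constant genes) are flagged and
#' the scan continues.
#'
#' @param expr Genes x samples expression matrix.
#' @param outcome Survival outcome (tibble with `sample_id`, `time`,
#'   `event`); samples are aligned by identifier when both sides carry them.
#' @param p_threshold Wald p-value threshold (default 0.05).
#' @param standardize If `TRUE`, z-score each gene before fitting.
#' @return A tibble with one row per gene: `gene_id`, `beta`, `hr`,
#'   `ci95_low`, `ci95_high`, `p_value`, `passed`, `failed`.
#' @export
univariate_cox_screen <- function(expr, outcome, p_threshold = 0.05,
                                  standardize = FALSE) {
  al <- align_samples(expr, outcome)
  expr <- al$expr
  rs <- cox_risk_structure(al$time, al$event)
  oc <- list(time = al$time, event = al$event)
  res <- purrr::map(rownames(expr), function(g) {
    x <- expr[g, ]
    if (standardize) {
      s <- stats::sd(x)
      if (is.finite(s) && s > 0) x <- (x - mean(x)) / s
    }
    fit <- tryCatch(
      suppressWarnings(fit_cox(matrix(x, ncol = 1),
                               data.frame(time = oc$time, event = oc$event))),
      error = function(e) NULL
    )
    if (is.null(fit) || !is.finite(fit$se[1]) || fit$se[1] == 0) {
      return(tibble::tibble(gene_id = g, beta = NA_real_, hr = NA_real_,
                            ci95_low = NA_real_, ci95_high = NA_real_,
                            p_value = NA_real_, passed = FALSE,
                            failed = TRUE))
    }
    b <- unname(fit$beta[1]); se <- fit$se[1]
    z <- b / se
    p <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
    tibble::tibble(
      gene_id = g, beta = b, hr = exp(b),
      ci95_low = exp(b - 1.96 * se), ci95_high = exp(b + 1.96 * se),
      p_value = p, passed = p < p_threshold, failed = FALSE
    )
  })
  dplyr::bind_rows(res)
}
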