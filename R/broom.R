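# broom-style tidiers for the package's fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname tidy.gene_signature
#' @export
tidy.cox_fit <- function(x, ...) {
  term <- names(x$beta) %||% paste0("x", seq_along(x$beta))
  z <- unname(x$beta) / x$se
  tibble::tibble(
    term = term, estimate = unname(x$beta), std.error = x$se,
    hr = exp(unname(x$beta)),
    conf.low = exp(unname(x$beta) - 1.96 * x$se),
    conf.high = exp(unname(x$beta) + 1.96 * x$se),
    statistic = z, p.value = 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  )
}

#' @rdname tidy.gene_signature
#' @export
glance.cox_fit <- function(x, ...) {
  tibble::tibble(loglik = x$loglik, n = x$n, n_events = x$n_events,
                 iterations = x$iterations, converged = x$converged)
}

#' Tidiers for stacksurv objects
#'
#' `tidy()` returns one row per term/gene/weight; `glance()` returns a
#' one-row model summary.
#'
#' @param x A fitted stacksurv object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.gene_signature <- function(x, ...) {
  tibble::tibble(gene = x$genes, coefficient = x$betas)
}

#' @rdname tidy.gene_signature
#' @export
glance.gene_signature <- function(x, ...) {
  tibble::tibble(n_genes = length(x$genes), provenance = x$provenance)
}

#' @rdname tidy.gene_signature
#' @export
tidy.stacking_weights <- function(x, ...) {
  tibble::tibble(submodel = x$submodel_ids, weight = x$w)
}

#' @rdname tidy.gene_signature
#' @export
glance.stacking_weights <- function(x, ...) {
  tibble::tibble(n_submodels = length(x$w), normalized = x$normalized,
                 loglik = x$loglik %||% NA_real_,
                 converged = x$converged %||% NA)
}

#' @rdname tidy.gene_signature
#' @export
tidy.td_roc <- function(x, ...) {
  tibble::tibble(fpr = x$fpr, tpr = x$tpr)
}

#' @rdname tidy.gene_signature
#' @export
glance.td_roc <- function(x, ...) {
  tibble::tibble(eval_time = x$eval_time, auc = x$auc, method = x$method,
                 n_cases = x$n_cases, n_controls = x$n_controls)
}

#' @rdname tidy.gene_signature
#' @export
tidy.sslasso_fit <- function(x, ...) {
  tibble::tibble(gene = names(x$beta_full), coefficient = unname(x$beta_full),
                 selected = x$beta_full != 0)
}

#' @rdname tidy.gene_signature
#' @export
glance.sslasso_fit <- function(x, ...) {
  tibble::tibble(n_selected = length(x$selected), best_s0 = x$best_s0,
                 converged = x$converged)
}

#' @rdname tidy.gene_signature
#' @export
tidy.km_curve <- function(x, ...) x$steps

#' @rdname tidy.gene_signature
#' @export
tidy.bootstrap_report <- function(x, ...) {
  tibble::tibble(replicate = seq_along(x$values), value = x$values)
}

#' @rdname tidy.gene_signature
#' @export
glance.bootstrap_report <- function(x, ...) {
  tibble::tibble(B = x$B, statistic = x$statistic, mean = x$mean,
                 ci95_low = x$ci95[1], ci95_high = x$ci95[2],
                 n_skipped = x$n_skipped)
}
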