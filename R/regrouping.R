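# Merge ELN2017 genetic risk categories with the model's dichotomized risk
# into three refined prognostic groups, and test their separation.

#' Merge ELN2017 groups with model risk groups
#'
#' Default mapping (the "remaining three subgroups" reading):
#' (Favorable, low) -> low; (Intermediate, low) and (Adverse, low) ->
#' intermediate; every high-model-risk subgroup -> high. The alternative
#' reading that sends (Favorable, high) to low regardless of model risk is
#' available via `favorable_high_low = TRUE`.
#'
#' @param eln Factor/character in {Favorable, Intermediate, Adverse}.
#' @param model_risk Factor/character in {low, high}.
#' @param sample_id Optional identifiers.
#' @param favorable_high_low Use the alternative reading for
#'   (Favorable, high).
#' @return Tibble `sample_id`, `eln`, `model_risk`, `merged` (factor
#'   low < intermediate < high).
#' @examples
#' merge_eln_model(c("Favorable", "Intermediate", "Adverse"),
#'                 c("low", "low", "high"))
#' @export
merge_eln_model <- function(eln, model_risk, sample_id = NULL,
                            favorable_high_low = FALSE) {
  eln <- as.character(eln)
  model_risk <- as.character(model_risk)
  if (length(eln) != length(model_risk)) {
    stop("eln and model_risk must have equal length", call. = FALSE)
  }
  eln_dom <- c("Favorable", "Intermediate", "Adverse")
  risk_dom <- c("low", "high")
  bad_e <- setdiff(unique(eln[!is.na(eln)]), eln_dom)
  if (length(bad_e)) stop("unknown ELN2017 category: ",
                          paste(bad_e, collapse = ", "), call. = FALSE)
  bad_r <- setdiff(unique(model_risk[!is.na(model_risk)]), risk_dom)
  if (length(bad_r)) stop("unknown model risk category: ",
                          paste(bad_r, collapse = ", "), call. = FALSE)
  merged <- dplyr::case_when(
    model_risk == "low" & eln == "Favorable" ~ "low",
    model_risk == "low" ~ "intermediate",
    favorable_high_low & eln == "Favorable" ~ "low",
    TRUE ~ "high"
  )
  merged[is.na(eln) | is.na(model_risk)] <- NA
  tibble::tibble(
    sample_id = sample_id %||% sprintf("sample%04d", seq_along(eln)),
    eln = factor(eln, levels = eln_dom),
    model_risk = factor(model_risk, levels = risk_dom),
    merged = factor(merged, levels = c("low", "intermediate", "high"))
  )
}

#' Survival separation of the merged risk groups
#'
#' Overall k-group log-rank test plus all pairwise log-rank tests with
#' Bonferroni decisions at `alpha / 3` (0.017 displayed convention for
#' three comparisons).
#'
#' @param labels A [merge_eln_model()] tibble (uses `merged`), or any
#'   vector of group labels.
#' @param outcome Survival outcome aligned to `labels`.
#' @param alpha Family-wise error rate (default 0.05).
#' @return List of class `"group_separation"`: `overall` (`chi2`, `df`,
#'   `p`), `pairwise` tibble (`group1`, `group2`, `chi2`, `p`,
#'   `significant` at `alpha / m`), `threshold`.
#' @export
group_separation <- function(labels, outcome, alpha = 0.05) {
  groups <- if (is.data.frame(labels)) labels$merged else labels
  oc <- as_outcome(outcome)
  keep <- !is.na(groups)
  groups <- droplevels(factor(groups[keep]))
  time <- oc$time[keep]; event <- oc$event[keep]
  if (nlevels(groups) < 2) stop("need at least 2 non-empty merged groups",
                                call. = FALSE)
  overall <- logrank_test(groups, tibble::tibble(time = time, event = event))
  pairs <- utils::combn(levels(groups), 2, simplify = FALSE)
  m <- length(pairs)
  pw <- purrr::map_dfr(pairs, function(pr) {
    idx <- groups %in% pr
    if (sum(groups[idx] == pr[1]) == 0 || sum(groups[idx] == pr[2]) == 0) {
      message("pair ", pr[1], " vs ", pr[2], " skipped (empty group)")
      return(tibble::tibble(group1 = pr[1], group2 = pr[2],
                            chi2 = NA_real_, p = NA_real_,
                            significant = NA))
    }
    lt <- logrank_test(droplevels(groups[idx]),
                       tibble::tibble(time = time[idx], event = event[idx]))
    tibble::tibble(group1 = pr[1], group2 = pr[2], chi2 = lt$chi2,
                   p = lt$p, significant = lt$p < alpha / m)
  })
  structure(list(overall = overall, pairwise = pw,
                 threshold = alpha / m), class = "group_separation")
}

#' @export
print.group_separation <- function(x, ...) {
  cat(sprintf("Overall log-rank: chi2 = %.3f, df = %d, p = %.4g\n",
              x$overall$chi2, x$overall$df, x$overall$p))
  cat(sprintf("Pairwise (Bonferroni threshold %.4f):\n", x$threshold))
  print(x$pairwise)
  invisible(x)
}
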