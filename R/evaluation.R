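# Discrimination, stratification and calibration for censored survival
# markers: cumulative/dynamic time-dependent ROC, maximally selected
# cut-points, Kaplan-Meier / log-rank, calibration tables, Bonferroni.

# KM estimate of S(eval_time) for a subset, carried forward past the last
# observed time.
.km_at <- function(time, event, eval_time) {
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  s <- summary(fit, times = eval_time, extend = TRUE)
  as.numeric(s$surv[1])
}

#' Cumulative/dynamic time-dependent ROC curve
#'
#' Cases are subjects with an event by `eval_time` (cumulative), controls
#' are subjects surviving beyond it (dynamic). Censoring before
#' `eval_time` is handled through a conditional Kaplan-Meier estimate of
#' `S(t | marker)`: by default the nearest-neighbor estimator (NNE) over
#' marker-sorted neighborhoods with span `0.25 n^(-0.20)`; `method = "km"`
#' uses the subset Kaplan-Meier of `{marker > c}` instead (on uncensored
#' data this variant reduces exactly to the Mann-Whitney U statistic).
#'
#' @param marker Per-sample numeric risk marker (higher = worse).
#' @param outcome Survival outcome.
#' @param eval_time Evaluation horizon (days), within follow-up range.
#' @param method `"nne"` (default) or `"km"`.
#' @param span NNE neighborhood half-width on the marker-quantile scale.
#' @return List of class `"td_roc"`: `eval_time`, `fpr`, `tpr`
#'   (non-decreasing from 0 to 1), `auc` (trapezoidal), `method`, `n`,
#'   `n_cases`, `n_controls`.
#' @export
td_roc <- function(marker, outcome, eval_time,
                   method = c("nne", "km"), span = NULL) {
  method <- match.arg(method)
  oc <- as_outcome(outcome)
  n <- length(marker)
  stopifnot(n == length(oc$time))
  if (eval_time <= 0 || eval_time >= max(oc$time)) {
    stop("eval_time must lie within the follow-up range", call. = FALSE)
  }
  n_cases <- sum(oc$time <= eval_time & oc$event == 1)
  n_controls <- sum(oc$time > eval_time)
  if (n_cases < 1 || n_controls < 1) {
    stop("need at least one case and one control at eval_time",
         call. = FALSE)
  }
  cuts <- sort(unique(marker), decreasing = TRUE)

  if (method == "nne") {
    if (is.null(span)) span <- 0.25 * n^(-0.20)
    Fm <- rank(marker, ties.method = "average") / n
    s_cond <- vapply(seq_len(n), function(i) {
      nb <- abs(Fm - Fm[i]) < span
      .km_at(oc$time[nb], oc$event[nb], eval_time)
    }, numeric(1))
    s_marg <- mean(s_cond)
    tp <- fp <- numeric(length(cuts))
    for (k in seq_along(cuts)) {
      above <- marker > cuts[k]
      joint <- sum(s_cond[above]) / n
      tp[k] <- (mean(above) - joint) / (1 - s_marg)
      fp[k] <- joint / s_marg
    }
  } else {
    s_marg <- .km_at(oc$time, oc$event, eval_time)
    tp <- fp <- numeric(length(cuts))
    for (k in seq_along(cuts)) {
      above <- marker > cuts[k]
      p_above <- mean(above)
      s_sub <- if (any(above)) .km_at(oc$time[above], oc$event[above],
                                      eval_time) else 1
      joint <- s_sub * p_above
      tp[k] <- (p_above - joint) / (1 - s_marg)
      fp[k] <- joint / s_marg
    }
  }
  tpr <- pmin(pmax(c(0, tp, 1), 0), 1)
  fpr <- pmin(pmax(c(0, fp, 1), 0), 1)
  tpr <- cummax(tpr); fpr <- cummax(fpr)    # guard tiny estimator wiggles
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(eval_time = eval_time, fpr = fpr, tpr = tpr, auc = auc,
                 method = method, n = n, n_cases = n_cases,
                 n_controls = n_controls), class = "td_roc")
}

#' @export
print.td_roc <- function(x, ...) {
  cat(sprintf("Time-dependent ROC at t = %g (%s): AUC = %.4f (%d cases, %d controls)\n",
              x$eval_time, x$method, x$auc, x$n_cases, x$n_controls))
  invisible(x)
}

# Standardized two-group log-rank statistic (group = marker > cut).
.logrank_z <- function(high, time, event) {
  ut <- sort(unique(time[event == 1]))
  U <- 0; V <- 0
  for (s in ut) {
    at <- time >= s
    nj <- sum(at); n1j <- sum(at & high)
    dj <- sum(time == s & event == 1)
    d1j <- sum(time == s & event == 1 & high)
    U <- U + d1j - dj * n1j / nj
    if (nj > 1) {
      V <- V + dj * (n1j / nj) * (1 - n1j / nj) * (nj - dj) / (nj - 1)
    }
  }
  if (V <= 0) return(0)
  U / sqrt(V)
}

#' Maximally selected log-rank cut-point
#'
#' Scans every admissible midpoint between consecutive distinct marker
#' values (both resulting groups must hold at least `minprop` of the
#' samples) and returns the cut maximizing the absolute standardized
#' two-group log-rank statistic. The reported naive log-rank p-value at the
#' selected cut carries no selection-bias correction; a warning says so.
#'
#' @param marker Per-sample numeric marker.
#' @param outcome Survival outcome.
#' @param minprop Minimum group proportion (default 0.1).
#' @return List of class `"cutpoint_result"`: `cutpoint`,
#'   `max_standardized_statistic`, `group_sizes` (low, high), `minprop`,
#'   `p_naive`, and the scanned `candidates` tibble.
#' @export
optimal_cutpoint <- function(marker, outcome, minprop = 0.1) {
  oc <- as_outcome(outcome)
  n <- length(marker)
  stopifnot(n == length(oc$time))
  vals <- sort(unique(marker))
  if (length(vals) < 2) stop("need at least 2 distinct marker values",
                             call. = FALSE)
  mids <- (utils::head(vals, -1) + utils::tail(vals, -1)) / 2
  n_low <- vapply(mids, function(c) sum(marker <= c), integer(1))
  ok <- n_low >= minprop * n & (n - n_low) >= minprop * n
  if (!any(ok)) stop("no admissible split satisfies minprop = ", minprop,
                     call. = FALSE)
  mids <- mids[ok]
  z <- vapply(mids, function(c) .logrank_z(marker > c, oc$time, oc$event),
              numeric(1))
  best <- which.max(abs(z))
  cut <- mids[best]
  high <- marker > cut
  chi2 <- z[best]^2
  warning("cut-point selected by maximal log-rank scan; the naive p-value ",
          "is optimistically biased by the selection", call. = FALSE)
  structure(list(
    cutpoint = cut, max_standardized_statistic = abs(z[best]),
    group_sizes = c(low = sum(!high), high = sum(high)), minprop = minprop,
    p_naive = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
    candidates = tibble::tibble(cutpoint = mids, z = z)
  ), class = "cutpoint_result")
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimator, returned as a tidy step table.
#'
#' @param outcome Survival outcome (or `time`/`event` in a data frame).
#' @return List of class `"km_curve"`: tibble `steps` (`time`, `at_risk`,
#'   `events`, `survival`) over event times, plus the underlying
#'   [survival::survfit] object as `fit`.
#' @export
km_curve <- function(outcome) {
  oc <- as_outcome(outcome)
  if (length(oc$time) < 1) stop("at least one subject required",
                                call. = FALSE)
  fit <- survival::survfit(survival::Surv(oc$time, oc$event) ~ 1)
  keep <- fit$n.event > 0
  structure(list(
    steps = tibble::tibble(time = fit$time[keep],
                           at_risk = fit$n.risk[keep],
                           events = fit$n.event[keep],
                           survival = fit$surv[keep]),
    fit = fit
  ), class = "km_curve")
}

#' K-group log-rank test
#'
#' Standard observed-minus-expected log-rank chi-square with
#' `df = #groups - 1` (via [survival::survdiff]).
#'
#' @param groups Group labels per sample (>= 2 non-empty groups).
#' @param outcome Survival outcome.
#' @return List `chi2`, `df`, `p`.
#' @export
logrank_test <- function(groups, outcome) {
  oc <- as_outcome(outcome)
  groups <- factor(groups)
  if (any(table(groups) == 0) || nlevels(droplevels(groups)) < 2) {
    stop("need at least 2 non-empty groups", call. = FALSE)
  }
  sd <- survival::survdiff(survival::Surv(oc$time, oc$event) ~ groups)
  df <- length(sd$n) - 1
  list(chi2 = sd$chisq, df = df,
       p = stats::pchisq(sd$chisq, df = df, lower.tail = FALSE))
}

#' Calibration of predicted survival probabilities
#'
#' Grouped mode bins samples into `n_groups` quantile bins of predicted
#' survival and pairs each bin's mean prediction with its Kaplan-Meier
#' estimate at `eval_time`; population mode (the default for opaque
#' machine-learning models) pairs the mean predicted survival with the
#' full-sample Kaplan-Meier value. Empty quantile bins are merged with a
#' neighbor and noted.
#'
#' @param predictions Predicted `S(eval_time | x)` per sample, in `[0, 1]`.
#' @param outcome Survival outcome.
#' @param eval_time Horizon (days).
#' @param n_groups Number of quantile bins in grouped mode.
#' @param mode `"grouped"` or `"population"`.
#' @return Tibble of class `"calibration_table"`: `group`, `predicted`,
#'   `observed`, `n`, with attributes `eval_time` and `merged_bins`.
#' @export
calibration <- function(predictions, outcome, eval_time, n_groups = 5,
                        mode = c("grouped", "population")) {
  mode <- match.arg(mode)
  oc <- as_outcome(outcome)
  if (any(predictions < 0 | predictions > 1)) {
    stop("predictions must be probabilities in [0, 1]", call. = FALSE)
  }
  if (mode == "population") {
    out <- tibble::tibble(
      group = "population", predicted = mean(predictions),
      observed = .km_at(oc$time, oc$event, eval_time),
      n = length(predictions)
    )
    attr(out, "eval_time") <- eval_time
    attr(out, "merged_bins") <- 0L
    class(out) <- c("calibration_table", class(out))
    return(out)
  }
  br <- unique(stats::quantile(predictions, probs = seq(0, 1,
                                                        length.out = n_groups + 1)))
  bin <- cut(predictions, breaks = br, include.lowest = TRUE)
  merged <- n_groups - nlevels(droplevels(bin))
  if (merged > 0) {
    message(merged, " empty quantile bin(s) merged with neighbors")
  }
  levs <- levels(droplevels(bin))
  out <- purrr::map_dfr(levs, function(l) {
    idx <- which(bin == l)
    tibble::tibble(group = l, predicted = mean(predictions[idx]),
                   observed = .km_at(oc$time[idx], oc$event[idx], eval_time),
                   n = length(idx))
  })
  attr(out, "eval_time") <- eval_time
  attr(out, "merged_bins") <- as.integer(max(merged, 0))
  class(out) <- c("calibration_table", class(out))
  out
}

#' Bonferroni multiple-testing adjustment
#'
#' Threshold form of the Bonferroni correction: a test is significant when
#' `p < alpha / m` (with `alpha = 0.05` and `m = 3` comparisons the
#' threshold is 0.0167, conventionally displayed as 0.017).
#'
#' @param p_values Raw p-values.
#' @param m Number of comparisons (default `length(p_values)`).
#' @param alpha Family-wise error rate (default 0.05).
#' @return Tibble `p`, `p_adjusted` (Bonferroni), `significant`, with
#'   attribute `threshold = alpha / m`.
#' @export
bonferroni_adjust <- function(p_values, m = length(p_values),
                              alpha = 0.05) {
  stopifnot(m >= 1)
  out <- tibble::tibble(
    p = p_values,
    p_adjusted = pmin(p_values * m, 1),
    significant = p_values < alpha / m
  )
  attr(out, "threshold") <- alpha / m
  out
}
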