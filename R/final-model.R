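# Machine-learning final models on {stacking linear predictor, age, FAB}:
# a uniform adapter over established survival learners, 10-fold grid-search
# tuning, selection by cross-validated time-dependent AUC, bootstrap
# internal validation, and per-patient death-probability prediction.
#
# Learners are invoked through library backends behind the adapter contract
# (fit / linear risk / survival function); the bespoke logic here is the
# tuning, selection, bootstrap and output contracts.

# step-function survival lookup: S = 1 before the first grid time,
# carried forward after the last.
.step_surv <- function(grid_times, surv, query) {
  idx <- findInterval(query, grid_times)
  out <- numeric(length(query))
  out[idx == 0] <- 1
  out[idx > 0] <- surv[pmax(idx[idx > 0], 1)]
  out
}

.breslow_basehaz <- function(time, event, lp) {
  ut <- sort(unique(time[event == 1]))
  elp <- exp(lp - max(lp))
  H0 <- vapply(ut, function(s) {
    sum(time == s & event == 1) / sum(elp[time >= s])
  }, numeric(1))
  list(times = ut, cumhaz = cumsum(H0), lp_shift = max(lp))
}

.breslow_surv <- function(bh, lp, times) {
  H <- stats::approx(bh$times, bh$cumhaz, xout = times, method = "constant",
                     yleft = 0, rule = 2)$y
  outer_val <- exp(-outer(exp(lp - bh$lp_shift), H))
  outer_val
}

# one-hot encoding over every declared factor level (so fold subsets encode
# identically); age and other numerics untransformed
.encode_full <- function(features) {
  df <- as.data.frame(features)
  num <- df[, vapply(df, is.numeric, logical(1)), drop = FALSE]
  X <- as.matrix(num)
  fac <- names(df)[vapply(df, is.factor, logical(1))]
  for (f in fac) {
    for (l in levels(df[[f]])) {
      X <- cbind(X, as.numeric(df[[f]] == l))
      colnames(X)[ncol(X)] <- paste0(f, "_", l)
    }
  }
  X
}

# training design: drop each factor's largest observed category (reference)
# and any level unobserved in the training data
.encode_features <- function(features) {
  df <- as.data.frame(features)
  X <- .encode_full(df)
  drop_cols <- character(0)
  fac <- names(df)[vapply(df, is.factor, logical(1))]
  for (f in fac) {
    tab <- table(df[[f]])
    ref <- names(tab)[which.max(tab)]
    drop_cols <- c(drop_cols, paste0(f, "_", ref),
                   paste0(f, "_", names(tab)[tab == 0]))
  }
  X[, setdiff(colnames(X), drop_cols), drop = FALSE]
}

# prediction design aligned to the training columns
.encode_to <- function(features, train_cols) {
  X <- .encode_full(features)
  miss <- setdiff(train_cols, colnames(X))
  for (m in miss) {
    X <- cbind(X, 0)
    colnames(X)[ncol(X)] <- m
  }
  X[, train_cols, drop = FALSE]
}

# ---- adapter registry ----------------------------------------------------
# Registry order also encodes the tie-break preference (simpler first).

.learner_registry <- function() {
  list(
    dummy = list(available = TRUE, backend = "marginal Kaplan-Meier",
                 default_grid = list(dummy = 1)),
    cox = list(available = TRUE, backend = "in-package Breslow Cox",
               default_grid = list(ridge = c(0, 0.1))),
    rsf = list(available = TRUE, backend = "ranger",
               default_grid = list(num_trees = c(250, 500),
                                   min_node_size = c(5, 15))),
    gbm = list(available = FALSE, backend = "gbm"),
    survival_svm = list(available = FALSE, backend = "survivalsvm"),
    xgboost_cox = list(available = TRUE, backend = "xgboost",
                       default_grid = list(nrounds = c(50, 150),
                                           max_depth = c(2, 3),
                                           eta = 0.1))
  )
}

#' Specify a survival learner for the final model
#'
#' @param name One of `"rsf"`, `"survival_svm"`, `"gbm"`, `"xgboost_cox"`,
#'   `"cox"` (linear baseline) or `"dummy"` (constant-prediction
#'   diagnostic baseline). Backends for `survival_svm` and `gbm` are not
#'   bundled; training such a spec fails naming the missing backend.
#' @param hyperparameter_grid Named list of candidate values, crossed into
#'   a grid (defaults per learner).
#' @param cv_folds Tuning folds (default 10).
#' @param rng_seed Integer seed.
#' @return An object of class `"learner_spec"`.
#' @export
learner_spec <- function(name, hyperparameter_grid = NULL, cv_folds = 10,
                         rng_seed = 1L) {
  reg <- .learner_registry()
  if (!name %in% names(reg)) {
    stop("unknown learner '", name, "'; registry holds: ",
         paste(names(reg), collapse = ", "), call. = FALSE)
  }
  if (is.null(hyperparameter_grid)) {
    hyperparameter_grid <- reg[[name]]$default_grid
  }
  if (is.null(hyperparameter_grid) || !length(hyperparameter_grid)) {
    stop("hyperparameter grid must be non-empty", call. = FALSE)
  }
  structure(list(name = name, hyperparameter_grid = hyperparameter_grid,
                 cv_folds = as.integer(cv_folds),
                 rng_seed = as.integer(rng_seed)),
            class = "learner_spec")
}

# fit one learner at one configuration; returns an object with
# $risk(newfeatures) and $surv(newfeatures, times)
.fit_adapter <- function(name, params, features, time, event, seed) {
  reg <- .learner_registry()
  if (!isTRUE(reg[[name]]$available)) {
    stop("learner backend unavailable: '", name, "' requires the '",
         reg[[name]]$backend, "' backend", call. = FALSE)
  }
  if (name == "dummy") {
    fit <- survival::survfit(survival::Surv(time, event) ~ 1)
    return(list(
      risk = function(nf) rep(0, nrow(as.data.frame(nf))),
      surv = function(nf, times) {
        s <- .step_surv(fit$time, fit$surv, times)
        matrix(rep(s, each = nrow(as.data.frame(nf))),
               nrow(as.data.frame(nf)), length(times))
      }
    ))
  }
  if (name == "cox") {
    X <- .encode_features(features)
    enc <- function(nf) .encode_to(nf, colnames(X))
    ridge <- params$ridge %||% 0
    fit <- fit_cox(X, data.frame(time = time, event = event),
                   penalty_weights = if (ridge > 0) rep(ridge, ncol(X)))
    lp_train <- drop(X %*% fit$beta)
    bh <- .breslow_basehaz(time, event, lp_train)
    return(list(
      risk = function(nf) drop(enc(nf) %*% fit$beta),
      surv = function(nf, times) .breslow_surv(bh, drop(enc(nf) %*% fit$beta),
                                               times)
    ))
  }
  if (name == "rsf") {
    df <- data.frame(time = time, event = event, as.data.frame(features))
    fit <- ranger::ranger(
      dependent.variable.name = "time", status.variable.name = "event",
      data = df, num.trees = params$num_trees %||% 500,
      min.node.size = params$min_node_size %||% 5,
      mtry = params$mtry, seed = seed, num.threads = 1
    )
    return(list(
      oob_cindex = 1 - fit$prediction.error,
      risk = function(nf) {
        pr <- stats::predict(fit, data = as.data.frame(nf), num.threads = 1)
        rowSums(pr$chf)           # ensemble mortality
      },
      surv = function(nf, times) {
        pr <- stats::predict(fit, data = as.data.frame(nf), num.threads = 1)
        sv <- pr$survival
        if (is.null(dim(sv))) sv <- matrix(sv, nrow = 1)
        t(apply(sv, 1, function(s)
          .step_surv(fit$unique.death.times, s, times)))
      }
    ))
  }
  if (name == "xgboost_cox") {
    X <- .encode_features(features)
    enc <- function(nf) .encode_to(nf, colnames(X))
    label <- ifelse(event == 1, time, -time)
    set.seed(seed)
    dtrain <- xgboost::xgb.DMatrix(data = X, label = label)
    fit <- xgboost::xgb.train(
      params = list(objective = "survival:cox",
                    max_depth = params$max_depth %||% 3,
                    eta = params$eta %||% 0.1, nthread = 1,
                    seed = seed),
      data = dtrain, nrounds = params$nrounds %||% 100, verbose = 0
    )
    pred_lp <- function(M) log(stats::predict(fit, xgboost::xgb.DMatrix(M)))
    bh <- .breslow_basehaz(time, event, pred_lp(X))
    return(list(
      risk = function(nf) pred_lp(enc(nf)),
      surv = function(nf, times) .breslow_surv(bh, pred_lp(enc(nf)), times)
    ))
  }
  stop("unreachable adapter: ", name, call. = FALSE)
}

.harrell_c <- function(time, event, risk) {
  cf <- survival::concordance(survival::Surv(time, event) ~ risk,
                              reverse = TRUE)
  as.numeric(cf$concordance)
}

#' Train a final-model learner with grid-search cross-validation
#'
#' Every grid configuration is scored by `cv_folds`-fold cross-validated
#' Harrell's concordance of the held-out risk predictions; the best
#' configuration is refit on all data. Deterministic under `rng_seed`.
#'
#' @param spec A [learner_spec].
#' @param features Data frame of complete features (post-imputation), e.g.
#'   `stacking_lp`, `age`, `fab`.
#' @param outcome Survival outcome.
#' @return Object of class `"final_model_fit"`: `learner`, `adapter`
#'   (opaque fitted state), `feature_names`, `best_params`, `cv_scores`
#'   (tibble, one row per grid cell), `rng_seed`.
#' @export
train_learner <- function(spec, features, outcome) {
  stopifnot(inherits(spec, "learner_spec"))
  oc <- as_outcome(outcome)
  features <- as.data.frame(features)
  if (anyNA(features)) stop("features contain missing values; impute first",
                            call. = FALSE)
  if (sum(oc$event) < 2) stop("at least 2 events required", call. = FALSE)
  grid <- expand.grid(spec$hyperparameter_grid, stringsAsFactors = FALSE)
  folds <- make_folds(tibble::tibble(time = oc$time, event = oc$event),
                      K = min(spec$cv_folds, floor(length(oc$time) / 2)),
                      rng_seed = spec$rng_seed)
  K <- attr(folds, "K")
  scores <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    params <- as.list(grid[g, , drop = FALSE])
    risk_oof <- rep(NA_real_, length(oc$time))
    ok <- TRUE
    for (k in seq_len(K)) {
      test <- folds$fold == k
      ad <- tryCatch(
        .fit_adapter(spec$name, params, features[!test, , drop = FALSE],
                     oc$time[!test], oc$event[!test],
                     seed = spec$rng_seed + 1000L * g + k),
        error = function(e) e
      )
      if (inherits(ad, "error")) {
        if (grepl("backend unavailable", conditionMessage(ad))) stop(ad)
        warning("grid cell ", g, " failed in fold ", k, ": ",
                conditionMessage(ad), call. = FALSE)
        ok <- FALSE
        break
      }
      risk_oof[test] <- ad$risk(features[test, , drop = FALSE])
    }
    scores[g] <- if (ok) .harrell_c(oc$time, oc$event, risk_oof) else NA_real_
  }
  if (all(is.na(scores))) stop("every grid configuration failed",
                               call. = FALSE)
  best <- which.max(scores)
  best_params <- as.list(grid[best, , drop = FALSE])
  adapter <- .fit_adapter(spec$name, best_params, features, oc$time,
                          oc$event, seed = spec$rng_seed)
  structure(list(
    learner = spec$name, adapter = adapter,
    feature_names = names(features), best_params = best_params,
    cv_scores = tibble::tibble(config = seq_len(nrow(grid)),
                               grid, cv_cindex = scores),
    rng_seed = spec$rng_seed, n = length(oc$time), n_events = sum(oc$event)
  ), class = "final_model_fit")
}

#' @export
print.final_model_fit <- function(x, ...) {
  cat("Final survival model:", x$learner, "on",
      paste(x$feature_names, collapse = ", "), "\n")
  cat("best configuration:",
      paste(names(x$best_params), unlist(x$best_params), sep = "=",
            collapse = ", "),
      sprintf("(CV C-index %.3f)\n", max(x$cv_scores$cv_cindex,
                                         na.rm = TRUE)))
  invisible(x)
}

#' Predicted survival function of a fitted final model
#'
#' @param model A [train_learner()] fit.
#' @param features New feature rows (same columns as training).
#' @param times Ascending evaluation times.
#' @return Samples x times matrix of `S(t | x)`, non-increasing in `t`,
#'   values in `[0, 1]`, `S(0) = 1`.
#' @export
predict_survival <- function(model, features, times) {
  stopifnot(inherits(model, "final_model_fit"))
  features <- as.data.frame(features)
  miss <- setdiff(model$feature_names, names(features))
  if (length(miss)) stop("missing feature(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  S <- model$adapter$surv(features[, model$feature_names, drop = FALSE],
                          times)
  S <- matrix(pmin(pmax(S, 0), 1), nrow(features), length(times))
  # enforce monotone non-increasing across the time grid
  t(apply(S, 1, function(s) rev(cummax(rev(s)))))
}

#' Predicted risk (linear predictor / mortality) of a fitted final model
#' @inheritParams predict_survival
#' @return Numeric risk per row (higher = worse prognosis).
#' @export
predict_risk <- function(model, features) {
  stopifnot(inherits(model, "final_model_fit"))
  features <- as.data.frame(features)
  model$adapter$risk(features[, model$feature_names, drop = FALSE])
}

#' Per-patient death-probability curve
#'
#' Returns `1 - S(t | x)` at the requested times: 0 at `t = 0`,
#' non-decreasing, within `[0, 1]`.
#'
#' @param model A [train_learner()] fit.
#' @param patient A single feature row (data frame or named list).
#' @param times Non-negative ascending times (days).
#' @return Tibble `time`, `death_probability`.
#' @export
predict_death_probability <- function(model, patient, times) {
  if (any(times < 0) || is.unsorted(times)) {
    stop("times must be non-negative and ascending", call. = FALSE)
  }
  patient <- as.data.frame(patient)
  stopifnot(nrow(patient) == 1)
  S <- predict_survival(model, patient, pmax(times, 0))
  p <- 1 - drop(S)
  p[times == 0] <- 0
  tibble::tibble(time = times, death_probability = p)
}

#' Select the best learner by cross-validated time-dependent AUC
#'
#' Each candidate learner is tuned by [train_learner()]'s grid search, then
#' scored by the mean pooled out-of-fold time-dependent AUC over
#' `eval_times` (1, 2, 3 years by default). Ties go to the learner earlier
#' in the registry order (simpler first).
#'
#' @param specs List of [learner_spec] objects (>= 2).
#' @param features,outcome As in [train_learner()].
#' @param eval_times Evaluation horizons in days.
#' @return List: `best` (name), `model` (the winning refit),
#'   `auc_table` (tibble learner x eval_time AUCs and means).
#' @export
select_learner <- function(specs, features, outcome,
                           eval_times = c(365, 730, 1095)) {
  stopifnot(length(specs) >= 2)
  oc <- as_outcome(outcome)
  features <- as.data.frame(features)
  eval_times <- sort(eval_times)
  reg_order <- names(.learner_registry())
  results <- list()
  for (spec in specs) {
    model <- tryCatch(train_learner(spec, features, outcome),
                      error = function(e) e)
    if (inherits(model, "error")) {
      warning("learner '", spec$name, "' failed: ",
              conditionMessage(model), call. = FALSE)
      next
    }
    folds <- make_folds(tibble::tibble(time = oc$time, event = oc$event),
                        K = min(spec$cv_folds,
                                floor(length(oc$time) / 2)),
                        rng_seed = spec$rng_seed)
    risk_oof <- rep(NA_real_, length(oc$time))
    for (k in seq_len(attr(folds, "K"))) {
      test <- folds$fold == k
      ad <- .fit_adapter(spec$name, model$best_params,
                         features[!test, , drop = FALSE],
                         oc$time[!test], oc$event[!test],
                         seed = spec$rng_seed + k)
      risk_oof[test] <- ad$risk(features[test, , drop = FALSE])
    }
    aucs <- vapply(eval_times, function(t) {
      tryCatch(td_roc(risk_oof, tibble::tibble(time = oc$time,
                                               event = oc$event), t)$auc,
               error = function(e) NA_real_)
    }, numeric(1))
    results[[spec$name]] <- list(model = model, aucs = aucs,
                                 mean_auc = mean(aucs, na.rm = TRUE))
  }
  if (!length(results)) stop("all learners failed", call. = FALSE)
  auc_table <- purrr::imap_dfr(results, function(r, nm) {
    tibble::tibble(learner = nm,
                   !!!stats::setNames(as.list(r$aucs),
                                      paste0("auc_", eval_times)),
                   mean_auc = r$mean_auc)
  })
  # argmax with registry-order tie-break (earlier = simpler wins ties)
  ord <- order(match(auc_table$learner, reg_order))
  auc_sorted <- auc_table[ord, ]
  best <- auc_sorted$learner[which.max(auc_sorted$mean_auc)]
  list(best = best, model = results[[best]]$model, auc_table = auc_table)
}

#' Bootstrap internal validation
#'
#' Each replicate resamples `n` subjects with replacement, refits via the
#' supplied closure, and evaluates the mean time-dependent AUC over
#' `eval_times` on the out-of-bag subjects. Replicates whose out-of-bag set
#' lacks cases or controls at some horizon are skipped and counted.
#'
#' @param fit_fun Closure `function(features, outcome)` returning an object
#'   accepted by `risk_fun`.
#' @param features,outcome Training data.
#' @param B Number of replicates (default 1000; scale down for quick runs).
#' @param eval_times Horizons in days.
#' @param rng_seed Integer seed (bit-for-bit reproducible).
#' @param risk_fun `function(model, features)` returning per-sample risk
#'   (default [predict_risk()]).
#' @return List of class `"bootstrap_report"`: `B`, `statistic`, `mean`,
#'   `ci95`, `values`, `n_skipped`.
#' @export
bootstrap_validate <- function(fit_fun, features, outcome, B = 1000,
                               eval_times = c(365, 730, 1095),
                               rng_seed = 1L, risk_fun = predict_risk) {
  stopifnot(B >= 1)
  oc <- as_outcome(outcome)
  features <- as.data.frame(features)
  n <- length(oc$time)

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()), add = TRUE)
  set.seed(rng_seed)

  values <- numeric(0)
  n_skipped <- 0L
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    oob <- setdiff(seq_len(n), idx)
    if (!length(oob)) { n_skipped <- n_skipped + 1L; next }
    model <- tryCatch(
      fit_fun(features[idx, , drop = FALSE],
              tibble::tibble(time = oc$time[idx], event = oc$event[idx])),
      error = function(e) NULL
    )
    if (is.null(model)) { n_skipped <- n_skipped + 1L; next }
    risk <- risk_fun(model, features[oob, , drop = FALSE])
    oob_oc <- tibble::tibble(time = oc$time[oob], event = oc$event[oob])
    aucs <- vapply(eval_times, function(t) {
      tryCatch(td_roc(risk, oob_oc, t)$auc, error = function(e) NA_real_)
    }, numeric(1))
    if (all(is.na(aucs))) { n_skipped <- n_skipped + 1L; next }
    values <- c(values, mean(aucs, na.rm = TRUE))
  }
  if (!length(values)) stop("no bootstrap replicate succeeded",
                            call. = FALSE)
  structure(list(
    B = B, statistic = paste0("mean time-dependent AUC at t = ",
                              paste(eval_times, collapse = "/")),
    mean = mean(values),
    ci95 = stats::quantile(values, c(0.025, 0.975), names = FALSE,
                           type = 7),
    values = values, n_skipped = n_skipped
  ), class = "bootstrap_report")
}

#' @export
print.bootstrap_report <- function(x, ...) {
  cat(sprintf("Bootstrap validation (B = %d, %d skipped): %s\n", x$B,
              x$n_skipped, x$statistic))
  cat(sprintf("mean = %.3f (95%% CI %.3f-%.3f)\n", x$mean, x$ci95[1],
              x$ci95[2]))
  invisible(x)
}
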