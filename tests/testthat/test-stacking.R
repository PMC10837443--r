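# Fold construction, out-of-fold discipline, constrained weight fitting and
# the stacking linear predictor.

test_that("folds are balanced, event-stratified and deterministic", {
  oc550 <- tibble::tibble(sample_id = sprintf("S%03d", 1:550),
                          time = as.numeric(1:550),
                          event = rep(c(1L, 0L), 275))
  f <- make_folds(oc550, K = 10, rng_seed = 3)
  expect_true(all(table(f$fold) == 55))
  ev_per <- table(f$fold[oc550$event == 1])
  expect_lte(diff(range(ev_per)), 1)
  expect_identical(f, make_folds(oc550, K = 10, rng_seed = 3))

  oc23 <- tibble::tibble(sample_id = sprintf("T%02d", 1:23),
                         time = as.numeric(1:23), event = rep(1L, 23))
  f23 <- make_folds(oc23, K = 10, rng_seed = 1)
  expect_setequal(unique(as.vector(table(f23$fold))), c(2, 3))
  expect_equal(sum(table(f23$fold)), 23)

  oc10 <- tibble::tibble(sample_id = sprintf("U%02d", 1:10),
                         time = as.numeric(1:10), event = rep(1L, 10))
  expect_true(all(table(make_folds(oc10, K = 10)$fold) == 1))

  # fewer events than folds cannot satisfy one-event-per-fold
  oc_bad <- tibble::tibble(sample_id = sprintf("V%02d", 1:30),
                           time = as.numeric(1:30),
                           event = c(rep(1L, 3), rep(0L, 27)))
  expect_error(make_folds(oc_bad, K = 10), "100 attempts")
})

test_that("a fixed signature's out-of-fold column equals its direct risk score", {
  co <- std_cohort()
  sig <- simulate_submodel_signatures(co$truth, 1, 1)[[1]]
  folds <- make_folds(co$outcome, K = 5, rng_seed = 2)
  oof <- oof_linear_predictors(list(submodel_spec("fix", "fixed_signature",
                                                  sig)),
                               co$expression, co$outcome, folds)
  direct <- risk_score(sig, co$expression)
  expect_equal(unname(oof[, "fix"]), direct$score, tolerance = 1e-12)
})

test_that("leave-one-out predictions match a manual fit-on-(n-1) loop", {
  set.seed(91)
  n <- 6
  expr <- matrix(rnorm(n, 8), 1, n,
                 dimnames = list("g1", sprintf("s%d", 1:n)))
  oc <- tibble::tibble(sample_id = colnames(expr),
                       time = c(3, 9, 5, 12, 7, 20) + 0.0,
                       event = rep(1L, n))
  recipe <- function(e, o) {
    fit <- fit_cox(t(e), o)
    gene_signature(rownames(e), unname(fit$beta))
  }
  folds <- make_folds(oc, K = n, rng_seed = 1)
  oof <- oof_linear_predictors(list(
    submodel_spec("refit", "refittable_signature", recipe)),
    expr, oc, folds)
  for (i in seq_len(n)) {
    sig_i <- recipe(expr[, -i, drop = FALSE], oc[-i, ])
    manual <- risk_score(sig_i, expr[, i, drop = FALSE])$score
    expect_equal(unname(oof[oc$sample_id[i], "refit"]), manual,
                 tolerance = 1e-8)
  }
})

test_that("sample order does not change out-of-fold values", {
  co <- std_cohort()
  sig <- simulate_submodel_signatures(co$truth, 1, 1)[[1]]
  folds <- make_folds(co$outcome, K = 5, rng_seed = 7)
  sms <- list(submodel_spec("fix", "fixed_signature", sig))
  oof1 <- oof_linear_predictors(sms, co$expression, co$outcome, folds)
  perm <- sample(ncol(co$expression))
  oof2 <- oof_linear_predictors(sms, co$expression[, perm],
                                co$outcome[perm, ], folds)
  expect_equal(unname(oof1[rownames(oof2), "fix"]),
               unname(oof2[, "fix"]), tolerance = 1e-12)
})

test_that("a single sub-model gets normalized weight 1 and basis inputs return the published weights", {
  set.seed(92)
  n <- 120
  lp <- rnorm(n)
  oc <- random_outcome(n, lp)
  oof <- matrix(lp, ncol = 1, dimnames = list(NULL, "only"))
  w <- fit_stacking_weights(oof, oc)
  expect_equal(w$w, 1)

  pub <- stacking_weights(c(crg = 0.68, mrna4 = 0.25, gene24 = 0.07))
  expect_equal(stacking_lp(pub, c(1, 0, 0)), 0.68)
  expect_equal(stacking_lp(pub, c(0, 1, 0)), 0.25)
  expect_equal(stacking_lp(pub, c(0, 0, 1)), 0.07)
  expect_equal(stacking_lp(pub, c(0, 0, 0)), 0)
  expect_error(stacking_lp(pub, c(1, 0)), "length")
})

test_that("an uninformative competitor receives a small normalized weight", {
  ws <- vapply(1:5, function(r) {
    set.seed(930 + r)
    n <- 500
    true_lp <- rnorm(n)
    oc <- random_outcome(n, true_lp)
    oof <- cbind(signal = true_lp, noise = rnorm(n))
    fit_stacking_weights(oof, oc)$w[2]
  }, numeric(1))
  expect_lte(median(ws), 0.1)
})

test_that("the constrained optimum dominates every single sub-model and scales correctly", {
  set.seed(94)
  n <- 300
  lp1 <- rnorm(n); lp2 <- 0.5 * lp1 + rnorm(n, sd = 0.8)
  oc <- random_outcome(n, 0.8 * lp1 + 0.3 * lp2)
  oof <- cbind(a = lp1, b = lp2)
  w <- fit_stacking_weights(oof, oc, normalize = FALSE)
  rs <- stacksurv:::cox_risk_structure(oc$time, oc$event)
  obj <- function(v) stacksurv:::cox_pl_loglik(oof, v, rs)
  expect_gte(obj(w$w) + 1e-8, obj(c(1, 0)))
  expect_gte(obj(w$w) + 1e-8, obj(c(0, 1)))

  # scaling one column by c > 0 scales its raw weight by 1/c and leaves the
  # fitted linear predictor unchanged
  oof_s <- cbind(a = 5 * lp1, b = lp2)
  w_s <- fit_stacking_weights(oof_s, oc, normalize = FALSE)
  expect_equal(w_s$w[1] * 5, w$w[1], tolerance = 1e-3)
  expect_equal(w_s$w[2], w$w[2], tolerance = 1e-3)
  expect_lt(max(abs(drop(oof %*% w$w) - drop(oof_s %*% w_s$w))), 1e-3)
})

test_that("weight fitting rejects degenerate inputs", {
  expect_error(stacking_weights(c(a = -0.1, b = 1.1)), "non-negative")
  expect_error(stacking_weights(c(a = 0.5, b = 0.4)), "sum to 1")
  set.seed(95)
  oc <- random_outcome(50)
  oof <- matrix(rnorm(50), ncol = 1, dimnames = list(NULL, "m"))
  expect_error(
    fit_stacking_weights(oof, tibble::tibble(time = oc$time,
                                             event = c(1L, 0L,
                                                       rep(0L, 48)))),
    "2 events")
})
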