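# Learner adapters, grid-search training, selection, bootstrap validation.

informative_features <- function(n = 250, seed = 130) {
  set.seed(seed)
  lp <- rnorm(n)
  oc <- random_outcome(n, 1.2 * lp)
  list(features = data.frame(stacking_lp = lp,
                             age = rnorm(n, 55, 10),
                             fab = factor(sample(paste0("M", 0:4), n,
                                                 replace = TRUE),
                                          levels = paste0("M", 0:7))),
       outcome = oc)
}

test_that("every available learner honours the survival-function contract", {
  d <- informative_features(150)
  times <- c(0, 50, 200, 600, 2000)
  for (name in c("cox", "rsf", "xgboost_cox", "dummy")) {
    spec <- learner_spec(name, cv_folds = 3, rng_seed = 1,
                         hyperparameter_grid = switch(name,
                           rsf = list(num_trees = 100),
                           xgboost_cox = list(nrounds = 30, max_depth = 2),
                           cox = list(ridge = 0),
                           dummy = list(dummy = 1)))
    m <- train_learner(spec, d$features, d$outcome)
    S <- predict_survival(m, d$features[1:5, ], times)
    expect_true(all(S >= 0 & S <= 1), info = name)
    expect_true(all(S[, 1] == 1), info = name)          # S(0) = 1
    expect_true(all(apply(S, 1, function(s) all(diff(s) <= 1e-12))),
                info = name)                             # non-increasing
  }
})

test_that("unavailable backends are rejected by name", {
  d <- informative_features(80)
  expect_error(train_learner(learner_spec("gbm", list(a = 1)),
                             d$features, d$outcome), "gbm")
  expect_error(train_learner(learner_spec("survival_svm", list(a = 1)),
                             d$features, d$outcome), "survivalsvm")
  expect_error(learner_spec("made_up"), "unknown learner")
})

test_that("training is deterministic under a fixed seed", {
  d <- informative_features(120)
  spec <- learner_spec("rsf", list(num_trees = c(50, 100)), cv_folds = 3,
                       rng_seed = 11)
  m1 <- train_learner(spec, d$features, d$outcome)
  m2 <- train_learner(spec, d$features, d$outcome)
  expect_identical(m1$best_params, m2$best_params)
  expect_equal(m1$cv_scores$cv_cindex, m2$cv_scores$cv_cindex)
  expect_equal(predict_risk(m1, d$features[1:10, ]),
               predict_risk(m2, d$features[1:10, ]))
})

test_that("an informative single feature gives the RSF useful out-of-bag concordance", {
  set.seed(132)
  n <- 300
  lp <- rnorm(n)
  oc <- random_outcome(n, 1.5 * lp)
  m <- train_learner(learner_spec("rsf", list(num_trees = 200),
                                  cv_folds = 3, rng_seed = 5),
                     data.frame(risk = lp), oc)
  expect_gte(m$adapter$oob_cindex, 0.7)
})

test_that("pure-noise features give chance-level cross-validated concordance", {
  cc <- vapply(1:3, function(r) {
    set.seed(132 + r)
    n <- 400
    oc <- random_outcome(n)
    m <- train_learner(learner_spec("cox", list(ridge = 0), cv_folds = 5,
                                    rng_seed = r),
                       data.frame(x1 = rnorm(n), x2 = rnorm(n)), oc)
    max(m$cv_scores$cv_cindex)
  }, numeric(1))
  expect_gte(mean(cc), 0.45)
  expect_lte(mean(cc), 0.55)
})

test_that("selection prefers an informative learner over the constant dummy", {
  d <- informative_features(200, seed = 134)
  sel <- select_learner(list(
    learner_spec("dummy", cv_folds = 3, rng_seed = 2),
    learner_spec("rsf", list(num_trees = 100), cv_folds = 3, rng_seed = 2)),
    d$features, d$outcome, eval_times = c(100, 300))
  expect_equal(sel$best, "rsf")
  expect_equal(sel$auc_table$mean_auc[sel$auc_table$learner == "dummy"],
               0.5, tolerance = 1e-9)
  # supplying eval_times in reverse order must not change the choice
  sel2 <- select_learner(list(
    learner_spec("dummy", cv_folds = 3, rng_seed = 2),
    learner_spec("rsf", list(num_trees = 100), cv_folds = 3, rng_seed = 2)),
    d$features, d$outcome, eval_times = c(300, 100))
  expect_equal(sel2$best, sel$best)
  expect_equal(sel2$auc_table$mean_auc, sel$auc_table$mean_auc)
})

test_that("the forest beats the linear Cox baseline on a sign-flipping interaction", {
  wins <- 0
  reps <- 5
  for (r in seq_len(reps)) {
    set.seed(1350 + r)
    n <- 300
    x <- rnorm(n)
    age <- rnorm(n, 55, 10)
    lp <- ifelse(age > 55, 1.3 * x, -1.3 * x)   # linear-in-x marginal ~ 0
    oc <- random_outcome(n, lp)
    feat <- data.frame(x = x, age = age)
    sel <- select_learner(list(
      learner_spec("cox", list(ridge = 0), cv_folds = 3, rng_seed = r),
      learner_spec("rsf", list(num_trees = 150, min_node_size = 10),
                   cv_folds = 3, rng_seed = r)),
      feat, oc, eval_times = stats::quantile(oc$time, c(0.3, 0.5)))
    at <- sel$auc_table
    if (at$mean_auc[at$learner == "rsf"] >
        at$mean_auc[at$learner == "cox"]) wins <- wins + 1
  }
  expect_gte(wins / reps, 0.8)
})

test_that("death-probability curves start at zero, stay in [0,1] and order by risk", {
  d <- informative_features(200, seed = 136)
  m <- train_learner(learner_spec("rsf", list(num_trees = 200),
                                  cv_folds = 3, rng_seed = 4),
                     d$features, d$outcome)
  hi <- d$features[which.max(d$features$stacking_lp), ]
  lo <- d$features[which.min(d$features$stacking_lp), ]
  times <- c(0, 100, 300, 600, 1200, 1e6)
  p_hi <- predict_death_probability(m, hi, times)$death_probability
  p_lo <- predict_death_probability(m, lo, times)$death_probability
  expect_equal(p_hi[1], 0)
  expect_equal(p_lo[1], 0)
  expect_true(all(diff(p_hi) >= -1e-12))
  expect_true(all(p_hi <= 1 & p_lo <= 1))
  expect_true(all(p_hi[-1] >= p_lo[-1]))
  expect_error(predict_death_probability(m, hi, c(300, 100)), "ascending")
  expect_error(predict_survival(m, hi["age"], 100), "missing feature")
})

test_that("bootstrap reports are reproducible, degenerate at B = 1, and cover the point estimate", {
  d <- informative_features(150, seed = 137)
  fit_fun <- function(f, o) train_learner(
    learner_spec("cox", list(ridge = 0), cv_folds = 3, rng_seed = 1), f, o)
  t_eval <- stats::quantile(d$outcome$time, c(0.4, 0.6))
  b1 <- bootstrap_validate(fit_fun, d$features, d$outcome, B = 1,
                           eval_times = t_eval, rng_seed = 8)
  expect_equal(b1$ci95[1], b1$ci95[2])
  expect_equal(b1$ci95[1], b1$mean)
  r1 <- bootstrap_validate(fit_fun, d$features, d$outcome, B = 25,
                           eval_times = t_eval, rng_seed = 9)
  r2 <- bootstrap_validate(fit_fun, d$features, d$outcome, B = 25,
                           eval_times = t_eval, rng_seed = 9)
  expect_identical(r1$values, r2$values)
  # CI brackets the full-data estimate
  full <- fit_fun(d$features, d$outcome)
  risk <- predict_risk(full, d$features)
  point <- mean(vapply(t_eval, function(t)
    td_roc(risk, d$outcome, t)$auc, numeric(1)))
  expect_gte(point, r1$ci95[1] - 0.05)
  expect_lte(point, r1$ci95[2] + 0.05)
})
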