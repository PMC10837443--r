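# Time-dependent ROC, maximally selected cut-points, KM/log-rank,
# calibration, Bonferroni.

test_that("td_roc on uncensored data reduces to the Mann-Whitney U statistic", {
  for (r in 1:5) {
    set.seed(110 + r)
    n <- 80
    marker <- rnorm(n)
    oc <- random_outcome(n, 1.2 * marker, censor = 0)
    t0 <- median(oc$time)
    roc <- td_roc(marker, oc, t0, method = "km")
    case <- oc$time <= t0
    u <- mean(outer(marker[case], marker[!case], ">") +
                0.5 * outer(marker[case], marker[!case], "=="))
    expect_lt(abs(roc$auc - u), 1e-9)
    # curves are proper: monotone 0 -> 1 and AUC equals its own trapezoid
    expect_true(all(diff(roc$tpr) >= 0) && all(diff(roc$fpr) >= 0))
    expect_equal(range(roc$tpr), c(0, 1))
    trap <- sum(diff(roc$fpr) * (head(roc$tpr, -1) + tail(roc$tpr, -1)) / 2)
    expect_lt(abs(roc$auc - trap), 1e-9)
    # the smoothed NNE default lands near the same value
    roc_nne <- td_roc(marker, oc, t0, method = "nne")
    expect_lt(abs(roc_nne$auc - u), 0.06)
  }
})

test_that("a marker that perfectly orders uncensored event times gives AUC 1", {
  n <- 40
  tm <- sort(rexp(n, 0.01))
  oc <- tibble::tibble(time = tm, event = 1L)
  marker <- -tm                     # higher marker = earlier death
  roc <- td_roc(marker, oc, median(tm), method = "km")
  expect_equal(roc$auc, 1)
})

test_that("td_roc AUC is invariant under strictly increasing marker transforms", {
  set.seed(112)
  n <- 150
  marker <- rnorm(n)
  oc <- random_outcome(n, marker)
  t0 <- median(oc$time)
  for (m in c("km", "nne")) {
    a1 <- td_roc(marker, oc, t0, method = m)$auc
    a2 <- td_roc(exp(2 * marker) + 5, oc, t0, method = m)$auc
    expect_equal(a1, a2, tolerance = 1e-12)
  }
})

test_that("an independent marker scores near 0.5 and degenerate horizons are rejected", {
  set.seed(113)
  n <- 2000
  marker <- rnorm(n)
  oc <- random_outcome(n)
  auc <- td_roc(marker, oc, median(oc$time))$auc
  expect_gte(auc, 0.47)
  expect_lte(auc, 0.53)
  expect_error(td_roc(marker, oc, max(oc$time) + 1), "follow-up range")
  expect_error(td_roc(marker, oc, min(oc$time) / 2), "case and .* control")
})

test_that("optimal_cutpoint equals a brute-force survdiff scan on random instances", {
  for (r in 1:20) {
    set.seed(1200 + r)
    n <- 60
    marker <- rnorm(n)
    oc <- random_outcome(n, 0.8 * marker)
    res <- suppressWarnings(optimal_cutpoint(marker, oc, minprop = 0.1))
    vals <- sort(unique(marker))
    mids <- (head(vals, -1) + tail(vals, -1)) / 2
    nl <- vapply(mids, function(c) sum(marker <= c), integer(1))
    mids <- mids[nl >= 0.1 * n & (n - nl) >= 0.1 * n]
    stats <- vapply(mids, function(c) {
      sd <- survival::survdiff(survival::Surv(oc$time, oc$event) ~
                                 (marker > c))
      sqrt(sd$chisq)
    }, numeric(1))
    expect_equal(res$cutpoint, mids[which.max(stats)])
    expect_equal(res$max_standardized_statistic, max(stats),
                 tolerance = 1e-8)
  }
})

test_that("the selected cut recovers two well-separated risk groups almost exactly", {
  # the log-rank argmax can drift a couple of order statistics past the
  # marker gap (the boundary samples are survival noise), so the check is
  # on the implied grouping: at most 2% of samples misclassified
  hits <- 0
  reps <- 10
  for (r in seq_len(reps)) {
    set.seed(1300 + r)
    n <- 400
    grp <- rep(0:1, each = n / 2)
    marker <- ifelse(grp == 1, rnorm(n, 3, 0.3), rnorm(n, 0, 0.3))
    oc <- random_outcome(n, log(5) * grp)
    res <- suppressWarnings(optimal_cutpoint(marker, oc))
    mis <- mean((marker > res$cutpoint) != (grp == 1))
    if (mis <= 0.02) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.9)
})

test_that("minprop = 0.5 admits only the median split", {
  set.seed(114)
  marker <- seq_len(20) + rnorm(20, sd = 0.01)
  oc <- random_outcome(20, 0.2 * scale(marker)[, 1])
  res <- suppressWarnings(optimal_cutpoint(marker, oc, minprop = 0.5))
  expect_equal(nrow(res$candidates), 1)
  expect_equal(sum(marker <= res$cutpoint), 10)
})

test_that("KM steps equal the hand-computed product-limit on the 6-subject example", {
  oc <- tibble::tibble(time = 1:6, event = c(1, 1, 0, 1, 0, 1))
  km <- km_curve(oc)
  expect_equal(km$steps$time, c(1, 2, 4, 6))
  expect_equal(km$steps$survival,
               c(5 / 6, 5 / 6 * 4 / 5, 5 / 6 * 4 / 5 * 2 / 3, 0),
               tolerance = 1e-12)
  # conservation: final value is the product of the per-step factors
  fac <- 1 - km$steps$events / km$steps$at_risk
  expect_equal(km$steps$survival[length(fac)], prod(fac),
               tolerance = 1e-12)
  # no events -> survival identically 1
  km0 <- km_curve(tibble::tibble(time = 1:5, event = rep(0, 5)))
  expect_true(all(km0$fit$surv == 1))
})

test_that("log-rank of a group against its own copy is zero and empty groups are rejected", {
  oc <- random_outcome(40, seed_lp <- rep(0, 40))
  dup <- rbind(oc, oc)
  lt <- logrank_test(rep(1:2, each = 40), dup)
  expect_lt(lt$chi2, 1e-10)
  expect_equal(lt$df, 1)
  expect_error(logrank_test(rep(1, 40), oc), "2 non-empty groups")
})

test_that("population calibration is self-consistent and flags gross miscalibration", {
  set.seed(115)
  oc <- random_outcome(200)
  t0 <- median(oc$time)
  km_val <- summary(survival::survfit(survival::Surv(oc$time, oc$event) ~ 1),
                    times = t0, extend = TRUE)$surv
  cal <- calibration(rep(km_val, 200), oc, t0, mode = "population")
  expect_equal(cal$predicted, cal$observed, tolerance = 1e-12)
  cal1 <- calibration(rep(1, 200), oc, t0, mode = "population")
  expect_gt(cal1$predicted, cal1$observed)
  expect_error(calibration(rep(1.2, 200), oc, t0), "probabilities")
})

test_that("grouped calibration is accurate when the model is the truth", {
  ok <- 0
  reps <- 5
  for (r in seq_len(reps)) {
    set.seed(1400 + r)
    n <- 500
    lp <- rnorm(n)
    h <- 0.005 * exp(lp)
    tm <- rexp(n, h)
    cens <- rexp(n, 0.002)
    oc <- tibble::tibble(time = pmin(tm, cens),
                         event = as.integer(tm <= cens))
    t0 <- 200
    pred <- exp(-h * t0)              # the true survival probabilities
    cal <- calibration(pred, oc, t0, n_groups = 5)
    if (max(abs(cal$predicted - cal$observed)) <= 0.1) ok <- ok + 1
  }
  expect_gte(ok / reps, 0.8)
})

test_that("Bonferroni threshold and decisions match the three-comparison convention", {
  res <- bonferroni_adjust(c(0.011, 0.02, 0.5), m = 3)
  thr <- attr(res, "threshold")
  expect_equal(thr, 0.05 / 3)
  expect_equal(round(thr, 3), 0.017)
  expect_true(res$significant[1])     # p = 0.011 clears 0.0167
  expect_false(res$significant[2])
  expect_equal(attr(bonferroni_adjust(0.03, m = 1), "threshold"), 0.05)
})
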