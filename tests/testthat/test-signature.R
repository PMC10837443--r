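# Spike-and-slab lasso selection, stepwise AIC, risk scores, PH check.

test_that("risk_score reproduces the published per-gene coefficients on unit vectors", {
  sig <- published_crg_signature()
  expect_length(sig$genes, 14)
  for (g in c("ARPC5L", "CYP19A1", "ULK1")) {
    expr <- matrix(0, 14, 1, dimnames = list(sig$genes, "p1"))
    expr[g, 1] <- 1
    expect_equal(risk_score(sig, expr)$score,
                 sig$betas[match(g, sig$genes)])
  }
  expect_equal(risk_score(sig, matrix(0, 14, 1,
                                      dimnames = list(sig$genes,
                                                      "p0")))$score, 0)
})

test_that("risk_score is an exact linear dot product", {
  set.seed(71)
  sig <- published_crg_signature()
  X <- matrix(rnorm(14 * 5), 14, 5,
              dimnames = list(sig$genes, sprintf("p%d", 1:5)))
  sc <- risk_score(sig, X)$score
  # independently coded dot product
  manual <- vapply(1:5, function(j) {
    s <- 0
    for (i in seq_along(sig$genes)) s <- s + sig$betas[i] * X[sig$genes[i], j]
    s
  }, numeric(1))
  expect_lt(max(abs(sc - manual)), 1e-12)
  # linearity: score(aX + bY) = a score(X) + b score(Y)
  Y <- matrix(rnorm(14 * 5), 14, 5, dimnames = dimnames(X))
  sc2 <- risk_score(sig, 2 * X + 3 * Y)$score
  expect_lt(max(abs(sc2 - (2 * sc + 3 * risk_score(sig, Y)$score))), 1e-10)
  expect_error(risk_score(sig, X[-1, , drop = FALSE]), "ARPC5L")
})

test_that("gene_signature drops zero coefficients and validates its inputs", {
  sig <- gene_signature(c("a", "b", "c"), c(1, 0, -2))
  expect_equal(sig$genes, c("a", "c"))
  expect_error(gene_signature(c("a", "b"), 1), "equal length")
  expect_error(gene_signature("a", 0), "nonzero")
  expect_error(gene_signature(c("a", "a"), c(1, 2)), "duplicate")
})

test_that("spike-and-slab EM at s0 = s1 degenerates to the fixed-penalty lasso", {
  set.seed(72)
  n <- 200; p <- 15
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, sprintf("g%02d", 1:p)))
  tm <- rexp(n, exp(0.7 * X[, 1] - 0.7 * X[, 2]))
  ev <- rbinom(n, 1, 0.8)
  oc <- tibble::tibble(time = tm, event = ev)
  em <- sslasso_select(t(X), oc, s0_grid = 0.5, s1 = 0.5,
                       cv_folds = 3, cv_replicates = 1, rng_seed = 1)
  direct <- stacksurv:::cox_lasso_cd(X, tm, ev, lambda = 1 / 0.5)
  expect_lt(max(abs(em$beta_full - direct$beta)), 1e-6)
})

test_that("a strong spike returns an empty selection on pure noise", {
  empties <- 0
  reps <- 10
  for (r in seq_len(reps)) {
    set.seed(800 + r)
    n <- 300; p <- 25
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, sprintf("g%02d", 1:p)))
    oc <- random_outcome(n)
    fit <- sslasso_select(t(X), oc, s0_grid = 0.008, s1 = 1,
                          cv_folds = 3, cv_replicates = 1, rng_seed = r)
    if (length(fit$selected) == 0) empties <- empties + 1
  }
  expect_gte(empties / reps, 0.8)
})

test_that("selected-set size grows with the spike scale (aggregate monotonicity)", {
  grid <- c(0.01, 0.1, 1)
  sizes <- matrix(NA_real_, 5, length(grid))
  for (r in 1:5) {
    set.seed(820 + r)
    n <- 250; p <- 20
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, sprintf("g%02d", 1:p)))
    lp <- 0.6 * X[, 1] - 0.6 * X[, 2] + 0.3 * X[, 3]
    oc <- random_outcome(n, lp)
    for (i in seq_along(grid)) {
      fit <- sslasso_select(t(X), oc, s0_grid = grid[i], s1 = 1,
                            cv_folds = 3, cv_replicates = 1, rng_seed = r)
      sizes[r, i] <- length(fit$selected)
    }
  }
  agg <- colMeans(sizes)
  expect_true(all(diff(agg) >= 0))
})

test_that("stepwise AIC equals the exhaustive subset minimum on 3 candidates", {
  for (r in 1:5) {
    set.seed(830 + r)
    n <- 200
    X <- matrix(rnorm(n * 3), n, 3,
                dimnames = list(NULL, c("gA", "gB", "gC")))
    lp <- 0.8 * X[, 1] + 0.4 * X[, 2]       # gC is noise
    oc <- random_outcome(n, lp)
    sig <- stepwise_aic(t(X), oc, start_genes = c("gA", "gB", "gC"))
    # independent oracle: every non-empty subset scored through coxph
    subsets <- unlist(lapply(1:3, function(k)
      combn(c("gA", "gB", "gC"), k, simplify = FALSE)), recursive = FALSE)
    aics <- vapply(subsets, function(s) {
      f <- survival::coxph(survival::Surv(oc$time, oc$event) ~ X[, s],
                           ties = "breslow")
      -2 * f$loglik[2] + 2 * length(s)
    }, numeric(1))
    null_aic <- -2 * survival::coxph(survival::Surv(oc$time, oc$event) ~ 1
                                     )$loglik[1]
    best <- subsets[[which.min(aics)]]
    expect_true(min(aics) < null_aic)      # oracle itself found signal
    expect_setequal(sig$genes, best)
    expect_lt(abs(attr(sig, "aic") - min(aics)), 1e-6)
  }
})

test_that("stepwise keeps a single strong candidate and rejects an empty start", {
  set.seed(84)
  n <- 150
  X <- matrix(rnorm(n), n, 1, dimnames = list(NULL, "g1"))
  oc <- random_outcome(n, 0.9 * X[, 1])
  sig <- stepwise_aic(t(X), oc, start_genes = "g1")
  expect_equal(sig$genes, "g1")
  expect_error(stepwise_aic(t(X), oc, start_genes = character(0)),
               "at least one")
})

test_that("PH check is calibrated under proportional hazards and detects a sign-switching effect", {
  # single-covariate model: global chi-square equals the per-covariate one
  set.seed(85)
  n <- 200
  x <- rnorm(n)
  oc <- random_outcome(n, 0.5 * x)
  pt1 <- ph_test(matrix(x, ncol = 1, dimnames = list(NULL, "x")), oc)
  expect_equal(pt1$global$chi2, pt1$per_covariate$chi2[1], tolerance = 1e-8)

  # power: effect +1 before the median event time, -1 after
  rejections <- 0
  reps <- 10
  for (r in seq_len(reps)) {
    set.seed(860 + r)
    n <- 500
    x <- rnorm(n)
    h <- 0.01
    t1 <- rexp(n, h * exp(x))
    cp <- log(2) / h                 # population median at x = 0
    tm <- ifelse(t1 <= cp, t1, cp + rexp(n, h * exp(-x)))
    pt <- ph_test(matrix(x, ncol = 1, dimnames = list(NULL, "x")),
                  tibble::tibble(time = tm, event = 1L))
    if (pt$global$p < 0.05) rejections <- rejections + 1
  }
  expect_gte(rejections / reps, 0.8)
  expect_error(ph_test(matrix(x, ncol = 1),
                       tibble::tibble(time = 1:3, event = c(1, 0, 0))),
               "2 events")
})
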