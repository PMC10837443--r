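# Breslow partial-likelihood engine shared by the univariate screen, the
# spike-and-slab lasso M-step, stepwise AIC and the stacking meta-fit.
# survival::coxph is deliberately NOT called here; it serves as the
# independent cross-check in the test suite.

# Precompute the time ordering and tie-group structure once per outcome.
cox_risk_structure <- function(time, event) {
  stopifnot(length(time) == length(event))
  if (any(!is.finite(time)) || any(time <= 0)) {
    stop("survival times must be finite and positive", call. = FALSE)
  }
  if (!all(event %in% c(0, 1))) {
    stop("event indicator must be 0 (censored) or 1 (dead)", call. = FALSE)
  }
  ord <- order(time)
  t_ord <- time[ord]
  grp <- cumsum(!duplicated(t_ord))          # tie group id, ascending time
  first <- which(!duplicated(t_ord))         # first row of each tie group
  d_grp <- as.vector(rowsum(event[ord], grp))
  list(
    ord = ord, n = length(time), grp = grp, first = first,
    d_ord = event[ord], d_grp = d_grp, n_events = sum(event)
  )
}

# Reverse cumulative sum: out[i] = sum(x[i:n])
.revcumsum <- function(x) rev(cumsum(rev(x)))

# Log-likelihood, gradient and observed information of the Breslow partial
# likelihood at linear predictor eta = X beta + offset.
cox_pl_deriv <- function(X, beta, rs, offset = NULL, order_applied = FALSE) {
  X <- as.matrix(X)
  p <- ncol(X)
  eta <- drop(X %*% beta)
  if (!is.null(offset)) eta <- eta + offset
  if (!order_applied) {
    Xo <- X[rs$ord, , drop = FALSE]
    eta_o <- eta[rs$ord]
  } else {
    Xo <- X
    eta_o <- eta
  }
  eta_c <- eta_o - max(eta_o)                # guard exp overflow
  w <- exp(eta_c)
  S0 <- .revcumsum(w)[rs$first]
  ev_grp <- rs$d_grp > 0
  wX <- w * Xo
  S1 <- apply(wX, 2, .revcumsum)[rs$first, , drop = FALSE]

  loglik <- sum(eta_o[rs$d_ord == 1]) -
    sum(rs$d_grp[ev_grp] * (log(S0[ev_grp]) + max(eta_o)))
  m <- S1 / S0                               # p columns, one row per group
  grad <- colSums(Xo[rs$d_ord == 1, , drop = FALSE]) -
    colSums(rs$d_grp[ev_grp] * m[ev_grp, , drop = FALSE])

  # observed information: sum_g d_g [ S2/S0 - m m' ]
  info <- matrix(0, p, p)
  for (j in seq_len(p)) {
    wXj <- wX * Xo[, j]
    S2j <- apply(wXj, 2, .revcumsum)[rs$first, , drop = FALSE]
    info[j, ] <- colSums(rs$d_grp[ev_grp] *
                           (S2j[ev_grp, , drop = FALSE] / S0[ev_grp])) -
      colSums(rs$d_grp[ev_grp] * m[ev_grp, j] * m[ev_grp, , drop = FALSE])
  }
  list(loglik = loglik, grad = grad, info = info)
}

# Log-likelihood only (used by CVPL and the stacking objective).
cox_pl_loglik <- function(X, beta, rs, offset = NULL) {
  eta <- drop(as.matrix(X) %*% beta)
  if (!is.null(offset)) eta <- eta + offset
  eta_o <- eta[rs$ord]
  mx <- max(eta_o)
  w <- exp(eta_o - mx)
  S0 <- .revcumsum(w)[rs$first]
  ev <- rs$d_grp > 0
  sum(eta_o[rs$d_ord == 1]) - sum(rs$d_grp[ev] * (log(S0[ev]) + mx))
}

# Per-sample first derivative g_i and (positive) diagonal curvature h_i of the
# partial likelihood in eta, for the IRLS working response of the lasso path.
cox_pl_eta_deriv <- function(eta, rs) {
  eta_o <- eta[rs$ord]
  mx <- max(eta_o)
  w <- exp(eta_o - mx)
  S0 <- .revcumsum(w)[rs$first]                  # risk-set sums per tie group
  dg <- rs$d_grp
  haz1 <- cumsum(dg / S0)[rs$grp]                # sum_{s <= t_i} d_s / S0(s)
  haz2 <- cumsum(dg / S0^2)[rs$grp]
  g_o <- rs$d_ord - w * haz1
  h_o <- w * haz1 - w^2 * haz2
  g <- numeric(rs$n); h <- numeric(rs$n)
  g[rs$ord] <- g_o
  h[rs$ord] <- h_o
  list(g = g, h = pmax(h, 1e-10))
}

#' Fit a Cox proportional hazards model by Newton-Raphson
#'
#' Maximizes the Breslow partial likelihood with step-halving so the
#' log-likelihood never decreases across iterations. An optional per-covariate
#' ridge penalty stabilizes degenerate columns (a fully constant, penalized
#' covariate stays at coefficient zero).
#'
#' @param covariates Numeric matrix (samples x covariates) or a single vector.
#' @param outcome A survival outcome: data frame with columns `time` (days)
#'   and `event` (1 = dead, 0 = censored), or a [survival::Surv] object.
#' @param penalty_weights Optional non-negative per-covariate ridge weights
#'   \eqn{\lambda_j}; the penalized log-likelihood is
#'   \eqn{l(\beta) - \tfrac12 \sum_j \lambda_j \beta_j^2}.
#' @param offset Optional per-sample offset added to the linear predictor.
#' @param tol Convergence threshold on the max absolute (penalized) score.
#' @param max_iter Maximum Newton iterations.
#'
#' @return A list of class `"cox_fit"`: `beta`, `loglik`, `covariance`
#'   (inverse observed information), `se`, `iterations`, `converged`,
#'   `flagged` (monotone-likelihood guard hit), `n`, `n_events`.
#' @examples
#' set.seed(1)
#' x <- rnorm(60)
#' time <- rexp(60, exp(0.7 * x))
#' fit <- fit_cox(x, data.frame(time = time, event = 1))
#' fit$beta
#' @export
fit_cox <- function(covariates, outcome, penalty_weights = NULL,
                    offset = NULL, tol = 1e-8, max_iter = 50) {
  X <- as.matrix(covariates)
  oc <- as_outcome(outcome)
  if (nrow(X) != length(oc$time)) {
    stop("covariates and outcome have different numbers of samples",
         call. = FALSE)
  }
  if (sum(oc$event) < 1) stop("no events in the outcome", call. = FALSE)
  if (any(!is.finite(X))) stop("covariates must be finite", call. = FALSE)
  p <- ncol(X)
  lam <- if (is.null(penalty_weights)) rep(0, p) else rep(penalty_weights,
                                                          length.out = p)
  if (any(lam < 0)) stop("penalty_weights must be non-negative", call. = FALSE)
  const_col <- apply(X, 2, function(col) diff(range(col)) == 0)
  if (any(const_col & lam == 0)) {
    stop("constant covariate column without penalty: ",
         paste(which(const_col & lam == 0), collapse = ", "), call. = FALSE)
  }
  rs <- cox_risk_structure(oc$time, oc$event)

  beta <- rep(0, p)
  d <- cox_pl_deriv(X, beta, rs, offset)
  pll <- d$loglik - 0.5 * sum(lam * beta^2)
  converged <- FALSE
  flagged <- FALSE
  iter <- 0
  cap <- 15
  while (iter < max_iter) {
    iter <- iter + 1
    score <- d$grad - lam * beta
    info <- d$info + diag(lam, p)
    step <- tryCatch(solve(info, score), error = function(e) {
      solve(info + diag(1e-8, p), score)
    })
    # step-halving: the penalized log-likelihood must not decrease
    alpha <- 1
    repeat {
      beta_new <- beta + alpha * step
      d_new <- cox_pl_deriv(X, beta_new, rs, offset)
      pll_new <- d_new$loglik - 0.5 * sum(lam * beta_new^2)
      if (pll_new >= pll - 1e-12 || alpha < 1e-4) break
      alpha <- alpha / 2
    }
    beta <- beta_new; d <- d_new; pll <- pll_new
    if (any(abs(beta) > cap)) {           # monotone likelihood guard
      flagged <- TRUE
      beta <- pmin(pmax(beta, -cap), cap)
      d <- cox_pl_deriv(X, beta, rs, offset)
      pll <- d$loglik - 0.5 * sum(lam * beta^2)
      warning("possible monotone likelihood; coefficients capped at |", cap,
              "|", call. = FALSE)
      break
    }
    if (max(abs(d$grad - lam * beta)) < tol) {
      converged <- TRUE
      break
    }
  }
  info <- d$info + diag(lam, p)
  cov <- tryCatch(solve(info), error = function(e) {
    matrix(NA_real_, p, p)
  })
  structure(list(
    beta = stats::setNames(drop(beta), colnames(X)),
    loglik = d$loglik, covariance = cov, se = sqrt(pmax(diag(cov), 0)),
    iterations = iter, converged = converged, flagged = flagged,
    n = rs$n, n_events = rs$n_events
  ), class = "cox_fit")
}

# Weighted-L1 penalized Cox fit (Breslow ties) by outer IRLS quadratic
# approximation + cyclic coordinate descent with an active-set strategy,
# compiled (src/cox_cd.cpp). `lambda` is per-coefficient and applies to
# |beta_j| on the (unscaled) partial log-likelihood, i.e. the objective is
# l(beta) - sum_j lambda_j |beta_j|.
cox_lasso_cd <- function(X, time, event, lambda, beta_init = NULL,
                         tol = 1e-8, max_outer = 100, max_sweeps = 1000) {
  X <- as.matrix(X)
  p <- ncol(X)
  lambda <- rep(lambda, length.out = p)
  rs <- cox_risk_structure(time, event)
  beta <- if (is.null(beta_init)) rep(0, p) else as.numeric(beta_init)
  # internal centring/scaling is an exact reparametrization (the partial
  # likelihood is shift-invariant; the penalty is rescaled per column) but
  # conditions the coordinate updates
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  out <- .cox_cd_fit(Xs, rs$ord - 1L, rs$grp - 1L, rs$first - 1L,
                     as.numeric(rs$d_grp), as.integer(rs$d_ord),
                     lambda / scl, beta * scl, tol,
                     as.integer(max_outer), as.integer(max_sweeps))
  list(beta = stats::setNames(as.numeric(out$beta) / scl, colnames(X)),
       loglik = out$loglik, objective = out$objective)
}

# ---- shared input coercion ---------------------------------------------

# Accept a survival outcome as a data frame (time/event, optionally
# time_days), a Surv object, or a list with $time/$event.
as_outcome <- function(outcome) {
  if (inherits(outcome, "Surv")) {
    return(list(time = as.numeric(outcome[, "time"]),
                event = as.numeric(outcome[, "status"])))
  }
  if (is.data.frame(outcome)) {
    tcol <- intersect(c("time", "time_days"), names(outcome))[1]
    if (is.na(tcol) || !"event" %in% names(outcome)) {
      stop("outcome needs `time` (or `time_days`) and `event` columns",
           call. = FALSE)
    }
    return(list(time = as.numeric(outcome[[tcol]]),
                event = as.numeric(outcome[["event"]]),
                sample_id = if ("sample_id" %in% names(outcome))
                  as.character(outcome[["sample_id"]]) else NULL))
  }
  if (is.list(outcome) && all(c("time", "event") %in% names(outcome))) {
    return(list(time = as.numeric(outcome$time),
                event = as.numeric(outcome$event),
                sample_id = outcome$sample_id))
  }
  stop("cannot interpret `outcome` as a survival outcome", call. = FALSE)
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("Cox model (Breslow ties), n =", x$n, ", events =", x$n_events, "\n")
  print(tibble::tibble(
    term = names(x$beta) %||% paste0("x", seq_along(x$beta)),
    beta = unname(x$beta), se = x$se, hr = exp(unname(x$beta))
  ))
  invisible(x)
}
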