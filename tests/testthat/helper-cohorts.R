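# Shared synthetic fixtures, built once per test run and memoized.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(key, maker) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, maker(), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# mid-sized cohort with 3 causal genes, used across modules
std_cohort <- function() {
  fixture("std_cohort", function() {
    simulate_cohort(sim_config(n_samples = 300, n_genes = 100,
                               n_correlated = 20, n_causal = 3,
                               rng_seed = 101))
  })
}

# small uncensored outcome generator for oracle checks
random_outcome <- function(n, lp = rep(0, n), censor = 0.3,
                           baseline = 0.01) {
  t_event <- rexp(n, baseline * exp(lp))
  if (censor > 0) {
    t_cens <- rexp(n, baseline * censor / (1 - censor))
    tibble::tibble(time = pmin(t_event, t_cens),
                   event = as.integer(t_event <= t_cens))
  } else {
    tibble::tibble(time = t_event, event = 1L)
  }
}

# independent partial-likelihood evaluation through survival::coxph
# (offset-only fit), used as the cross-check engine
coxph_loglik_at <- function(lp, time, event) {
  fit <- survival::coxph(survival::Surv(time, event) ~ offset(lp),
                         ties = "breslow")
  fit$loglik[1]
}
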