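# Analytic curves reused across tests.

oracle_exp <- function(rate, target = "event") {
  cond_surv_fn(function(t, w) exp(-rate * pmax(t, 0)),
               Q = function(p, w) -log(p) / rate,
               target = target)
}

oracle_one <- function(target = "censoring") {
  cond_surv_fn(function(t, w) rep(1, length(t)),
               Q = function(p, w) rep(Inf, length(p)), target = target)
}

# fitted covariate-free exponential with rate exactly 1
# (2 events over total follow-up 2)
fit_exponential_fixture <- function() {
  fit_survival(rc_data(W = c(0, 0), Y = c(0.5, 1.5), Delta = c(1, 1)),
               model_spec("exponential"))
}

# covariate-free exponential right-censored sample as an rc_data object
sim_exp_data <- function(n, rate_t = 0.5, rate_c = 0.3, seed = 1) {
  set.seed(seed)
  t_ <- rexp(n, rate_t)
  c_ <- rexp(n, rate_c)
  rc_data(W = rep(0, n), Y = pmin(t_, c_), Delta = as.numeric(t_ <= c_))
}
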