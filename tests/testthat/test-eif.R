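test_that("lower prediction bounds combine quantile, censoring cap and horizon", {
  S1 <- oracle_exp(1)
  G1 <- oracle_one()
  L <- build_lpb(S1, G1, tau = 0.1)
  expect_equal(predict(L, 0), -log(0.9), tolerance = 1e-10)

  # censoring cap: min(log 2, -log(0.001)) = log 2
  L2 <- build_lpb(S1, oracle_exp(1, target = "censoring"), tau = 0.5,
                  eta2 = 0.001)
  expect_equal(predict(L2, 0), log(2), tolerance = 1e-10)

  # horizon cap
  L3 <- build_lpb(S1, G1, tau = 0.5, t0 = 0.25)
  expect_equal(predict(L3, 0), 0.25)

  # tau -> 0: bound -> 0 and plug-in coverage -> 1
  L4 <- build_lpb(S1, G1, tau = 1e-6)
  expect_lt(predict(L4, 0), 1e-5)
  expect_gt(plugin_coverage(S1, L4, 0), 1 - 1e-5)

  expect_error(build_lpb(S1, G1, tau = 0), "tau")
  expect_error(build_lpb(S1, G1, tau = 0.1, eta2 = 1), "eta2")
})

test_that("phi matches its analytic closed form for exponential nuisances", {
  # S = G = exp(-t), L = 1: the hazard integral is int_0^u exp(2v) dv
  S <- oracle_exp(1)
  G <- oracle_exp(1, target = "censoring")
  phi_exact <- function(y, delta) {
    upper <- min(y, 1)
    integral <- (exp(2 * upper) - 1) / 2
    ind <- if (y <= 1 && delta == 1) exp(2 * y) else 0
    exp(-1) * (1 - (ind - integral))
  }
  expect_equal(phi_exact(0.5, 1), exp(-1) * (1 - exp(1) + (exp(1) - 1) / 2))
  for (o in list(c(0.5, 1), c(2, 1), c(0.5, 0), c(2, 0), c(1, 1))) {
    expect_equal(phi_eif(S, G, 1, w = 0, delta = o[2], y = o[1]),
                 phi_exact(o[1], o[2]), tolerance = 2e-6)
  }
  # dual route: numeric quadrature oracle for the integral term
  quad <- stats::integrate(function(u) exp(2 * u), 0, 0.5)$value
  expect_equal(phi_eif(S, G, 1, w = 0, delta = 1, y = 0.5),
               exp(-1) * (1 - (exp(1) - quad)), tolerance = 2e-6)
})

test_that("the trivial bound L = 0 gives phi = 1 for every observation", {
  S <- oracle_exp(0.7)
  G <- oracle_exp(0.2, target = "censoring")
  for (o in list(c(0.5, 1), c(2, 0), c(0, 1))) {
    expect_identical(phi_eif(S, G, lpb_zero(), w = 0, delta = o[2], y = o[1]),
                     1)
  }
})

test_that("plug-in coverage averages the fitted survival at the bound", {
  S <- cond_surv_fn(function(t, w) exp(-w * pmax(t, 0)),
                    Q = function(p, w) -log(p) / w)
  expect_equal(plugin_coverage(S, function(w) 1 / w, W_cal = c(1, 2)),
               exp(-1), tolerance = 1e-12)
  expect_equal(plugin_coverage(S, lpb_zero(), W_cal = c(1, 2)), 1)
  expect_equal(plugin_coverage(S, function(w) 0.5, W_cal = 2), exp(-1))
  expect_error(plugin_coverage(S, lpb_zero(), W_cal = numeric(0)[-1]), "empty")
})

test_that("one-step estimate equals the mean of phi and variance matches", {
  dd <- sim_exp_data(150, seed = 4)
  S <- fit_survival(dd, model_spec("km"))
  G <- fit_censoring(dd, model_spec("km"))
  L <- 0.8
  est <- suppressWarnings(one_step_coverage(S, G, L, dd, beta = 0.05))
  phi <- vapply(seq_len(nobs_rc(dd)), function(i) {
    suppressWarnings(phi_eif(S, G, L, dd$W[i, ], dd$Delta[i], dd$Y[i]))
  }, 0)
  expect_equal(est$psi_onestep, mean(phi), tolerance = 1e-13)
  expect_equal(est$psi_plugin, sc_eval(S, L, 0))
  expect_equal(est$sigma, sqrt(mean((phi - est$psi_plugin)^2)),
               tolerance = 1e-12)
  expect_equal(est$clb, est$psi_onestep - qnorm(0.95) * est$sigma /
                 sqrt(est$n_cal))
})

test_that("wald confidence lower bounds follow the normal quantile", {
  # z_{0.05} = 1.6448536... frozen from the standard normal quantile table
  expect_equal(wald_clb(0.92, 0.3, 900, 0.05), 0.92 - 1.6448536 * 0.01,
               tolerance = 1e-7)
  expect_equal(wald_clb(0.5, 0, 100, 0.05), 0.5)
  expect_equal(wald_clb(0.5, 0.3, 100, 0.5), 0.5)  # z = 0 at beta = 1/2
  expect_error(wald_clb(0.5, -1, 100, 0.05), "sigma")
  expect_error(wald_clb(0.5, 0.1, 0, 0.05), "n")
  expect_error(wald_clb(0.5, 0.1, 100, 1), "beta")
})

test_that("without censoring the one-step matches the uncensored fraction", {
  set.seed(31)
  n <- 5000
  t_ <- rexp(n, 1)
  dd <- rc_data(W = rep(0, n), Y = t_, Delta = rep(1, n))
  S <- oracle_exp(1)
  G <- oracle_one()
  L <- 0.3
  est <- one_step_coverage(S, G, L, dd)
  brute <- mean(t_ > L)
  se <- sqrt(exp(-L) * (1 - exp(-L)) / n)
  expect_lt(abs(est$psi_onestep - brute), 3 * se)
  expect_lt(abs(est$psi_onestep - exp(-L)), 4 * se)
})

test_that("batched and per-row influence engines agree", {
  setting <- sim_setting(2)
  sim <- sim_generate(setting, 400, seed = 91)
  tau_grid <- c(0.05, 0.1, 0.2, 0.4)
  pairs <- list(
    list(S = fit_survival(sim$data, model_spec("weibull")),
         G = fit_censoring(sim$data, model_spec("km")), tol = 1e-6),
    list(S = fit_survival(sim$data, model_spec("lognormal")),
         G = fit_censoring(sim$data, model_spec("coxph")), tol = 1e-6),
    list(S = fit_survival(sim$data, model_spec("coxph")),
         G = fit_censoring(sim$data, model_spec("weibull")), tol = 1e-10),
    list(S = fit_survival(sim$data, model_spec("km")),
         G = fit_censoring(sim$data, model_spec("km")), tol = 1e-10),
    list(S = oracle_survival(setting),
         G = oracle_censoring(setting), tol = 1e-6))
  for (pr in pairs) {
    Lmat <- pmin(tcsurv:::quantile_matrix(pr$S, 1 - tau_grid, sim$data$W),
                 tcsurv:::quantile_matrix(pr$G, 1e-3, sim$data$W)[, 1], 20)
    fast <- suppressWarnings(tcsurv:::eif_core(pr$S, pr$G, sim$data, Lmat))
    ref <- suppressWarnings(tcsurv:::eif_core_ref(pr$S, pr$G, sim$data, Lmat))
    expect_equal(colMeans(fast$SL), colMeans(ref$SL), tolerance = 1e-10)
    expect_equal(colMeans(fast$PHI), colMeans(ref$PHI), tolerance = pr$tol)
  }
})

test_that("influence function is mean zero under the true nuisances", {
  setting <- sim_setting(2)
  S0 <- oracle_survival(setting)
  G0 <- oracle_censoring(setting)
  L <- build_lpb(S0, G0, tau = 0.1)
  psi0 <- true_coverage(L, setting)$estimate
  sim <- sim_generate(setting, n = 20000, seed = 123)
  est <- one_step_coverage(S0, G0, L, sim$data)
  # psi_onestep - psi0 = mean of the (mean-zero) influence function
  expect_lt(abs(est$psi_onestep - psi0),
            4 * est$sigma / sqrt(est$n_cal))
})
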