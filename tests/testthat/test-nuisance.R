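test_that("product-limit estimates match hand computation and survfit", {
  d <- rc_data(W = rep(0, 3), Y = c(1, 2, 3), Delta = c(1, 0, 1))
  S <- fit_survival(d, model_spec("km"))
  expect_equal(sc_eval(S, c(1, 2, 3), w = 0), c(2 / 3, 2 / 3, 0))
  expect_equal(sc_eval(S, 0.5, w = 0), 1)
  expect_equal(sc_eval_left(S, 1, w = 0), 1)

  # censoring target: indicator flip gives the product limit of C
  G <- fit_censoring(d, model_spec("km"))
  expect_equal(sc_eval(G, c(1, 2), w = 0), c(1, 1 / 2))
  d2 <- rc_data(W = rep(0, 2), Y = c(1, 2), Delta = c(0, 1))
  expect_equal(sc_eval(fit_censoring(d2, model_spec("km")), 1, 0), 1 / 2)

  # symmetry: swapping the roles of T and C swaps the two fits
  d_swap <- rc_data(W = d$W, Y = d$Y, Delta = 1 - d$Delta)
  S_swap <- fit_survival(d_swap, model_spec("km"))
  expect_equal(sc_eval(S_swap, c(1, 2, 3), 0), sc_eval(G, c(1, 2, 3), 0))

  # independent cross-check against survival::survfit on continuous data
  dd <- sim_exp_data(300, seed = 5)
  S2 <- fit_survival(dd, model_spec("km"))
  sf <- survival::survfit(survival::Surv(dd$Y, dd$Delta) ~ 1)
  expect_equal(sc_eval(S2, sf$time, 0), sf$surv, tolerance = 1e-12)
})

test_that("uncensored data yield a censoring survival identically one", {
  d <- rc_data(W = runif(20), Y = rexp(20), Delta = rep(1, 20))
  G <- fit_censoring(d, model_spec("weibull"))
  expect_equal(sc_eval(G, c(0.1, 1, max(d$Y)), w = 0.5), rep(1, 3))
})

test_that("event model requires at least one event", {
  d <- rc_data(W = 1:5, Y = 1:5, Delta = rep(0, 5))
  expect_error(fit_survival(d, model_spec("km")), "no observed events")
})

test_that("Weibull fit recovers exponential data at large n", {
  set.seed(2024)
  n <- 5000
  w <- runif(n)
  d <- rc_data(W = w, Y = rexp(n, 1), Delta = rep(1, n))
  fit <- fit_survival(d, model_spec("weibull"))
  expect_equal(1 / fit$scale, 1, tolerance = 0.05)    # Weibull shape ~ 1
  expect_equal(unname(fit$coef[2]), 0, tolerance = 0.05)  # no covariate effect
  expect_equal(sc_eval(fit, 1, w = 0.5), exp(-1), tolerance = 0.03)
})

test_that("generalized-inverse quantiles follow their definition", {
  # step curve: S = 1 on [0,2), 0.6 on [2,5), 0.2 on [5, Inf)
  d <- rc_data(W = rep(0, 5), Y = c(2, 2, 5, 5, 5), Delta = c(1, 1, 1, 1, 0))
  S <- fit_survival(d, model_spec("km"))
  expect_equal(sc_eval(S, c(1, 2, 4, 5, 7), 0), c(1, 0.6, 0.6, 0.2, 0.2))
  expect_equal(sc_quantile(S, 0.7, 0), 2)
  expect_equal(sc_quantile(S, 0.5, 0), 5)
  expect_equal(sc_quantile(S, 0.6, 0), 2)   # inf of {t : S(t) <= 0.6}
  expect_equal(sc_quantile(S, 1, 0), 0)
  expect_equal(sc_quantile(S, 0.1, 0), Inf) # never reached on the grid
  expect_error(sc_quantile(S, -0.1, 0), "0, 1")
  expect_error(sc_quantile(S, 1.1, 0), "0, 1")

  # smooth closed form: Exp(0.1)
  G <- oracle_censoring(sim_setting(1))
  expect_equal(sc_quantile(G, 0.9, w = 1), -log(0.9) / 0.1, tolerance = 1e-10)
  expect_equal(sc_quantile(G, 1, w = 1), 0)

  # consistency property on fitted curves: S(q(p)) <= p, S(t) > p before q(p)
  dd <- sim_exp_data(200, seed = 8)
  for (fit in list(fit_survival(dd, model_spec("km")),
                   fit_survival(dd, model_spec("weibull")))) {
    for (p in c(0.9, 0.5, 0.25)) {
      q <- sc_quantile(fit, p, 0)
      expect_lte(sc_eval(fit, q, 0), p + 1e-12)
      tt <- seq(0, q * 0.999, length.out = 50)
      expect_true(all(sc_eval(fit, tt, 0) > p))
    }
  }
})

test_that("cumulative-hazard increments reproduce the curve", {
  # rate-1 exponential via the closed-form family: Lambda(0.5) = 0.5
  fit <- fit_exponential_fixture()
  inc <- sc_cumhaz(fit, w = 0, upper = 0.5)
  expect_equal(sum(inc$dLambda), 0.5, tolerance = 1e-9)
  expect_length(sc_cumhaz(fit, w = 0, upper = 0)$u, 0L)

  # discrete hazards of the step curve 1 -> 0.6 -> 0.2
  d <- rc_data(W = rep(0, 5), Y = c(2, 2, 5, 5, 5), Delta = c(1, 1, 1, 1, 0))
  S <- fit_survival(d, model_spec("km"))
  inc <- sc_cumhaz(S, w = 0, upper = 6)
  expect_equal(inc$u, c(2, 5))
  expect_equal(inc$dLambda, c(0.4, (0.6 - 0.2) / 0.6))
  # product integral rebuilds the step curve exactly
  expect_equal(cumprod(1 - inc$dLambda), c(0.6, 0.2), tolerance = 1e-12)

  # smooth family: exp(-sum dLambda) matches S within 1e-6
  dd <- sim_exp_data(400, seed = 3)
  wb <- fit_survival(dd, model_spec("weibull"))
  for (t in c(0.5, 1, 3)) {
    inc <- sc_cumhaz(wb, w = 0, upper = t)
    expect_equal(exp(-sum(inc$dLambda)), sc_eval(wb, t, 0), tolerance = 1e-6)
  }
})

test_that("cox and forest fits produce valid monotone curves", {
  set.seed(77)
  n <- 400
  w <- cbind(w1 = runif(n, 0, 4))
  t_ <- rexp(n, 0.2 * exp(0.3 * w[, 1]))
  c_ <- rexp(n, 0.2)
  d <- rc_data(W = w, Y = pmin(t_, c_), Delta = as.numeric(t_ <= c_))
  for (fam in c("coxph", "rsf")) {
    fit <- fit_survival(d, model_spec(fam))
    cv <- sc_curve(fit, w = 2)
    expect_true(all(diff(cv$surv) <= 1e-12))
    expect_true(all(cv$surv >= 0 & cv$surv <= 1))
    # higher covariate = higher hazard = lower survival (strong effect)
    expect_lt(sc_eval(fit, 2, w = 3.8), sc_eval(fit, 2, w = 0.2) + 1e-8)
  }
  # cox recovers the log-linear effect approximately
  cx <- fit_survival(d, model_spec("coxph"))
  expect_equal(unname(cx$coef["w1"]), 0.3, tolerance = 0.12)
})

test_that("cv-select picks a candidate and returns a usable fit", {
  set.seed(11)
  sim <- sim_generate(sim_setting(2), n = 300, seed = 11)
  fit <- fit_survival(sim$data, model_spec("cv_select"))
  expect_s3_class(fit, "cond_surv")
  expect_true(fit$selected %in% c("km", "weibull", "lognormal", "coxph"))
  expect_length(fit$cv_scores, 4L)
  s <- sc_eval(fit, c(0.5, 1, 2, 5), w = 1)
  expect_true(all(diff(s) <= 1e-12) && all(s >= 0 & s <= 1))
  # the censoring side: flip and fit
  G <- fit_censoring(sim$data, model_spec("cv_select"))
  expect_s3_class(G, "cond_surv")
})
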