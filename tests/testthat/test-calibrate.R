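test_that("prefix-maximal selection follows the acceptance rule", {
  grid <- c(0.05, 0.10, 0.15, 0.20)
  # 0.15 breaks the prefix; 0.20 is unreachable despite its CLB being fine
  expect_equal(select_tau_apac(grid, c(0.95, 0.91, 0.89, 0.92), 0.1), 0.10)
  expect_equal(select_tau_apac(grid, c(0.95, 0.95, 0.92, 0.91), 0.1), 0.20)
  expect_true(is.na(select_tau_apac(grid, c(0.89, 0.95, 0.95, 0.95), 0.1)))
  expect_error(select_tau_apac(numeric(0), numeric(0), 0.1), "empty")

  expect_equal(select_tau_marginal(c(0.05, 0.10), c(0.93, 0.905), 0.1), 0.10)
  expect_true(is.na(select_tau_marginal(c(0.05, 0.10), c(0.89, 0.95), 0.1)))

  # marginal selection is never more conservative than the CLB-based one,
  # and truncating the grid above the selection never changes it
  set.seed(5)
  for (rep in 1:25) {
    K <- sample(3:12, 1)
    grid <- sort(runif(K, 0.01, 0.5))
    psi <- runif(K, 0.85, 1)
    clb <- psi - runif(K, 0, 0.05)
    t_apac <- select_tau_apac(grid, clb, 0.1)
    t_marg <- select_tau_marginal(grid, psi, 0.1)
    if (!is.na(t_apac)) {
      expect_true(!is.na(t_marg) && t_marg >= t_apac)
      keep <- grid <= t_apac
      expect_equal(select_tau_apac(grid[keep], clb[keep], 0.1), t_apac)
    }
  }
})

test_that("calibration is deterministic and honours its own acceptance rule", {
  sim <- sim_generate(sim_setting(2), n = 400, seed = 21)
  cfg <- calibration_config(surv_spec = model_spec("weibull"),
                            cens_spec = model_spec("km"), seed = 21)
  f1 <- tcsurv_calibrate(sim$data, cfg)
  f2 <- tcsurv_calibrate(sim$data, cfg)
  expect_equal(f1$tau_hat, f2$tau_hat)
  expect_equal(f1$table, f2$table)
  expect_equal(predict(f1, sim$data$W[1:5, , drop = FALSE]),
               predict(f2, sim$data$W[1:5, , drop = FALSE]))

  expect_false(is.na(f1$tau_hat))
  row <- f1$table[match(f1$tau_hat, f1$table$tau), ]
  expect_gte(row$clb, 1 - cfg$alpha)
  # every prefix element also passes
  expect_true(all(f1$table$clb[f1$table$tau <= f1$tau_hat] >= 1 - cfg$alpha))
  # the per-tau table covers the whole grid
  expect_equal(f1$table$tau, cfg$tau_grid)
  expect_true(all(f1$table$sigma >= 0))
  expect_true(all(f1$table$psi_plugin >= 0 & f1$table$psi_plugin <= 1))
})

test_that("marginal mode is never more conservative than apac mode", {
  sim <- sim_generate(sim_setting(2), n = 400, seed = 44)
  base <- calibration_config(surv_spec = model_spec("weibull"),
                             cens_spec = model_spec("km"), seed = 44)
  marg <- base
  marg$mode <- "marginal"
  f_apac <- tcsurv_calibrate(sim$data, base)
  f_marg <- tcsurv_calibrate(sim$data, marg)
  expect_equal(f_apac$table$psi_onestep, f_marg$table$psi_onestep)
  expect_false(is.na(f_marg$tau_hat))
  expect_gte(f_marg$tau_hat, f_apac$tau_hat)
  # marginal selection targets the point estimate itself
  row <- f_marg$table[match(f_marg$tau_hat, f_marg$table$tau), ]
  expect_gte(row$psi_onestep, 1 - marg$alpha)
})

test_that("a tiny tau grid under heavy censoring stays conservative", {
  setting <- sim_setting(3)   # ~73% censored
  sim <- sim_generate(setting, n = 300, seed = 33)
  cfg <- calibration_config(tau_grid = 0.001,
                            surv_spec = model_spec("weibull"),
                            cens_spec = model_spec("weibull"), seed = 33)
  fit <- suppressMessages(tcsurv_calibrate(sim$data, cfg))
  tc <- true_coverage(fit$lpb, setting)$estimate
  expect_gte(tc, 0.95)   # NONE fallback or a near-zero bound: coverage ~ 1
  expect_true(all(predict(fit, sim$data$W) >= 0))
})

test_that("the zero-bound fallback is returned when no tau qualifies", {
  # calibration rows far too few for any CLB to clear 0.99
  sim <- sim_generate(sim_setting(3), n = 40, seed = 3)
  cfg <- calibration_config(alpha = 0.01, beta = 0.01,
                            tau_grid = c(0.3, 0.4, 0.5),
                            surv_spec = model_spec("km"),
                            cens_spec = model_spec("km"), seed = 3)
  fit <- suppressMessages(suppressWarnings(tcsurv_calibrate(sim$data, cfg)))
  if (is.na(fit$tau_hat)) {
    expect_equal(predict(fit, sim$data$W), rep(0, nobs_rc(sim$data)))
    expect_equal(true_coverage(fit$lpb, sim_setting(3))$estimate, 1)
  } else {
    succeed("a tau qualified on this draw; fallback not exercised")
  }
})
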