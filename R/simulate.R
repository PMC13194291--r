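# Synthetic benchmark settings with oracle access to the truth.
#
# Common template: W ~ Unif([0, 4]^p), T | W ~ LogNormal(mu(W), sigma(W)^2),
# C | W exponential or lognormal.  Six settings ranging from univariate with
# independent censoring to 10-dimensional with covariate-dependent censoring
# and heteroscedastic noise.

#' Benchmark simulation settings
#'
#' Returns the definition of one of six synthetic settings: covariates
#' `W ~ Unif([0, 4]^p)`, event time `T | W ~ LogNormal(mu(W), sigma(W)^2)`
#' and a censoring law `C | W`:
#'
#' | id | p  | mu(w)                          | sigma(w)    | C given W                  |
#' |----|----|--------------------------------|-------------|----------------------------|
#' | 1  | 1  | `0.632 sqrt(w)`                | 1           | Exp(0.1)                   |
#' | 2  | 1  | `3` if `w > 2` else `w`        | 0.5         | Exp(0.1)                   |
#' | 3  | 1  | `2` if `w > 2` else `w`        | 0.5         | Exp(0.25 + (6 + w)/100)    |
#' | 4  | 1  | `3` if `w > 2` else `1.5 w`    | 0.5         | LogNormal(2 + (2 - w)/50, 0.5^2) |
#' | 5  | 10 | `0.126 (w1 + sqrt(w3 w5)) + 1` | 1           | Exp(w10/10 + 1/20)         |
#' | 6  | 10 | as 5                           | `(w2 + 2)/4`| Exp(w10/10 + 1/20)         |
#'
#' Exponential laws are rate-parameterized and LogNormal(a, b^2) means
#' `log C ~ N(a, b^2)`.  See the methods vignette for how the Setting 1
#' parameters were pinned down and for the design censoring rates.
#'
#' @param id Setting number, 1 to 6.
#' @return A `sim_setting` object: list with `id`, `p`, `mu(W)`, `sigma(W)`
#'   (functions of the covariate matrix), and the censoring law (`cens_sample`,
#'   `cens_surv(t, w)`, `cens_quantile(p, w)`).
#' @export
sim_setting <- function(id) {
  if (!id %in% 1:6) stop("unknown setting id: ", id)
  exp_cens <- function(rate_fun) list(
    sample = function(W) rexp(nrow(W), rate_fun(W)),
    surv = function(t, w) exp(-rate_fun(rbind(w)) * pmax(t, 0)),
    quantile = function(p, w) -log(p) / rate_fun(rbind(w)),
    bx = function(U, W) exp(-rate_fun(W) * pmax(U, 0)),
    bxq = function(P, W) outer(1 / rate_fun(W), -log(P)))
  cens <- switch(id,
    exp_cens(function(W) rep(0.1, nrow(W))),
    exp_cens(function(W) rep(0.1, nrow(W))),
    exp_cens(function(W) 0.25 + (6 + W[, 1]) / 100),
    list(sample = function(W) exp(2 + (2 - W[, 1]) / 50 + 0.5 * rnorm(nrow(W))),
         surv = function(t, w) {
           a <- 2 + (2 - w[1]) / 50
           ifelse(t <= 0, 1, pnorm((log(pmax(t, 1e-300)) - a) / 0.5,
                                   lower.tail = FALSE))
         },
         quantile = function(p, w) exp(2 + (2 - w[1]) / 50 +
                                         0.5 * qnorm(1 - p)),
         bx = function(U, W) {
           a <- 2 + (2 - W[, 1]) / 50
           pnorm((log(pmax(U, 0)) - a) / 0.5, lower.tail = FALSE)
         },
         bxq = function(P, W) exp((2 + (2 - W[, 1]) / 50) +
                                    outer(rep(0.5, nrow(W)), qnorm(1 - P)))),
    exp_cens(function(W) W[, 10] / 10 + 1 / 20),
    exp_cens(function(W) W[, 10] / 10 + 1 / 20))
  mu <- switch(id,
    function(W) 0.632 * sqrt(W[, 1]),
    function(W) ifelse(W[, 1] > 2, 3, W[, 1]),
    function(W) ifelse(W[, 1] > 2, 2, W[, 1]),
    function(W) ifelse(W[, 1] > 2, 3, 1.5 * W[, 1]),
    function(W) 0.126 * (W[, 1] + sqrt(W[, 3] * W[, 5])) + 1,
    function(W) 0.126 * (W[, 1] + sqrt(W[, 3] * W[, 5])) + 1)
  sigma <- switch(id,
    function(W) rep(1, nrow(W)),
    function(W) rep(0.5, nrow(W)),
    function(W) rep(0.5, nrow(W)),
    function(W) rep(0.5, nrow(W)),
    function(W) rep(1, nrow(W)),
    function(W) (W[, 2] + 2) / 4)
  structure(list(id = id, p = if (id >= 5) 10L else 1L, mu = mu, sigma = sigma,
                 cens_sample = cens$sample, cens_surv = cens$surv,
                 cens_quantile = cens$quantile, cens_bx = cens$bx,
                 cens_bxq = cens$bxq),
            class = "sim_setting")
}

#' Generate a synthetic right-censored dataset
#'
#' Draws `W ~ Unif([0, 4]^p)`, `T = exp(mu(W) + sigma(W) Z)` with standard
#' normal `Z`, `C` from the setting's censoring law, and returns the observed
#' dataset `(W, Delta, Y)` together with the full `T` and `C` (oracle use
#' only; the calibration machinery never sees them).
#'
#' @param setting A [sim_setting()].
#' @param n Number of observations.
#' @param seed Optional integer seed (restores the caller's RNG state).
#' @return List with `data` (an [rc_data]), `T` and `C`.
#' @examples
#' sim <- sim_generate(sim_setting(2), n = 100, seed = 1)
#' mean(sim$data$Delta == 0)   # censoring fraction
#' @export
sim_generate <- function(setting, n, seed = NULL) {
  stopifnot(inherits(setting, "sim_setting"), n >= 1)
  with_seed(seed, {
    W <- matrix(runif(n * setting$p, 0, 4), n, setting$p)
    colnames(W) <- paste0("w", seq_len(setting$p))
    T_ <- exp(setting$mu(W) + setting$sigma(W) * rnorm(n))
    C_ <- setting$cens_sample(W)
    list(data = rc_data(W = W, Y = pmin(T_, C_),
                        Delta = as.numeric(T_ <= C_)),
         T = T_, C = C_)
  })
}

# ---- oracle nuisances ----------------------------------------------------

#' Oracle conditional survival and censoring functions of a setting
#'
#' Closed-form `S0(t | w) = 1 - Phi((log t - mu(w)) / sigma(w))` and the
#' matching censoring survival, wrapped as `cond_surv` objects so they can be
#' used anywhere a fitted nuisance can (true-nuisance diagnostics,
#' true-coverage evaluation, misspecification experiments).
#'
#' @param setting A [sim_setting()].
#' @return A `cond_surv` object of family `"oracle"`.
#' @examples
#' S0 <- oracle_survival(sim_setting(2))
#' sc_eval(S0, exp(1), w = 1)   # = 0.5: log t equals mu(1) = 1
#' @export
oracle_survival <- function(setting) {
  stopifnot(inherits(setting, "sim_setting"))
  S <- function(t, w) {
    m <- setting$mu(rbind(w)); s <- setting$sigma(rbind(w))
    ifelse(t <= 0, 1, pnorm((log(pmax(t, 1e-300)) - m) / s,
                            lower.tail = FALSE))
  }
  Q <- function(p, w) {
    m <- setting$mu(rbind(w)); s <- setting$sigma(rbind(w))
    exp(m + s * qnorm(1 - p))
  }
  structure(list(family = "oracle", target = "event", p = setting$p,
                 Sfun = S, Qfun = Q,
                 bx = function(U, W) {
                   m <- setting$mu(W); s <- setting$sigma(W)
                   pnorm((log(pmax(U, 0)) - m) / s, lower.tail = FALSE)
                 },
                 bxq = function(P, W) {
                   exp(setting$mu(W) +
                         outer(setting$sigma(W), qnorm(1 - P)))
                 }),
            class = c("cs_oracle", "cond_surv"))
}

#' @rdname oracle_survival
#' @export
oracle_censoring <- function(setting) {
  stopifnot(inherits(setting, "sim_setting"))
  structure(list(family = "oracle", target = "censoring", p = setting$p,
                 Sfun = function(t, w) setting$cens_surv(t, w),
                 Qfun = function(p, w) setting$cens_quantile(p, w),
                 bx = setting$cens_bx, bxq = setting$cens_bxq),
            class = c("cs_oracle", "cond_surv"))
}

#' @export
sc_curve.cs_oracle <- function(fit, w) {
  smooth_curve(S = function(t) fit$Sfun(t, w),
               Q = if (!is.null(fit$Qfun)) function(p) fit$Qfun(p, w))
}

# ---- evaluation ----------------------------------------------------------

#' True coverage of a bound under a simulation setting
#'
#' `Pr(T > L(W))` for a fresh draw: computed by exact quadrature of
#' `S0(L(w) | w)` over the covariate law for univariate settings
#' (`method = "quadrature"`), or by Monte Carlo over `n_mc` fresh covariate
#' draws (with a standard error) otherwise.
#'
#' @param L An `lpb` object, function, or numeric bound.
#' @param setting A [sim_setting()].
#' @param n_mc Monte Carlo draws (`method = "mc"`).
#' @param seed Optional seed for the Monte Carlo draws.
#' @param method `"auto"` picks quadrature for `p = 1`, Monte Carlo otherwise.
#' @param n_quad Quadrature grid size for univariate settings.
#' @return List with `estimate` and `se` (`se = 0` for quadrature).
#' @export
true_coverage <- function(L, setting, n_mc = 1e5, seed = NULL,
                          method = c("auto", "quadrature", "mc"),
                          n_quad = 2001L) {
  method <- match.arg(method)
  if (method == "auto") method <- if (setting$p == 1L) "quadrature" else "mc"
  S0 <- oracle_survival(setting)
  s_at <- function(W, Lv) bx_eval(S0, matrix(Lv, ncol = 1L), W)[, 1L]
  if (method == "quadrature") {
    if (setting$p != 1L) stop("quadrature evaluation requires p = 1")
    w <- seq(0, 4, length.out = n_quad)
    s <- s_at(matrix(w, ncol = 1L), lpb_values(L, w))
    # trapezoid over Unif(0, 4) density
    est <- sum(diff(w) * (s[-1] + s[-n_quad]) / 2) / 4
    list(estimate = est, se = 0)
  } else {
    with_seed(seed, {
      W <- matrix(runif(n_mc * setting$p, 0, 4), n_mc, setting$p)
      s <- s_at(W, lpb_values(L, W))
      list(estimate = mean(s), se = sd(s) / sqrt(n_mc))
    })
  }
}

#' Test-set evaluation of a lower prediction bound
#'
#' Empirical coverage `mean(T > L(W))` and average bound `mean(L(W))` over a
#' test set with known event times.
#'
#' @param L An `lpb` object, function, or numeric bound.
#' @param T_test True event times of the test rows (oracle side of a
#'   simulation, or uncensored holdout data).
#' @param W_test Covariate matrix of the test rows.
#' @return List with `empirical_coverage` and `average_lpb`.
#' @export
evaluate_lpb <- function(L, T_test, W_test) {
  W_test <- as_cov_matrix(W_test)
  stopifnot(length(T_test) == nrow(W_test))
  Lv <- lpb_values(L, W_test)
  list(empirical_coverage = mean(T_test > Lv), average_lpb = mean(Lv))
}

#' Wilson score confidence interval for a binomial proportion
#'
#' @param k Number of successes.
#' @param n Number of trials.
#' @param conf Confidence level.
#' @return Named vector with `lower`, `estimate`, `upper`.
#' @examples
#' wilson_interval(190, 200)
#' @export
wilson_interval <- function(k, n, conf = 0.95) {
  stopifnot(n >= 1, k >= 0, k <= n)
  z <- qnorm(1 - (1 - conf) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(lower = center - half, estimate = p, upper = center + half)
}

#' PAC-proportion experiment
#'
#' Replicates the training-set conditional validity experiment: for each of
#' `reps` replications, draw a fresh dataset of `2 n` rows (split in half
#' into training and calibration by the driver), calibrate a bound, and
#' evaluate its true coverage under the setting's oracle.  Reports the
#' proportion of replications whose true coverage reaches `1 - alpha`,
#' with a 95% Wilson score interval.
#'
#' @param setting A [sim_setting()].
#' @param n Per-split sample size (the calibration set size).
#' @param reps Number of replications.
#' @param config A [calibration_config()]; its `seed` is ignored, the
#'   per-replication seeds derive from `seed`.
#' @param seed Integer base seed.
#' @param n_mc Monte Carlo size for true-coverage evaluation when `p > 1`.
#' @return A `pac_report` object: list with per-replication `coverage`,
#'   `tau_hat` and `average_lpb`, the `pac_proportion` and its Wilson
#'   interval, and the experiment parameters.
#' @examples
#' \donttest{
#' cfg <- calibration_config(surv_spec = model_spec("weibull"),
#'                           cens_spec = model_spec("km"))
#' rep <- pac_experiment(sim_setting(2), n = 200, reps = 20, config = cfg,
#'                       seed = 1)
#' rep$pac_proportion
#' }
#' @export
pac_experiment <- function(setting, n, reps, config = calibration_config(),
                           seed = 1L, n_mc = 2e4) {
  coverage <- numeric(reps)
  tau_hat <- numeric(reps)
  avg_lpb <- numeric(reps)
  for (r in seq_len(reps)) {
    cfg <- config
    cfg$seed <- NULL
    sim <- sim_generate(setting, 2L * n, seed = seed + 7919L * r)
    fit <- with_seed(seed + 7919L * r + 1L,
                     suppressWarnings(suppressMessages(
                       tcsurv_calibrate(sim$data, cfg))))
    coverage[r] <- true_coverage(fit$lpb, setting, n_mc = n_mc,
                                 seed = seed + 7919L * r + 2L)$estimate
    tau_hat[r] <- fit$tau_hat
    avg_lpb[r] <- mean(predict(fit, sim$data$W))
  }
  k <- sum(coverage >= 1 - config$alpha)
  structure(list(setting = setting$id, n = n, reps = reps,
                 alpha = config$alpha, beta = config$beta,
                 coverage = coverage, tau_hat = tau_hat,
                 average_lpb = avg_lpb,
                 pac_proportion = k / reps,
                 wilson = wilson_interval(k, reps)),
            class = "pac_report")
}

#' @export
print.pac_report <- function(x, ...) {
  cat(sprintf(
    "PAC experiment: setting %d, n = %d, %d reps, target coverage >= %g\n",
    x$setting, x$n, x$reps, 1 - x$alpha))
  cat(sprintf("  proportion with adequate coverage: %.3f (Wilson 95%%: %.3f-%.3f; target >= %g)\n",
              x$pac_proportion, x$wilson["lower"], x$wilson["upper"],
              1 - x$beta))
  cat(sprintf("  mean true coverage %.3f | mean average LPB %.3f\n",
              mean(x$coverage), mean(x$average_lpb)))
  invisible(x)
}
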