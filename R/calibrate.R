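#' Calibration configuration
#'
#' Settings for the split one-step calibration driver [tcsurv_calibrate()].
#'
#' @param alpha Target miscoverage in (0, 1): the selected bound aims at
#'   coverage `>= 1 - alpha`.
#' @param beta Confidence parameter in (0, 1) for the Wald confidence lower
#'   bounds (and hence for the training-set conditional guarantee).
#' @param tau_grid Strictly increasing candidate quantile levels in (0, 1).
#'   The default, 0.005 to 0.5 in steps of 0.005, brackets the usual
#'   `alpha = 0.1` target densely; all grid points share one nuisance fit, so
#'   a fine grid is cheap.
#' @param eta2 Censoring-survival floor used in the bound parameterization.
#' @param split_prop Calibration proportion `c`; `round(c * N)` rows are
#'   calibrated on, the rest train the nuisances.
#' @param surv_spec,cens_spec [model_spec()]s for the event and censoring
#'   models.
#' @param mode `"apac"` selects the largest tau whose whole grid prefix has
#'   Wald CLB `>= 1 - alpha` (training-set conditional validity);
#'   `"marginal"` applies the same prefix scan to the one-step point
#'   estimates instead (marginal validity).
#' @param t0 Horizon capping the bound; default `NULL` means the 0.99
#'   empirical quantile of the training follow-up times.
#' @param seed Optional integer seed controlling the split and any stochastic
#'   model fitting.
#' @return A `calibration_config` object.
#' @export
calibration_config <- function(alpha = 0.1, beta = 0.05,
                               tau_grid = seq(0.005, 0.5, by = 0.005),
                               eta2 = 1e-3, split_prop = 0.5,
                               surv_spec = model_spec(),
                               cens_spec = model_spec(),
                               mode = c("apac", "marginal"),
                               t0 = NULL, seed = NULL) {
  mode <- match.arg(mode)
  if (alpha <= 0 || alpha >= 1 || beta <= 0 || beta >= 1)
    stop("alpha and beta must lie strictly in (0, 1)")
  if (!length(tau_grid) || any(tau_grid <= 0 | tau_grid >= 1) ||
      is.unsorted(tau_grid, strictly = TRUE))
    stop("tau_grid must be strictly increasing within (0, 1)")
  if (eta2 <= 0 || eta2 >= 1) stop("eta2 must lie strictly in (0, 1)")
  if (split_prop <= 0 || split_prop >= 1)
    stop("split_prop must lie strictly in (0, 1)")
  structure(list(alpha = alpha, beta = beta, tau_grid = tau_grid, eta2 = eta2,
                 split_prop = split_prop, surv_spec = surv_spec,
                 cens_spec = cens_spec, mode = mode, t0 = t0, seed = seed),
            class = "calibration_config")
}

#' Prefix-maximal tuning-parameter selection
#'
#' `select_tau_apac()` returns the largest grid value `tau` such that every
#' grid value `tau' <= tau` has Wald confidence lower bound `>= 1 - alpha`;
#' `NA` when already the smallest grid value fails (the caller then falls
#' back to the trivial bound `L = 0`).  `select_tau_marginal()` applies the
#' same prefix scan with the one-step point estimates in place of the CLBs.
#'
#' @param tau_grid Strictly increasing candidate values.
#' @param clb,psi Per-tau Wald CLBs / one-step coverage estimates, aligned
#'   with `tau_grid`.
#' @param alpha Target miscoverage.
#' @return The selected tau, or `NA_real_` if none qualifies.
#' @examples
#' select_tau_apac(c(0.05, 0.10, 0.15, 0.20), c(0.95, 0.91, 0.89, 0.92), 0.1)
#' @export
select_tau_apac <- function(tau_grid, clb, alpha) {
  if (!length(tau_grid)) stop("tau_grid is empty")
  stopifnot(length(clb) == length(tau_grid))
  prefix_max(tau_grid, clb >= 1 - alpha)
}

#' @rdname select_tau_apac
#' @export
select_tau_marginal <- function(tau_grid, psi, alpha) {
  if (!length(tau_grid)) stop("tau_grid is empty")
  stopifnot(length(psi) == length(tau_grid))
  prefix_max(tau_grid, psi >= 1 - alpha)
}

prefix_max <- function(tau_grid, ok) {
  bad <- which(!ok)
  if (!length(bad)) return(tau_grid[length(tau_grid)])
  if (bad[1] == 1L) return(NA_real_)
  tau_grid[bad[1] - 1L]
}

#' Calibrate a lower prediction bound on right-censored data
#'
#' The split one-step driver: (i) split the data into training and
#' calibration sets; (ii) fit the conditional survival and censoring models
#' on the training rows only; (iii) for every tau on the grid, build the
#' candidate bound and compute its plug-in and one-step coverage estimates,
#' influence variance and Wald CLB on the calibration rows; (iv) select the
#' tuning parameter by the mode's prefix rule.  Calibration outcomes never
#' enter the nuisance fits or the bound construction; only calibration
#' covariates and the influence averages do.
#'
#' @param data An [rc_data] object.
#' @param config A [calibration_config()].
#' @return An object of class `tcsurv_fit`: list with the selected `tau_hat`
#'   (`NA` if no grid value qualified), the fitted `lpb` (the trivial zero
#'   bound on fallback), the per-tau `table` (data frame with `tau`,
#'   `psi_plugin`, `psi_onestep`, `sigma`, `clb`), the `mode`, fitted
#'   nuisances `S` and `G`, the `split`, and the `config`.
#' @examples
#' sim <- sim_generate(sim_setting(2), n = 400, seed = 7)
#' cfg <- calibration_config(surv_spec = model_spec("weibull"),
#'                           cens_spec = model_spec("km"), seed = 7)
#' fit <- tcsurv_calibrate(sim$data, cfg)
#' head(predict(fit, sim$data$W))
#' @export
tcsurv_calibrate <- function(data, config = calibration_config()) {
  stopifnot(inherits(data, "rc_data"), inherits(config, "calibration_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  split <- rc_split(data, c = config$split_prop)
  train <- rc_subset(data, split$train)
  cal <- rc_subset(data, split$cal)
  S <- fit_survival(train, config$surv_spec)
  G <- fit_censoring(train, config$cens_spec)
  t0 <- config$t0 %||% unname(quantile(train$Y, 0.99))
  tab <- coverage_sweep(S, G, cal, config$tau_grid, config$eta2, t0,
                        config$beta)
  tau_hat <- switch(config$mode,
    apac = select_tau_apac(tab$tau, tab$clb, config$alpha),
    marginal = select_tau_marginal(tab$tau, tab$psi_onestep, config$alpha))
  if (is.na(tau_hat)) {
    message("no tuning parameter on the grid passed the acceptance rule; ",
            "falling back to the trivial bound L = 0")
    lpb <- lpb_zero()
  } else {
    lpb <- build_lpb(S, G, tau_hat, config$eta2, t0)
    if (config$mode == "apac")
      stopifnot(tab$clb[match(tau_hat, tab$tau)] >= 1 - config$alpha)
  }
  structure(list(tau_hat = tau_hat, lpb = lpb, table = tab,
                 mode = config$mode, S = S, G = G, t0 = t0, split = split,
                 config = config),
            class = "tcsurv_fit")
}

#' @export
predict.tcsurv_fit <- function(object, newdata, ...) {
  predict(object$lpb, newdata)
}

#' @export
print.tcsurv_fit <- function(x, ...) {
  cat(sprintf("Calibrated lower prediction bound (%s mode)\n", x$mode))
  cat(sprintf("  split: %d training / %d calibration rows\n",
              length(x$split$train), length(x$split$cal)))
  cat(sprintf("  nuisances: S ~ %s, G ~ %s; horizon t0 = %.4g\n",
              x$S$selected %||% x$S$family, x$G$selected %||% x$G$family,
              x$t0))
  if (is.na(x$tau_hat)) {
    cat("  no tau qualified; trivial bound L = 0 in force\n")
  } else {
    row <- x$table[match(x$tau_hat, x$table$tau), ]
    cat(sprintf(
      "  tau_hat = %g | one-step coverage %.4f | %g%% CLB %.4f (target >= %g)\n",
      x$tau_hat, row$psi_onestep, 100 * (1 - x$config$beta), row$clb,
      1 - x$config$alpha))
  }
  invisible(x)
}
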