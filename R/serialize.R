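# JSON serialization of fitted nuisance models and calibration results, and
# YAML configuration parsing for the command-line interface.
#
# JSON schema for a cond_surv object: {"family": ..., "target": ..., "p": ...}
# plus family-specific fields:
#   km:                  "times", "surv"          (step grid + values)
#   exponential:         "rate"
#   weibull / lognormal: "coef" (named, incl. intercept), "scale"
#   coxph:               "coef", "b_time", "b_haz" (baseline cumhaz grid)
# Random survival forests are not serializable.

#' Serialize a fitted conditional survival model to JSON
#'
#' @param fit A `cond_surv` object (any family except `"rsf"` / `"oracle"`).
#' @return A JSON string.
#' @seealso [sc_from_json()]
#' @export
sc_to_json <- function(fit) {
  stopifnot(inherits(fit, "cond_surv"))
  base <- list(family = fit$family, target = fit$target, p = fit$p)
  extra <- switch(fit$family,
    km = list(times = fit$curve$times, surv = fit$curve$surv),
    exponential = list(rate = fit$rate),
    weibull = ,
    lognormal = list(coef = as.list(fit$coef), scale = fit$scale,
                     cov_names = fit$cov_names),
    coxph = list(coef = as.list(fit$coef), b_time = fit$b_time,
                 b_haz = fit$b_haz, cov_names = fit$cov_names),
    stop("family '", fit$family, "' is not serializable"))
  jsonlite::toJSON(c(base, extra), auto_unbox = TRUE, digits = NA)
}

#' Restore a fitted conditional survival model from JSON
#'
#' @param json A JSON string produced by [sc_to_json()].
#' @return A `cond_surv` object.
#' @export
sc_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  out <- switch(x$family,
    km = structure(list(family = "km",
                        curve = step_curve(x$times, x$surv)),
                   class = c("cs_km", "cond_surv")),
    exponential = structure(list(family = "exponential", rate = x$rate),
                            class = c("cs_exp", "cond_surv")),
    weibull = ,
    lognormal = structure(list(family = x$family, coef = unlist(x$coef),
                               scale = x$scale, cov_names = x$cov_names),
                          class = c(paste0("cs_", x$family), "cond_surv")),
    coxph = structure(list(family = "coxph", coef = unlist(x$coef),
                           b_time = x$b_time, b_haz = x$b_haz,
                           cov_names = x$cov_names),
                      class = c("cs_coxph", "cond_surv")),
    stop("unknown family in JSON: ", x$family))
  out$target <- x$target
  out$p <- x$p
  out
}

#' Serialize a calibration result to JSON
#'
#' Stores the selection table, the selected tuning parameter, the bound
#' parameters and both serialized nuisances, enough to reconstruct the bound
#' and predict on new covariates.
#'
#' @param fit A `tcsurv_fit` from [tcsurv_calibrate()].
#' @return A JSON string.
#' @export
result_to_json <- function(fit) {
  stopifnot(inherits(fit, "tcsurv_fit"))
  jsonlite::toJSON(list(
    mode = fit$mode, tau_hat = fit$tau_hat, t0 = fit$t0,
    eta2 = fit$config$eta2, alpha = fit$config$alpha, beta = fit$config$beta,
    n_train = length(fit$split$train), n_cal = length(fit$split$cal),
    table = fit$table,
    S = if (!is.na(fit$tau_hat)) jsonlite::fromJSON(sc_to_json(fit$S)),
    G = if (!is.na(fit$tau_hat)) jsonlite::fromJSON(sc_to_json(fit$G))),
    auto_unbox = TRUE, digits = NA, null = "null")
}

#' Restore a lower prediction bound from a serialized calibration result
#'
#' @param json A JSON string produced by [result_to_json()].
#' @return An `lpb` object (the trivial zero bound when no tau qualified).
#' @export
lpb_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  if (is.null(x$tau_hat) || is.na(x$tau_hat)) return(lpb_zero())
  build_lpb(sc_from_json(jsonlite::toJSON(x$S, auto_unbox = TRUE, digits = NA)),
            sc_from_json(jsonlite::toJSON(x$G, auto_unbox = TRUE, digits = NA)),
            tau = x$tau_hat, eta2 = x$eta2, t0 = x$t0)
}

#' Build a calibration configuration from a YAML file
#'
#' Recognized keys mirror the arguments of [calibration_config()]
#' (`alpha`, `beta`, `eta2`, `split_prop`, `mode`, `t0`, `seed`,
#' `tau_grid: {from, to, by}` or an explicit list) plus `surv_model` and
#' `cens_model` blocks with a `family` key and optional hyperparameters
#' passed to [model_spec()].
#'
#' @param path Path to a YAML file.
#' @return A `calibration_config` object.
#' @export
config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  spec_of <- function(block) {
    if (is.null(block)) return(model_spec())
    do.call(model_spec, block)
  }
  grid <- y$tau_grid
  if (is.list(grid) && !is.null(grid$from))
    grid <- seq(grid$from, grid$to, by = grid$by)
  args <- list(surv_spec = spec_of(y$surv_model),
               cens_spec = spec_of(y$cens_model))
  for (key in c("alpha", "beta", "eta2", "split_prop", "mode", "t0", "seed"))
    if (!is.null(y[[key]])) args[[key]] <- y[[key]]
  if (!is.null(grid)) args$tau_grid <- as.numeric(grid)
  do.call(calibration_config, args)
}
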