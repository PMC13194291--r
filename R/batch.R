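# Batched curve kernels.
#
# The influence-function sweep evaluates, for every calibration row i, the
# fitted curves at O(ngrid) time points.  Doing that through per-row closures
# dominates runtime, so each parametric family provides matrix kernels:
# given U (n x m, row i evaluated under covariate row i of W) return the
# matching matrix of survival values / cumulative hazards, and given a level
# vector P return the n x length(P) quantile matrix.  Families without
# kernels (random survival forests, user-supplied functions) return NULL and
# the per-row reference path in eif.R is used instead.  Vectors of length n
# recycle down the columns of an n x m matrix, i.e. act as per-row scalars.

bx_eval <- function(fit, U, W) UseMethod("bx_eval")
bx_eval_left <- function(fit, U, W) UseMethod("bx_eval_left")
bx_H <- function(fit, U, W) UseMethod("bx_H")          # cumulative hazard
bx_quantile <- function(fit, P, W) UseMethod("bx_quantile")
bx_step_info <- function(fit, W) UseMethod("bx_step_info")

#' @export
bx_eval.default <- function(fit, U, W) NULL
#' @export
bx_eval_left.default <- function(fit, U, W) bx_eval(fit, U, W)  # smooth: same
#' @export
bx_H.default <- function(fit, U, W) NULL
#' @export
bx_quantile.default <- function(fit, P, W) NULL
#' @export
bx_step_info.default <- function(fit, W) NULL

# ---- covariate-free exponential -----------------------------------------

#' @export
bx_eval.cs_exp <- function(fit, U, W) exp(-fit$rate * pmax(U, 0))
#' @export
bx_H.cs_exp <- function(fit, U, W) fit$rate * pmax(U, 0)
#' @export
bx_quantile.cs_exp <- function(fit, P, W) {
  q <- -log(P) / fit$rate
  q[P >= 1] <- 0
  matrix(q, nrow(W), length(P), byrow = TRUE)
}

# ---- Weibull AFT:  H(t|w) = t^{1/b} exp(-lp/b) --------------------------

aft_lp_vec <- function(fit, W) as.numeric(cbind(1, W) %*% fit$coef)

#' @export
bx_H.cs_weibull <- function(fit, U, W) {
  pmax(U, 0)^(1 / fit$scale) * exp(-aft_lp_vec(fit, W) / fit$scale)
}
#' @export
bx_eval.cs_weibull <- function(fit, U, W) exp(-bx_H(fit, U, W))
#' @export
bx_quantile.cs_weibull <- function(fit, P, W) {
  q <- exp(aft_lp_vec(fit, W)) %o% (-log(P))^fit$scale
  q[, P >= 1] <- 0
  q
}

# ---- log-normal AFT ------------------------------------------------------

#' @export
bx_eval.cs_lognormal <- function(fit, U, W) {
  # log(0) = -Inf gives S = 1 at t = 0 as required
  pnorm((log(pmax(U, 0)) - aft_lp_vec(fit, W)) / fit$scale,
        lower.tail = FALSE)
}
#' @export
bx_H.cs_lognormal <- function(fit, U, W) {
  -log(pmax(bx_eval(fit, U, W), 1e-300))
}
#' @export
bx_quantile.cs_lognormal <- function(fit, P, W) {
  exp(aft_lp_vec(fit, W) + outer(rep(fit$scale, nrow(W)), qnorm(1 - P), "*"))
}

# ---- covariate-free product limit ---------------------------------------

#' @export
bx_eval.cs_km <- function(fit, U, W) {
  matrix(curve_eval(fit$curve, as.vector(U)), nrow(U))
}
#' @export
bx_eval_left.cs_km <- function(fit, U, W) {
  matrix(curve_eval_left(fit$curve, as.vector(U)), nrow(U))
}
#' @export
bx_quantile.cs_km <- function(fit, P, W) {
  matrix(curve_quantile(fit$curve, P), nrow(W), length(P), byrow = TRUE)
}
#' @export
bx_step_info.cs_km <- function(fit, W) {
  list(times = fit$curve$times,
       surv = matrix(fit$curve$surv, nrow(W), length(fit$curve$times),
                     byrow = TRUE))
}

# ---- Cox proportional hazards:  S = exp(-H0 e^lp), shared jump grid -----

cox_H0 <- function(fit, u, left = FALSE) {
  idx <- findInterval(u, fit$b_time, left.open = left)
  c(0, fit$b_haz)[idx + 1L]
}

#' @export
bx_eval.cs_coxph <- function(fit, U, W) {
  lp <- as.numeric(W %*% fit$coef)
  exp(-matrix(cox_H0(fit, as.vector(U)), nrow(U)) * exp(lp))
}
#' @export
bx_eval_left.cs_coxph <- function(fit, U, W) {
  lp <- as.numeric(W %*% fit$coef)
  exp(-matrix(cox_H0(fit, as.vector(U), left = TRUE), nrow(U)) * exp(lp))
}
#' @export
bx_quantile.cs_coxph <- function(fit, P, W) {
  # smallest jump time with H0 >= -log(p) e^{-lp}
  lp <- as.numeric(W %*% fit$coef)
  thr <- outer(exp(-lp), -log(P))
  j <- findInterval(as.vector(thr), fit$b_haz, left.open = TRUE) + 1L
  q <- matrix(c(fit$b_time, Inf)[pmin(j, length(fit$b_time) + 1L)], nrow(W))
  q[, P >= 1] <- 0
  q
}
#' @export
bx_step_info.cs_coxph <- function(fit, W) {
  lp <- as.numeric(W %*% fit$coef)
  list(times = fit$b_time, surv = exp(-outer(exp(lp), fit$b_haz)))
}

# ---- analytic oracles ----------------------------------------------------
# Oracle objects may carry vectorized closures `bx` (S over a matrix of
# times) and `bxq` (quantiles); see oracle_survival()/oracle_censoring().

#' @export
bx_eval.cs_oracle <- function(fit, U, W) {
  if (is.null(fit$bx)) return(NULL)
  fit$bx(U, W)
}
#' @export
bx_eval_left.cs_oracle <- function(fit, U, W) bx_eval(fit, U, W)
#' @export
bx_H.cs_oracle <- function(fit, U, W) {
  s <- bx_eval(fit, U, W)
  if (is.null(s)) return(NULL)
  -log(pmax(s, 1e-300))
}
#' @export
bx_quantile.cs_oracle <- function(fit, P, W) {
  if (is.null(fit$bxq)) return(NULL)
  fit$bxq(P, W)
}

# ---- shared helpers ------------------------------------------------------

# n x K quantile matrix with per-row fallback through the curve interface
quantile_matrix <- function(fit, P, W) {
  W <- as_cov_matrix(W)
  qm <- bx_quantile(fit, P, W)
  if (!is.null(qm)) return(qm)
  curves <- sc_curves(fit, W)
  qv <- vapply(curves, function(cv) curve_quantile(cv, P),
               numeric(length(P)))
  if (length(P) == 1L) matrix(qv, ncol = 1L) else t(qv)
}

# in-place cumulative sums along rows
row_cumsums <- function(X) {
  if (ncol(X) > 1L)
    for (j in 2:ncol(X)) X[, j] <- X[, j] + X[, j - 1L]
  X
}

has_bx_eval <- function(fit, W) {
  !is.null(bx_eval(fit, matrix(1), W[1L, , drop = FALSE]))
}
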