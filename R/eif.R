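# Coverage functional, efficient influence function, one-step estimator.
#
# For a lower prediction bound L the coverage is Psi(P; L) = Pr_P(T > L(W)).
# Its nonparametric efficient influence function at (S, G) is
#
#   phi(S, G; L)(w, delta, y) - Psi(P; L),   with
#   phi = S(L(w)|w) * [ 1 - { 1(0 < y <= L(w), delta = 1) / (S(y-|w) G(y-|w))
#                             - int_(0, L(w)^y] dLambda(u|w) / (S(u-|w) G(u-|w)) } ]
#
# where Lambda is the cumulative hazard of S.  Left limits are used in every
# denominator: for continuous laws they coincide with the written form, and
# for step-function nuisances this consistent convention is exactly what
# makes the product-limit (Kaplan-Meier) plug-in solve the estimating
# equation (see the methods vignette).
#
# Two evaluation engines compute phi over a calibration set: a batched one
# working on matrices via the family kernels in batch.R (used whenever both
# nuisances provide kernels) and a per-row reference path over the curve
# interface.  For step-function nuisances the two are exactly equal; for
# smooth nuisances they differ only in the quadrature grid of the hazard
# integral (the batched engine grids (0, y] once per row, the per-row path
# grids (0, L ^ y] per bound), both O(ngrid^-2) accurate.

EPS_CLIP <- 1e-6

#' Build a lower prediction bound function from fitted nuisances
#'
#' The LPB at level `tau` is
#' `L(w) = min(S^{-1}(1 - tau | w), G^{-1}(eta2 | w), t0)`:
#' the fitted `tau`-quantile of the conditional event time, capped at the
#' time by which censoring survival drops to `eta2` (so that the data retain
#' information about coverage at `L`) and at the horizon `t0`.
#'
#' @param S,G Fitted `cond_surv` objects for the event and censoring times.
#' @param tau Quantile level in (0, 1); smaller values give more conservative
#'   (lower) bounds.
#' @param eta2 Censoring-survival floor in (0, 1); default `1e-3`.
#' @param t0 Horizon capping the bound; defaults to `Inf` (no cap).  The
#'   calibration driver sets it to the 0.99 empirical quantile of the
#'   training follow-up times.
#' @return An object of class `lpb` with a [predict()] method mapping a
#'   covariate matrix to per-row bounds.
#' @examples
#' d <- rc_data(W = runif(50), Y = rexp(50), Delta = rbinom(50, 1, 0.7))
#' S <- fit_survival(d, model_spec("km")); G <- fit_censoring(d, model_spec("km"))
#' L <- build_lpb(S, G, tau = 0.1)
#' predict(L, runif(3))
#' @export
build_lpb <- function(S, G, tau, eta2 = 1e-3, t0 = Inf) {
  if (!is.numeric(tau) || tau <= 0 || tau >= 1)
    stop("tau must lie strictly in (0, 1)")
  if (!is.numeric(eta2) || eta2 <= 0 || eta2 >= 1)
    stop("eta2 must lie strictly in (0, 1)")
  structure(list(S = S, G = G, tau = tau, eta2 = eta2, t0 = t0),
            class = "lpb")
}

#' The trivial lower prediction bound L = 0
#'
#' Fallback emitted when no tuning parameter on the grid passes the
#' acceptance rule; it has coverage 1 by construction.
#' @return An `lpb` object whose predictions are identically zero.
#' @export
lpb_zero <- function() {
  structure(list(S = NULL, G = NULL, tau = NA_real_, eta2 = NA_real_, t0 = 0),
            class = "lpb")
}

#' @export
predict.lpb <- function(object, newdata, ...) {
  W <- as_cov_matrix(newdata)
  if (is.na(object$tau)) return(rep(0, nrow(W)))
  pmin(quantile_matrix(object$S, 1 - object$tau, W)[, 1],
       quantile_matrix(object$G, object$eta2, W)[, 1], object$t0)
}

#' @export
print.lpb <- function(x, ...) {
  if (is.na(x$tau)) cat("Trivial lower prediction bound L = 0\n")
  else cat(sprintf(
    "Lower prediction bound: tau = %g, eta2 = %g, horizon t0 = %g\n",
    x$tau, x$eta2, x$t0))
  invisible(x)
}

# Coerce an LPB specification (lpb object, function of a covariate row, or
# numeric vector) to per-row values over W.
lpb_values <- function(L, W) {
  W <- as_cov_matrix(W)
  if (inherits(L, "lpb")) predict(L, W)
  else if (is.function(L)) apply(W, 1, L)
  else if (is.numeric(L) && length(L) %in% c(1L, nrow(W))) rep_len(L, nrow(W))
  else stop("L must be an lpb object, a function of w, or a numeric vector")
}

# ---- per-observation reference path --------------------------------------

# phi for one observation given its precomputed curves.
phi_one <- function(cs, cg, Lv, y, delta, eps_clip = EPS_CLIP, ngrid = 512L) {
  s_L <- curve_eval(cs, Lv)
  inc <- curve_cumhaz(cs, min(Lv, y), ngrid)
  integ <- 0
  nclamp <- 0L
  if (length(inc$u)) {
    sden <- curve_eval_left(cs, inc$u_eval)
    gden <- curve_eval_left(cg, inc$u_eval)
    nclamp <- sum(sden < eps_clip | gden < eps_clip)
    integ <- sum(inc$dLambda / (pmax(sden, eps_clip) * pmax(gden, eps_clip)))
  }
  ind <- 0
  if (y > 0 && y <= Lv && delta == 1) {  # events at exactly 0 lie outside (0, L]
    sy <- curve_eval_left(cs, y)
    gy <- curve_eval_left(cg, y)
    nclamp <- nclamp + (sy < eps_clip || gy < eps_clip)
    ind <- 1 / (pmax(sy, eps_clip) * pmax(gy, eps_clip))
  }
  list(phi = s_L * (1 - (ind - integ)), s_L = s_L, nclamp = nclamp)
}

#' Efficient-influence-function kernel phi for one observation
#'
#' Evaluates the uncentered influence kernel `phi(S, G; L)` at the
#' observation `(w, delta, y)`.  Subtracting the plug-in coverage gives the
#' estimated efficient influence function of the coverage functional.
#'
#' @inheritParams build_lpb
#' @param L An `lpb` object, a function `w -> L(w)`, or a numeric bound.
#' @param w Covariate profile of the observation.
#' @param delta Event indicator (0/1).
#' @param y Follow-up time.
#' @param eps_clip Denominator floor for `S` and `G`; values below it are
#'   clamped (with a warning) to keep the inverse weights finite.
#' @param ngrid Grid cells for the hazard integral of smooth curves.
#' @return The scalar `phi` value.
#' @export
phi_eif <- function(S, G, L, w, delta, y, eps_clip = EPS_CLIP, ngrid = 512L) {
  Lv <- lpb_values(L, matrix(w, nrow = 1L))
  res <- phi_one(sc_curve(S, w), sc_curve(G, w), Lv, y, delta, eps_clip, ngrid)
  if (res$nclamp > 0)
    warning(sprintf("clamped %d denominator value(s) below %g", res$nclamp,
                    eps_clip))
  res$phi
}

# reference engine: loop observations through the curve interface
eif_core_ref <- function(S, G, cal, Lmat, eps_clip = EPS_CLIP, ngrid = 512L) {
  n <- nobs_rc(cal)
  K <- ncol(Lmat)
  Sc <- sc_curves(S, cal$W)
  Gc <- sc_curves(G, cal$W)
  PHI <- matrix(0, n, K)
  SL <- matrix(0, n, K)
  nclamp <- 0L
  for (i in seq_len(n)) {
    cs <- Sc[[i]]
    cg <- Gc[[i]]
    y <- cal$Y[i]
    L <- Lmat[i, ]
    SL[i, ] <- curve_eval(cs, L)
    inc <- curve_cumhaz(cs, y, ngrid)
    if (length(inc$u)) {
      sden <- curve_eval_left(cs, inc$u_eval)
      gden <- curve_eval_left(cg, inc$u_eval)
      nclamp <- nclamp + sum(sden < eps_clip | gden < eps_clip)
      wint <- inc$dLambda / (pmax(sden, eps_clip) * pmax(gden, eps_clip))
      csum <- c(0, cumsum(wint))
      up <- pmin(L, y)
      v <- findInterval(up, inc$u)
      integ <- csum[v + 1L]
      if (inc$type == "smooth") {        # partial-cell share of the grid cell
        h <- inc$u[1L]
        fr <- pmax(up - c(0, inc$u)[v + 1L], 0) / h
        nx <- which(v < length(inc$u) & fr > 0)
        integ[nx] <- integ[nx] + fr[nx] * wint[v[nx] + 1L]
      }
    } else integ <- numeric(K)
    ind <- numeric(K)
    if (cal$Delta[i] == 1 && y > 0) {
      hit <- y <= L
      if (any(hit)) {
        sy <- curve_eval_left(cs, y)
        gy <- curve_eval_left(cg, y)
        nclamp <- nclamp + (sy < eps_clip || gy < eps_clip)
        ind[hit] <- 1 / (pmax(sy, eps_clip) * pmax(gy, eps_clip))
      }
    }
    PHI[i, ] <- SL[i, ] * (1 - (ind - integ))
  }
  list(SL = SL, PHI = PHI, nclamp = nclamp)
}

# ---- batched engine ------------------------------------------------------

# smooth S: exact cumulative-hazard increments on a uniform (0, y] grid per
# row, 1/(SG) at cell midpoints, truncated at L by index arithmetic.
eif_chunk_smooth <- function(S, G, y, delta, W, L, eps_clip, ngrid) {
  nc <- length(y)
  K <- ncol(L)
  Ufull <- y %o% (0:ngrid / ngrid)
  H <- bx_H(S, Ufull, W)
  dL <- H[, -1L, drop = FALSE] - H[, -(ngrid + 1L), drop = FALSE]
  mids <- (Ufull[, -1L, drop = FALSE] + Ufull[, -(ngrid + 1L), drop = FALSE]) / 2
  Sden <- bx_eval(S, mids, W)
  Gden <- bx_eval_left(G, mids, W)
  nclamp <- sum(Sden < eps_clip) + sum(Gden < eps_clip)
  WI <- dL / (pmax(Sden, eps_clip) * pmax(Gden, eps_clip))
  CS <- row_cumsums(WI)
  ratio <- pmin(L / pmax(y, 1e-300), 1)   # y recycles down columns
  ratio[L <= 0] <- 0
  if (any(y <= 0)) ratio[y <= 0, ] <- 0
  rm_ <- ratio * ngrid
  idxm <- pmin(floor(rm_), ngrid)
  fr <- rm_ - idxm                        # partial-cell fraction in [0, 1)
  INT <- matrix(0, nc, K)
  for (k in seq_len(K)) {
    v <- idxm[, k]
    pos <- which(v > 0)
    INT[pos, k] <- CS[cbind(pos, v[pos])]
    nx <- which(v < ngrid & fr[, k] > 0)
    INT[nx, k] <- INT[nx, k] + fr[nx, k] * WI[cbind(nx, v[nx] + 1L)]
  }
  SL <- bx_eval(S, L, W)
  Sy <- bx_eval(S, matrix(y, nc, 1L), W)[, 1L]
  Gy <- bx_eval_left(G, matrix(y, nc, 1L), W)[, 1L]
  nclamp <- nclamp + sum(Sy < eps_clip) + sum(Gy < eps_clip)
  wy <- ifelse(delta == 1 & y > 0,
               1 / (pmax(Sy, eps_clip) * pmax(Gy, eps_clip)), 0)
  PHI <- SL * (1 - ((L >= y) * wy - INT))
  list(SL = SL, PHI = PHI, nclamp = nclamp)
}

# step S on a shared jump grid (product limit, Cox): exact discrete hazards.
eif_chunk_step <- function(S, G, y, delta, W, L, eps_clip) {
  nc <- length(y)
  K <- ncol(L)
  info <- bx_step_info(S, W)
  tt <- info$times
  J <- length(tt)
  Sm <- info$surv
  SmL <- cbind(rep(1, nc), Sm[, -J, drop = FALSE])
  dL <- (SmL - Sm) / pmax(SmL, 1e-300)
  dL[SmL <= 0] <- 0
  M <- outer(y, tt, ">=")
  if (any(tt <= 0)) M[, tt <= 0] <- FALSE
  Gden <- bx_eval_left(G, matrix(tt, nc, J, byrow = TRUE), W)
  live <- M & dL > 0
  nclamp <- sum(SmL < eps_clip & live) + sum(Gden < eps_clip & live)
  CS <- row_cumsums(M * dL / (pmax(SmL, eps_clip) * pmax(Gden, eps_clip)))
  U <- pmin(L, y)                          # y recycles down columns
  idxm <- matrix(findInterval(as.vector(U), tt), nc)
  idxL <- matrix(findInterval(as.vector(L), tt), nc)
  INT <- matrix(0, nc, K)
  SL <- matrix(1, nc, K)
  for (k in seq_len(K)) {
    v <- idxm[, k]
    pos <- which(v > 0)
    INT[pos, k] <- CS[cbind(pos, v[pos])]
    v <- idxL[, k]
    pos <- which(v > 0)
    SL[pos, k] <- Sm[cbind(pos, v[pos])]
  }
  iy <- findInterval(y, tt, left.open = TRUE)
  Sy <- ifelse(iy > 0, Sm[cbind(seq_len(nc), pmax(iy, 1L))], 1)
  Gy <- bx_eval_left(G, matrix(y, nc, 1L), W)[, 1L]
  nclamp <- nclamp + sum(Sy < eps_clip) + sum(Gy < eps_clip)
  wy <- ifelse(delta == 1 & y > 0,
               1 / (pmax(Sy, eps_clip) * pmax(Gy, eps_clip)), 0)
  PHI <- SL * (1 - ((L >= y) * wy - INT))
  list(SL = SL, PHI = PHI, nclamp = nclamp)
}

# dispatch: batched when both nuisances provide kernels, else reference.
eif_core <- function(S, G, cal, Lmat, eps_clip = EPS_CLIP, ngrid = 512L,
                     chunk = 2048L) {
  n <- nobs_rc(cal)
  W <- cal$W
  w1 <- W[1L, , drop = FALSE]
  g_ok <- has_bx_eval(G, W)
  s_smooth <- g_ok && !is.null(bx_H(S, matrix(1), w1))
  s_step <- g_ok && !s_smooth && !is.null(bx_step_info(S, w1))
  if (!s_smooth && !s_step)
    return(eif_core_ref(S, G, cal, Lmat, eps_clip, ngrid))
  SL <- matrix(0, n, ncol(Lmat))
  PHI <- matrix(0, n, ncol(Lmat))
  nclamp <- 0L
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    Wc <- W[idx, , drop = FALSE]
    Lc <- Lmat[idx, , drop = FALSE]
    res <- if (s_smooth)
      eif_chunk_smooth(S, G, cal$Y[idx], cal$Delta[idx], Wc, Lc, eps_clip,
                       ngrid)
    else eif_chunk_step(S, G, cal$Y[idx], cal$Delta[idx], Wc, Lc, eps_clip)
    SL[idx, ] <- res$SL
    PHI[idx, ] <- res$PHI
    nclamp <- nclamp + res$nclamp
  }
  list(SL = SL, PHI = PHI, nclamp = nclamp)
}

warn_clamped <- function(nclamp, eps_clip) {
  if (nclamp > 0)
    warning(sprintf("clamped %d denominator value(s) below %g", nclamp,
                    eps_clip))
}

# ---- estimators ----------------------------------------------------------

#' Plug-in coverage estimate
#'
#' The calibration-set average of `S(L(w) | w)`: the coverage of `L` under
#' the fitted event-time model, before the one-step correction.
#'
#' @inheritParams phi_eif
#' @param W_cal Covariate matrix of the calibration rows.
#' @return A probability in `[0, 1]`.
#' @export
plugin_coverage <- function(S, L, W_cal) {
  W_cal <- as_cov_matrix(W_cal)
  if (nrow(W_cal) == 0L) stop("calibration covariate set is empty")
  Lv <- lpb_values(L, W_cal)
  Sc <- sc_curves(S, W_cal)
  mean(vapply(seq_len(nrow(W_cal)),
              function(i) curve_eval(Sc[[i]], Lv[i]), 0))
}

#' One-step corrected coverage estimate with Wald confidence lower bound
#'
#' Adds the empirical average of the estimated efficient influence function
#' over the calibration set to the plug-in coverage; by construction the
#' corrected estimate equals the empirical mean of `phi`.  The influence
#' variance is estimated by the empirical second moment of
#' `phi - plug-in`, and a one-sided `(1 - beta)` Wald confidence lower bound
#' for the true coverage is reported.
#'
#' `L` must be built from data independent of `cal` for the inference to be
#' valid; the calibration driver [tcsurv_calibrate()] enforces this.
#'
#' @inheritParams phi_eif
#' @param cal An [rc_data] object with the calibration rows.
#' @param beta One-sided confidence parameter in (0, 1).
#' @return An object of class `coverage_estimate`: list with `psi_plugin`,
#'   `psi_onestep` (uncorrected to `[0, 1]`; `psi_onestep_trunc` is the
#'   truncated copy for display), `sigma`, `n_cal`, `beta` and `clb`.
#' @examples
#' sim <- sim_generate(sim_setting(2), n = 200, seed = 1)
#' S <- oracle_survival(sim_setting(2)); G <- oracle_censoring(sim_setting(2))
#' est <- one_step_coverage(S, G, build_lpb(S, G, 0.1), sim$data)
#' est$clb
#' @export
one_step_coverage <- function(S, G, L, cal, beta = 0.05,
                              eps_clip = EPS_CLIP, ngrid = 512L) {
  stopifnot(inherits(cal, "rc_data"))
  n <- nobs_rc(cal)
  Lv <- lpb_values(L, cal$W)
  core <- eif_core(S, G, cal, matrix(Lv, ncol = 1L), eps_clip, ngrid)
  warn_clamped(core$nclamp, eps_clip)
  psi_plugin <- mean(core$SL[, 1L])
  D <- core$PHI[, 1L] - psi_plugin
  psi_onestep <- psi_plugin + mean(D)
  sigma <- sqrt(mean(D^2))
  structure(list(psi_plugin = psi_plugin, psi_onestep = psi_onestep,
                 psi_onestep_trunc = min(max(psi_onestep, 0), 1),
                 sigma = sigma, n_cal = n, beta = beta,
                 clb = wald_clb(psi_onestep, sigma, n, beta)),
            class = "coverage_estimate")
}

#' Wald confidence lower bound
#'
#' One-sided normal-approximation lower bound
#' `psi - z_beta * sigma / sqrt(n)`, with `z_beta` the `(1 - beta)` standard
#' normal quantile.
#'
#' @param psi Point estimate.
#' @param sigma Influence-function standard deviation estimate, `>= 0`.
#' @param n Number of calibration observations, `>= 1`.
#' @param beta One-sided confidence parameter in (0, 1).
#' @return The lower confidence limit.
#' @examples
#' wald_clb(0.92, 0.3, 900, 0.05)
#' @export
wald_clb <- function(psi, sigma, n, beta) {
  if (!is.numeric(sigma) || any(sigma < 0)) stop("sigma must be >= 0")
  if (!is.numeric(n) || any(n < 1)) stop("n must be >= 1")
  if (!is.numeric(beta) || any(beta <= 0 | beta >= 1))
    stop("beta must lie strictly in (0, 1)")
  psi - qnorm(1 - beta) * sigma / sqrt(n)
}

#' @export
print.coverage_estimate <- function(x, ...) {
  cat(sprintf(
    "Coverage estimate (n = %d):\n  plug-in %.4f | one-step %.4f | sigma %.4f | %g%% CLB %.4f\n",
    x$n_cal, x$psi_plugin, x$psi_onestep_trunc, x$sigma,
    100 * (1 - x$beta), x$clb))
  invisible(x)
}

# Sweep the whole tau grid in one pass over the calibration set.
# Returns a data.frame with one row per tau.
coverage_sweep <- function(S, G, cal, tau_grid, eta2, t0, beta,
                           eps_clip = EPS_CLIP, ngrid = 512L) {
  n <- nobs_rc(cal)
  qS <- quantile_matrix(S, 1 - tau_grid, cal$W)
  gcap <- quantile_matrix(G, eta2, cal$W)[, 1L]
  Lmat <- pmin(qS, gcap, t0)               # gcap recycles down columns
  core <- eif_core(S, G, cal, Lmat, eps_clip, ngrid)
  warn_clamped(core$nclamp, eps_clip)
  psi_plugin <- colMeans(core$SL)
  D <- core$PHI - matrix(psi_plugin, n, length(tau_grid), byrow = TRUE)
  psi_onestep <- psi_plugin + colMeans(D)
  sigma <- sqrt(colMeans(D^2))
  data.frame(tau = tau_grid, psi_plugin = psi_plugin,
             psi_onestep = psi_onestep, sigma = sigma,
             clb = wald_clb(psi_onestep, sigma, n, beta))
}
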