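# Per-covariate-profile survival curves.
#
# Every fitted conditional survival model ("cond_surv" object) can produce,
# for a single covariate profile w, a curve in one of two internal forms:
#
#   step:   list(type = "step", times, surv)
#           right-continuous; S(t) = 1 for t < times[1], S(t) = surv[k] for
#           times[k] <= t < times[k+1].  Jumps sit at observed event times.
#   smooth: list(type = "smooth", S, Q, H)
#           S(t) vectorized survival, Q(p) generalized-inverse quantile,
#           H(t) cumulative hazard (-log S by default).
#
# All downstream quantities (quantiles, cumulative-hazard increments, the
# influence-function integrals) are computed from this representation, so the
# fitting backends stay interchangeable.

step_curve <- function(times, surv) {
  o <- order(times)
  list(type = "step", times = times[o], surv = pmin(pmax(surv[o], 0), 1))
}

smooth_curve <- function(S, Q = NULL, H = NULL) {
  if (is.null(H)) H <- function(t) -log(pmax(S(t), 1e-300))
  list(type = "smooth", S = S, Q = Q, H = H)
}

# S(t); right-continuous, S(t) = 1 for t <= 0.
curve_eval <- function(cv, t) {
  if (cv$type == "step") {
    idx <- findInterval(t, cv$times)
    c(1, cv$surv)[idx + 1L]
  } else {
    s <- unname(cv$S(pmax(t, 0)))
    s[s < 0] <- 0
    s[s > 1] <- 1
    s[t <= 0] <- 1
    s
  }
}

# Left limit S(t-).
curve_eval_left <- function(cv, t) {
  if (cv$type == "step") {
    idx <- findInterval(t, cv$times, left.open = TRUE)
    c(1, cv$surv)[idx + 1L]
  } else {
    curve_eval(cv, t)
  }
}

# Generalized inverse: inf{t >= 0 : S(t) <= p}; +Inf if the curve never
# reaches p on its representation.
curve_quantile <- function(cv, p) {
  if (any(p < 0 | p > 1)) stop("quantile level p must lie in [0, 1]")
  if (cv$type == "step") {
    ns <- length(cv$surv)
    rev_surv <- rev(cv$surv)             # non-decreasing
    m <- findInterval(p, rev_surv)       # count of surv values <= p
    out <- ifelse(m > 0, cv$times[pmin(ns - m + 1L, ns)], Inf)
    out[p >= 1] <- 0
    out
  } else if (!is.null(cv$Q)) {
    out <- unname(cv$Q(p))  # closed forms are vectorized over p
    out[p >= 1] <- 0
    pmax(out, 0)
  } else {
    out <- numeric(length(p))
    for (j in seq_along(p)) {
      pj <- p[j]
      if (pj >= 1) { out[j] <- 0; next }
      # numeric inversion: expand an upper bracket, then bisect
      hi <- 1
      while (cv$S(hi) > pj && hi < 1e12) hi <- hi * 2
      if (cv$S(hi) > pj) { out[j] <- Inf; next }
      out[j] <- stats::uniroot(function(t) cv$S(t) - pj, c(0, hi),
                               tol = 1e-10)$root
    }
    out
  }
}

# Cumulative-hazard increments of the curve on (0, upper].
#
# Step curves: exact discrete hazards dLambda(u) = [S(u-) - S(u)] / S(u-) at
# each downward jump u <= upper, with u_eval = u (denominator terms downstream
# are taken as left limits there).  Smooth curves: increments of H on a
# uniform grid of `ngrid` cells, with u_eval at cell midpoints so that sums of
# dLambda / f(u_eval) approximate the Lebesgue integral to O(ngrid^-2).
curve_cumhaz <- function(cv, upper, ngrid = 512L) {
  if (upper <= 0) return(list(u = numeric(0), dLambda = numeric(0),
                              u_eval = numeric(0)))
  if (cv$type == "step") {
    s_left <- c(1, cv$surv[-length(cv$surv)])
    drop <- s_left - cv$surv
    sel <- which(cv$times > 0 & cv$times <= upper & drop > 0)
    if (length(sel) && any(s_left[sel] <= 0))
      stop("positivity failure: survival curve hits 0 before a later jump")
    list(u = cv$times[sel], dLambda = drop[sel] / s_left[sel],
         u_eval = cv$times[sel], type = "step")
  } else {
    grid <- upper * ((0:ngrid) / ngrid)
    H <- unname(cv$H(grid))
    list(u = grid[-1L], dLambda = diff(H),
         u_eval = (grid[-1L] + grid[-(ngrid + 1L)]) / 2, type = "smooth")
  }
}

#' Evaluate a fitted conditional survival function
#'
#' `sc_eval()` returns `S(t | w)` (right-continuous), `sc_eval_left()` the
#' left limit `S(t- | w)`, `sc_quantile()` the generalized inverse
#' `inf\{t >= 0 : S(t | w) <= p\}` (with `+Inf` when the fitted curve never
#' reaches `p`), and `sc_cumhaz()` the cumulative-hazard increments of the
#' curve up to `upper` as a list with components `u`, `dLambda` and `u_eval`.
#'
#' @param fit A fitted `cond_surv` object from [fit_survival()],
#'   [fit_censoring()] or [oracle_survival()].
#' @param t,p Numeric vector of evaluation times / quantile levels in `[0, 1]`.
#' @param w A single covariate profile (numeric vector of length `p`).
#' @param upper Upper limit of the cumulative-hazard increments.
#' @param ngrid Number of grid cells used for smooth (parametric) curves.
#' @return `sc_eval`/`sc_eval_left`: numeric vector of survival probabilities
#'   in `[0, 1]`; `sc_quantile`: numeric vector of times; `sc_cumhaz`: a list
#'   of increment locations and sizes.
#' @examples
#' d <- rc_data(W = rep(0, 3), Y = c(1, 2, 3), Delta = c(1, 0, 1))
#' km <- fit_survival(d, model_spec("km"))
#' sc_eval(km, c(1, 2, 3), w = 0)
#' sc_quantile(km, 0.5, w = 0)
#' @export
sc_eval <- function(fit, t, w) curve_eval(sc_curve(fit, w), t)

#' @rdname sc_eval
#' @export
sc_eval_left <- function(fit, t, w) curve_eval_left(sc_curve(fit, w), t)

#' @rdname sc_eval
#' @export
sc_quantile <- function(fit, p, w) curve_quantile(sc_curve(fit, w), p)

#' @rdname sc_eval
#' @export
sc_cumhaz <- function(fit, w, upper, ngrid = 512L) {
  if (upper < 0) stop("upper must be >= 0")
  curve_cumhaz(sc_curve(fit, w), upper, ngrid)
}

#' Survival curve for one covariate profile
#'
#' Internal-facing generic mapping a fitted `cond_surv` object and a single
#' covariate profile to the curve representation used by [sc_eval()] and
#' friends.  `sc_curves()` is the batched version over the rows of a matrix;
#' backends with vectorized predictions (Cox, random survival forest)
#' override it to avoid per-row prediction calls.
#'
#' @param fit A `cond_surv` object.
#' @param w A single covariate profile.
#' @param W A covariate matrix, one profile per row.
#' @return `sc_curve()`: a curve object; `sc_curves()`: a list of curve
#'   objects, one per row of `W`.
#' @keywords internal
#' @export
sc_curve <- function(fit, w) UseMethod("sc_curve")

#' @rdname sc_curve
#' @export
sc_curves <- function(fit, W) UseMethod("sc_curves")

#' @export
sc_curves.default <- function(fit, W) {
  W <- as_cov_matrix(W)
  lapply(seq_len(nrow(W)), function(i) sc_curve(fit, W[i, ]))
}

as_cov_matrix <- function(W) {
  if (is.data.frame(W)) W <- as.matrix(W)
  if (!is.matrix(W)) W <- matrix(as.numeric(W), ncol = 1L)
  storage.mode(W) <- "double"
  W
}
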