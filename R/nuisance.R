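# Conditional survival / censoring model fitting.
#
# A fitted model is a "cond_surv" object: a small list carrying the family
# name, the modeled target ("event" or "censoring") and whatever parameters
# the family needs to produce per-profile curves through sc_curve().

#' Specify a conditional survival model family
#'
#' @param family One of `"cv_select"` (choose among `candidates` by K-fold
#'   cross-validated IPCW integrated Brier score), `"km"` (covariate-free
#'   product-limit), `"weibull"` / `"lognormal"` (accelerated failure time via
#'   [survival::survreg()]), `"coxph"` (Cox proportional hazards with Breslow
#'   baseline), `"rsf"` (random survival forest via [ranger::ranger()]), or
#'   `"exponential"` (covariate-free exponential, mainly useful as a
#'   deliberately crude reference model).
#' @param candidates Families tried by `"cv_select"`.
#' @param nfolds Number of cross-validation folds for `"cv_select"`.
#' @param num_trees,min_node_size Forest hyperparameters for `"rsf"`.
#' @return A `model_spec` object.
#' @examples
#' model_spec("weibull")
#' model_spec("cv_select", candidates = c("km", "coxph"))
#' @export
model_spec <- function(family = c("cv_select", "km", "weibull", "lognormal",
                                  "coxph", "rsf", "exponential"),
                       candidates = c("km", "weibull", "lognormal", "coxph"),
                       nfolds = 5L, num_trees = 250L, min_node_size = 15L) {
  family <- match.arg(family)
  structure(list(family = family, candidates = candidates,
                 nfolds = as.integer(nfolds), num_trees = as.integer(num_trees),
                 min_node_size = as.integer(min_node_size)),
            class = "model_spec")
}

#' Fit a conditional survival function for the event time
#'
#' Fits `S(t | w) = Pr(T > t | W = w)` on the supplied (training) data with
#' the requested model family.  `fit_censoring()` fits the censoring survival
#' `G(t | w) = Pr(C > t | W = w)` by flipping the event indicator; at tied
#' follow-up times the counting-process convention "events before censorings"
#' is applied, so censored subjects at a tied time are no longer at risk of
#' being censored after the events at that time have been removed.
#'
#' @param train An [rc_data] object; the event model requires at least one
#'   observed event.
#' @param spec A [model_spec()].
#' @return A `cond_surv` object usable with [sc_eval()], [sc_quantile()],
#'   [sc_cumhaz()] and [build_lpb()].
#' @examples
#' d <- rc_data(W = rep(0, 3), Y = c(1, 2, 3), Delta = c(1, 0, 1))
#' S <- fit_survival(d, model_spec("km"))
#' sc_eval(S, 1:3, w = 0)
#' @export
fit_survival <- function(train, spec = model_spec()) {
  stopifnot(inherits(train, "rc_data"), inherits(spec, "model_spec"))
  if (sum(train$Delta == 1) == 0)
    stop("cannot fit the event-time model: no observed events (all Delta = 0)")
  fit_target(train$Y, train$Delta, train$W, spec, target = "event",
             competing_first = NULL)
}

#' @rdname fit_survival
#' @export
fit_censoring <- function(train, spec = model_spec()) {
  stopifnot(inherits(train, "rc_data"), inherits(spec, "model_spec"))
  d_cens <- 1 - train$Delta
  if (sum(d_cens) == 0) {
    # uncensored data: G is identically 1 over the observed follow-up range
    return(structure(list(family = "km", target = "censoring",
                          p = ncol(train$W),
                          curve = step_curve(max(train$Y), 1)),
                     class = c("cs_km", "cond_surv")))
  }
  fit_target(train$Y, d_cens, train$W, spec, target = "censoring",
             competing_first = train$Delta)
}

fit_target <- function(y, d, W, spec, target, competing_first) {
  fit <- switch(spec$family,
    km          = fit_km(y, d, competing_first),
    exponential = fit_exponential(y, d),
    weibull     = fit_aft(y, d, W, "weibull"),
    lognormal   = fit_aft(y, d, W, "lognormal"),
    coxph       = fit_cox(y, d, W),
    rsf         = fit_rsf(y, d, W, spec),
    cv_select   = fit_cvselect(y, d, W, spec, competing_first))
  fit$target <- target
  fit$p <- ncol(W)
  fit
}

# ---- product-limit -------------------------------------------------------

# Product-limit estimator with an explicit tie convention: subjects counted
# in `competing_first` leave the risk set just before the modeled events at
# the same time.  Used directly for the censoring ("reverse") Kaplan-Meier;
# for the event target the offset is NULL and this is the ordinary KM.
product_limit_curve <- function(y, d, competing_first = NULL) {
  tt <- sort(unique(y))
  ys <- sort(y)
  n <- length(y)
  at_risk <- n - findInterval(tt, ys, left.open = TRUE)  # #{y >= u}
  grp <- match(y, tt)
  dN <- as.numeric(rowsum(d, grp))
  off <- if (is.null(competing_first)) 0
         else as.numeric(rowsum(competing_first, grp))
  denom <- at_risk - off
  haz <- ifelse(dN > 0, dN / pmax(denom, dN), 0)
  surv <- cumprod(1 - haz)
  keep <- dN > 0
  step_curve(tt[keep], surv[keep])
}

fit_km <- function(y, d, competing_first) {
  structure(list(family = "km",
                 curve = product_limit_curve(y, d, competing_first)),
            class = c("cs_km", "cond_surv"))
}

#' @export
sc_curve.cs_km <- function(fit, w) fit$curve

#' @export
sc_curves.cs_km <- function(fit, W) {
  W <- as_cov_matrix(W)
  rep(list(fit$curve), nrow(W))
}

# ---- covariate-free exponential -----------------------------------------

fit_exponential <- function(y, d) {
  if (sum(y) <= 0) stop("cannot fit exponential model: total follow-up is 0")
  structure(list(family = "exponential", rate = sum(d) / sum(y)),
            class = c("cs_exp", "cond_surv"))
}

#' @export
sc_curve.cs_exp <- function(fit, w) {
  rate <- fit$rate
  smooth_curve(S = function(t) exp(-rate * pmax(t, 0)),
               Q = function(p) -log(p) / rate,
               H = function(t) rate * pmax(t, 0))
}

# ---- accelerated failure time (survreg) ---------------------------------

fit_aft <- function(y, d, W, dist) {
  keep <- apply(W, 2, function(x) length(unique(x)) > 1L)
  df <- as.data.frame(W[, keep, drop = FALSE])
  df$.y <- pmax(y, 1e-10)   # survreg needs strictly positive times
  df$.d <- d
  rhs <- if (any(keep)) paste(colnames(W)[keep], collapse = " + ") else "1"
  fml <- stats::as.formula(paste("survival::Surv(.y, .d) ~", rhs))
  fit <- survival::survreg(fml, data = df, dist = dist)
  if (anyNA(fit$coefficients))
    stop(dist, " AFT fit failed: NA coefficients (degenerate design?)")
  coef <- c(fit$coefficients[1], stats::setNames(rep(0, ncol(W)), colnames(W)))
  coef[names(fit$coefficients)[-1]] <- fit$coefficients[-1]
  structure(list(family = dist, coef = coef, scale = fit$scale,
                 cov_names = colnames(W)),
            class = c(paste0("cs_", dist), "cond_surv"))
}

aft_lp <- function(fit, w) unname(fit$coef[1] + sum(fit$coef[-1] * w))

#' @export
sc_curve.cs_weibull <- function(fit, w) {
  lp <- aft_lp(fit, w); b <- fit$scale
  smooth_curve(
    S = function(t) exp(-(pmax(t, 0) * exp(-lp))^(1 / b)),
    Q = function(p) exp(lp) * (-log(p))^b,
    H = function(t) (pmax(t, 0) * exp(-lp))^(1 / b))
}

#' @export
sc_curve.cs_lognormal <- function(fit, w) {
  lp <- aft_lp(fit, w); b <- fit$scale
  smooth_curve(
    S = function(t) ifelse(t <= 0, 1, pnorm((log(pmax(t, 1e-300)) - lp) / b,
                                            lower.tail = FALSE)),
    Q = function(p) exp(lp + b * qnorm(1 - p)))
}

# ---- Cox proportional hazards -------------------------------------------

fit_cox <- function(y, d, W) {
  df <- as.data.frame(W)
  df$.y <- y
  df$.d <- d
  fml <- stats::as.formula(paste(
    "survival::Surv(.y, .d) ~", paste(colnames(W), collapse = " + ")))
  fit <- survival::coxph(fml, data = df, ties = "breslow")
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0    # aliased columns contribute nothing
  bh <- survival::basehaz(fit, centered = FALSE)
  inc <- c(bh$hazard[1], diff(bh$hazard)) > 0
  structure(list(family = "coxph", coef = beta,
                 b_time = bh$time[inc], b_haz = bh$hazard[inc],
                 cov_names = colnames(W)),
            class = c("cs_coxph", "cond_surv"))
}

#' @export
sc_curve.cs_coxph <- function(fit, w) {
  lp <- sum(fit$coef * w)
  step_curve(fit$b_time, exp(-fit$b_haz * exp(lp)))
}

#' @export
sc_curves.cs_coxph <- function(fit, W) {
  W <- as_cov_matrix(W)
  lp <- as.numeric(W %*% fit$coef)
  lapply(lp, function(l) step_curve(fit$b_time, exp(-fit$b_haz * exp(l))))
}

# ---- random survival forest ---------------------------------------------

fit_rsf <- function(y, d, W, spec) {
  df <- as.data.frame(W)
  df$.y <- y
  df$.d <- d
  fit <- ranger::ranger(
    stats::as.formula(paste("survival::Surv(.y, .d) ~",
                            paste(colnames(W), collapse = " + "))),
    data = df, num.trees = spec$num_trees,
    min.node.size = spec$min_node_size)
  structure(list(family = "rsf", fit = fit, cov_names = colnames(W)),
            class = c("cs_rsf", "cond_surv"))
}

#' @export
sc_curve.cs_rsf <- function(fit, w) sc_curves(fit, matrix(w, nrow = 1L))[[1L]]

#' @export
sc_curves.cs_rsf <- function(fit, W) {
  W <- as_cov_matrix(W)
  colnames(W) <- fit$cov_names
  pr <- predict(fit$fit, data = as.data.frame(W))
  tt <- pr$unique.death.times
  sv <- pr$survival
  if (is.null(dim(sv))) sv <- matrix(sv, nrow = nrow(W))
  lapply(seq_len(nrow(W)), function(i) {
    s <- cummin(pmin(pmax(sv[i, ], 0), 1))  # enforce monotonicity
    step_curve(tt, s)
  })
}

# ---- cross-validated family selection -----------------------------------

fit_cvselect <- function(y, d, W, spec, competing_first) {
  n <- length(y)
  K <- max(2L, min(spec$nfolds, n))
  folds <- sample(rep(seq_len(K), length.out = n))
  grid <- sort(unique(stats::quantile(y, seq(0.05, 0.9, length.out = 40),
                                      names = FALSE)))
  grid <- grid[grid > 0]
  scores <- matrix(NA_real_, K, length(spec$candidates),
                   dimnames = list(NULL, spec$candidates))
  for (k in seq_len(K)) {
    tr <- folds != k
    te <- !tr
    if (sum(d[tr]) == 0 || sum(te) == 0) next
    # censoring weights for the scored target, from the training part:
    # "censoring" for the modeled event is everything that is not one of its
    # events, with the usual events-first tie handling.
    Gw <- product_limit_curve(y[tr], 1 - d[tr], competing_first = d[tr])
    for (fam in spec$candidates) {
      fit_k <- try(fit_target(y[tr], d[tr], W[tr, , drop = FALSE],
                              model_spec(fam, num_trees = spec$num_trees,
                                         min_node_size = spec$min_node_size),
                              target = "cv", competing_first = NULL),
                   silent = TRUE)
      if (inherits(fit_k, "try-error")) next
      scores[k, fam] <- ipcw_ibs(fit_k, y[te], d[te], W[te, , drop = FALSE],
                                 Gw, grid)
    }
  }
  mean_scores <- colMeans(scores, na.rm = TRUE)
  if (all(!is.finite(mean_scores)))
    stop("cv_select: no candidate family could be fitted")
  best <- names(mean_scores)[which.min(mean_scores)]
  fit <- fit_target(y, d, W, model_spec(best, num_trees = spec$num_trees,
                                        min_node_size = spec$min_node_size),
                    target = "cv", competing_first = competing_first)
  fit$cv_scores <- mean_scores
  fit$selected <- best
  fit
}

# IPCW integrated Brier score of `fit` on held-out rows over a time grid,
# with censoring weights from the product-limit curve `Gw`.
ipcw_ibs <- function(fit, y, d, W, Gw, grid) {
  n <- length(y)
  ng <- length(grid)
  U <- matrix(grid, n, ng, byrow = TRUE)
  Smat <- bx_eval(fit, U, W)                 # n x ng
  if (is.null(Smat)) {
    curves <- sc_curves(fit, W)
    Smat <- t(matrix(vapply(curves, function(cv) curve_eval(cv, grid),
                            numeric(ng)), nrow = ng))
  }
  Gy <- pmax(curve_eval_left(Gw, y), 1e-4)             # length n, by column
  Gt <- matrix(pmax(curve_eval(Gw, grid), 1e-4), n, ng, byrow = TRUE)
  bs <- colMeans(((U >= y) & (d == 1)) * Smat^2 / Gy +
                   (U < y) * (1 - Smat)^2 / Gt)
  if (ng == 1L) return(bs)
  sum(diff(grid) * (bs[-1] + bs[-ng]) / 2) / diff(range(grid))
}

# ---- analytic conditional survival functions ----------------------------

#' Wrap analytic conditional survival functions as a fitted model
#'
#' Turns user-supplied closed-form functions into a `cond_surv` object usable
#' anywhere a fitted nuisance is: known data-generating laws, deliberately
#' misspecified models, or externally fitted models.
#'
#' @param S Function `(t, w) -> Pr(survival beyond t given w)`, vectorized
#'   over `t`.
#' @param Q Optional quantile function `(p, w) -> inf\{t : S(t|w) <= p\}`,
#'   vectorized over `p` (with `Q(0) = Inf` where the support is unbounded);
#'   numeric inversion is used when omitted.
#' @param p Covariate dimension.
#' @param target `"event"` or `"censoring"` (informational).
#' @return A `cond_surv` object of family `"oracle"`.
#' @examples
#' S <- cond_surv_fn(function(t, w) exp(-w * pmax(t, 0)),
#'                   Q = function(p, w) -log(p) / w)
#' sc_eval(S, 1, w = 2)   # exp(-2)
#' @export
cond_surv_fn <- function(S, Q = NULL, p = 1L, target = "event") {
  structure(list(family = "oracle", target = target, p = as.integer(p),
                 Sfun = S, Qfun = Q),
            class = c("cs_oracle", "cond_surv"))
}

#' @export
print.cond_surv <- function(x, ...) {
  cat(sprintf("Conditional survival model: family '%s'%s, %d covariate(s)\n",
              x$family,
              if (!is.null(x$selected)) paste0(" (cv-selected)") else "",
              x$p %||% NA_integer_))
  invisible(x)
}
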