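#' Left-truncated right-censored survival response
#'
#' @param entry delayed-entry times (days, >= 0)
#' @param exit exit times (death or censoring; must exceed entry)
#' @param status 1 = death, 0 = censored
#' @return data.frame of class `surv_response`
#' @export
surv_response <- function(entry, exit, status) {
  entry <- as.numeric(entry)
  exit <- as.numeric(exit)
  status <- as.integer(status)
  if (any(!is.finite(entry)) || any(!is.finite(exit)))
    stop("entry/exit times must be finite")
  if (any(entry < 0)) stop("entry times must be >= 0")
  if (any(exit <= entry)) stop("entry < exit must hold for every subject")
  if (!all(status %in% c(0L, 1L))) stop("status must be 0 or 1")
  structure(data.frame(entry = entry, exit = exit, status = status),
            class = c("surv_response", "data.frame"))
}

# internal: coerce strata to 0-based integer codes
strata_codes <- function(strata, n) {
  if (is.null(strata)) return(list(codes = rep(0L, n), levels = "all"))
  f <- factor(strata)
  list(codes = as.integer(f) - 1L, levels = levels(f))
}

#' Fit a lasso-penalized Cox model on left-truncated data
#'
#' Maximizes the lasso-penalized Cox partial log-likelihood with risk sets
#' restricted to `entry < t <= exit` (risk-set adjustment for left
#' truncation) and Breslow tie handling, by iteratively reweighted least
#' squares with cyclic coordinate descent, warm starts along a decreasing
#' lambda path, and an active-set strategy. Convergence at every path point
#' is certified by a Karush-Kuhn-Tucker check on the exact
#' partial-likelihood gradient. Features are standardized internally and
#' coefficients reported on the original scale.
#'
#' When `lambda_path` is omitted it is built automatically: the unpenalized
#' covariates (penalty factor 0) are fitted first, `lambda_max` is the
#' largest absolute gradient component over penalized features at that
#' solution, and the path has `nlambda` log-spaced points down to
#' `lambda_min_ratio * lambda_max`.
#'
#' @param x numeric feature matrix (finite; no missing values)
#' @param y a [surv_response()]
#' @param penalty_factors nonnegative per-feature weights; 0 = unpenalized
#'   (default all 1)
#' @param lambda_path optional decreasing positive path
#' @param strata optional stratum labels (separate risk sets and baselines,
#'   shared coefficients)
#' @param nlambda,lambda_min_ratio automatic path length and depth
#' @param tol coordinate-descent convergence tolerance (standardized scale)
#' @param kkt_tol outer-loop KKT convergence target
#' @param maxit_outer,maxit_inner iteration caps
#' @param early_stop terminate the path when the deviance ratio saturates
#'   (>= 0.99 of the saturated deviance) or stops improving (default: only
#'   for automatically built paths, which are then truncated; explicit paths
#'   are padded with the last solved coefficients to keep the grid aligned)
#' @return object of class `pancox_coxfit`
#' @export
fit_penalized_cox <- function(x, y, penalty_factors = NULL,
                              lambda_path = NULL, strata = NULL,
                              nlambda = 100, lambda_min_ratio = 0.01,
                              tol = 1e-7, kkt_tol = 5e-7,
                              maxit_outer = 200, maxit_inner = 1000,
                              early_stop = NULL) {
  early_stop <- early_stop %||% is.null(lambda_path)
  auto_path <- is.null(lambda_path)
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- sprintf("x%d", seq_len(ncol(x)))
  if (!inherits(y, "surv_response")) y <- surv_response(y$entry, y$exit, y$status)
  n <- nrow(x)
  stopifnot(nrow(y) == n)
  if (sum(y$status) == 0) stop("no events: cannot fit a Cox model")
  if (any(!is.finite(x))) stop("x must be finite after preprocessing")
  p <- ncol(x)
  pf <- penalty_factors %||% rep(1, p)
  stopifnot(length(pf) == p, all(pf >= 0))

  sc <- strata_codes(strata, n)
  centers <- colMeans(x)
  scales <- apply(x, 2, sd)
  keep <- scales > 0
  if (any(!keep & pf == 0))
    warning(sprintf("constant unpenalized column(s) dropped: %s",
                    paste(colnames(x)[!keep & pf == 0], collapse = ", ")))
  xs <- sweep(x[, keep, drop = FALSE], 2, centers[keep], "-")
  xs <- sweep(xs, 2, scales[keep], "/")
  pfk <- pf[keep]
  pk <- ncol(xs)

  # automatic lambda path from the null (unpenalized-covariates-only) model
  if (is.null(lambda_path)) {
    beta0 <- rep(0, pk)
    if (any(pfk == 0)) {
      sub <- cpp_coxnet_path(xs[, pfk == 0, drop = FALSE], y$entry, y$exit,
                             y$status, sc$codes, length(sc$levels),
                             rep(0, sum(pfk == 0)), 0,
                             tol, maxit_outer, maxit_inner, kkt_tol, FALSE)
      beta0[pfk == 0] <- sub$beta[, 1]
    }
    q <- cpp_cox_quantities(xs, beta0, y$entry, y$exit, y$status,
                            sc$codes, length(sc$levels))
    g <- abs(q$grad_beta)
    lam_max <- max(g[pfk > 0] / pfk[pfk > 0], 1e-8) * (1 + 1e-6)
    lambda_path <- exp(seq(log(lam_max), log(lam_max * lambda_min_ratio),
                           length.out = nlambda))
  } else {
    lambda_path <- as.numeric(lambda_path)
    if (is.unsorted(rev(lambda_path))) stop("lambda_path must be decreasing")
  }

  fitc <- cpp_coxnet_path(xs, y$entry, y$exit, y$status, sc$codes,
                          length(sc$levels), pfk, lambda_path,
                          tol, maxit_outer, maxit_inner, kkt_tol, early_stop)
  if (auto_path && fitc$n_used < length(lambda_path)) {
    # deviance saturated: truncate the automatic path to the solved points
    use <- seq_len(fitc$n_used)
    lambda_path <- lambda_path[use]
    fitc$beta <- fitc$beta[, use, drop = FALSE]
    for (f in c("loglik", "kkt", "iters", "sweeps"))
      fitc[[f]] <- fitc[[f]][use]
  }
  beta_std <- matrix(0, p, length(lambda_path),
                     dimnames = list(colnames(x), NULL))
  beta_std[keep, ] <- fitc$beta
  beta <- beta_std / ifelse(scales > 0, scales, 1)

  structure(list(
    features = colnames(x), lambda = lambda_path,
    beta = beta, beta_std = beta_std,
    centers = centers, scales = scales, penalty_factors = pf,
    strata_levels = sc$levels, has_strata = !is.null(strata),
    loglik = fitc$loglik, kkt = fitc$kkt, iters = fitc$iters,
    sweeps = fitc$sweeps,
    selected_lambda = NULL, cv_curve = NULL, breslow = NULL,
    n = n, n_events = sum(y$status)
  ), class = "pancox_coxfit")
}

#' @export
print.pancox_coxfit <- function(x, ...) {
  cat(sprintf("Left-truncated lasso Cox fit: %d subjects, %d events, %d features\n",
              x$n, x$n_events, length(x$features)))
  cat(sprintf("lambda path: %d points in [%.4g, %.4g]; max KKT violation %.2e\n",
              length(x$lambda), min(x$lambda), max(x$lambda),
              max(x$kkt, na.rm = TRUE)))
  if (!is.null(x$selected_lambda))
    cat(sprintf("selected lambda: %.4g (%d nonzero coefficients)\n",
                x$selected_lambda,
                sum(coef(x) != 0)))
  invisible(x)
}

# index of a lambda on the path (default: selected, else smallest)
lambda_index <- function(fit, lambda = NULL) {
  lam <- lambda %||% fit$selected_lambda %||% min(fit$lambda)
  which.min(abs(fit$lambda - lam))
}

#' @export
coef.pancox_coxfit <- function(object, lambda = NULL, ...) {
  object$beta[, lambda_index(object, lambda)]
}

#' KKT certificate for a penalized Cox path
#'
#' Recomputes the exact partial-likelihood gradient at every path point on
#' the standardized scale and returns the maximum subgradient violation:
#' for zero penalized coefficients, `max(0, |g_j| - lambda * pf_j)`; for
#' nonzero (or unpenalized) ones, `|g_j + lambda * pf_j * sign(beta_j)|`.
#'
#' @param fit a `pancox_coxfit`
#' @param x,y the training data the fit was produced from
#' @param strata optional stratum labels used at fit time
#' @return numeric vector of violations, one per path point
#' @export
kkt_certificate <- function(fit, x, y, strata = NULL) {
  x <- as.matrix(x)
  keep <- fit$scales > 0
  xs <- sweep(x[, keep, drop = FALSE], 2, fit$centers[keep], "-")
  xs <- sweep(xs, 2, fit$scales[keep], "/")
  sc <- strata_codes(strata, nrow(x))
  pf <- fit$penalty_factors[keep]
  vapply(seq_along(fit$lambda), function(l) {
    b <- fit$beta_std[keep, l]
    q <- cpp_cox_quantities(xs, b, y$entry, y$exit, y$status,
                            sc$codes, length(sc$levels))
    g <- q$grad_beta
    thr <- fit$lambda[l] * pf
    v <- ifelse(b != 0 | pf == 0,
                abs(g + thr * sign(b)),
                pmax(0, abs(g) - thr))
    max(v)
  }, numeric(1))
}

# align new data columns with the fit's features
align_columns <- function(fit, x_new) {
  x_new <- as.matrix(x_new)
  if (is.null(colnames(x_new))) {
    if (ncol(x_new) != length(fit$features))
      stop("x_new has no column names and the wrong number of columns")
    colnames(x_new) <- fit$features
  }
  missing <- setdiff(fit$features, colnames(x_new))
  extra <- setdiff(colnames(x_new), fit$features)
  if (length(missing) || length(extra))
    stop(sprintf("feature mismatch; missing: [%s]; extra: [%s]",
                 paste(missing, collapse = ", "),
                 paste(extra, collapse = ", ")))
  x_new[, fit$features, drop = FALSE]
}

# linear predictor on the centred scale (consistent between train/predict)
cox_linear_predictor <- function(fit, x_new, lambda = NULL) {
  x_new <- align_columns(fit, x_new)
  b <- fit$beta[, lambda_index(fit, lambda)]
  drop(sweep(x_new, 2, fit$centers, "-") %*% b)
}

#' Predicted risk scores
#'
#' Risk = exponential of the linear predictor of the penalized Cox model.
#'
#' @param fit a `pancox_coxfit`
#' @param x_new feature matrix whose columns match the fit
#' @param lambda path point to use (default: CV-selected, else smallest)
#' @return positive risk scores, strictly increasing in the linear predictor
#' @export
predict_risk <- function(fit, x_new, lambda = NULL) {
  exp(cox_linear_predictor(fit, x_new, lambda))
}

# cumulative baseline hazard for one stratum at given linear predictors
breslow_cumhaz <- function(entry, exit, status, lp) {
  et <- sort(unique(exit[status == 1]))
  if (length(lp) == 0 || length(et) == 0)
    return(data.frame(time = numeric(), cumhaz = numeric()))
  w <- exp(lp - max(lp))
  scale_back <- exp(max(lp))
  Sk <- vapply(et, function(t) sum(w[entry < t & t <= exit]), numeric(1))
  dk <- vapply(et, function(t) sum(exit == t & status == 1), numeric(1))
  data.frame(time = et, cumhaz = cumsum(dk / (Sk * scale_back)))
}

#' Breslow cumulative baseline hazard
#'
#' `H0(t) = sum over event times t_i <= t of d_i / sum_{j in R(t_i)}
#' exp(lp_j)` with left-truncated risk sets, per stratum.
#'
#' @param fit a `pancox_coxfit`
#' @param x_train,y_train the training data
#' @param strata optional stratum labels (must match the fit)
#' @param lambda path point (default: selected)
#' @return `fit` with a `breslow` element: named list of per-stratum step
#'   functions given as data.frames (time, cumhaz)
#' @export
breslow_baseline <- function(fit, x_train, y_train, strata = NULL,
                             lambda = NULL) {
  lp <- cox_linear_predictor(fit, x_train, lambda)
  sc <- strata_codes(strata, nrow(as.matrix(x_train)))
  bl <- lapply(seq_along(sc$levels), function(s) {
    i <- sc$codes == s - 1L
    breslow_cumhaz(y_train$entry[i], y_train$exit[i], y_train$status[i], lp[i])
  })
  names(bl) <- sc$levels
  fit$breslow <- bl
  fit$breslow_lambda <- fit$lambda[lambda_index(fit, lambda)]
  fit
}

# evaluate a cumulative-hazard step function at times t (right-continuous)
eval_cumhaz <- function(bl, t) {
  if (nrow(bl) == 0) return(rep(0, length(t)))
  idx <- findInterval(t, bl$time)
  c(0, bl$cumhaz)[idx + 1]
}

#' Predicted survival probabilities
#'
#' `S(t | x) = exp(-H0_stratum(t) * exp(lp))` from the Breslow baseline.
#'
#' @param fit a `pancox_coxfit` carrying a [breslow_baseline()]
#' @param x_new feature matrix
#' @param times nonnegative ascending evaluation times
#' @param strata_new stratum label per new subject (when the fit is
#'   stratified)
#' @param lambda path point (default: the baseline's)
#' @return matrix subjects x times of survival probabilities
#' @export
predict_survival <- function(fit, x_new, times, strata_new = NULL,
                             lambda = NULL) {
  if (is.null(fit$breslow)) stop("call breslow_baseline() first")
  if (is.unsorted(times) || any(times < 0))
    stop("times must be nonnegative and ascending")
  lp <- cox_linear_predictor(fit, x_new, lambda %||% fit$breslow_lambda)
  n <- length(lp)
  if (is.null(strata_new)) {
    if (length(fit$breslow) > 1)
      stop("strata_new required for a stratified fit")
    strata_new <- rep(names(fit$breslow)[1], n)
  }
  unknown <- setdiff(unique(strata_new), names(fit$breslow))
  if (length(unknown) > 0)
    stop(sprintf("unknown stratum: %s", paste(unknown, collapse = ", ")))
  out <- matrix(NA_real_, n, length(times))
  for (s in unique(strata_new)) {
    H <- eval_cumhaz(fit$breslow[[s]], times)
    i <- strata_new == s
    out[i, ] <- exp(-outer(exp(lp[i]), H))
  }
  dimnames(out) <- list(rownames(x_new), times)
  out
}
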