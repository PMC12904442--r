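#' Left-truncation-aware concordance index
#'
#' Ordered pair (i, j) is comparable iff subject i dies
#' (`status_i = 1`) and subject j is in the risk set at that death and
#' outlives it: `entry_j < exit_i < exit_j`. Concordant when
#' `score_i > score_j`; score ties count 1/2.
#'
#' @param entry,exit,status survival response components
#' @param scores finite risk scores (higher = riskier)
#' @return list with `c_index`, `n_comparable`, `concordant`
#' @export
concordance_index <- function(entry, exit, status, scores) {
  if (any(!is.finite(scores))) stop("scores must be finite")
  r <- cpp_cindex(as.numeric(entry), as.numeric(exit), as.integer(status),
                  as.numeric(scores))
  if (r$comparable == 0) stop("no comparable pairs")
  list(c_index = r$concordant / r$comparable,
       n_comparable = r$comparable, concordant = r$concordant)
}

# Kaplan-Meier with delayed-entry risk sets, via survival::survfit
km_fit <- function(entry, exit, status) {
  sf <- survival::survfit(
    survival::Surv(entry, exit, status) ~ 1,
    data = data.frame(entry = entry, exit = exit, status = status))
  data.frame(time = sf$time, surv = sf$surv, n_risk = sf$n.risk,
             n_event = sf$n.event)
}

# evaluate a KM step function; left = TRUE gives S(t-)
eval_km <- function(km, t, left = FALSE) {
  if (nrow(km) == 0) return(rep(1, length(t)))
  idx <- if (left) findInterval(t, km$time, left.open = TRUE)
         else findInterval(t, km$time)
  c(1, km$surv)[idx + 1]
}

#' Integrated Brier score with IPCW
#'
#' Computes the censoring-weighted Brier score over a time grid and its
#' trapezoidal average over `[first test event time, 95th percentile of
#' test exit times]`. The censoring-survival function G is a
#' left-truncation-adjusted Kaplan-Meier of the censoring distribution
#' fitted on the training response; weights are capped at `weight_cap`.
#'
#' @param y_train,y_test [surv_response()] objects
#' @param predicted_survival matrix, test subjects x `time_grid`
#' @param time_grid ascending evaluation times matching the prediction
#'   columns
#' @param weight_cap maximum IPCW weight (default 20)
#' @return list with `ibs`, `times`, `bs` (the Brier curve)
#' @export
integrated_brier_score <- function(y_train, y_test, predicted_survival,
                                   time_grid, weight_cap = 20) {
  stopifnot(ncol(predicted_survival) == length(time_grid),
            nrow(predicted_survival) == nrow(y_test))
  ev <- y_test$exit[y_test$status == 1]
  if (length(ev) == 0) stop("no events in the test set")
  lo <- min(ev)
  hi <- quantile(y_test$exit, 0.95, names = FALSE)
  use <- which(time_grid >= lo & time_grid <= hi)
  if (length(use) == 0) use <- which.min(abs(time_grid - lo))
  times <- time_grid[use]
  G <- km_fit(y_train$entry, y_train$exit, 1L - y_train$status)
  g_at_exit <- pmax(eval_km(G, y_test$exit, left = TRUE), 1 / weight_cap)
  bs <- vapply(seq_along(times), function(k) {
    t <- times[k]
    S <- predicted_survival[, use[k]]
    g_t <- max(eval_km(G, t), 1 / weight_cap)
    died <- y_test$exit <= t & y_test$status == 1
    alive <- y_test$exit > t
    contrib <- numeric(nrow(y_test))
    contrib[died] <- S[died]^2 / g_at_exit[died]
    contrib[alive] <- (1 - S[alive])^2 / g_t
    mean(contrib)
  }, numeric(1))
  ibs <- if (length(times) == 1) bs else {
    sum(diff(times) * (head(bs, -1) + tail(bs, -1)) / 2) / diff(range(times))
  }
  list(ibs = ibs, times = times, bs = bs)
}

#' Median-split risk stratification and hazard ratio
#'
#' Splits test subjects into low/high risk at the per-cohort median of the
#' training risk scores, fits a one-covariate unpenalized Cox model (with
#' left-truncated risk sets) of the low-risk indicator, and reports the
#' hazard ratio as hazard(low)/hazard(high) — below 1 when the scores are
#' prognostic — with a Wald 95% CI, plus per-group Kaplan-Meier curves.
#'
#' @param train_scores,test_scores risk scores on a common scale
#' @param y_test test [surv_response()]
#' @param cohort_train,cohort_test cohort (cancer-type) labels; medians are
#'   computed per training cohort
#' @return list with `groups`, `hr`, `ci`, `km_curves`, `degenerate`
#' @export
risk_stratify_and_hr <- function(train_scores, test_scores, y_test,
                                 cohort_train = NULL, cohort_test = NULL) {
  if (is.null(cohort_train)) cohort_train <- rep("all", length(train_scores))
  if (is.null(cohort_test)) cohort_test <- rep("all", length(test_scores))
  med <- tapply(train_scores, cohort_train, median)
  thr <- med[as.character(cohort_test)]
  groups <- ifelse(test_scores > thr, "high", "low")
  degenerate <- length(unique(groups)) < 2
  hr <- ci <- c(NA_real_, NA_real_)
  km <- list()
  for (g in unique(groups)) {
    i <- groups == g
    km[[g]] <- km_fit(y_test$entry[i], y_test$exit[i], y_test$status[i])
  }
  if (!degenerate) {
    d <- data.frame(entry = y_test$entry, exit = y_test$exit,
                    status = y_test$status, low = as.numeric(groups == "low"))
    cf <- tryCatch(
      survival::coxph(survival::Surv(entry, exit, status) ~ low, data = d,
                      ties = "breslow"),
      error = function(e) NULL)
    if (!is.null(cf) && is.finite(coef(cf)[1])) {
      b <- coef(cf)[1]
      se <- sqrt(diag(cf$var))[1]
      hr <- exp(b)
      ci <- exp(b + c(-1, 1) * qnorm(0.975) * se)
    } else degenerate <- TRUE
  }
  list(groups = groups, hr = unname(hr[1]), ci = unname(ci),
       km_curves = km, degenerate = degenerate)
}

# resample row indices, optionally within strata
resample_idx <- function(n, strata = NULL) {
  if (is.null(strata)) return(sample.int(n, n, replace = TRUE))
  idx <- integer(0)
  for (lev in unique(strata)) {
    i <- which(strata == lev)
    idx <- c(idx, i[sample.int(length(i), length(i), replace = TRUE)])
  }
  idx
}

subset_rows <- function(x, idx) {
  if (is.null(x)) return(NULL)
  if (is.matrix(x) || is.data.frame(x)) x[idx, , drop = FALSE] else x[idx]
}

#' Bias-corrected bootstrap percentile interval
#'
#' Resamples train and test rows with replacement (optionally stratified),
#' recomputes the statistic, and returns the bias-corrected percentile
#' interval: `z0 = qnorm(#\{theta* < theta_hat\}/B)` and endpoints at the
#' `pnorm(2 z0 +/- z_\{1-alpha/2\})` quantiles of the bootstrap
#' distribution (acceleration a = 0).
#'
#' @param statistic_fn function of (train_data, test_data) returning a real
#' @param train_data,test_data vectors, matrices or data.frames (either may
#'   be NULL)
#' @param B bootstrap replicates (>= 100)
#' @param seed integer seed
#' @param alpha interval level (default 0.05)
#' @param train_strata,test_strata optional resampling strata labels
#' @return list with `point`, `lower`, `upper`, `z0`, `replicates`
#' @export
bc_bootstrap_ci <- function(statistic_fn, train_data, test_data, B = 1000,
                            seed = 1L, alpha = 0.05,
                            train_strata = NULL, test_strata = NULL) {
  stopifnot(B >= 100)
  point <- statistic_fn(train_data, test_data)
  n_tr <- if (is.null(train_data)) 0 else NROW(train_data)
  n_te <- if (is.null(test_data)) 0 else NROW(test_data)
  set.seed(seed)
  reps <- vapply(seq_len(B), function(b) {
    tr <- if (n_tr > 0) subset_rows(train_data, resample_idx(n_tr, train_strata))
    te <- if (n_te > 0) subset_rows(test_data, resample_idx(n_te, test_strata))
    tryCatch(statistic_fn(tr, te), error = function(e) NA_real_)
  }, numeric(1))
  reps <- reps[is.finite(reps)]
  if (length(reps) < B / 2)
    stop("too many failed bootstrap replicates")
  if (all(reps == point)) {
    warning("degenerate bootstrap distribution; interval collapses to the point")
    return(list(point = point, lower = point, upper = point, z0 = 0,
                replicates = reps))
  }
  frac <- sum(reps < point) / length(reps)
  frac <- min(max(frac, 1 / (2 * length(reps))), 1 - 1 / (2 * length(reps)))
  z0 <- qnorm(frac)
  za <- qnorm(1 - alpha / 2)
  qs <- pnorm(c(2 * z0 - za, 2 * z0 + za))
  ci <- unname(quantile(reps, qs))
  list(point = point, lower = ci[1], upper = ci[2], z0 = z0,
       replicates = reps)
}
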