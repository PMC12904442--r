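#' Cross-validated lambda selection by concordance
#'
#' Builds the lambda path on the full training data, then for each of
#' `n_folds` folds (stratified by `fold_strata`, typically cancer type
#' crossed with event status) refits the path on the in-fold data with warm
#' starts and scores the held-out linear predictors by the
#' left-truncation-aware concordance index. Per-lambda scores are computed
#' within each fold and averaged; the lambda maximizing the mean score is
#' selected, with ties broken towards the largest lambda (the sparser
#' model).
#'
#' @param x,y,penalty_factors,strata,... as in [fit_penalized_cox()]
#' @param n_folds number of folds (>= 2)
#' @param fold_strata factor used to stratify fold assignment (default:
#'   event status)
#' @param seed integer seed controlling fold assignment
#' @return the full-data `pancox_coxfit` with `selected_lambda`,
#'   `cv_curve` (data.frame lambda/mean_cindex) and `folds` attached
#' @export
cross_validate_lambda <- function(x, y, penalty_factors = NULL,
                                  strata = NULL, n_folds = 5,
                                  fold_strata = NULL, seed = 1L, ...) {
  stopifnot(n_folds >= 2)
  x <- as.matrix(x)
  if (!inherits(y, "surv_response")) y <- surv_response(y$entry, y$exit, y$status)
  n <- nrow(x)
  fs <- interaction(fold_strata %||% rep(1, n), y$status, drop = TRUE)

  assign_folds <- function(sd) {
    set.seed(sd)
    folds <- integer(n)
    for (lev in levels(fs)) {
      i <- which(fs == lev)
      folds[i] <- sample(rep_len(seq_len(n_folds), length(i)))
    }
    folds
  }
  folds <- assign_folds(seed)
  for (attempt in 1:10) {
    ev <- vapply(seq_len(n_folds), function(f)
      sum(y$status[folds != f]) > 0 && sum(y$status[folds == f]) > 0,
      logical(1))
    if (all(ev)) break
    if (attempt == 10) stop("could not build folds with events in every fold")
    warning("fold without events; refolding")
    folds <- assign_folds(seed + attempt)
  }

  full <- fit_penalized_cox(x, y, penalty_factors = penalty_factors,
                            strata = strata, ...)
  lam <- full$lambda
  scores <- matrix(NA_real_, n_folds, length(lam))
  for (f in seq_len(n_folds)) {
    tr <- folds != f
    fit_f <- fit_penalized_cox(x[tr, , drop = FALSE],
                               surv_response(y$entry[tr], y$exit[tr], y$status[tr]),
                               penalty_factors = penalty_factors,
                               lambda_path = lam, early_stop = TRUE,
                               strata = if (!is.null(strata)) strata[tr], ...)
    xh <- sweep(as.matrix(x[!tr, , drop = FALSE]), 2, fit_f$centers, "-")
    lp <- xh %*% fit_f$beta
    scores[f, ] <- cpp_cindex_multi(y$entry[!tr], y$exit[!tr],
                                    y$status[!tr], lp)
  }
  mean_c <- colMeans(scores, na.rm = TRUE)
  best <- which.max(mean_c) # path is decreasing, ties -> largest lambda
  full$selected_lambda <- lam[best]
  full$cv_curve <- data.frame(lambda = lam, mean_cindex = mean_c)
  full$folds <- folds
  full
}
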