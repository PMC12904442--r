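#' k-nearest-neighbour imputation
#'
#' Distances between a row needing imputation and each donor row are
#' Euclidean over co-observed features, scaled by the number of co-observed
#' features: `d(i, j) = sqrt(sum((x_i - x_j)^2) / n_co)`. Each missing cell
#' is filled with the unweighted mean of the k nearest donors that observe
#' that feature; binary features are rounded to \{0, 1\} at 0.5 with ties
#' going to 0. When fewer than k eligible donors exist all available donors
#' are used; with none, the donor-column median. Deterministic: distance
#' ties break by donor order.
#'
#' @param block numeric matrix with missing entries (rows = subjects)
#' @param k neighbour count (>= 1)
#' @param donors donor matrix with identical columns (training rows); default
#'   is the complete-feature rows of `block` itself
#' @param reference_block optional auxiliary donor rows (e.g. an external
#'   reference cohort); used only as donors, never returned
#' @return the completed block (same dimensions as `block`)
#' @export
impute_knn <- function(block, k = 5, donors = NULL, reference_block = NULL) {
  stopifnot(k >= 1)
  block <- as.matrix(block)
  if (is.null(donors)) donors <- block
  donors <- as.matrix(donors)
  if (!is.null(reference_block)) {
    reference_block <- as.matrix(reference_block)
    stopifnot(ncol(reference_block) == ncol(block))
    donors <- rbind(donors, reference_block)
  }
  stopifnot(ncol(donors) == ncol(block))
  no_obs <- rowSums(!is.na(block)) == 0
  if (any(no_obs))
    stop(sprintf("row(s) with no observed features: %s",
                 paste(which(no_obs), collapse = ", ")))
  # binary behaviour is a fitted property: detect it on the donor rows
  is_bin <- apply(donors, 2, function(c) all(c[!is.na(c)] %in% c(0, 1)))
  need <- which(rowSums(is.na(block)) > 0)
  dobs <- !is.na(donors)
  for (i in need) {
    xi <- block[i, ]
    oi <- !is.na(xi)
    # squared distance over co-observed features, scaled by their number
    diff2 <- sweep(donors[, oi, drop = FALSE], 2, xi[oi], "-")^2
    nco <- rowSums(dobs[, oi, drop = FALSE])
    d2 <- rowSums(diff2, na.rm = TRUE) / pmax(nco, 1)
    d2[nco == 0] <- Inf
    for (j in which(!oi)) {
      elig <- which(dobs[, j] & is.finite(d2))
      if (length(elig) == 0) {
        v <- median(donors[, j], na.rm = TRUE)
        if (is.na(v))
          stop(sprintf("no donor observes feature %d; screen it out first", j))
      } else {
        sel <- elig[order(d2[elig])][seq_len(min(k, length(elig)))]
        v <- mean(donors[sel, j])
      }
      if (is_bin[j]) v <- if (v > 0.5) 1 else 0
      block[i, j] <- v
    }
  }
  block
}

# ridge-stabilized least squares: solve (X'X + eps I) b = X'y
ridge_fit <- function(X, y, eps = 1e-4) {
  Xc <- cbind(1, X)
  A <- crossprod(Xc) + diag(eps, ncol(Xc))
  drop(solve(A, crossprod(Xc, y)))
}

# ridge-stabilized logistic regression via a few IRLS steps
logit_fit <- function(X, y, eps = 1e-4, iters = 8) {
  Xc <- cbind(1, X)
  b <- rep(0, ncol(Xc))
  for (it in seq_len(iters)) {
    eta <- pmin(30, pmax(-30, drop(Xc %*% b)))
    p <- 1 / (1 + exp(-eta))
    w <- pmax(p * (1 - p), 1e-6)
    z <- eta + (y - p) / w
    A <- crossprod(Xc * w, Xc) + diag(eps, ncol(Xc))
    bn <- drop(solve(A, crossprod(Xc * w, z)))
    if (max(abs(bn - b)) < 1e-8) { b <- bn; break }
    b <- bn
  }
  b
}

#' Chained-equation imputation with predictive mean matching
#'
#' Initializes missing continuous cells with the training-column median and
#' binary cells with the training mode, then cycles over incomplete columns
#' for `n_iterations` sweeps. Continuous targets are imputed by predictive
#' mean matching (linear model, donor pool of `donor_pool` training rows
#' with the closest predictions, one drawn at random); binary targets by a
#' Bernoulli draw from a logistic model. Models are fitted on training rows
#' only and applied to all rows. For tractability each column is predicted
#' from at most `max_predictors` other columns, chosen once by absolute
#' correlation on the initialized training data.
#'
#' @param block numeric matrix/data.frame with missing entries
#' @param n_iterations chained sweeps (default 10)
#' @param n_datasets number m of completed datasets (independent chains)
#' @param seed integer seed; chain b uses `seed + 1000 * (b - 1)`
#' @param training_rows logical or integer index of training rows (default:
#'   all rows)
#' @param donor_pool PMM donor-pool size
#' @param max_predictors cap on predictors per imputation model
#' @return list of `n_datasets` completed matrices
#' @export
impute_chained <- function(block, n_iterations = 10, n_datasets = 1,
                           seed = 1L, training_rows = NULL, donor_pool = 5,
                           max_predictors = 15) {
  block <- as.matrix(block)
  n <- nrow(block)
  p <- ncol(block)
  tr <- rep(FALSE, n)
  if (is.null(training_rows)) tr <- rep(TRUE, n)
  else if (is.logical(training_rows)) tr <- training_rows
  else tr[training_rows] <- TRUE
  miss <- is.na(block)
  targets <- which(colSums(miss) > 0)
  if (length(targets) == 0) return(rep(list(block), n_datasets))
  fully_missing <- colSums(!miss[tr, , drop = FALSE]) == 0
  if (any(fully_missing[targets]))
    stop(sprintf("column(s) entirely missing in training rows: %s",
                 paste(colnames(block)[targets][fully_missing[targets]],
                       collapse = ", ")))
  is_bin <- apply(block[tr, , drop = FALSE], 2,
                  function(c) all(c[!is.na(c)] %in% c(0, 1)))

  init <- block
  for (j in seq_len(p)) {
    obs <- block[tr, j]
    obs <- obs[!is.na(obs)]
    fill <- if (is_bin[j]) {
      as.numeric(mean(obs) >= 0.5)
    } else median(obs)
    init[miss[, j], j] <- fill
  }
  # fixed predictor sets from initialized training data
  preds <- list()
  if (p > 1) {
    cm <- suppressWarnings(abs(stats::cor(init[tr, , drop = FALSE])))
    cm[!is.finite(cm)] <- 0
    diag(cm) <- 0
  }
  for (j in targets) {
    others <- setdiff(seq_len(p), j)
    if (length(others) > max_predictors)
      others <- others[order(cm[j, others], decreasing = TRUE)][seq_len(max_predictors)]
    preds[[as.character(j)]] <- others
  }

  out <- vector("list", n_datasets)
  for (b in seq_len(n_datasets)) {
    set.seed(seed + 1000L * (b - 1L))
    x <- init
    for (it in seq_len(n_iterations)) {
      for (j in targets) {
        pj <- preds[[as.character(j)]]
        mrows <- which(miss[, j])
        fit_rows <- which(tr & !miss[, j])
        X <- x[, pj, drop = FALSE]
        if (is_bin[j]) {
          b0 <- logit_fit(X[fit_rows, , drop = FALSE], x[fit_rows, j])
          eta <- pmin(30, pmax(-30, drop(cbind(1, X[mrows, , drop = FALSE]) %*% b0)))
          x[mrows, j] <- rbinom(length(mrows), 1, 1 / (1 + exp(-eta)))
        } else {
          b0 <- ridge_fit(X[fit_rows, , drop = FALSE], x[fit_rows, j])
          yhat_d <- drop(cbind(1, X[fit_rows, , drop = FALSE]) %*% b0)
          yhat_m <- drop(cbind(1, X[mrows, , drop = FALSE]) %*% b0)
          o <- order(yhat_d)
          yd <- yhat_d[o]
          vd <- x[fit_rows, j][o]
          nd <- length(yd)
          pool <- min(donor_pool, nd)
          pos <- findInterval(yhat_m, yd)
          for (idx in seq_along(mrows)) {
            lo <- max(1, min(pos[idx] - pool + 1, nd - pool + 1))
            cand <- lo:(lo + pool - 1)
            # candidates nearest in predicted value
            cand <- cand[order(abs(yd[cand] - yhat_m[idx]))][seq_len(pool)]
            x[mrows[idx], j] <- vd[sample(cand, 1)]
          }
        }
      }
    }
    out[[b]] <- x
  }
  out
}

#' Impute a feature container in place
#'
#' Applies [impute_knn()] to the genomic binary block and [impute_chained()]
#' to incomplete clinical columns (demographic, treatment, lab/vitals);
#' cancer-specific columns are median-imputed within their in-scope training
#' rows (out-of-scope cells are zeroed later by [finalize_matrix()]).
#' Categorical columns are mode-imputed from training rows. Only the first
#' completed chained dataset flows back into the container.
#'
#' @param fm a screened `pancox_features` object
#' @param training_ids training subject ids
#' @param subject_cancers named vector mapping subject id to cancer type
#' @param k kNN neighbour count
#' @param reference_block optional auxiliary donor rows for the genomic kNN
#' @param n_iterations,n_datasets,seed passed to [impute_chained()]
#' @return `fm` with missing in-scope values completed and an `imputation`
#'   manifest attached
#' @export
impute_features <- function(fm, training_ids, subject_cancers = NULL,
                            k = 5, reference_block = NULL,
                            n_iterations = 10, n_datasets = 1, seed = 1L) {
  tr <- fm$subject_id %in% training_ids
  vals <- fm$values
  meta <- fm$meta
  counts <- vapply(vals, function(c) sum(is.na(c)), integer(1))

  gen_bin <- meta$name[meta$modality == "genomic" & meta$type == "binary"]
  gen_bin <- gen_bin[vapply(vals[gen_bin], anyNA, logical(1))]
  if (length(gen_bin) > 0) {
    gcols <- meta$name[meta$modality == "genomic" & meta$type != "categorical"]
    gblock <- as.matrix(vals[, gcols, drop = FALSE])
    done <- impute_knn(gblock, k = k, donors = gblock[tr, , drop = FALSE],
                       reference_block = reference_block)
    for (nm in gen_bin) vals[[nm]] <- done[, nm]
  }

  cs_cols <- meta$name[!is.na(meta$cancer_scope)]
  for (nm in cs_cols) {
    if (!anyNA(vals[[nm]])) next
    scope <- meta$cancer_scope[meta$name == nm]
    in_scope <- subject_cancers[fm$subject_id] %in% scope
    med <- median(vals[[nm]][in_scope & tr], na.rm = TRUE)
    fill <- in_scope & is.na(vals[[nm]])
    vals[[nm]][fill] <- med
  }

  clin <- meta$name[meta$modality %in% c("demographic", "treatment", "lab_vitals") &
                    meta$type %in% c("continuous", "binary")]
  clin_na <- clin[vapply(vals[clin], anyNA, logical(1))]
  if (length(clin_na) > 0) {
    cblock <- as.matrix(vals[, clin, drop = FALSE])
    done <- impute_chained(cblock, n_iterations = n_iterations,
                           n_datasets = n_datasets, seed = seed,
                           training_rows = tr)[[1]]
    for (nm in clin_na) vals[[nm]] <- done[, nm]
  }

  cat_cols <- meta$name[meta$type == "categorical"]
  for (nm in cat_cols) {
    if (!anyNA(vals[[nm]])) next
    tab <- table(vals[[nm]][tr])
    mode_lev <- names(tab)[which.max(tab)]
    if (is.factor(vals[[nm]])) {
      vals[[nm]][is.na(vals[[nm]])] <- mode_lev
    } else vals[[nm]][is.na(vals[[nm]])] <- mode_lev
  }

  fm$values <- vals
  fm$imputation <- list(method = c(genomic = "knn", clinical = "chained"),
                        k = k, n_iterations = n_iterations,
                        n_datasets = n_datasets, seed = seed,
                        imputed_counts = counts[counts > 0])
  fm
}
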