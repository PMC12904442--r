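#' Data-driven feature screening
#'
#' Removes features that are zero-variance, near-zero-variance (binary/dummy
#' variables with fewer than `nzv_min_count` positive counts) or missing in
#' more than `max_missing_fraction` of the training cohort. All statistics
#' are computed on training subjects only and the verdicts applied
#' identically to the remaining rows. For cancer-specific features the
#' missingness fraction is computed among in-scope training subjects, since
#' out-of-scope missingness is structural, not informative.
#'
#' @param fm a `pancox_features` object from [build_feature_matrix()]
#' @param config a [feature_config()]
#' @param training_ids subject ids that constitute the training set
#' @param subject_cancers optional named vector mapping subject id to cancer
#'   type (needed when cancer-specific features are present)
#' @return `fm` with screened columns removed and a `screen` report
#'   (data.frame: feature, reason, statistic) attached
#' @export
screen_features <- function(fm, config = feature_config(), training_ids,
                            subject_cancers = NULL) {
  stopifnot(length(training_ids) > 0)
  tr <- fm$subject_id %in% training_ids
  if (!any(tr)) stop("no training subjects found in feature matrix")
  report <- NULL
  drop <- character()
  for (nm in names(fm$values)) {
    col <- fm$values[[nm]]
    info <- fm$meta[fm$meta$name == nm, ]
    rows <- tr
    if (!is.na(info$cancer_scope) && !is.null(subject_cancers)) {
      rows <- tr & subject_cancers[fm$subject_id] %in% info$cancer_scope
    }
    x <- col[rows]
    miss <- if (sum(rows) > 0) mean(is.na(x)) else 1
    obs <- x[!is.na(x)]
    reason <- NULL
    statistic <- NA_real_
    if (length(obs) == 0 || length(unique(obs)) == 1) {
      reason <- "zero_variance"
      statistic <- length(unique(obs))
    } else if (info$type == "binary" && sum(obs == 1) < config$nzv_min_count) {
      reason <- "near_zero_variance"
      statistic <- sum(obs == 1)
    } else if (miss > config$max_missing_fraction) {
      reason <- "missingness"
      statistic <- miss
    }
    if (!is.null(reason)) {
      drop <- c(drop, nm)
      report <- rbind(report, data.frame(feature = nm, reason = reason,
                                         statistic = statistic,
                                         stringsAsFactors = FALSE))
    }
  }
  fm$values <- fm$values[, setdiff(names(fm$values), drop), drop = FALSE]
  fm$meta <- fm$meta[!fm$meta$name %in% drop, , drop = FALSE]
  fm$screen <- report %||%
    data.frame(feature = character(), reason = character(),
               statistic = numeric(), stringsAsFactors = FALSE)
  fm
}

#' Finalize the feature matrix for modeling
#'
#' Sets cancer-specific features to 0 for out-of-scope subjects (structured
#' missingness is zeroed, not imputed), one-hot encodes categorical features
#' with the training-majority level as the dropped reference (dummies with
#' fewer than `nzv_min_count` positive training counts are removed, recorded
#' in the screen report), z-scores continuous features with training
#' mean/SD, and clips them at +/- `z_truncation`. Binary features stay on
#' the 0/1 scale. All fitted statistics are pure functions of training rows.
#'
#' @param fm a screened (and imputed) `pancox_features` object
#' @param training_ids training subject ids
#' @param subject_cancers named vector mapping subject id to cancer type
#' @param config a [feature_config()]
#' @return `fm` with `values` replaced by an all-numeric matrix `x` and a
#'   `finalize` slot holding the fitted statistics
#' @export
finalize_matrix <- function(fm, training_ids, subject_cancers = NULL,
                            config = feature_config()) {
  tr <- fm$subject_id %in% training_ids
  n <- length(fm$subject_id)
  cols <- list()
  meta_out <- NULL
  stats <- list(center = c(), scale = c(), ref_levels = list(),
                dummy_dropped = character())
  for (nm in names(fm$values)) {
    col <- fm$values[[nm]]
    info <- fm$meta[fm$meta$name == nm, ]
    info$parent <- nm # original (pre-one-hot) feature name
    if (!is.na(info$cancer_scope)) {
      if (is.null(subject_cancers))
        stop("subject_cancers needed to finalize cancer-specific features")
      out_scope <- !(subject_cancers[fm$subject_id] %in% info$cancer_scope)
      col[out_scope] <- 0
    }
    if (info$type == "categorical") {
      f <- factor(col)
      tab <- table(f[tr])
      ref <- names(tab)[which.max(tab)] # majority level = reference
      stats$ref_levels[[nm]] <- ref
      for (lev in setdiff(levels(f), ref)) {
        dnm <- paste0(nm, "_", lev)
        d <- as.numeric(f == lev)
        if (sum(d[tr], na.rm = TRUE) < config$nzv_min_count) {
          stats$dummy_dropped <- c(stats$dummy_dropped, dnm)
          fm$screen <- rbind(fm$screen,
                             data.frame(feature = dnm,
                                        reason = "near_zero_variance",
                                        statistic = sum(d[tr], na.rm = TRUE),
                                        stringsAsFactors = FALSE))
          next
        }
        cols[[dnm]] <- d
        meta_out <- rbind(meta_out,
                          transform(info, name = dnm, type = "binary"))
      }
    } else if (info$type == "binary") {
      cols[[nm]] <- as.numeric(col)
      meta_out <- rbind(meta_out, info)
    } else {
      x <- as.numeric(col)
      mu <- mean(x[tr], na.rm = TRUE)
      s <- sd(x[tr], na.rm = TRUE)
      if (!is.finite(s) || s == 0)
        stop(sprintf("zero training SD for feature '%s' after screening", nm))
      z <- (x - mu) / s
      z <- pmin(config$z_truncation, pmax(-config$z_truncation, z))
      stats$center[nm] <- mu
      stats$scale[nm] <- s
      cols[[nm]] <- z
      meta_out <- rbind(meta_out, info)
    }
  }
  x <- do.call(cbind, cols)
  rownames(x) <- fm$subject_id
  fm$x <- x
  fm$meta_final <- meta_out
  fm$finalize <- stats
  fm
}
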