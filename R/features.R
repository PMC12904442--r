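#' Feature-engineering configuration
#'
#' @param windows lookback window lengths in days for lab time-series
#'   summaries
#' @param apen_m approximate-entropy template length
#' @param apen_r_factor approximate-entropy tolerance as a multiple of the
#'   series standard deviation
#' @param nzv_min_count minimum positive training count for a dummy (binary)
#'   variable to survive near-zero-variance screening
#' @param max_missing_fraction features missing in more than this fraction of
#'   the training cohort are removed
#' @param z_truncation continuous features are clipped at +/- this many
#'   z-scores after normalization
#' @return object of class `feature_config`
#' @export
feature_config <- function(windows = c(60, 720), apen_m = 2,
                           apen_r_factor = 0.2, nzv_min_count = 20,
                           max_missing_fraction = 0.30, z_truncation = 3) {
  stopifnot(all(windows > 0), apen_m >= 1, apen_r_factor > 0,
            nzv_min_count > 0, max_missing_fraction > 0, z_truncation > 0)
  structure(list(windows = windows, apen_m = as.integer(apen_m),
                 apen_r_factor = apen_r_factor,
                 nzv_min_count = nzv_min_count,
                 max_missing_fraction = max_missing_fraction,
                 z_truncation = z_truncation),
            class = "feature_config")
}

#' Approximate entropy (ApEn)
#'
#' Pincus approximate entropy with self-matches included:
#' `ApEn = Phi_m(r) - Phi_{m+1}(r)` where `Phi_k(r)` is the mean over
#' templates of the log fraction of templates within Chebyshev distance `r`.
#'
#' @param x numeric series (in temporal order)
#' @param m template length (>= 1)
#' @param r tolerance (>= 0); typically 0.2 * sd(x)
#' @return ApEn, or `NA` if `length(x) < m + 1`
#' @export
approximate_entropy <- function(x, m = 2, r = 0.2 * sd(x)) {
  n <- length(x)
  if (n < m + 1) return(NA_real_)
  if (is.na(r) || r < 0) stop("approximate_entropy: tolerance r must be >= 0")
  phi <- function(k) {
    nt <- n - k + 1
    tm <- matrix(NA_real_, nt, k)
    for (j in seq_len(k)) tm[, j] <- x[(j - 1) + seq_len(nt)]
    cnt <- numeric(nt)
    for (i in seq_len(nt)) {
      d <- abs(tm - rep(tm[i, ], each = nt))
      cnt[i] <- sum(apply(d, 1, max) <= r)
    }
    mean(log(cnt / nt))
  }
  phi(m) - phi(m + 1)
}

# the 11 per-(analyte, window) summary names, in a fixed order
lab_summary_stats <- c("mean", "median", "variance", "max", "min", "apen",
                       "diff_last2", "slope_last2", "n_tests", "test_ratio",
                       "prop_abnormal")

# summaries for one (subject, analyte) series already restricted to the
# window; v = raw values, t = obs times, vn = limit-normalized values
lab_series_summaries <- function(v, t, lln, uln, record_len, window_days,
                                 config) {
  out <- setNames(rep(NA_real_, length(lab_summary_stats)), lab_summary_stats)
  n <- length(v)
  out["n_tests"] <- n
  avail <- max(1, min(window_days, record_len))
  out["test_ratio"] <- n / avail
  if (n == 0) return(out)
  vn <- (v - lln) / (uln - lln)
  out["mean"] <- mean(vn)
  out["median"] <- median(vn)
  out["max"] <- max(vn)
  out["min"] <- min(vn)
  out["prop_abnormal"] <- mean(v < lln | v > uln) # limits inclusive-normal
  if (n >= 2) {
    out["variance"] <- var(vn)
    o <- order(t)
    v2 <- vn[o][(n - 1):n]
    t2 <- t[o][(n - 1):n]
    out["diff_last2"] <- v2[2] - v2[1]
    if (t2[2] != t2[1]) out["slope_last2"] <- (v2[2] - v2[1]) / (t2[2] - t2[1])
  }
  if (n >= config$apen_m + 1) {
    vo <- vn[order(t)]
    s <- sd(vo)
    out["apen"] <- approximate_entropy(vo, config$apen_m,
                                       config$apen_r_factor * max(s, 0))
  }
  out
}

#' Windowed summaries of longitudinal lab series
#'
#' Restricts observations to the half-open window `[-window_days, 0)` days
#' relative to the index date, normalizes values to the limits of normal via
#' `(v - lln)/(uln - lln)`, and emits 11 summaries per (subject, analyte):
#' mean, median, variance, max, min, approximate entropy, difference and
#' slope of the last two values, number of tests, ratio of tests to the
#' available window, and the proportion of abnormal values (strictly outside
#' `[lln, uln]`; the limits themselves count as normal).
#'
#' @param series lab-series table (`subject_id`, `analyte_id`, `obs_time`,
#'   `value`, `lln`, `uln`)
#' @param window_days positive window length in days
#' @param config a [feature_config()]
#' @param subject_ids subjects to emit rows for (default: those in `series`)
#' @return wide data.frame: `subject_id` plus one column per
#'   (analyte, summary), named `<analyte>_w<window>_<stat>`
#' @export
summarize_lab_series <- function(series, window_days, config = feature_config(),
                                 subject_ids = NULL) {
  stopifnot(window_days > 0)
  if (nrow(series) > 0) {
    if (any(series$uln <= series$lln))
      stop("lab series data error: uln <= lln")
    if (any(!is.finite(series$value)))
      stop("lab series data error: non-finite values")
  }
  if (is.null(subject_ids)) subject_ids <- unique(series$subject_id)
  analytes <- sort(unique(series$analyte_id))
  # record length per subject from the full (unwindowed) record
  rec_len <- tapply(-series$obs_time, series$subject_id, max)
  inw <- series$obs_time >= -window_days & series$obs_time < 0
  sw <- series[inw, , drop = FALSE]
  cols <- as.vector(t(outer(analytes, lab_summary_stats, function(a, s)
    sprintf("%s_w%03d_%s", a, window_days, s))))
  out <- matrix(NA_real_, length(subject_ids), length(cols),
                dimnames = list(subject_ids, cols))
  # defaults for subjects/analytes with no in-window observations
  for (a in analytes) {
    out[, sprintf("%s_w%03d_n_tests", a, window_days)] <- 0
    out[, sprintf("%s_w%03d_test_ratio", a, window_days)] <- 0
  }
  if (nrow(sw) > 0) {
    key <- paste(sw$subject_id, sw$analyte_id, sep = "\r")
    groups <- split(seq_len(nrow(sw)), key)
    for (g in groups) {
      sid <- sw$subject_id[g[1]]
      a <- sw$analyte_id[g[1]]
      rl <- rec_len[[sid]]
      s <- lab_series_summaries(sw$value[g], sw$obs_time[g],
                                sw$lln[g[1]], sw$uln[g[1]],
                                if (is.null(rl) || is.na(rl)) 0 else rl,
                                window_days, config)
      out[sid, sprintf("%s_w%03d_%s", a, window_days, names(s))] <- s
    }
  }
  data.frame(subject_id = subject_ids, out, row.names = NULL,
             check.names = FALSE, stringsAsFactors = FALSE)
}

#' Encode panel genomics into model features
#'
#' Emits one binary column per (gene, variant class) with unmeasured calls
#' kept missing (imputed downstream), one impacted/not flag per pathway
#' (impacted iff any member gene has a reported alteration of any class),
#' and the componentwise mean of the embedding vectors of all affected genes
#' (the zero vector when none are affected).
#'
#' @param profiles long gene-variant table (`subject_id`, `gene_id`,
#'   `variant_class`, `status` with NA = unmeasured)
#' @param pathways named list of gene-id sets
#' @param embeddings numeric matrix, one row per gene
#' @param subject_ids subjects to emit rows for
#' @return wide data.frame keyed by `subject_id`
#' @export
encode_genomics <- function(profiles, pathways, embeddings,
                            subject_ids = NULL) {
  if (is.null(subject_ids)) subject_ids <- unique(profiles$subject_id)
  cls_abbr <- c(short_variant = "sv", copy_number = "cn", rearrangement = "re")
  feat <- paste0(profiles$gene_id, "_", cls_abbr[profiles$variant_class])
  ufeat <- sort(unique(feat))
  n <- length(subject_ids)
  gm <- matrix(NA_real_, n, length(ufeat),
               dimnames = list(subject_ids, ufeat))
  dup <- duplicated(paste(profiles$subject_id, feat))
  if (any(dup)) stop("duplicate (subject, gene, variant class) records")
  gm[cbind(match(profiles$subject_id, subject_ids), match(feat, ufeat))] <-
    profiles$status
  # affected = any reported alteration of any class, per (subject, gene)
  rep1 <- profiles[!is.na(profiles$status) & profiles$status == 1, , drop = FALSE]
  aff <- split(rep1$gene_id, rep1$subject_id)
  pw <- matrix(0, n, length(pathways),
               dimnames = list(subject_ids, paste0("pw_", names(pathways))))
  d <- ncol(embeddings)
  em <- matrix(0, n, d, dimnames = list(subject_ids, paste0("nemb_", colnames(embeddings))))
  for (i in seq_len(n)) {
    genes <- unique(aff[[subject_ids[i]]])
    if (is.null(genes) || length(genes) == 0) next
    for (p in seq_along(pathways)) {
      if (any(genes %in% pathways[[p]])) pw[i, p] <- 1
    }
    miss <- setdiff(genes, rownames(embeddings))
    if (length(miss) > 0)
      stop(sprintf("affected gene(s) absent from embedding table: %s",
                   paste(miss, collapse = ", ")))
    em[i, ] <- colMeans(embeddings[genes, , drop = FALSE])
  }
  data.frame(subject_id = subject_ids, gm, pw, em, row.names = NULL,
             check.names = FALSE, stringsAsFactors = FALSE)
}

#' Assemble the raw model feature matrix from cohort tables
#'
#' Combines demographics, treatment-timing variables, shared clinical risk
#' factors, cancer-specific features, windowed lab summaries and genomic
#' encodings into a single feature container with per-feature modality
#' metadata. No screening, imputation or normalization happens here.
#'
#' @param cohort a `pancox_cohort` from [simulate_cohort()] (or any list with
#'   the same tables)
#' @param config a [feature_config()]
#' @return object of class `pancox_features`: list with `values`
#'   (data.frame, numeric and factor columns), `subject_id`, `meta`
#' @export
build_feature_matrix <- function(cohort, config = feature_config()) {
  subj <- cohort$subjects
  ids <- subj$subject_id
  vals <- data.frame(row.names = seq_along(ids))
  meta <- NULL
  add <- function(df, modality, window = NA, scope = NA, type = NULL) {
    for (nm in setdiff(names(df), "subject_id")) {
      col <- df[[nm]][match(ids, df$subject_id)]
      vals[[nm]] <<- col
      ty <- if (!is.null(type)) type
            else if (is.factor(col) || is.character(col)) "categorical"
            else if (all(col %in% c(0, 1, NA))) "binary" else "continuous"
      meta <<- rbind(meta, data.frame(name = nm, modality = modality,
                                      window = window, cancer_scope = scope,
                                      type = ty, stringsAsFactors = FALSE))
    }
  }
  demo <- subj[, c("subject_id", "age", "sex", "race", "smoking_status",
                   "stage", "ecog")]
  demo$sex <- factor(demo$sex)
  demo$race <- factor(demo$race)
  demo$smoking_status <- factor(demo$smoking_status)
  add(demo, "demographic")
  add(data.frame(subject_id = subj$subject_id,
                 cancer_type = factor(subj$cancer_type)),
      "demographic", type = "categorical")
  add(subj[, c("subject_id", "time_dx_to_1l", "index_year")], "treatment")
  add(data.frame(subject_id = subj$subject_id, entry_time = subj$entry_time),
      "treatment", type = "continuous")
  if (!is.null(cohort$clinical) && ncol(cohort$clinical) > 1)
    add(cohort$clinical, "demographic", type = "continuous")
  if (!is.null(cohort$cancer_specific) && ncol(cohort$cancer_specific) > 1) {
    cs <- cohort$cancer_specific
    for (nm in setdiff(names(cs), "subject_id")) {
      scope <- sub("^cs_(c[0-9]+)_.*$", "\\1", nm)
      add(cs[, c("subject_id", nm)], "cancer_specific", scope = scope,
          type = "continuous")
    }
  }
  for (w in config$windows) {
    labw <- summarize_lab_series(cohort$labs, w, config, subject_ids = ids)
    add(labw, "lab_vitals", window = w, type = "continuous")
  }
  if (!is.null(cohort$genomics) && nrow(cohort$genomics) > 0) {
    gen <- encode_genomics(cohort$genomics, cohort$pathways,
                           cohort$embeddings, subject_ids = ids)
    gtypes <- ifelse(grepl("^nemb_", setdiff(names(gen), "subject_id")),
                     "continuous", "binary")
    for (j in seq_along(gtypes)) {
      nm <- setdiff(names(gen), "subject_id")[j]
      add(gen[, c("subject_id", nm)], "genomic", type = gtypes[j])
    }
  }
  structure(list(values = vals, subject_id = ids, meta = meta,
                 screen = NULL, finalize = NULL),
            class = "pancox_features")
}
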