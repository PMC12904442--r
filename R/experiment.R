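#' Train/test split stratified by cancer type
#'
#' @param subjects subject table with `subject_id` and `cancer_type`
#' @param test_fraction held-out fraction (default 0.2)
#' @param seed integer seed
#' @return list with `train_ids` and `test_ids` (disjoint, exhaustive;
#'   per-cancer test counts within +/-1 of `round(test_fraction * n_c)`)
#' @export
stratified_split <- function(subjects, test_fraction = 0.2, seed = 1L) {
  counts <- table(subjects$cancer_type)
  if (any(counts < 2))
    stop(sprintf("cancer type(s) with fewer than 2 subjects: %s",
                 paste(names(counts)[counts < 2], collapse = ", ")))
  set.seed(seed)
  test_ids <- character(0)
  for (ct in names(counts)) {
    ids <- subjects$subject_id[subjects$cancer_type == ct]
    n_test <- max(1, round(test_fraction * length(ids)))
    test_ids <- c(test_ids, sample(ids, n_test))
  }
  list(train_ids = setdiff(subjects$subject_id, test_ids),
       test_ids = test_ids)
}

#' Evaluation configuration for the comparison harness
#'
#' @param bootstrap_B bootstrap replicates for c-index/IBS intervals
#'   (0 disables intervals; the paper-scale value is 1000)
#' @param bootstrap_mode `"fast"` re-evaluates predictions on resampled test
#'   rows only; `"refit"` also resamples training rows and refits the model
#'   at the selected lambda before re-evaluating
#' @param alpha interval level
#' @param ibs_grid_size number of time-grid points for the Brier curve
#' @return list of class `eval_config`
#' @export
eval_config <- function(bootstrap_B = 0, bootstrap_mode = c("fast", "refit"),
                        alpha = 0.05, ibs_grid_size = 51) {
  structure(list(bootstrap_B = bootstrap_B,
                 bootstrap_mode = match.arg(bootstrap_mode),
                 alpha = alpha, ibs_grid_size = ibs_grid_size),
            class = "eval_config")
}

#' Comparator model specification
#'
#' `benchmark` is a small clinical model (cancer type, age, sex, race,
#' smoking status, stage, ECOG, time from diagnosis to first-line therapy,
#' and the entry time from first-line start to genomic test); `ropro_like`
#' adds up to 20 laboratory window summaries; `full` uses every surviving
#' feature.
#'
#' @param name one of `"benchmark"`, `"ropro_like"`, `"full"`, or a custom
#'   label when `features` is given
#' @param features optional explicit parent-feature name list
#' @param strata logical: fit with cancer-type strata instead of adjustment
#' @return list of class `model_spec`
#' @export
model_spec <- function(name = c("benchmark", "ropro_like", "full"),
                       features = NULL, strata = FALSE) {
  if (is.null(features)) name <- match.arg(name)
  structure(list(name = name, features = features, strata = strata),
            class = "model_spec")
}

benchmark_features <- c("cancer_type", "age", "sex", "race",
                        "smoking_status", "stage", "ecog",
                        "time_dx_to_1l", "entry_time")

# parent-level feature list for a spec, given finalized metadata
spec_parents <- function(spec, meta_final) {
  parents <- unique(meta_final$parent)
  if (!is.null(spec$features)) return(intersect(spec$features, parents))
  if (spec$name == "full") return(parents)
  bench <- intersect(benchmark_features, parents)
  if (spec$name == "benchmark") return(bench)
  labs <- sort(parents[meta_final$modality[match(parents, meta_final$parent)] ==
                       "lab_vitals"])
  labs <- grep("_(mean|min|max|prop_abnormal)$", labs, value = TRUE)
  union(bench, head(labs, 20))
}

# screen -> impute -> finalize for one training scope
prepare_scope <- function(fmraw, ids, train_ids, subject_cancers, fconfig,
                          knn_k, seed) {
  fm <- subset_features(fmraw, ids)
  fm <- screen_features(fm, fconfig, train_ids, subject_cancers)
  fm <- impute_features(fm, train_ids, subject_cancers, k = knn_k, seed = seed)
  finalize_matrix(fm, train_ids, subject_cancers, fconfig)
}

# row subset of a raw pancox_features container
subset_features <- function(fm, ids) {
  i <- match(ids, fm$subject_id)
  fm$values <- fm$values[i, , drop = FALSE]
  fm$subject_id <- fm$subject_id[i]
  fm
}

# fit + evaluate one (scope, spec) on one or more test cohorts
fit_and_evaluate <- function(fm, y_all, train_ids, test_sets, spec,
                             cancer_of, ecfg, cv_seed, nlambda = 100,
                             unpenalized_parents =
                               c("entry_time", "cancer_type")) {
  parents <- spec_parents(spec, fm$meta_final)
  cols <- fm$meta_final$name[fm$meta_final$parent %in% parents]
  x <- fm$x[, cols, drop = FALSE]
  tr <- fm$subject_id %in% train_ids
  ytr <- surv_response(y_all$entry[tr], y_all$exit[tr], y_all$status[tr])
  pf <- ifelse(fm$meta_final$parent[match(cols, fm$meta_final$name)] %in%
               unpenalized_parents, 0, 1)
  strata_tr <- if (spec$strata) cancer_of[fm$subject_id[tr]]
  fit <- cross_validate_lambda(x[tr, , drop = FALSE], ytr,
                               penalty_factors = pf, strata = strata_tr,
                               fold_strata = cancer_of[fm$subject_id[tr]],
                               seed = cv_seed, nlambda = nlambda)
  fit <- breslow_baseline(fit, x[tr, , drop = FALSE], ytr, strata = strata_tr)
  train_scores <- predict_risk(fit, x[tr, , drop = FALSE])
  names(train_scores) <- fm$subject_id[tr]
  rows <- list()
  for (ts in test_sets) {
    te <- fm$subject_id %in% ts$ids
    yte <- surv_response(y_all$entry[te], y_all$exit[te], y_all$status[te])
    scores <- predict_risk(fit, x[te, , drop = FALSE])
    rows[[ts$cancer]] <- tryCatch(
      evaluate_scope(fit, x, tr, te, ytr, yte, train_scores, scores,
                     cancer_of, fm$subject_id, ts$cancer, ecfg,
                     strata_tr = strata_tr, spec = spec, pf = pf),
      error = function(e) {
        warning(sprintf("evaluation failed for %s/%s: %s", ts$cancer,
                        spec$name, conditionMessage(e)))
        unfit_row(ts$cancer, spec$name, sum(tr), sum(yte$status))
      })
  }
  list(rows = rows, fit = fit)
}

# placeholder row for a cohort that could not be fitted or evaluated
unfit_row <- function(cancer, spec_name, n_train, n_events) {
  data.frame(cancer_type = cancer, model_spec = spec_name,
             c_index = NA_real_, c_lo = NA_real_, c_hi = NA_real_,
             ibs = NA_real_, ibs_lo = NA_real_, ibs_hi = NA_real_,
             hr_low_vs_high = NA_real_, hr_lo = NA_real_, hr_hi = NA_real_,
             hr_degenerate = TRUE, n_selected_features = 0L,
             n_train = n_train, n_events = n_events, unfit = TRUE,
             stringsAsFactors = FALSE)
}

evaluate_scope <- function(fit, x, tr, te, ytr, yte, train_scores, scores,
                           cancer_of, subject_id, cancer, ecfg, strata_tr,
                           spec, pf = NULL) {
  ci <- concordance_index(yte$entry, yte$exit, yte$status, scores)
  # censoring KM and the Brier grid come from the evaluated cancer's rows
  tr_c <- tr & cancer_of[subject_id] %in% cancer
  ytr_c <- surv_response(ytr$entry[cancer_of[subject_id[tr]] %in% cancer],
                         ytr$exit[cancer_of[subject_id[tr]] %in% cancer],
                         ytr$status[cancer_of[subject_id[tr]] %in% cancer])
  ev <- yte$exit[yte$status == 1]
  grid <- seq(min(ev), max(quantile(yte$exit, 0.95, names = FALSE), min(ev) + 1),
              length.out = ecfg$ibs_grid_size)
  strata_te <- if (spec$strata) cancer_of[subject_id[te]]
  S <- predict_survival(fit, x[te, , drop = FALSE], grid,
                        strata_new = strata_te)
  ibs <- integrated_brier_score(ytr_c, yte, S, grid)
  strat <- risk_stratify_and_hr(
    train_scores[cancer_of[names(train_scores)] %in% cancer],
    scores, yte,
    cohort_train = rep(cancer, sum(cancer_of[names(train_scores)] %in% cancer)),
    cohort_test = rep(cancer, length(scores)))
  c_lo <- c_hi <- ibs_lo <- ibs_hi <- NA_real_
  if (ecfg$bootstrap_B >= 100) {
    te_df <- data.frame(entry = yte$entry, exit = yte$exit,
                        status = yte$status, score = scores,
                        row = seq_along(scores))
    refit <- ecfg$bootstrap_mode == "refit"
    tr_df <- if (refit) data.frame(row = seq_len(sum(tr)))
    xtr <- x[tr, , drop = FALSE]
    xte <- x[te, , drop = FALSE]
    sel_lambda <- fit$selected_lambda %||% min(fit$lambda)
    refit_scores <- function(trd, ted) {
      # refit at the selected lambda on resampled training rows,
      # preprocessing statistics reused
      yb <- surv_response(ytr$entry[trd$row], ytr$exit[trd$row],
                          ytr$status[trd$row])
      f2 <- fit_penalized_cox(xtr[trd$row, , drop = FALSE], yb,
                              penalty_factors = pf,
                              lambda_path = sel_lambda,
                              strata = if (!is.null(strata_tr)) strata_tr[trd$row])
      list(fit = f2, y_train = yb, rows = trd$row,
           scores = predict_risk(f2, xte[ted$row, , drop = FALSE]))
    }
    cstat <- function(trd, ted) {
      sc <- if (refit) refit_scores(trd, ted)$scores else ted$score
      concordance_index(ted$entry, ted$exit, ted$status, sc)$c_index
    }
    bs_c <- tryCatch(
      bc_bootstrap_ci(cstat, tr_df, te_df, B = ecfg$bootstrap_B,
                      seed = 7L, alpha = ecfg$alpha),
      error = function(e) NULL)
    if (!is.null(bs_c)) { c_lo <- bs_c$lower; c_hi <- bs_c$upper }
    istat <- function(trd, ted) {
      yb <- surv_response(ted$entry, ted$exit, ted$status)
      if (refit) {
        r2 <- refit_scores(trd, ted)
        f2 <- breslow_baseline(r2$fit, xtr[r2$rows, , drop = FALSE], r2$y_train,
                               strata = if (!is.null(strata_tr)) strata_tr[r2$rows])
        S2 <- predict_survival(f2, xte[ted$row, , drop = FALSE], grid,
                               strata_new = if (!is.null(strata_tr))
                                 cancer_of[subject_id[te]][ted$row])
        integrated_brier_score(ytr_c, yb, S2, grid)$ibs
      } else {
        integrated_brier_score(ytr_c, yb, S[ted$row, , drop = FALSE], grid)$ibs
      }
    }
    bs_i <- tryCatch(
      bc_bootstrap_ci(istat, tr_df, te_df, B = ecfg$bootstrap_B,
                      seed = 11L, alpha = ecfg$alpha),
      error = function(e) NULL)
    if (!is.null(bs_i)) { ibs_lo <- bs_i$lower; ibs_hi <- bs_i$upper }
  }
  data.frame(
    cancer_type = cancer, model_spec = spec$name,
    c_index = ci$c_index, c_lo = c_lo, c_hi = c_hi,
    ibs = ibs$ibs, ibs_lo = ibs_lo, ibs_hi = ibs_hi,
    hr_low_vs_high = strat$hr, hr_lo = strat$ci[1], hr_hi = strat$ci[2],
    hr_degenerate = strat$degenerate,
    n_selected_features = sum(coef(fit) != 0),
    n_train = sum(tr), n_events = sum(yte$status),
    unfit = FALSE, stringsAsFactors = FALSE)
}

#' Pan-cancer versus single-cancer model comparison
#'
#' For each comparator model specification, fits one pan-cancer model on the
#' pooled training data (screening, imputation and normalization statistics
#' from the pooled training rows; cancer-type and entry-time covariates
#' unpenalized) and one single-cancer model per cohort (its own screening
#' and normalization statistics; no cancer-type covariate), then evaluates
#' both on every cancer's held-out test subjects. Risk stratification uses
#' per-cohort training medians in both scopes.
#'
#' @param cohort a `pancox_cohort`
#' @param model_specs character names or a list of [model_spec()] objects
#' @param ecfg an [eval_config()]
#' @param fconfig a [feature_config()]
#' @param test_fraction held-out fraction
#' @param knn_k genomic kNN neighbour count
#' @param seed integer seed driving the split, imputation and CV folds
#' @param single_cancers cancers to fit single-cancer models for (default:
#'   all; restricting saves time when only some contrasts are of interest)
#' @param nlambda lambda-path length passed to the solver
#' @return data.frame of class `pancox_comparison`, one row per
#'   (cancer, model spec, training scope)
#' @export
run_pan_vs_single <- function(cohort,
                              model_specs = c("benchmark", "ropro_like", "full"),
                              ecfg = eval_config(), fconfig = feature_config(),
                              test_fraction = 0.2, knn_k = 5, seed = 1L,
                              single_cancers = NULL, nlambda = 100) {
  if (is.character(model_specs))
    model_specs <- lapply(model_specs, model_spec)
  subj <- cohort$subjects
  cancer_of <- setNames(as.character(subj$cancer_type), subj$subject_id)
  cancers <- sort(unique(as.character(subj$cancer_type)))
  sp <- stratified_split(subj, test_fraction, seed)
  fmraw <- build_feature_matrix(cohort, fconfig)
  y_all <- surv_response(subj$entry_time, subj$exit_time, subj$event_status)
  rownames(y_all) <- subj$subject_id

  y_for <- function(ids) {
    i <- match(ids, subj$subject_id)
    structure(data.frame(entry = y_all$entry[i], exit = y_all$exit[i],
                         status = y_all$status[i]),
              class = c("surv_response", "data.frame"))
  }

  out <- list()
  # pan scope: one preprocessing + one model per spec, evaluated per cancer
  pan_fm <- prepare_scope(fmraw, subj$subject_id, sp$train_ids, cancer_of,
                          fconfig, knn_k, seed)
  test_sets <- lapply(cancers, function(ct)
    list(cancer = ct,
         ids = intersect(sp$test_ids, subj$subject_id[cancer_of == ct])))
  for (si in seq_along(model_specs)) {
    spec <- model_specs[[si]]
    res <- fit_and_evaluate(pan_fm, y_for(pan_fm$subject_id), sp$train_ids,
                            test_sets, spec, cancer_of, ecfg,
                            cv_seed = seed + 100L * si, nlambda = nlambda)
    for (ct in names(res$rows)) {
      r <- res$rows[[ct]]
      r$training_scope <- "pan"
      r$seed <- seed
      out[[length(out) + 1]] <- r
    }
  }
  # single scopes: per-cancer preprocessing and models
  for (ct in intersect(cancers, single_cancers %||% cancers)) {
    ids_c <- subj$subject_id[cancer_of == ct]
    train_c <- intersect(sp$train_ids, ids_c)
    test_c <- intersect(sp$test_ids, ids_c)
    y_tr_c <- y_for(train_c)
    for (si in seq_along(model_specs)) {
      spec <- model_specs[[si]]
      if (sum(y_tr_c$status) == 0) {
        r <- unfit_row(ct, spec$name, length(train_c), 0L)
        r$training_scope <- "single"
        r$seed <- seed
        out[[length(out) + 1]] <- r
        next
      }
      fm_c <- prepare_scope(fmraw, ids_c, train_c, cancer_of, fconfig,
                            knn_k, seed)
      res <- tryCatch(
        fit_and_evaluate(fm_c, y_for(fm_c$subject_id), train_c,
                         list(list(cancer = ct, ids = test_c)), spec,
                         cancer_of, ecfg, cv_seed = seed + 100L * si,
                         nlambda = nlambda),
        error = function(e) e)
      if (inherits(res, "error")) {
        warning(sprintf("single-cancer fit failed for %s/%s: %s",
                        ct, spec$name, conditionMessage(res)))
        r <- unfit_row(ct, spec$name, length(train_c), sum(y_tr_c$status))
        r$training_scope <- "single"
        r$seed <- seed
        out[[length(out) + 1]] <- r
        next
      }
      r <- res$rows[[ct]]
      r$training_scope <- "single"
      r$seed <- seed
      out[[length(out) + 1]] <- r
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("pancox_comparison", "data.frame")
  res
}
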