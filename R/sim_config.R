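#' Default laboratory catalogue for the cohort simulator
#'
#' Six analytes loosely modelled on common oncology panels (haemoglobin,
#' albumin, alkaline phosphatase, AST, leukocytes, platelets). `lln`/`uln`
#' are the lower/upper limits of normal on the analyte's native scale,
#' `rate` the expected number of observations per 720-day lookback window,
#' `shift` the per-unit-of-risk drift of the analyte mean expressed in
#' half-widths of the normal range (negative = falls with risk), and
#' `noise_sd` the residual SD, also in half-widths.
#'
#' @return data.frame with columns analyte_id, lln, uln, rate, shift, noise_sd
#' @export
default_lab_catalog <- function() {
  data.frame(
    analyte_id = c("hgb", "alb", "alp", "ast", "wbc", "plt"),
    lln = c(12, 3.5, 44, 10, 4.0, 150),
    uln = c(16, 5.0, 147, 40, 11.0, 400),
    rate = c(10, 8, 8, 8, 10, 10),
    shift = c(-0.5, -0.6, 0.7, 0.6, 0.4, -0.4),
    noise_sd = c(0.5, 0.5, 0.6, 0.6, 0.6, 0.5),
    stringsAsFactors = FALSE
  )
}

#' Default gene-variant catalogue
#'
#' Per gene-variant prevalence is interpolated between `prev_lo` and
#' `prev_hi` across cancer types so prevalence is cancer-dependent, echoing
#' real panel data where e.g. TP53 short variants dominate some cohorts.
#'
#' @return data.frame with columns gene_id, variant_class, prev_lo, prev_hi
#' @export
default_gene_catalog <- function() {
  genes <- sprintf("g%02d", 1:10)
  data.frame(
    gene_id = c(genes, genes[1:4], genes[1:2]),
    variant_class = c(rep("short_variant", 10), rep("copy_number", 4),
                      rep("rearrangement", 2)),
    prev_lo = c(seq(0.60, 0.03, length.out = 10), rep(0.05, 4), rep(0.02, 2)),
    prev_hi = c(seq(0.70, 0.10, length.out = 10), rep(0.20, 4), rep(0.08, 2)),
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration for synthetic clinico-genomic cohorts
#'
#' Describes K cancer cohorts with Weibull proportional-hazards survival,
#' delayed database entry (time from first-line therapy start to genomic
#' test) inducing left truncation, independent right censoring plus an
#' administrative horizon, prognostic laboratory trajectories, binary
#' gene-variant calls with per-cancer prevalence, and cancer-specific
#' features with structured missingness.
#'
#' The linear predictor of subject i in cancer c is
#' `x_shared . shared_beta + x_specific(c) . specific_beta[[c]] + g . genomic_beta`
#' where the first three shared covariates are standardized age, ECOG
#' performance status and sex, the remainder standard-normal clinical risk
#' factors, `x_specific` standard-normal cancer-specific factors observed
#' only within cohort c, and `g` the gene-variant indicators.
#'
#' @param n_cancers number of cancer cohorts K
#' @param cohort_sizes post-truncation target size per cohort (all >= 2)
#' @param n_shared_features number of shared covariates (>= 3; the first
#'   three are age, ECOG and sex)
#' @param n_specific_features per-cancer count of cancer-specific covariates
#' @param shared_beta log-hazard ratios for the shared covariates
#' @param specific_beta list of per-cancer log-hazard-ratio vectors
#' @param genomic_beta optional named log-HR vector over gene-variant
#'   features (default all zero)
#' @param gene_catalog data.frame as [default_gene_catalog()]
#' @param lab_catalog data.frame as [default_lab_catalog()]
#' @param weibull_shape,weibull_scale per-cancer baseline Weibull parameters
#'   (days; both strictly positive, recycled to length K)
#' @param entry_mean_days mean of the exponential entry-time distribution
#' @param censor_rate daily hazard of independent censoring (>= 0)
#' @param admin_horizon_days administrative cutoff in days
#' @param embedding_dim dimension d of the gene-embedding table
#' @param unmeasured_rate fraction of (subject, gene-variant) calls left
#'   unmeasured (panel did not assess them)
#' @param clinical_missing_rate MCAR missingness applied to a few clinical
#'   features (ECOG, stage, smoking status, comorbidity index)
#' @param lab_window_days lookback window over which lab observations are
#'   generated
#' @param seed integer seed; identical configs give identical cohorts
#' @return object of class `sim_config`
#' @export
sim_config <- function(n_cancers = 6,
                       cohort_sizes = c(150, 300, 500, 800, 1200, 2000),
                       n_shared_features = 10,
                       n_specific_features = rep(2L, n_cancers),
                       shared_beta = c(0.35, 0.30, 0.10, 0.5, -0.4, 0.3,
                                       -0.25, 0.2, 0, 0)[seq_len(n_shared_features)],
                       specific_beta = rep(list(c(0.3, -0.3)), n_cancers),
                       genomic_beta = NULL,
                       gene_catalog = default_gene_catalog(),
                       lab_catalog = default_lab_catalog(),
                       weibull_shape = 1.1,
                       weibull_scale = c(300, 420, 540, 660, 780, 900),
                       entry_mean_days = 60,
                       censor_rate = 1 / 2000,
                       admin_horizon_days = 3650,
                       embedding_dim = 16,
                       unmeasured_rate = 0.05,
                       clinical_missing_rate = 0.05,
                       lab_window_days = 720,
                       seed = 1L) {
  cfg <- list(
    n_cancers = as.integer(n_cancers),
    cohort_sizes = as.integer(rep_len(cohort_sizes, n_cancers)),
    n_shared_features = as.integer(n_shared_features),
    n_specific_features = as.integer(rep_len(n_specific_features, n_cancers)),
    shared_beta = as.numeric(shared_beta),
    specific_beta = lapply(seq_len(n_cancers), function(c)
      as.numeric(rep_len(specific_beta, n_cancers)[[c]])),
    genomic_beta = genomic_beta,
    gene_catalog = gene_catalog,
    lab_catalog = lab_catalog,
    weibull_shape = rep_len(as.numeric(weibull_shape), n_cancers),
    weibull_scale = rep_len(as.numeric(weibull_scale), n_cancers),
    entry_mean_days = as.numeric(entry_mean_days),
    censor_rate = as.numeric(censor_rate),
    admin_horizon_days = as.numeric(admin_horizon_days),
    embedding_dim = as.integer(embedding_dim),
    unmeasured_rate = as.numeric(unmeasured_rate),
    clinical_missing_rate = as.numeric(clinical_missing_rate),
    lab_window_days = as.numeric(lab_window_days),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  bad <- function(field, msg) {
    stop(sprintf("invalid simulation config field '%s': %s", field, msg),
         call. = FALSE)
  }
  if (cfg$n_cancers < 1) bad("n_cancers", "must be >= 1")
  if (length(cfg$cohort_sizes) != cfg$n_cancers || any(cfg$cohort_sizes < 2))
    bad("cohort_sizes", "must give one count >= 2 per cancer")
  if (cfg$n_shared_features < 3)
    bad("n_shared_features", "must be >= 3 (age, ECOG, sex come first)")
  if (length(cfg$shared_beta) != cfg$n_shared_features)
    bad("shared_beta", "length must equal n_shared_features")
  for (c in seq_len(cfg$n_cancers)) {
    if (length(cfg$specific_beta[[c]]) != cfg$n_specific_features[c])
      bad("specific_beta", sprintf("cancer %d: length must equal n_specific_features", c))
  }
  gc <- cfg$gene_catalog
  if (!all(c("gene_id", "variant_class", "prev_lo", "prev_hi") %in% names(gc)))
    bad("gene_catalog", "needs gene_id, variant_class, prev_lo, prev_hi")
  if (any(gc$prev_lo < 0 | gc$prev_lo > 1 | gc$prev_hi < 0 | gc$prev_hi > 1))
    bad("gene_catalog", "prevalences must lie in [0, 1]")
  lc <- cfg$lab_catalog
  if (nrow(lc) > 0 && any(lc$uln <= lc$lln))
    bad("lab_catalog", "uln must exceed lln")
  if (any(cfg$weibull_shape <= 0)) bad("weibull_shape", "must be > 0")
  if (any(cfg$weibull_scale <= 0)) bad("weibull_scale", "must be > 0")
  if (cfg$entry_mean_days < 0) bad("entry_mean_days", "must be >= 0")
  if (cfg$censor_rate < 0) bad("censor_rate", "must be >= 0")
  if (cfg$admin_horizon_days <= 0) bad("admin_horizon_days", "must be > 0")
  if (cfg$embedding_dim < 1) bad("embedding_dim", "must be >= 1")
  invisible(cfg)
}
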