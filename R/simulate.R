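#' Simulate a linked clinico-genomic cohort
#'
#' Draws K cancer cohorts under a Weibull proportional-hazards model with
#' delayed database entry (left truncation), independent right censoring and
#' an administrative horizon. Emits five linked tables (subjects, lab series,
#' gene-variant profiles, gene embeddings, pathway map) plus the generating
#' truth (covariates, coefficients, the hidden linear predictor) for oracle
#' tests. Cohort sizes are post-truncation targets, achieved by oversampling;
#' truncated draws are removed, never redrawn with new outcomes.
#'
#' @param config a [sim_config()] object
#' @return a list of class `pancox_cohort` with elements `subjects`,
#'   `labs`, `genomics`, `embeddings`, `pathways`, `clinical`,
#'   `cancer_specific`, `truth` and `config`
#' @export
simulate_cohort <- function(config) {
  validate_sim_config(config)
  cfg <- config
  set.seed(cfg$seed)
  K <- cfg$n_cancers
  cancers <- sprintf("c%02d", seq_len(K))
  gv <- cfg$gene_catalog
  gv_names <- paste0(gv$gene_id, "_", c(short_variant = "sv", copy_number = "cn",
                                        rearrangement = "re")[gv$variant_class])
  genes <- unique(gv$gene_id)
  gbeta <- rep(0, nrow(gv))
  if (!is.null(cfg$genomic_beta)) {
    if (is.null(names(cfg$genomic_beta)) ||
        !all(names(cfg$genomic_beta) %in% gv_names))
      stop("genomic_beta must be named by gene-variant feature (e.g. 'g01_sv')")
    gbeta[match(names(cfg$genomic_beta), gv_names)] <- cfg$genomic_beta
  }

  # gene embeddings: fixed random unit vectors
  emb <- matrix(rnorm(length(genes) * cfg$embedding_dim), length(genes))
  emb <- emb / sqrt(rowSums(emb^2))
  rownames(emb) <- genes
  colnames(emb) <- sprintf("emb_%02d", seq_len(cfg$embedding_dim))

  # pathway map: contiguous, partially overlapping gene sets
  ng <- length(genes)
  cuts <- unique(pmin(ng, c(ceiling(ng / 3), ceiling(2 * ng / 3), ng)))
  pathways <- list()
  lo <- 1
  for (i in seq_along(cuts)) {
    pathways[[sprintf("pw%02d", i)]] <- genes[lo:cuts[i]]
    lo <- max(1, cuts[i]) # one-gene overlap between consecutive sets
  }

  n_raw_total <- 0L
  n_removed_total <- 0L
  subj_list <- list()
  truth_shared <- list()
  truth_spec <- list()
  gmat_list <- list()

  for (c in seq_len(K)) {
    need <- cfg$cohort_sizes[c]
    kept <- NULL
    keptX <- NULL
    keptV <- NULL
    keptG <- NULL
    retention <- 0.7
    while (is.null(kept) || nrow(kept) < need) {
      short <- need - if (is.null(kept)) 0L else nrow(kept)
      m <- max(20L, ceiling(1.3 * short / max(0.05, retention)))
      d <- draw_raw_subjects(cfg, c, m, gv, gbeta)
      ok <- d$subjects$exit_time > d$subjects$entry_time
      n_raw_total <- n_raw_total + m
      n_removed_total <- n_removed_total + sum(!ok)
      retention <- max(0.05, mean(ok))
      kept <- rbind(kept, d$subjects[ok, , drop = FALSE])
      keptX <- rbind(keptX, d$X[ok, , drop = FALSE])
      keptV <- rbind(keptV, d$V[ok, , drop = FALSE])
      keptG <- rbind(keptG, d$G[ok, , drop = FALSE])
    }
    idx <- seq_len(need)
    kept <- kept[idx, , drop = FALSE]
    kept$subject_id <- sprintf("%s_s%05d", cancers[c], idx)
    subj_list[[c]] <- kept
    truth_shared[[c]] <- keptX[idx, , drop = FALSE]
    truth_spec[[c]] <- keptV[idx, , drop = FALSE]
    gmat_list[[c]] <- keptG[idx, , drop = FALSE]
  }

  subjects <- do.call(rbind, subj_list)
  rownames(subjects) <- NULL
  X_shared <- do.call(rbind, truth_shared)
  G_all <- do.call(rbind, gmat_list)
  rownames(X_shared) <- rownames(G_all) <- subjects$subject_id
  colnames(G_all) <- gv_names

  # genomic long table with unmeasured entries flagged NA
  n <- nrow(subjects)
  unmeas <- matrix(runif(n * nrow(gv)) < cfg$unmeasured_rate, n)
  gstat <- G_all
  gstat[unmeas] <- NA_integer_
  genomics <- data.frame(
    subject_id = rep(subjects$subject_id, times = nrow(gv)),
    gene_id = rep(gv$gene_id, each = n),
    variant_class = rep(gv$variant_class, each = n),
    status = as.integer(gstat),
    stringsAsFactors = FALSE
  )

  # shared clinical factors beyond (age, ecog, sex) are observable features
  p_sh <- cfg$n_shared_features
  clinical <- data.frame(subject_id = subjects$subject_id,
                         stringsAsFactors = FALSE)
  if (p_sh > 3) {
    extra <- X_shared[, 4:p_sh, drop = FALSE]
    colnames(extra) <- sprintf("cf%02d", 4:p_sh)
    clinical <- cbind(clinical, as.data.frame(extra))
  }

  # cancer-specific observable features: structured missingness by design
  cs <- data.frame(subject_id = subjects$subject_id, stringsAsFactors = FALSE)
  for (c in seq_len(K)) {
    pc <- cfg$n_specific_features[c]
    if (pc == 0) next
    block <- matrix(NA_real_, n, pc)
    rows <- subjects$cancer_type == cancers[c]
    block[rows, ] <- truth_spec[[c]]
    colnames(block) <- sprintf("cs_%s_f%02d", cancers[c], seq_len(pc))
    cs <- cbind(cs, as.data.frame(block))
  }

  # MCAR missingness on a few observed clinical fields (truth is retained)
  if (cfg$clinical_missing_rate > 0) {
    for (col in c("ecog", "stage", "smoking_status")) {
      subjects[[col]][runif(n) < cfg$clinical_missing_rate] <- NA
    }
    if (ncol(clinical) > 1) {
      j <- 2L # first emitted clinical factor
      clinical[[j]][runif(n) < cfg$clinical_missing_rate] <- NA
    }
  }

  labs <- draw_lab_series(cfg, subjects)

  out <- list(
    subjects = subjects,
    labs = labs,
    genomics = genomics,
    embeddings = emb,
    pathways = pathways,
    clinical = clinical,
    cancer_specific = cs,
    truth = list(
      X_shared = X_shared,
      X_specific = setNames(truth_spec, cancers),
      G = G_all,
      shared_beta = cfg$shared_beta,
      specific_beta = cfg$specific_beta,
      genomic_beta = setNames(gbeta, gv_names),
      truncation_fraction = n_removed_total / n_raw_total
    ),
    config = cfg
  )
  class(out) <- "pancox_cohort"
  out
}

# one batch of raw (pre-truncation) subjects for cancer c
draw_raw_subjects <- function(cfg, c, m, gv, gbeta) {
  K <- cfg$n_cancers
  age <- pmin(85, pmax(18, round(rnorm(m, 64, 11))))
  ecog <- sample(0:4, m, replace = TRUE, prob = c(0.35, 0.40, 0.15, 0.07, 0.03))
  sex <- sample(c("F", "M"), m, replace = TRUE)
  p_sh <- cfg$n_shared_features
  X <- cbind((age - 64) / 11, ecog, as.numeric(sex == "F"))
  if (p_sh > 3) X <- cbind(X, matrix(rnorm(m * (p_sh - 3)), m))
  colnames(X) <- c("age_z", "ecog", "sex_f",
                   if (p_sh > 3) sprintf("cf%02d", 4:p_sh))
  pc <- cfg$n_specific_features[c]
  V <- matrix(rnorm(m * pc), m, pc)

  # per-cancer prevalence interpolated across the cancer index
  frac <- if (K == 1) 0 else (c - 1) / (K - 1)
  prev <- gv$prev_lo + (gv$prev_hi - gv$prev_lo) * frac
  G <- matrix(rbinom(m * nrow(gv), 1, rep(prev, each = m)), m)

  lp <- drop(X %*% cfg$shared_beta) +
    (if (pc > 0) drop(V %*% cfg$specific_beta[[c]]) else 0) +
    drop(G %*% gbeta)

  shape <- cfg$weibull_shape[c]
  scale <- cfg$weibull_scale[c]
  t_death <- scale * (-log(runif(m)) / exp(lp))^(1 / shape)
  c_indep <- if (cfg$censor_rate > 0) rexp(m, cfg$censor_rate) else rep(Inf, m)
  c_all <- pmin(c_indep, cfg$admin_horizon_days)
  status <- as.integer(t_death <= c_all)
  exit <- ceiling(pmin(t_death, c_all))
  entry <- if (cfg$entry_mean_days > 0)
    floor(rexp(m, 1 / cfg$entry_mean_days)) else rep(0, m)

  subjects <- data.frame(
    subject_id = NA_character_,
    cancer_type = sprintf("c%02d", c),
    age = age,
    sex = sex,
    race = sample(c("A", "B", "C", "D"), m, replace = TRUE,
                  prob = c(0.6, 0.2, 0.12, 0.08)),
    smoking_status = sample(c("never", "former", "current"), m,
                            replace = TRUE, prob = c(0.42, 0.38, 0.20)),
    stage = sample(1:4, m, replace = TRUE, prob = c(0.08, 0.12, 0.25, 0.55)),
    ecog = ecog,
    time_dx_to_1l = round(rexp(m, 1 / 90)),
    index_year = sample(2011:2020, m, replace = TRUE),
    entry_time = entry,
    exit_time = exit,
    event_status = status,
    true_lp = lp,
    stringsAsFactors = FALSE
  )
  list(subjects = subjects, X = X, V = V, G = G)
}

# longitudinal lab values whose mean drifts with the subject's risk
draw_lab_series <- function(cfg, subjects) {
  lc <- cfg$lab_catalog
  n <- nrow(subjects)
  if (is.null(lc) || nrow(lc) == 0 || n == 0) {
    return(data.frame(subject_id = character(), analyte_id = character(),
                      obs_time = numeric(), value = numeric(),
                      lln = numeric(), uln = numeric(),
                      stringsAsFactors = FALSE))
  }
  W <- cfg$lab_window_days
  out <- vector("list", nrow(lc))
  for (a in seq_len(nrow(lc))) {
    counts <- rpois(n, lc$rate[a] * W / 720)
    tot <- sum(counts)
    if (tot == 0) next
    sid <- rep(subjects$subject_id, counts)
    lp <- rep(subjects$true_lp, counts)
    half <- (lc$uln[a] - lc$lln[a]) / 2
    mid <- (lc$uln[a] + lc$lln[a]) / 2
    value <- mid + (lc$shift[a] * lp + rnorm(tot, 0, lc$noise_sd[a])) * half
    obs_time <- floor(runif(tot, -W, 0))
    df <- data.frame(subject_id = sid, analyte_id = lc$analyte_id[a],
                     obs_time = obs_time, value = value,
                     lln = lc$lln[a], uln = lc$uln[a],
                     stringsAsFactors = FALSE)
    out[[a]] <- df[order(df$subject_id, df$obs_time), ]
  }
  labs <- do.call(rbind, out)
  rownames(labs) <- NULL
  labs
}

#' Remove subjects never observed because of delayed entry
#'
#' Subjects whose exit time is at or before their database-entry time are
#' never seen in a left-truncated registry and are dropped.
#'
#' @param subjects a subject table with `entry_time` and `exit_time`
#' @return list with `subjects` (retained rows), `truncation_fraction`
#'   and `n_removed`
#' @export
apply_left_truncation <- function(subjects) {
  stopifnot(all(c("entry_time", "exit_time") %in% names(subjects)))
  ok <- subjects$exit_time > subjects$entry_time
  res <- list(subjects = subjects[ok, , drop = FALSE],
              truncation_fraction = mean(!ok),
              n_removed = sum(!ok))
  if (nrow(res$subjects) == 0)
    warning("all subjects removed by left truncation")
  res
}

#' Concordance of the generating linear predictor
#'
#' The c-index of the hidden true linear predictor against the observed
#' (entry, exit, status) outcome: the attainable discrimination ceiling for
#' any model fitted to the simulated cohort.
#'
#' @param subjects subject table carrying `true_lp`
#' @return c-index in \[0, 1\]
#' @export
true_model_cindex <- function(subjects) {
  stopifnot("true_lp" %in% names(subjects))
  concordance_index(subjects$entry_time, subjects$exit_time,
                    subjects$event_status, subjects$true_lp)$c_index
}
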