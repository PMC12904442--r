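series_df <- function(sid, t, v, lln = 10, uln = 20, analyte = "a1") {
  n <- length(t)
  data.frame(subject_id = rep_len(sid, n), analyte_id = rep_len(analyte, n),
             obs_time = t, value = v, lln = rep_len(lln, n),
             uln = rep_len(uln, n), stringsAsFactors = FALSE)
}

test_that("single-observation and boundary cases follow the conventions", {
  s <- series_df("s1", -5, 20) # value exactly at uln
  w <- summarize_lab_series(s, 60, subject_ids = "s1")
  g <- function(stat) w[[sprintf("a1_w060_%s", stat)]]
  expect_equal(g("mean"), 1)
  expect_equal(g("median"), 1)
  expect_equal(g("max"), 1)
  expect_equal(g("min"), 1)
  expect_equal(g("n_tests"), 1)
  expect_true(is.na(g("variance")))
  expect_true(is.na(g("diff_last2")))
  expect_true(is.na(g("slope_last2")))
  expect_true(is.na(g("apen")))
  # limits themselves count as normal
  s2 <- series_df(c("s1", "s1"), c(-10, -5), c(10, 20))
  w2 <- summarize_lab_series(s2, 60, subject_ids = "s1")
  expect_equal(w2$a1_w060_prop_abnormal, 0)
  # no observations: counts zero, values missing
  w3 <- summarize_lab_series(s, 60, subject_ids = c("s1", "s2"))
  expect_equal(w3$a1_w060_n_tests[2], 0)
  expect_equal(w3$a1_w060_test_ratio[2], 0)
  expect_true(is.na(w3$a1_w060_mean[2]))
  # same-day index labs are excluded (half-open window)
  w4 <- summarize_lab_series(series_df("s1", 0, 15), 60, subject_ids = "s1")
  expect_equal(w4$a1_w060_n_tests, 0)
})

test_that("lab series data errors are raised", {
  bad <- series_df("s1", -5, 15, lln = 20, uln = 10)
  expect_error(summarize_lab_series(bad, 60), "uln")
  expect_error(summarize_lab_series(series_df("s1", -5, Inf), 60), "finite")
  expect_error(summarize_lab_series(series_df("s1", -5, 15), -1))
})

test_that("all 11 window summaries match naive recomputation on random series", {
  set.seed(31)
  cfg <- feature_config()
  for (r in 1:100) {
    n <- sample(1:25, 1)
    t <- floor(runif(n, -900, 0))
    v <- rnorm(n, 15, 4)
    s <- series_df(rep("s1", n), t, v)
    for (w in c(60, 720)) {
      got <- summarize_lab_series(s, w, cfg, subject_ids = "s1")
      got <- unlist(got[sprintf("a1_w%03d_%s", w, pancox:::lab_summary_stats)])
      rl <- if (n > 0) max(-t) else 0
      want <- naive_lab_summaries(v, t, 10, 20, rl, w)
      expect_equal(unname(got), unname(want), tolerance = 1e-12)
    }
  }
})

test_that("approximate entropy matches brute force and orders signal complexity", {
  expect_equal(approximate_entropy(rep(3.3, 10), 2, 0.1), 0)
  x <- c(0.1, 0.9, 0.2, 0.8, 0.15, 0.85)
  expect_equal(approximate_entropy(x, 2, 0.3), apen_brute(x, 2, 0.3),
               tolerance = 1e-12)
  expect_true(is.na(approximate_entropy(c(1, 2), 2, 0.1)))
  set.seed(8)
  ap_per <- ap_rnd <- numeric(100)
  for (i in 1:100) {
    per <- rep(c(0, 1), 15) + rnorm(30, 0, 0.01)
    rnd <- runif(30)
    ap_per[i] <- approximate_entropy(per, 2, 0.2 * sd(per))
    ap_rnd[i] <- approximate_entropy(rnd, 2, 0.2 * sd(rnd))
  }
  expect_lt(mean(ap_per), mean(ap_rnd))
})

test_that("genomic encoding emits indicators, pathway flags and embedding means", {
  emb <- matrix(c(1, 0, 0, 1, 1, 1), 3, 2, byrow = TRUE,
                dimnames = list(c("gA", "gB", "gC"), c("e1", "e2")))
  pw <- list(p1 = c("gA", "gB"), p2 = "gC")
  prof <- data.frame(
    subject_id = c("s1", "s1", "s2", "s2", "s3", "s3", "s3"),
    gene_id = c("gA", "gB", "gA", "gB", "gA", "gB", "gC"),
    variant_class = c("short_variant", "short_variant", "short_variant",
                      "copy_number", "short_variant", "short_variant",
                      "rearrangement"),
    status = c(0L, 0L, 1L, NA, 1L, 1L, 1L),
    stringsAsFactors = FALSE)
  g <- encode_genomics(prof, pw, emb, subject_ids = c("s1", "s2", "s3"))
  # no alterations: flags and embeddings all zero
  expect_equal(unname(unlist(g[1, c("pw_p1", "pw_p2", "nemb_e1", "nemb_e2")])),
               c(0, 0, 0, 0))
  # unmeasured stays missing, never silently zero
  expect_true(is.na(g$gB_cn[2]))
  # one affected gene: embedding equals that gene's vector
  expect_equal(unname(unlist(g[2, c("nemb_e1", "nemb_e2")])), c(1, 0))
  expect_equal(g$pw_p1[2], 1)
  # three affected genes: componentwise mean
  expect_equal(unname(unlist(g[3, c("nemb_e1", "nemb_e2")])),
               c((1 + 0 + 1) / 3, (0 + 1 + 1) / 3))
  expect_equal(unname(unlist(g[3, c("pw_p1", "pw_p2")])), c(1, 1))
  # affected gene missing from the embedding table
  prof2 <- prof
  prof2$gene_id[5] <- "gZ"
  expect_error(encode_genomics(prof2, pw, emb), "gZ")
})

make_fm <- function(vals, types, scopes = NULL) {
  n <- nrow(vals)
  meta <- data.frame(name = names(vals),
                     modality = "demographic", window = NA,
                     cancer_scope = scopes %||% rep(NA, ncol(vals)),
                     type = types, stringsAsFactors = FALSE)
  structure(list(values = vals, subject_id = rownames(vals) %||%
                   sprintf("s%03d", seq_len(n)),
                 meta = meta, screen = NULL, finalize = NULL),
            class = "pancox_features")
}

test_that("screening applies the count, variance and missingness rules exactly", {
  n <- 100
  ids <- sprintf("s%03d", 1:n)
  vals <- data.frame(
    d19 = c(rep(1, 19), rep(0, n - 19)),
    d20 = c(rep(1, 20), rep(0, n - 20)),
    m31 = c(rep(NA, 31), rnorm(n - 31)),
    m29 = c(rep(NA, 29), rnorm(n - 29)),
    cst = rep(4.2, n),
    ok = rnorm(n),
    row.names = ids)
  fm <- make_fm(vals, c("binary", "binary", "continuous", "continuous",
                        "continuous", "continuous"))
  out <- screen_features(fm, feature_config(), training_ids = ids)
  expect_setequal(out$screen$feature, c("d19", "m31", "cst"))
  expect_setequal(names(out$values), c("d20", "m29", "ok"))
  expect_equal(out$screen$reason[out$screen$feature == "d19"],
               "near_zero_variance")
  expect_equal(out$screen$reason[out$screen$feature == "m31"], "missingness")
  expect_equal(out$screen$reason[out$screen$feature == "cst"], "zero_variance")
})

test_that("screening statistics come from training rows only", {
  n <- 60
  ids <- sprintf("s%03d", 1:n)
  train <- ids[1:40]
  # 25 positives overall but only 15 in the training rows -> removed
  vals <- data.frame(d = c(rep(1, 15), rep(0, 25), rep(1, 10), rep(0, 10)),
                     ok = rnorm(n), row.names = ids)
  fm <- make_fm(vals, c("binary", "continuous"))
  out <- screen_features(fm, feature_config(), training_ids = train)
  expect_true("d" %in% out$screen$feature)
})

test_that("finalize z-scores, clips, one-hot encodes and zeroes out-of-scope", {
  n <- 120
  ids <- sprintf("s%03d", 1:n)
  set.seed(4)
  x <- rnorm(n)
  x[1] <- mean(x[-1]) + 50 * sd(x[-1]) # extreme outlier
  cat_col <- factor(c(rep("M", 70), rep("F", 30), rep("X", 20)))
  cs <- rnorm(n)
  vals <- data.frame(cont = x, cat = cat_col, cs_c01_f01 = cs,
                     row.names = ids)
  fm <- make_fm(vals, c("continuous", "categorical", "continuous"),
                scopes = c(NA, NA, "c01"))
  cancers <- setNames(rep(c("c01", "c02"), each = n / 2), ids)
  out <- finalize_matrix(fm, training_ids = ids, subject_cancers = cancers)
  expect_equal(max(out$x[, "cont"]), 3) # clipped at +3 z
  # majority level M is the dropped reference
  expect_false("cat_M" %in% colnames(out$x))
  expect_setequal(grep("^cat_", colnames(out$x), value = TRUE),
                  c("cat_F", "cat_X"))
  expect_true(all(out$x[, "cat_F"] %in% c(0, 1)))
  # out-of-scope cancer-specific values zeroed before normalization
  zeroed <- out$x[cancers[ids] == "c02", "cs_c01_f01"]
  expect_equal(length(unique(zeroed)), 1)
  # feature-count bookkeeping: inputs - categoricals + emitted dummies
  expect_equal(ncol(out$x), 3 - 1 + 2)
  # raw value 5 training SDs above the mean -> exactly the truncation bound
  vals2 <- data.frame(v = c(rnorm(n)), row.names = ids)
  fm2 <- make_fm(vals2, "continuous")
  st <- finalize_matrix(fm2, ids)$finalize
  vals2$v[1] <- st$center["v"] + 5 * st$scale["v"]
  # refit stats change; apply the 5-SD rule on a fixed training subset
  fm3 <- make_fm(vals2, "continuous")
  out3 <- finalize_matrix(fm3, training_ids = ids[-1])
  mu <- mean(vals2$v[-1]); s <- sd(vals2$v[-1])
  expect_equal(out3$x[1, "v"], min(3, (vals2$v[1] - mu) / s))
  expect_error(finalize_matrix(make_fm(data.frame(k = rep(1, n),
                                                  row.names = ids),
                                       "continuous"), ids),
               "zero training SD")
})

test_that("fitted preprocessing statistics are pure functions of training rows", {
  cfg <- tiny_config(seed = 21)
  ch <- simulate_cohort(cfg)
  co <- setNames(as.character(ch$subjects$cancer_type), ch$subjects$subject_id)
  sp <- stratified_split(ch$subjects, seed = 2)
  fm <- build_feature_matrix(ch, feature_config())
  prep <- function(fmx) {
    s <- screen_features(fmx, feature_config(), sp$train_ids, co)
    finalize_matrix(impute_features(s, sp$train_ids, co, seed = 9),
                    sp$train_ids, co)
  }
  a <- prep(fm)
  # corrupt every test row: fitted statistics must not move
  fm2 <- fm
  te <- !(fm2$subject_id %in% sp$train_ids)
  for (nm in names(fm2$values)) {
    if (is.numeric(fm2$values[[nm]]))
      fm2$values[[nm]][te] <- fm2$values[[nm]][te] * 5 + 100
  }
  b <- prep(fm2)
  expect_identical(a$finalize$center, b$finalize$center)
  expect_identical(a$finalize$scale, b$finalize$scale)
  expect_identical(a$screen, b$screen)
  expect_identical(a$finalize$ref_levels, b$finalize$ref_levels)
  # and training rows finalize identically (idempotent given the stats)
  tr <- fm$subject_id %in% sp$train_ids
  expect_identical(a$x[tr, ], b$x[tr, ])
})
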