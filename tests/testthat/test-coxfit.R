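# shared small fit fixture
lt_data <- function(n = 250, p = 3, beta = c(0.8, -0.5, 0.3), seed = 42,
                    entry_mean = 100) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, dimnames = list(NULL, sprintf("f%d", 1:p)))
  sim_surv(x, beta, entry_mean = entry_mean)
}

test_that("surv_response validates its contract", {
  expect_error(surv_response(c(0, 5), c(3, 4), c(1, 0)), "entry < exit")
  expect_error(surv_response(-1, 3, 1), ">= 0")
  expect_error(surv_response(0, 3, 2), "status")
  y <- surv_response(c(0, 1), c(5, 9), c(1L, 0L))
  expect_s3_class(y, "surv_response")
})

test_that("all penalized coefficients are exactly zero at lambda_max", {
  d <- lt_data()
  f <- fit_penalized_cox(d$x, d$y)
  expect_true(all(f$beta[, 1] == 0))
  expect_gt(sum(f$beta[, ncol(f$beta)] != 0), 0)
  # unpenalized covariates move even at lambda_max
  f2 <- fit_penalized_cox(d$x, d$y, penalty_factors = c(0, 1, 1))
  expect_true(f2$beta[1, 1] != 0)
  expect_true(all(f2$beta[2:3, 1] == 0))
})

test_that("row permutation leaves the coefficient path unchanged", {
  d <- lt_data(n = 150)
  f1 <- fit_penalized_cox(d$x, d$y)
  set.seed(1)
  pm <- sample(nrow(d$x))
  f2 <- fit_penalized_cox(d$x[pm, ], surv_response(d$y$entry[pm],
                                                   d$y$exit[pm],
                                                   d$y$status[pm]),
                          lambda_path = f1$lambda)
  expect_equal(f1$beta, f2$beta, tolerance = 1e-6)
})

test_that("near-zero penalty matches the generic-optimizer oracle and coxph", {
  d <- lt_data(n = 300)
  lam_max <- fit_penalized_cox(d$x, d$y)$lambda[1]
  f <- fit_penalized_cox(d$x, d$y, lambda_path = c(lam_max * 1e-4))
  oracle <- cox_optim_oracle(d$x, d$y$entry, d$y$exit, d$y$status)
  expect_lt(max(abs(coef(f) - oracle)), 1e-3)
  cph <- survival::coxph(
    survival::Surv(entry, exit, status) ~ f1 + f2 + f3,
    data = data.frame(d$y, d$x), ties = "breslow")
  f0 <- fit_penalized_cox(d$x, d$y, penalty_factors = rep(0, 3),
                          lambda_path = 0)
  expect_lt(max(abs(coef(f0) - coef(cph))), 1e-3)
})

test_that("the KKT certificate holds along the path and flags corruption", {
  d <- lt_data(n = 200, p = 6, beta = c(0.6, -0.6, 0.3, 0, 0, 0), seed = 3)
  f <- fit_penalized_cox(d$x, d$y)
  v <- kkt_certificate(f, d$x, d$y)
  expect_lt(max(v), 1e-6)
  f$beta_std[2, 10] <- f$beta_std[2, 10] + 0.05
  expect_gt(max(kkt_certificate(f, d$x, d$y)), 1e-3)
})

test_that("stratified fits use separate risk sets", {
  d <- lt_data(n = 300, seed = 5)
  g <- rep(c("a", "b"), length.out = nrow(d$x))
  f <- fit_penalized_cox(d$x, d$y, penalty_factors = rep(0, 3),
                         lambda_path = 0, strata = g)
  cph <- survival::coxph(
    survival::Surv(entry, exit, status) ~ f1 + f2 + f3 +
      survival::strata(g),
    data = data.frame(d$y, d$x, g = g), ties = "breslow")
  expect_lt(max(abs(coef(f) - coef(cph))), 1e-3)
})

test_that("errors: no events, missing values, bad path", {
  x <- matrix(rnorm(20), 10, 2)
  y0 <- surv_response(rep(0, 10), 1:10, rep(0L, 10))
  expect_error(fit_penalized_cox(x, y0), "no events")
  y1 <- surv_response(rep(0, 10), 1:10, rep(1L, 10))
  xna <- x; xna[1] <- NA
  expect_error(fit_penalized_cox(xna, y1), "finite")
  expect_error(fit_penalized_cox(x, y1, lambda_path = c(1, 2)), "decreasing")
})

test_that("predict_risk is exp(linear predictor) with aligned columns", {
  d <- lt_data(n = 120)
  f <- fit_penalized_cox(d$x, d$y)
  # at lambda_max all coefficients are zero: every score is 1
  expect_equal(unname(predict_risk(f, d$x, lambda = f$lambda[1])),
               rep(1, nrow(d$x)))
  b <- coef(f)
  x0 <- d$x[1, , drop = FALSE]
  x1 <- x0; x1[1, 2] <- x1[1, 2] + 1
  r <- predict_risk(f, rbind(x0, x1))
  expect_equal(unname(r[2] / r[1]), unname(exp(b[2])), tolerance = 1e-10)
  # 3-subject hand computation
  xh <- matrix(c(0, 1, -1, 2, 0.5, 1), 3, 2)
  colnames(xh) <- c("f1", "f2")
  fh <- f; fh$features <- c("f1", "f2")
  fh$beta <- matrix(c(0.5, -1), 2, 1); fh$lambda <- 1
  fh$centers <- c(f1 = 0, f2 = 0); fh$scales <- c(f1 = 1, f2 = 1)
  fh$selected_lambda <- NULL
  expect_equal(unname(predict_risk(fh, xh)),
               exp(c(0.5 * 0 - 1 * 2, 0.5 * 1 - 1 * 0.5, 0.5 * -1 - 1 * 1)))
  expect_error(predict_risk(f, d$x[, 1:2]), "missing")
})

test_that("Breslow baseline matches closed forms and brute force", {
  # no censoring/truncation, all lp = 0, distinct times: Nelson-Aalen
  n <- 25
  y <- surv_response(rep(0, n), seq_len(n) * 10, rep(1L, n))
  x <- matrix(rnorm(n), n, 1, dimnames = list(NULL, "f1"))
  f <- fit_penalized_cox(x, y, lambda_path = 99) # beta = 0
  f <- breslow_baseline(f, x, y, lambda = 99)
  expect_equal(f$breslow$all$cumhaz, cumsum(1 / (n - seq_len(n) + 1)))
  # no events: cumulative hazard identically zero
  bz <- pancox:::breslow_cumhaz(rep(0, 4), 1:4, rep(0L, 4), rnorm(4))
  expect_equal(nrow(bz), 0)
  expect_equal(pancox:::eval_cumhaz(bz, c(0, 10)), c(0, 0))
  # random left-truncated instance vs naive double loop
  d <- lt_data(n = 150, seed = 9)
  ft <- fit_penalized_cox(d$x, d$y)
  ft <- breslow_baseline(ft, d$x, d$y)
  lp <- log(predict_risk(ft, d$x))
  et <- sort(unique(d$y$exit[d$y$status == 1]))
  H <- numeric(length(et))
  acc <- 0
  for (k in seq_along(et)) {
    dk <- sum(d$y$exit == et[k] & d$y$status == 1)
    Sk <- 0
    for (j in seq_len(nrow(d$x)))
      if (d$y$entry[j] < et[k] && et[k] <= d$y$exit[j]) Sk <- Sk + exp(lp[j])
    acc <- acc + dk / Sk
    H[k] <- acc
  }
  expect_equal(ft$breslow$all$cumhaz, H, tolerance = 1e-10)
})

test_that("predict_survival is a proper survival function", {
  d <- lt_data(n = 200, seed = 13)
  f <- fit_penalized_cox(d$x, d$y)
  f <- breslow_baseline(f, d$x, d$y)
  times <- c(0, 50, 100, 400, 1000, 2500)
  S <- predict_survival(f, d$x, times)
  expect_equal(unname(S[, 1]), rep(1, nrow(d$x)))
  expect_true(all(S >= 0 & S <= 1))
  expect_true(all(apply(S, 1, function(s) all(diff(s) <= 1e-12))))
  # very high risk: survival collapses past the first event
  xhi <- d$x[1, , drop = FALSE] * 0
  xhi[1, ] <- c(50, -50, 50) * sign(coef(f))[1:3]
  expect_error(predict_survival(f, d$x, c(5, 1)), "ascending")
  expect_error(predict_survival(f, d$x, times, strata_new = rep("zz", 200)),
               "unknown stratum")
})
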