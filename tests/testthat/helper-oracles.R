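# Definition-level oracles, written independently of the package internals:
# plain loops and textbook formulas only.

# brute-force concordance: ordered pairs, left-truncation-aware risk sets
cindex_brute <- function(entry, exit, status, scores) {
  conc <- 0
  comp <- 0
  n <- length(exit)
  for (i in seq_len(n)) {
    if (status[i] != 1) next
    for (j in seq_len(n)) {
      if (j == i) next
      if (entry[j] < exit[i] && exit[i] < exit[j]) {
        comp <- comp + 1
        if (scores[i] > scores[j]) conc <- conc + 1
        else if (scores[i] == scores[j]) conc <- conc + 0.5
      }
    }
  }
  list(c = conc / comp, comparable = comp)
}

# vectorized variant for larger n (still an independent route)
cindex_outer <- function(entry, exit, status, scores) {
  comp <- outer(status == 1, rep(TRUE, length(exit))) &
    outer(exit, entry, ">") & outer(exit, exit, "<")
  diag(comp) <- FALSE
  sgt <- outer(scores, scores, ">")
  seq_ <- outer(scores, scores, "==")
  (sum(sgt & comp) + 0.5 * sum(seq_ & comp)) / sum(comp)
}

# Pincus approximate entropy by exhaustive template enumeration
apen_brute <- function(x, m, r) {
  n <- length(x)
  if (n < m + 1) return(NA_real_)
  phi <- function(k) {
    nt <- n - k + 1
    lc <- numeric(nt)
    for (i in seq_len(nt)) {
      cnt <- 0
      for (j in seq_len(nt)) {
        dmax <- 0
        for (u in 0:(k - 1)) {
          d <- abs(x[i + u] - x[j + u])
          if (d > dmax) dmax <- d
        }
        if (dmax <= r) cnt <- cnt + 1
      }
      lc[i] <- log(cnt / nt)
    }
    sum(lc) / nt
  }
  phi(m) - phi(m + 1)
}

# naive windowed lab summaries, straight from the definitions
naive_lab_summaries <- function(v, t, lln, uln, record_len, window,
                                m = 2, rfac = 0.2) {
  keep <- t >= -window & t < 0
  v <- v[keep]; t <- t[keep]
  n <- length(v)
  out <- c(mean = NA, median = NA, variance = NA, max = NA, min = NA,
           apen = NA, diff_last2 = NA, slope_last2 = NA,
           n_tests = n, test_ratio = n / max(1, min(window, record_len)),
           prop_abnormal = NA)
  if (n == 0) return(out)
  z <- (v - lln) / (uln - lln)
  out["mean"] <- sum(z) / n
  zs <- sort(z)
  out["median"] <- if (n %% 2 == 1) zs[(n + 1) / 2]
                   else (zs[n / 2] + zs[n / 2 + 1]) / 2
  out["max"] <- zs[n]; out["min"] <- zs[1]
  nab <- 0
  for (i in seq_len(n)) if (v[i] < lln || v[i] > uln) nab <- nab + 1
  out["prop_abnormal"] <- nab / n
  if (n >= 2) {
    mu <- sum(z) / n
    out["variance"] <- sum((z - mu)^2) / (n - 1)
    o <- order(t)
    z2 <- z[o][c(n - 1, n)]; t2 <- t[o][c(n - 1, n)]
    out["diff_last2"] <- z2[2] - z2[1]
    out["slope_last2"] <- if (t2[2] == t2[1]) NA else (z2[2] - z2[1]) / (t2[2] - t2[1])
  }
  if (n >= m + 1) {
    zo <- z[order(t)]
    s <- sqrt(sum((zo - mean(zo))^2) / (n - 1))
    out["apen"] <- apen_brute(zo, m, rfac * s)
  }
  out
}

# generic-optimizer maximum of the left-truncated Cox partial likelihood
cox_optim_oracle <- function(x, entry, exit, status) {
  negll <- function(b) {
    lp <- drop(x %*% b)
    s <- 0
    for (i in which(status == 1)) {
      risk <- entry < exit[i] & exit[i] <= exit
      s <- s + lp[i] - log(sum(exp(lp[risk])))
    }
    -s
  }
  optim(rep(0, ncol(x)), negll, method = "BFGS",
        control = list(maxit = 1000, reltol = 1e-14))$par
}

# quick Weibull proportional-hazards draw on an explicit design matrix
sim_surv <- function(x, beta, scale = 500, shape = 1, entry_mean = 0,
                     cens_rate = 1 / 1500, admin = 3000) {
  n <- nrow(x)
  lp <- drop(x %*% beta)
  t_death <- scale * (-log(runif(n)) / exp(lp))^(1 / shape)
  cens <- if (cens_rate > 0) pmin(rexp(n, cens_rate), admin) else rep(admin, n)
  entry <- if (entry_mean > 0) rexp(n, 1 / entry_mean) else rep(0, n)
  exit <- pmin(t_death, cens)
  keep <- exit > entry
  list(x = x[keep, , drop = FALSE],
       y = surv_response(entry[keep], exit[keep], status = as.integer(
         t_death <= cens)[keep]),
       lp = lp[keep], kept = mean(keep))
}

# small, fast simulation config used across tests
tiny_config <- function(..., seed = 1L) {
  sim_config(n_cancers = 2, cohort_sizes = c(80, 120),
             n_shared_features = 5,
             shared_beta = c(0.3, 0.2, 0.1, 0.5, -0.4),
             n_specific_features = c(1, 1),
             specific_beta = list(0.3, -0.3),
             lab_catalog = default_lab_catalog()[1:2, ],
             weibull_scale = c(350, 500),
             ..., seed = seed)
}
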