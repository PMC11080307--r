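# Independent brute-force oracles and tiny fixtures shared across tests.
# These are deliberately written as plain loops, separate from the package's
# vectorized implementations.

# deterministic small censored cohort
random_cohort <- function(n, seed, cens_rate = 1 / 800, lambda = 1 / 1000) {
  set.seed(seed)
  tt <- rexp(n, lambda)
  cc <- rexp(n, cens_rate)
  survival_cohort(data.frame(
    time = pmin(tt, cc), event = as.integer(tt <= cc),
    x = rnorm(n)))
}

# univariate_fit object with known (not estimated) parameters
known_fit <- function(family, params) {
  structure(list(family = family, params = params, loglik = NA_real_,
                 n = NA_integer_), class = "univariate_fit")
}

# reverse Kaplan-Meier by explicit product loop
brute_reverse_km <- function(time, event, at) {
  ct <- sort(unique(time[event == 0]))
  sapply(at, function(t0) {
    g <- 1
    for (u in ct) {
      if (u > t0) break
      g <- g * (1 - sum(time == u & event == 0) / sum(time >= u))
    }
    g
  })
}

# IPCW Brier score by double loop
brute_brier <- function(surv, time, event, times, G, G_minus) {
  n <- length(time)
  out <- numeric(length(times))
  for (j in seq_along(times)) {
    t0 <- times[j]
    acc <- 0
    for (i in seq_len(n)) {
      if (time[i] > t0) {
        acc <- acc + (1 - surv[i, j])^2 / G(t0)
      } else if (event[i] == 1) {
        acc <- acc + (0 - surv[i, j])^2 / G_minus(time[i])
      }
    }
    out[j] <- acc / n
  }
  out
}

# IPCW cumulative/dynamic AUC by double loop over case-control pairs
brute_auc <- function(risk, time, event, times, G_minus) {
  out <- numeric(length(times))
  for (j in seq_along(times)) {
    t0 <- times[j]
    cases <- which(time <= t0 & event == 1)
    controls <- which(time > t0)
    if (length(cases) == 0 || length(controls) == 0) {
      out[j] <- NA_real_
      next
    }
    num <- 0
    den <- 0
    for (i in cases) {
      wi <- 1 / G_minus(time[i])
      for (k in controls) {
        cmp <- if (risk[i, j] > risk[k, j]) 1
               else if (risk[i, j] == risk[k, j]) 0.5 else 0
        num <- num + wi * cmp
        den <- den + wi
      }
    }
    out[j] <- num / den
  }
  out
}

# KS statistic via stats::ks.test against the fitted CDF
oracle_ks_D <- function(x, cdf) {
  unname(stats::ks.test(x, cdf)$statistic)
}

# Schoenfeld residuals by explicit risk-set loop (no ties assumed)
brute_schoenfeld <- function(time, event, X, beta) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]; X <- X[ord, , drop = FALSE]
  rows <- which(event == 1)
  out <- matrix(NA_real_, length(rows), ncol(X))
  for (r in seq_along(rows)) {
    i <- rows[r]
    risk <- which(time >= time[i])
    w <- exp(drop(X[risk, , drop = FALSE] %*% beta))
    zbar <- colSums(X[risk, , drop = FALSE] * w) / sum(w)
    out[r, ] <- X[i, ] - zbar
  }
  out
}

# Cox partial log-likelihood for one binary covariate, explicit loop
brute_cox_loglik <- function(time, event, z, beta) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- which(time >= time[i])
    ll <- ll + beta * z[i] - log(sum(exp(beta * z[risk])))
  }
  ll
}

# Nelson-Aalen by explicit loop
brute_nelson_aalen <- function(time, event, at) {
  et <- sort(unique(time[event == 1]))
  sapply(at, function(t0) {
    h <- 0
    for (u in et) {
      if (u > t0) break
      h <- h + sum(time == u & event == 1) / sum(time >= u)
    }
    h
  })
}

default_covs <- c("age", "grade2", "grade3", "rad_1", "rad_2", "rad_3")

# generate + encode + z-score a cohort from a spec (training-only pipeline)
prepared_cohort <- function(spec) {
  ch <- encode_grade(generate_cohort(spec))
  zscore_normalize(ch, NULL, c("age", "rad_1", "rad_2", "rad_3"))$train
}
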