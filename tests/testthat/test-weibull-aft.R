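test_that("fixed-shape exponential fit recovers the closed-form MLE", {
  ch <- survival_cohort(data.frame(time = c(1, 2, 3, 4), event = 1))
  fit <- fit_weibull_aft(ch, shape = 1)
  expect_equal(fit$lambda, 4 / 10, tolerance = 1e-7)
  expect_equal(fit$gamma, 1)
})

test_that("AFT and PH parameterizations convert exactly and round-trip", {
  expect_equal(aft_to_ph(0, 1, 0), list(gamma = 1, lambda = 1, beta = 0))
  expect_equal(aft_to_ph(0, 0.5, numeric(0))$gamma, 2)
  set.seed(1)
  for (r in 1:1000) {
    mu <- rnorm(1); sigma <- exp(rnorm(1)); alpha <- rnorm(3)
    ph <- aft_to_ph(mu, sigma, alpha)
    back <- ph_to_aft(ph$gamma, ph$lambda, ph$beta)
    expect_equal(back$mu, mu, tolerance = 1e-12)
    expect_equal(back$sigma, sigma, tolerance = 1e-12)
    expect_equal(back$alpha, alpha, tolerance = 1e-12)
  }
  expect_error(aft_to_ph(0, -1, 0), "sigma")
  expect_error(ph_to_aft(-2, 1, 0), "gamma")
})

test_that("every fitted model satisfies the scale-linkage identities", {
  ch <- prepared_cohort(cohort_spec(n_subjects = 350, seed = 14))
  fit <- fit_weibull_aft(ch, default_covs)
  expect_equal(fit$gamma, 1 / fit$sigma, tolerance = 1e-10)
  expect_equal(fit$lambda, exp(-fit$mu / fit$sigma), tolerance = 1e-8 * fit$lambda)
  expect_equal(unname(fit$beta), unname(-fit$alpha / fit$sigma),
               tolerance = 1e-10)
  # covariance symmetric positive semi-definite
  expect_equal(fit$covariance, t(fit$covariance), tolerance = 1e-12)
  expect_gte(min(eigen(fit$covariance, symmetric = TRUE)$values), -1e-10)
})

test_that("the fit agrees with survreg and is a local optimum", {
  ch <- prepared_cohort(cohort_spec(n_subjects = 400, seed = 8))
  fit <- fit_weibull_aft(ch, default_covs)
  sv <- survival::survreg(
    survival::Surv(time, event) ~ age + grade2 + grade3 + rad_1 + rad_2 + rad_3,
    data = as.data.frame(ch))
  expect_equal(fit$gamma, 1 / sv$scale, tolerance = 1e-6)
  expect_equal(unname(fit$beta), unname(-coef(sv)[-1] / sv$scale),
               tolerance = 1e-6)
  expect_equal(fit$loglik, sv$loglik[2], tolerance = 1e-8)

  # log-likelihood beats 100 random perturbations of size 0.05
  internal <- c(log(fit$gamma), log(fit$lambda), fit$beta)
  ll_at <- function(par) {
    m <- weibull_aft_model(exp(par[1]), exp(par[2]),
                           setNames(par[-(1:2)], names(fit$beta)))
    X <- as.matrix(as.data.frame(ch)[default_covs])
    eta <- drop(X %*% m$beta)
    H <- m$lambda * exp(eta) * ch$time^m$gamma
    sum(ch$event * log(m$gamma * m$lambda * ch$time^(m$gamma - 1) * exp(eta))) -
      sum(H)
  }
  set.seed(10)
  for (r in 1:100) {
    pert <- internal + 0.05 * rnorm(length(internal))
    expect_gte(fit$loglik, ll_at(pert))
  }
})

test_that("hazard ratios and event time ratios match the published arithmetic", {
  ref <- reference_effects("training")
  m <- weibull_aft_model(attr(ref, "gamma"), attr(ref, "lambda"),
                         setNames(ref$weibull_coef, ref$predictor))
  for (i in seq_len(nrow(ref))) {
    # printed inputs are rounded to 4 decimals, so allow 1e-3 absolutely
    expect_lt(abs(hazard_ratio(m, ref$predictor[i])$estimate -
                    ref$weibull_hr[i]), 1e-3)
    expect_lt(abs(event_time_ratio(m, ref$predictor[i])$estimate -
                    ref$weibull_etr[i]), 1e-3)
  }
  # structural special cases
  m0 <- weibull_aft_model(1.5, 1e-4, c(a = 0, b = log(2)))
  expect_equal(hazard_ratio(m0, "a")$estimate, 1)
  expect_equal(hazard_ratio(m0, "b")$estimate, 2)
  m1 <- weibull_aft_model(1, 1e-4, c(a = 0.7))
  expect_equal(event_time_ratio(m1, "a")$estimate,
               1 / hazard_ratio(m1, "a")$estimate, tolerance = 1e-12)
  expect_error(hazard_ratio(m1, "nope"), "unknown covariate")
})

test_that("ETR < 1 exactly when HR > 1 (positive shape links the signs)", {
  set.seed(3)
  for (r in 1:200) {
    g <- exp(rnorm(1)); b <- rnorm(1)
    m <- weibull_aft_model(g, exp(rnorm(1)), c(x = b))
    hr <- hazard_ratio(m, "x")$estimate
    etr <- event_time_ratio(m, "x")$estimate
    if (b != 0) expect_identical(hr > 1, etr < 1)
  }
})

test_that("percentile times invert the survival function", {
  # unit exponential: S(1) = e^-1 so t_{e^-1} = 1
  m <- weibull_aft_model(1, 1)
  expect_equal(percentile_time(m, p = exp(-1)), 1, tolerance = 1e-12)
  # closed-form oracle at the published training shape/scale
  g <- 0.9929; lam <- 3.0447e-05
  m2 <- weibull_aft_model(g, lam)
  t95 <- percentile_time(m2, p = 0.95)
  expect_equal(t95, (-log(0.95) / lam)^(1 / g), tolerance = 1e-12)
  expect_equal(predict_survival(m2, times = t95), 0.95, tolerance = 1e-10)
  # doubling lambda halves t_p when gamma = 1
  m3 <- weibull_aft_model(1, 2e-4)
  m4 <- weibull_aft_model(1, 1e-4)
  expect_equal(percentile_time(m4, p = 0.9) / percentile_time(m3, p = 0.9), 2,
               tolerance = 1e-12)
  expect_error(percentile_time(m2, p = 1.2), "survival probability")
  expect_error(percentile_time(m2, p = 0), "survival probability")
})

test_that("time ratios cancel the percentile and reduce to the ETR", {
  m <- weibull_aft_model(1.4, 2e-5, c(x = 0.8, y = -0.3))
  expect_equal(time_ratio(m, c(1, 2), c(1, 2)), 1)
  expect_equal(time_ratio(m, c(1, 0), c(0, 0)),
               event_time_ratio(m, "x")$estimate, tolerance = 1e-12)
  expect_equal(time_ratio(m, c(2, 1), c(0, 3), p = 0.5),
               time_ratio(m, c(2, 1), c(0, 3), p = 0.95), tolerance = 1e-12)
  # consistency with explicit percentile-time quotient
  q <- percentile_time(m, c(2, 1), 0.5) / percentile_time(m, c(0, 3), 0.5)
  expect_equal(time_ratio(m, c(2, 1), c(0, 3)), q, tolerance = 1e-12)
})

test_that("predicted survival behaves like a survival function", {
  m <- weibull_aft_model(1, 1)
  expect_equal(predict_survival(m, times = 0), 1)
  expect_equal(predict_survival(m, times = 1), exp(-1), tolerance = 1e-12)
  s <- predict_survival(m, times = seq(0, 5, by = 0.1))
  expect_true(all(diff(s) <= 0))
  expect_error(predict_survival(m, times = -1), "non-negative")

  # KM of a large uncensored simulated cohort tracks predictions at deciles
  spec <- cohort_spec(n_subjects = 8000, admin_censor_time = 1e9,
                      dropout_rate = 0, seed = 21)
  ch <- prepared_cohort(spec)
  fit <- fit_weibull_aft(ch, default_covs)
  km <- survival::survfit(survival::Surv(time, event) ~ 1,
                          data = as.data.frame(ch))
  dec <- quantile(ch$time, seq(0.1, 0.9, 0.1))
  S_km <- stepfun(km$time, c(1, km$surv))(dec)
  S_fit <- colMeans(
    parasurv:::survival_matrix_weibull(fit, ch, as.numeric(dec)))
  expect_lt(max(abs(S_km - S_fit)), 0.02)
})

test_that("degenerate designs are rejected with informative errors", {
  ch <- prepared_cohort(cohort_spec(n_subjects = 80, seed = 5))
  ch$event <- 0
  expect_error(fit_weibull_aft(ch, "age"), "no events")
  ch2 <- prepared_cohort(cohort_spec(n_subjects = 80, seed = 5))
  ch2$dup <- ch2$age
  expect_error(fit_weibull_aft(ch2, c("age", "dup")), "dup")
  expect_error(fit_weibull_aft(ch2, c("age", "missing_col")), "missing_col")
})

test_that("cumulative-hazard check matches brute force and flags good fits", {
  # Nelson-Aalen increments equal d_i / n_at_risk_i (brute-force loop)
  ch <- random_cohort(60, seed = 42)
  na <- nelson_aalen(ch)
  expect_equal(na$cumhaz, brute_nelson_aalen(ch$time, ch$event, na$time),
               tolerance = 1e-12)
  # identical curves have discrepancy 0
  expect_equal(max(abs(na$cumhaz - na$cumhaz)), 0)
  # well-specified cohort: parametric and nonparametric curves stay close
  spec <- cohort_spec(n_subjects = 5000, seed = 31)
  big <- prepared_cohort(spec)
  fit <- fit_weibull_aft(big, default_covs)
  cd <- check_distribution(fit, big)
  expect_true(all(diff(cd$nonparametric) >= 0))
  expect_true(all(diff(cd$parametric) >= 0))
  q90 <- quantile(big$time, 0.9)
  sub <- cd[cd$time <= q90, ]
  expect_lt(max(abs(sub$nonparametric - sub$parametric)), 0.15)
  expect_error(check_distribution(fit, big[0, ]), "empty")
})
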