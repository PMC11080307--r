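test_that("4-subject fit matches a brute-force partial-likelihood grid", {
  ch <- survival_cohort(data.frame(time = c(1, 2, 3, 4), event = 1,
                                   z = c(1, 0, 1, 0)))
  fit <- fit_cox(ch, "z")
  grid <- seq(-5, 5, by = 1e-4)
  ll <- vapply(grid, function(b) brute_cox_loglik(ch$time, ch$event, ch$z, b),
               numeric(1))
  expect_equal(unname(fit$beta), grid[which.max(ll)], tolerance = 2e-4)
  expect_equal(unname(fit$loglik), max(ll), tolerance = 1e-6)
})

test_that("Cox recovers the Weibull-generated truth (PH holds)", {
  spec <- cohort_spec(n_subjects = 2500, seed = 17)
  ch <- prepared_cohort(spec)
  fit <- fit_cox(ch, default_covs)
  se <- sqrt(diag(fit$covariance))
  truth <- spec$beta_true
  expect_true(all(abs(fit$beta - truth) < 3 * se))
})

test_that("degenerate designs error instead of fitting silently", {
  ch <- random_cohort(40, seed = 3)
  ch$const <- 5
  expect_error(fit_cox(ch, c("x", "const")), "const")
  ch0 <- ch
  ch0$event <- 0
  expect_error(fit_cox(ch0, "x"), "no events")
})

test_that("Schoenfeld residuals satisfy the score identity and brute force", {
  ch <- prepared_cohort(cohort_spec(n_subjects = 250, seed = 23))
  fit <- fit_cox(ch, default_covs)
  sr <- schoenfeld_residuals(fit, ch)
  expect_equal(nrow(sr$residuals), fit$n_events)
  expect_lt(max(abs(colSums(sr$residuals))), 1e-8)
  expect_identical(sr$time, sort(ch$time[ch$event == 1]))

  # 10-subject no-ties instance against an explicit risk-set loop
  set.seed(91)
  small <- survival_cohort(data.frame(
    time = sample(seq(10, 100, by = 7), 10), event = rep(c(1, 1, 1, 1, 0), 2),
    z1 = rnorm(10), z2 = rnorm(10)))
  fs <- fit_cox(small, c("z1", "z2"))
  srs <- schoenfeld_residuals(fs, small)
  brute <- brute_schoenfeld(small$time, small$event,
                            as.matrix(as.data.frame(small)[c("z1", "z2")]),
                            fs$beta)
  expect_equal(unname(srs$residuals), unname(brute), tolerance = 1e-12)

  # scaled residuals follow the Grambsch-Therneau convention
  manual <- sweep(fit$n_events * sr$residuals %*% fit$covariance, 2,
                  fit$beta, `+`)
  expect_equal(unname(sr$scaled), unname(manual), tolerance = 1e-12)
  expect_error(schoenfeld_residuals(fit, ch[-1, ]), "does not match")
})

test_that("PH test transforms are consistent and guarded", {
  # death times equal to their rank in the whole sample (all censored
  # follow-up is later), so the rank and identity transforms feed the score
  # test identical regressors and must agree exactly
  set.seed(6)
  n <- 60
  ch <- survival_cohort(data.frame(
    time = c(1:30 + 0, runif(30, 40, 90)),
    event = rep(c(1, 0), each = 30), x = rnorm(n), y = rnorm(n)))
  fit <- fit_cox(ch, c("x", "y"))
  a <- ph_test(fit, transform = "identity")
  b <- ph_test(fit, transform = "rank")
  expect_equal(a$chisq, b$chisq, tolerance = 1e-10)
  expect_equal(a$p, b$p, tolerance = 1e-10)
  expect_true(all(a$p >= 0 & a$p <= 1))
  expect_identical(a$covariate[nrow(a)], "GLOBAL")

  few <- survival_cohort(data.frame(time = c(1, 2, 3, 4),
                                    event = c(1, 1, 0, 0),
                                    x = c(0.3, -1, 2, 0.1)))
  ffew <- fit_cox(few, "x")
  expect_error(ph_test(ffew), "at least 3 events")
})

test_that("martingale residuals sum to zero, are bounded, and match brute force", {
  ch <- prepared_cohort(cohort_spec(n_subjects = 220, seed = 29))
  fit <- fit_cox(ch, default_covs)
  mr <- martingale_residuals(fit, ch)
  expect_lt(abs(sum(mr)), 1e-6)
  expect_true(all(mr <= 1))

  # null model: residual = event - Nelson-Aalen at the subject's own time
  small <- random_cohort(35, seed = 44)
  f0 <- fit_cox(small, NULL)
  m0 <- martingale_residuals(f0, small)
  na_own <- brute_nelson_aalen(small$time, small$event, small$time)
  expect_equal(m0, small$event - na_own, tolerance = 1e-8)
})

test_that("Cox survival predictions are proper step functions", {
  ch <- prepared_cohort(cohort_spec(n_subjects = 300, seed = 37))
  fit <- fit_cox(ch, default_covs)
  z <- rep(0, length(default_covs))
  tms <- seq(0, 4000, by = 50)
  s <- predict_survival_cox(fit, z, tms)
  expect_equal(s[1], 1)
  expect_true(all(diff(s) <= 0))
  expect_true(any(attr(s, "extrapolated")))
  expect_false(attr(s, "extrapolated")[1])
  expect_error(predict_survival_cox(fit, z, -5), "non-negative")

  # with a pure-noise covariate the Breslow baseline tracks the KM curve
  set.seed(11)
  noise <- random_cohort(1000, seed = 61)
  fn <- fit_cox(noise, "x")
  km <- survival::survfit(survival::Surv(time, event) ~ 1,
                          data = as.data.frame(noise))
  grid <- quantile(noise$time, seq(0.1, 0.9, 0.1))
  s_cox <- predict_survival_cox(fn, fn$means, as.numeric(grid))
  s_km <- stepfun(km$time, c(1, km$surv))(grid)
  expect_lt(max(abs(s_cox - s_km)), 0.02)
})

test_that("Efron and Breslow coincide exactly without ties", {
  ch <- random_cohort(150, seed = 13)  # continuous times, no ties
  fe <- fit_cox(ch, "x", ties = "efron")
  fb <- fit_cox(ch, "x", ties = "breslow")
  expect_equal(fe$beta, fb$beta, tolerance = 1e-10)
  expect_equal(fe$loglik, fb$loglik, tolerance = 1e-10)
})
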