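test_that("reverse-KM censoring weights match brute force and conventions", {
  # no censoring: G = 1 everywhere
  ch <- survival_cohort(data.frame(time = c(3, 1, 7, 5), event = 1))
  cw <- censoring_weights(ch)
  expect_equal(cw$G(c(0, 2, 6, 10)), rep(1, 4))

  # all censored: G equals the KM of the censoring times
  ch2 <- random_cohort(40, seed = 5)
  ch2$event <- 0
  cw2 <- censoring_weights(ch2)
  at <- sort(unique(ch2$time))
  expect_equal(cw2$G(at), brute_reverse_km(ch2$time, ch2$event, at),
               tolerance = 1e-12)

  # general censored case, including left limits
  ch3 <- random_cohort(60, seed = 8)
  cw3 <- censoring_weights(ch3)
  at3 <- c(sort(unique(ch3$time)), 10, 500)
  expect_equal(cw3$G(at3), brute_reverse_km(ch3$time, ch3$event, at3),
               tolerance = 1e-12)
  eps <- 1e-9
  expect_equal(cw3$G_minus(at3), brute_reverse_km(ch3$time, ch3$event, at3 - eps),
               tolerance = 1e-9)
  expect_equal(cw3$G(0), 1)
  expect_true(all(diff(cw3$surv) <= 0))

  # invariant to covariates of event subjects
  ch4 <- ch3
  ch4$x <- rev(ch4$x)
  cw4 <- censoring_weights(ch4)
  expect_identical(cw3$surv, cw4$surv)
})

test_that("Brier curve reproduces closed forms and the double-loop oracle", {
  # perfect forecaster on uncensored data scores 0 everywhere
  tt <- c(10, 20, 30, 40, 50, 60)
  ch <- survival_cohort(data.frame(time = tt, event = 1))
  grid <- c(15, 35, 55)
  perfect <- outer(tt, grid, `>`) * 1
  expect_equal(brier_curve(perfect, ch, grid)$value, rep(0, 3))

  # constant 1/2 forecaster on uncensored data: 0.25 at the median (and
  # indeed at every time, since (indicator - 1/2)^2 is always 1/4)
  half <- matrix(0.5, length(tt), length(grid))
  expect_equal(brier_curve(half, ch, grid)$value, rep(0.25, 3))

  # censored n = 30 instance against the hand-rolled IPCW double loop
  ch2 <- random_cohort(30, seed = 77)
  grid2 <- quantile(ch2$time, c(0.2, 0.4, 0.6, 0.8))
  grid2 <- as.numeric(grid2)
  set.seed(1)
  surv <- matrix(runif(30 * 4), 30, 4)
  cw <- censoring_weights(ch2)
  expect_equal(brier_curve(surv, ch2, grid2)$value,
               brute_brier(surv, ch2$time, ch2$event, grid2, cw$G, cw$G_minus),
               tolerance = 1e-12)

  # a grid beyond the censoring support errors with advice
  ch3 <- survival_cohort(data.frame(time = c(1, 2, 3, 4),
                                    event = c(1, 1, 0, 0)))
  expect_error(brier_curve(matrix(0.5, 4, 1), ch3, 5), "truncate")
})

test_that("AUC curve is 1 for a separating score, 0.5 for noise, and matches brute force", {
  tt <- c(10, 20, 30, 40, 50, 60)
  ch <- survival_cohort(data.frame(time = tt, event = 1))
  grid <- c(15, 35, 55)
  risk <- -tt  # earlier death = higher risk: perfect separation
  crv <- auc_curve(risk, ch, grid)
  expect_equal(crv$value, rep(1, 3))
  expect_false(any(attr(crv, "undefined")))

  # exchangeable scores: AUC near 1/2 across the grid
  ch2 <- random_cohort(2000, seed = 15)
  grid2 <- as.numeric(quantile(ch2$time[ch2$event == 1], c(0.2, 0.5, 0.8)))
  set.seed(2)
  noise <- rnorm(2000)
  crv2 <- auc_curve(noise, ch2, grid2)
  expect_lt(max(abs(crv2$value - 0.5)), 0.03)

  # small censored instance against the pairwise double loop
  ch3 <- random_cohort(30, seed = 99)
  grid3 <- as.numeric(quantile(ch3$time, c(0.3, 0.6, 0.9)))
  set.seed(3)
  risk3 <- matrix(rnorm(30 * 3), 30, 3)
  risk3[1, ] <- risk3[2, ]  # force a tie to exercise the 1/2 rule
  cw3 <- censoring_weights(ch3)
  expect_equal(auc_curve(risk3, ch3, grid3)$value,
               brute_auc(risk3, ch3$time, ch3$event, grid3, cw3$G_minus),
               tolerance = 1e-12)

  # no cases yet -> undefined, flagged, not dropped
  early <- min(ch3$time) / 2
  crv4 <- auc_curve(risk3[, 1], ch3, early)
  expect_true(is.na(crv4$value))
  expect_true(attr(crv4, "undefined"))
  expect_equal(nrow(crv4), 1)
})

test_that("null-model curves use the marginal KM and ignore covariates", {
  # uncensored with KM(t*) = 0.5 at the median: null Brier = 0.25
  tt <- 1:10
  ch <- survival_cohort(data.frame(time = tt, event = 1))
  crv <- null_model_curve(ch, 5.5, "brier")
  expect_equal(crv$value, 0.25)
  expect_identical(crv$model, "null")

  # AUC undefined for a constant score
  crva <- null_model_curve(ch, 5.5, "auc")
  expect_true(is.na(crva$value))
  expect_true(all(attr(crva, "undefined")))

  # independent of covariates
  ch2 <- random_cohort(50, seed = 21)
  ch3 <- ch2
  ch3$x <- ch3$x * 100
  g <- as.numeric(quantile(ch2$time, c(0.3, 0.6)))
  expect_equal(null_model_curve(ch2, g, "brier")$value,
               null_model_curve(ch3, g, "brier")$value)

  # under a correct informative model the null Brier is worse on average
  diffs <- vapply(1:50, function(r) {
    spec <- cohort_spec(n_subjects = 1000, seed = 3000 + r)
    ch <- prepared_cohort(spec)
    fit <- fit_weibull_aft(ch, default_covs)
    grid <- default_time_grid(ch, n_points = 8)
    s <- parasurv:::survival_matrix_weibull(fit, ch, grid)
    mean(null_model_curve(ch, grid, "brier")$value) -
      mean(brier_curve(s, ch, grid)$value)
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})

test_that("bootstrap bands behave as resampling summaries", {
  ch <- prepared_cohort(cohort_spec(n_subjects = 200, seed = 41))
  grid <- default_time_grid(ch, n_points = 6)
  refit <- function(boot, times) {
    f <- fit_weibull_aft(boot, default_covs)
    parasurv:::survival_matrix_weibull(f, boot, times)
  }
  b1 <- bootstrap_curves(refit, ch, grid, "brier", B = 1, seed = 2)
  expect_equal(b1$upper - b1$lower, rep(0, nrow(b1)))

  b2 <- bootstrap_curves(refit, ch, grid, "brier", B = 5, seed = 7)
  b3 <- bootstrap_curves(refit, ch, grid, "brier", B = 5, seed = 7)
  expect_identical(b2, b3)
  expect_true(all(b2$upper >= b2$lower))

  # width shrinks with cohort size at fixed B
  width_at <- function(n) {
    ch <- prepared_cohort(cohort_spec(n_subjects = n, seed = 53))
    g <- default_time_grid(ch, n_points = 6)
    b <- bootstrap_curves(refit, ch, g, "brier", B = 8, seed = 11)
    median(b$upper - b$lower)
  }
  expect_lt(width_at(700), width_at(120))
})
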