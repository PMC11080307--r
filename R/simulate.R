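#' Generate a synthetic right-censored survival cohort
#'
#' Draws covariates (truncated-normal age, categorical tumour grade,
#' exchangeably correlated standard-normal radiomic scores), then latent
#' Weibull event times by inverse-transform sampling from the
#' proportional-hazards model \eqn{h(t|z) = \gamma \lambda t^{\gamma-1}
#' e^{\beta' z}}, i.e. \eqn{T = (-\log U / (\lambda e^{\beta' z}))^{1/\gamma}}
#' with \eqn{U \sim} Uniform(0,1).  Censoring is the minimum of the
#' administrative cutoff and an independent exponential dropout time; the
#' observed time is `min(T, censoring)` with `event = 1` iff the latent event
#' time is the minimum (ties resolve in favour of the event).
#'
#' Each block of draws (age, grade, radiomics, event times, dropout) uses its
#' own named random stream derived from `spec$seed`, so the generated cohort
#' is bitwise reproducible and adding a covariate stream leaves the
#' event-time draws untouched.
#'
#' @param spec a [cohort_spec()].
#' @return A [survival_cohort()] with columns `subject_id`, `time`, `event`,
#'   `age`, `grade`, `rad_1..rad_k`.
#' @export
generate_cohort <- function(spec) {
  validate_cohort_spec(spec)
  n <- spec$n_subjects
  k <- spec$n_radiomic

  age <- with_seed(stream_seed(spec$seed, "age"), {
    lo <- pnorm(18, spec$age_mean, spec$age_sd)
    hi <- pnorm(100, spec$age_mean, spec$age_sd)
    qnorm(runif(n, lo, hi), spec$age_mean, spec$age_sd)
  })
  grade <- with_seed(stream_seed(spec$seed, "grade"),
    sample.int(3L, n, replace = TRUE, prob = spec$grade_probs))
  rad <- with_seed(stream_seed(spec$seed, "radiomic"), {
    if (k > 0) {
      sigma <- matrix(spec$radiomic_corr, k, k)
      diag(sigma) <- 1
      matrix(rnorm(n * k), n, k) %*% chol(sigma)
    } else matrix(numeric(0), n, 0)
  })
  colnames(rad) <- if (k > 0) paste0("rad_", seq_len(k)) else character(0)

  b <- as.numeric(spec$beta_true)
  terms <- cbind((age - spec$age_mean) / spec$age_sd * b[1],
                 (grade == 2) * b[2],
                 (grade == 3) * b[3],
                 if (k > 0) sweep(rad, 2, b[-(1:3)], `*`))
  lp <- rowSums(terms)
  if (any(!is.finite(lp)) || any(lp > 700)) {
    nm <- c("age", "grade2", "grade3", colnames(rad))
    worst <- nm[which.max(apply(abs(terms), 2, max))]
    abort_config(paste0(
      "non-finite linear predictor (overflow); offending coefficient: ", worst))
  }

  latent <- with_seed(stream_seed(spec$seed, "event"), {
    u <- runif(n)
    (-log(u) / (spec$lambda_true * exp(lp)))^(1 / spec$gamma_true)
  })
  dropout <- with_seed(stream_seed(spec$seed, "censor"), {
    if (spec$dropout_rate > 0) rexp(n, spec$dropout_rate) else rep(Inf, n)
  })
  censor <- pmin(dropout, spec$admin_censor_time)
  obs <- pmin(latent, censor)
  event <- as.integer(latent <= censor)

  survival_cohort(data.frame(subject_id = seq_len(n), time = obs,
                             event = event, age = age, grade = grade, rad,
                             check.names = FALSE))
}

#' Split a cohort into disjoint training and testing subsets
#'
#' Deterministic given `seed`; the two pieces partition the input (every
#' subject appears exactly once across the outputs).
#'
#' @param cohort a [survival_cohort()].
#' @param test_fraction proportion of subjects assigned to the test set,
#'   strictly between 0 and 1.
#' @param seed integer seed for the subject draw.
#' @return A list with elements `train` and `test`, both `survival_cohort`s.
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_subjects = 491, seed = 2))
#' parts <- split_cohort(cohort, test_fraction = 80 / 491, seed = 9)
#' c(nrow(parts$train), nrow(parts$test))  # 411 and 80
#' @export
split_cohort <- function(cohort, test_fraction, seed) {
  cohort <- as_survival_cohort(cohort)
  if (!is.finite(test_fraction) || test_fraction <= 0 || test_fraction >= 1)
    abort_config("test_fraction must lie strictly between 0 and 1")
  n <- nrow(cohort)
  n_test <- round(n * test_fraction)
  if (n_test < 1 || n_test >= n)
    abort_config("test_fraction would leave an empty split")
  idx <- with_seed(stream_seed(seed, "split"), sample.int(n, n_test))
  list(train = survival_cohort(cohort[-idx, , drop = FALSE]),
       test = survival_cohort(cohort[sort(idx), , drop = FALSE]))
}
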