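#' Fit a Weibull accelerated-failure-time / proportional-hazards model
#'
#' Maximizes the right-censored log-likelihood
#' \deqn{\ell = \sum_{i: d_i = 1} \log h(t_i|z_i) - \sum_i H(t_i|z_i)}
#' with hazard \eqn{h(t|z) = \gamma \lambda t^{\gamma-1} e^{\beta' z}} and
#' cumulative hazard \eqn{H(t|z) = \lambda e^{\beta' z} t^{\gamma}}.  The
#' optimizer works on the unconstrained internal parameterization
#' \eqn{(\log\gamma, \log\lambda, \beta)} with an analytic gradient
#' (quasi-Newton warm start from the exponential model, Newton polishing to a
#' gradient max-norm below `gtol`).  The observed-information inverse at the
#' optimum supplies the covariance; the AFT-scale parameterization
#' (\eqn{\mu = -\log\lambda / \gamma}, \eqn{\sigma = 1/\gamma},
#' \eqn{\alpha = -\beta/\gamma}) is populated alongside the PH scale.
#'
#' @param cohort a [survival_cohort()]; `time` in days, `event` 0/1.
#' @param covariates character vector of covariate column names (already
#'   encoded: use [encode_grade()] first for the categorical grade).  May be
#'   `NULL` for an intercept-only (baseline Weibull) model.
#' @param shape optional fixed value for the shape \eqn{\gamma}; when given,
#'   only scale and coefficients are estimated (e.g. `shape = 1` fits the
#'   exponential special case).
#' @param conf_level two-sided confidence level used by downstream effect
#'   summaries; default 0.95.
#' @param control list; `maxit` (default 500), `gtol` (gradient max-norm
#'   tolerance at the optimum, default 1e-8).
#'
#' @return An object of class `weibull_aft` with elements `gamma`, `lambda`,
#'   `beta`, `mu`, `sigma`, `alpha`, `covariance` (internal scale:
#'   log-shape, log-scale, beta), `loglik`, `n`, `n_events`,
#'   `covariate_names`, `conf_level`.
#' @seealso [hazard_ratio()], [event_time_ratio()], [percentile_time()],
#'   [predict_survival()], [check_distribution()]
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_subjects = 400, seed = 3))
#' cohort <- encode_grade(cohort)
#' fit <- fit_weibull_aft(cohort, c("age", "grade2", "grade3", "rad_1"))
#' hazard_ratio(fit, "rad_1")
#' @export
fit_weibull_aft <- function(cohort, covariates = NULL, shape = NULL,
                            conf_level = 0.95, control = list()) {
  ctl <- modifyList(list(maxit = 500L, gtol = 1e-8), control)
  cohort <- as_survival_cohort(cohort)
  X <- design_matrix(cohort, covariates)
  t <- cohort$time
  d <- cohort$event
  n <- length(t)
  if (sum(d) < 1) abort_data("no events: cannot fit a survival model")
  check_full_rank(X)
  if (!is.null(shape) && (!is.finite(shape) || shape <= 0))
    abort_config("fixed shape must be > 0")

  p <- ncol(X)
  logt <- log(t)
  fixed <- !is.null(shape)
  # internal parameter vector: [log gamma,] log lambda, beta
  unpack <- function(par) {
    lg <- if (fixed) log(shape) else par[1]
    off <- if (fixed) 0L else 1L
    list(lg = lg, ll = par[off + 1L],
         b = if (p > 0) par[off + 1L + seq_len(p)] else numeric(0))
  }
  nll <- function(par) {
    q <- unpack(par)
    g <- exp(q$lg)
    eta <- if (p > 0) drop(X %*% q$b) else rep(0, n)
    H <- exp(q$ll + eta + g * logt)
    -(sum(d * (q$lg + q$ll + (g - 1) * logt + eta)) - sum(H))
  }
  gr <- function(par) {
    q <- unpack(par)
    g <- exp(q$lg)
    eta <- if (p > 0) drop(X %*% q$b) else rep(0, n)
    H <- exp(q$ll + eta + g * logt)
    g_ll <- -(sum(d) - sum(H))
    g_b <- if (p > 0) -drop(crossprod(X, d - H)) else numeric(0)
    if (fixed) c(g_ll, g_b)
    else c(-(sum(d) + g * sum(d * logt) - g * sum(H * logt)), g_ll, g_b)
  }

  par0 <- c(if (!fixed) 0, log(sum(d) / sum(t)), rep(0, p))
  opt <- optim(par0, nll, gr, method = "BFGS",
               control = list(maxit = ctl$maxit, reltol = 1e-14))
  par <- opt$par
  # Newton polish to drive the score to (near) zero
  for (it in seq_len(50)) {
    gvec <- gr(par)
    if (max(abs(gvec)) < ctl$gtol) break
    hess <- optimHess(par, nll, gr)
    step <- tryCatch(solve(hess, gvec), error = function(e) NULL)
    if (is.null(step)) break
    cand <- par - step
    # halve the step if it does not improve
    half <- 0
    while (!is.finite(nll(cand)) || nll(cand) > nll(par) + 1e-12) {
      step <- step / 2
      cand <- par - step
      half <- half + 1
      if (half > 30) break
    }
    if (max(abs(cand - par)) == 0) break
    par <- cand
  }
  gvec <- gr(par)
  if (max(abs(gvec)) > max(ctl$gtol, 1e-6))
    abort_convergence(sprintf(
      "Weibull fit did not converge (gradient max-norm %.3g)", max(abs(gvec))),
      last_iterate = par)

  hess <- optimHess(par, nll, gr)
  covariance <- tryCatch(solve(hess), error = function(e)
    abort_convergence("singular observed information at the optimum",
                      last_iterate = par))
  covariance <- (covariance + t(covariance)) / 2

  q <- unpack(par)
  gamma <- exp(q$lg)
  lambda <- exp(q$ll)
  beta <- setNames(q$b, colnames(X))
  if (fixed) {
    # embed into the full internal scale with a zero-variance shape row
    full <- matrix(0, p + 2L, p + 2L)
    full[-1L, -1L] <- covariance
    covariance <- full
  }
  dimnames(covariance) <- rep(list(c("log_gamma", "log_lambda", colnames(X))), 2)

  sigma <- 1 / gamma
  structure(list(
    gamma = gamma, lambda = lambda, beta = beta,
    mu = -sigma * log(lambda), sigma = sigma, alpha = -beta * sigma,
    covariance = covariance, loglik = -nll(par),
    n = n, n_events = sum(d), covariate_names = colnames(X),
    conf_level = conf_level, shape_fixed = fixed), class = "weibull_aft")
}

# Build the (no-intercept) design matrix from named cohort columns.
design_matrix <- function(cohort, covariates) {
  if (is.null(covariates) || length(covariates) == 0)
    return(matrix(numeric(0), nrow(cohort), 0))
  missing_cols <- setdiff(covariates, names(cohort))
  if (length(missing_cols) > 0)
    abort_data(paste0("covariate column(s) not found in cohort: ",
                      paste(missing_cols, collapse = ", "),
                      " (did you run encode_grade()?)"))
  X <- as.matrix(as.data.frame(cohort)[covariates])
  if (!is.numeric(X)) abort_data("covariates must be numeric")
  if (anyNA(X)) abort_data("covariates contain missing values; run drop_incomplete()")
  storage.mode(X) <- "double"
  X
}

check_full_rank <- function(X) {
  if (ncol(X) == 0) return(invisible(TRUE))
  const <- colnames(X)[apply(X, 2, function(v) max(v) == min(v))]
  if (length(const) > 0)
    abort_data(paste0("constant covariate column(s): ",
                      paste(const, collapse = ", ")))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    abort_data(paste0("design matrix is rank deficient; collinear column(s): ",
                      paste(bad, collapse = ", ")))
  }
  invisible(TRUE)
}

#' Convert between AFT and PH parameterizations of the Weibull model
#'
#' The two scales are linked by \eqn{\gamma = 1/\sigma},
#' \eqn{\lambda = e^{-\mu/\sigma}} and \eqn{\beta = -\alpha/\sigma}; the
#' round trip is the identity.
#'
#' @param mu AFT intercept (log-days).
#' @param sigma AFT scale, > 0.
#' @param alpha AFT-scale coefficient vector.
#' @return `aft_to_ph` returns `list(gamma, lambda, beta)`;
#'   `ph_to_aft` returns `list(mu, sigma, alpha)`.
#' @examples
#' aft_to_ph(mu = 0, sigma = 1, alpha = 0)    # gamma 1, lambda 1, beta 0
#' ph_to_aft(gamma = 2, lambda = 1, beta = 0) # sigma 0.5
#' @export
aft_to_ph <- function(mu, sigma, alpha = numeric(0)) {
  if (!is.finite(sigma) || sigma <= 0) abort_config("sigma must be > 0")
  list(gamma = 1 / sigma, lambda = exp(-mu / sigma), beta = -alpha / sigma)
}

#' @rdname aft_to_ph
#' @param gamma Weibull shape, > 0.
#' @param lambda Weibull scale, > 0.
#' @param beta PH-scale coefficient vector.
#' @export
ph_to_aft <- function(gamma, lambda, beta = numeric(0)) {
  if (!is.finite(gamma) || gamma <= 0) abort_config("gamma must be > 0")
  if (!is.finite(lambda) || lambda <= 0) abort_config("lambda must be > 0")
  sigma <- 1 / gamma
  list(mu = -sigma * log(lambda), sigma = sigma, alpha = -beta * sigma)
}

#' Assemble a `weibull_aft` model from known parameters
#'
#' Useful for closed-form work with published coefficients (no data needed):
#' the returned object supports [hazard_ratio()], [event_time_ratio()],
#' [percentile_time()], [time_ratio()] and [predict_survival()]; confidence
#' intervals are `NA` unless a covariance is supplied.
#'
#' @param gamma,lambda Weibull shape and scale.
#' @param beta named PH-scale coefficient vector.
#' @param covariance optional covariance on the internal scale
#'   (log-shape, log-scale, beta).
#' @param conf_level confidence level for derived intervals.
#' @return A `weibull_aft` object.
#' @export
weibull_aft_model <- function(gamma, lambda, beta = numeric(0),
                              covariance = NULL, conf_level = 0.95) {
  if (!is.finite(gamma) || gamma <= 0) abort_config("gamma must be > 0")
  if (!is.finite(lambda) || lambda <= 0) abort_config("lambda must be > 0")
  p <- length(beta)
  if (is.null(names(beta)) && p > 0) names(beta) <- paste0("x", seq_len(p))
  if (is.null(covariance)) covariance <- matrix(NA_real_, p + 2L, p + 2L)
  dimnames(covariance) <- rep(list(c("log_gamma", "log_lambda", names(beta))), 2)
  aft <- ph_to_aft(gamma, lambda, beta)
  structure(list(gamma = gamma, lambda = lambda, beta = beta,
                 mu = aft$mu, sigma = aft$sigma, alpha = aft$alpha,
                 covariance = covariance, loglik = NA_real_,
                 n = NA_integer_, n_events = NA_integer_,
                 covariate_names = names(beta), conf_level = conf_level,
                 shape_fixed = FALSE), class = "weibull_aft")
}

beta_index <- function(model, covariate) {
  i <- match(covariate, model$covariate_names)
  if (is.na(i)) abort_config(paste0("unknown covariate: ", covariate))
  i
}

new_effect_estimate <- function(name, estimate, ci_low, ci_high, scale) {
  structure(data.frame(name = name, estimate = estimate, ci_low = ci_low,
                       ci_high = ci_high, scale = scale,
                       stringsAsFactors = FALSE),
            class = c("effect_estimate", "data.frame"))
}

#' Hazard ratio for one covariate of a fitted Weibull model
#'
#' \eqn{HR = e^{\beta_i}}, with Wald interval
#' \eqn{\exp(\beta_i \pm z_{1-\alpha/2}\, se(\beta_i))} from the model
#' covariance.
#'
#' @param model a `weibull_aft` object.
#' @param covariate covariate name.
#' @param conf_level confidence level; defaults to the model's.
#' @return An `effect_estimate` row (`name`, `estimate`, `ci_low`,
#'   `ci_high`, `scale = "HR"`).
#' @export
hazard_ratio <- function(model, covariate, conf_level = model$conf_level) {
  i <- beta_index(model, covariate)
  b <- model$beta[i]
  se <- sqrt(model$covariance[i + 2L, i + 2L])
  z <- z_crit(conf_level)
  new_effect_estimate(covariate, exp(b),
                      exp(b - z * se), exp(b + z * se), "HR")
}

#' Event time ratio (acceleration factor) for one covariate
#'
#' \eqn{ETR = e^{-\beta_i/\gamma}}: the multiplicative change in the time at
#' which any fixed survival percentile is reached, per unit increase in the
#' covariate.  Values below 1 mean shorter survival.  The interval comes from
#' the delta method on \eqn{(\log\gamma, \beta_i)} using the joint
#' covariance: \eqn{\log ETR = -\beta_i e^{-\log\gamma}} has gradient
#' \eqn{(\beta_i/\gamma,\; -1/\gamma)}.
#'
#' @inheritParams hazard_ratio
#' @return An `effect_estimate` row with `scale = "ETR"`.
#' @export
event_time_ratio <- function(model, covariate, conf_level = model$conf_level) {
  i <- beta_index(model, covariate)
  b <- model$beta[i]
  g <- model$gamma
  log_etr <- -b / g
  idx <- c(1L, i + 2L)  # (log gamma, beta_i)
  grad <- c(b / g, -1 / g)
  v <- drop(grad %*% model$covariance[idx, idx] %*% grad)
  se <- sqrt(v)
  z <- z_crit(conf_level)
  new_effect_estimate(covariate, exp(log_etr),
                      exp(log_etr - z * se), exp(log_etr + z * se), "ETR")
}

#' Time at which a given survival probability is reached
#'
#' Inverts \eqn{S(t|z) = \exp(-\lambda e^{\beta' z} t^{\gamma})}:
#' \eqn{t_p = [-\log(p) / (\lambda e^{\beta' z})]^{1/\gamma}}, where `p` is a
#' *survival* probability (e.g. `p = 0.95` gives the time by which 5\% of
#' subjects with covariates `z` have died).  Percentile conventions vary
#' between packages; here `predict_survival(model, z, percentile_time(model,
#' z, p))` returns `p` by construction.
#'
#' @param model a `weibull_aft` object.
#' @param z covariate vector in the model's covariate order (default: none).
#' @param p survival probability strictly between 0 and 1.
#' @return Time in days.
#' @export
percentile_time <- function(model, z = numeric(0), p = 0.95) {
  if (!is.finite(p) || p <= 0 || p >= 1)
    abort_config("p must be a survival probability strictly in (0, 1)")
  (-log(p) / (model$lambda * exp(lp_at(model, z))))^(1 / model$gamma)
}

lp_at <- function(model, z) {
  p <- length(model$beta)
  if (p == 0) return(0)
  if (length(z) != p)
    abort_config(sprintf("z must have length %d (model covariates)", p))
  sum(model$beta * z)
}

#' Ratio of percentile times between two covariate profiles
#'
#' \eqn{t_p(z_1)/t_p(z_0) = e^{\beta'(z_0 - z_1)/\gamma}}; the survival
#' probability `p` cancels, so the ratio is the same for every percentile
#' (`p` is accepted for interface symmetry and ignored in the arithmetic).
#' For a unit increase in a single covariate this reduces to its
#' [event_time_ratio()].
#'
#' @param model a `weibull_aft` object.
#' @param z1,z0 covariate vectors being compared.
#' @param p survival probability in (0, 1); does not affect the result.
#' @return The time ratio (dimensionless).
#' @export
time_ratio <- function(model, z1, z0, p = 0.95) {
  if (!is.finite(p) || p <= 0 || p >= 1)
    abort_config("p must be a survival probability strictly in (0, 1)")
  exp((lp_at(model, z0) - lp_at(model, z1)) / model$gamma)
}

#' Predicted survival probabilities from a Weibull model
#'
#' \eqn{S(t|z) = \exp(-\lambda e^{\beta' z} t^{\gamma})}; equals 1 at `t = 0`
#' and is non-increasing in `t`.
#'
#' @param model a `weibull_aft` object.
#' @param z covariate vector in the model's covariate order.
#' @param times vector of non-negative times in days.
#' @return Vector of survival probabilities, one per time.
#' @export
predict_survival <- function(model, z = numeric(0), times) {
  if (any(!is.finite(times)) || any(times < 0))
    abort_config("times must be non-negative")
  exp(-model$lambda * exp(lp_at(model, z)) * times^model$gamma)
}

# survival matrix (n subjects x length(times)) for a whole cohort
survival_matrix_weibull <- function(model, cohort, times) {
  X <- design_matrix(cohort, model$covariate_names)
  eta <- if (ncol(X) > 0) drop(X %*% model$beta) else rep(0, nrow(cohort))
  exp(-outer(model$lambda * exp(eta), times^model$gamma))
}

#' Nelson-Aalen estimator of the marginal cumulative hazard
#'
#' Increment \eqn{d_i / n_i} at each distinct event time (deaths over number
#' at risk).
#'
#' @param cohort a [survival_cohort()].
#' @param times evaluation grid; defaults to the distinct event times.
#' @return data.frame with columns `time` and `cumhaz`.
#' @export
nelson_aalen <- function(cohort, times = NULL) {
  cohort <- as_survival_cohort(cohort)
  if (nrow(cohort) == 0) abort_data("empty cohort")
  et <- sort(unique(cohort$time[cohort$event == 1]))
  inc <- vapply(et, function(u)
    sum(cohort$time == u & cohort$event == 1) / sum(cohort$time >= u),
    numeric(1))
  H <- cumsum(inc)
  if (is.null(times)) return(data.frame(time = et, cumhaz = H))
  f <- stepfun(et, c(0, H))
  data.frame(time = times, cumhaz = f(times))
}

#' Parametric vs nonparametric cumulative-hazard diagnostic
#'
#' Overlays the Nelson-Aalen estimate of the marginal cumulative hazard with
#' the fitted model's population-averaged cumulative hazard
#' \eqn{-\log \bar S(t)}, \eqn{\bar S(t) = n^{-1}\sum_i S(t|z_i)}, on a shared
#' time grid — the visual goodness-of-fit check for the Weibull family
#' (both curves start at 0 and are non-decreasing; a well-specified model
#' keeps them close over the bulk of follow-up).
#'
#' @param model a fitted `weibull_aft`.
#' @param cohort the cohort the model was fitted to (or any comparable one).
#' @param times evaluation grid; defaults to the cohort's distinct event
#'   times.
#' @return An object of class `cumhaz_check`: data.frame columns `time`,
#'   `nonparametric`, `parametric`, plus attribute `max_discrepancy`.
#' @export
check_distribution <- function(model, cohort, times = NULL) {
  cohort <- as_survival_cohort(cohort)
  if (nrow(cohort) == 0) abort_data("empty cohort")
  na <- nelson_aalen(cohort, times)
  S <- survival_matrix_weibull(model, cohort, na$time)
  Hp <- -log(colMeans(S))
  out <- data.frame(time = na$time, nonparametric = na$cumhaz,
                    parametric = Hp)
  structure(out, class = c("cumhaz_check", "data.frame"),
            max_discrepancy = max(abs(out$nonparametric - out$parametric)))
}

#' @export
print.weibull_aft <- function(x, ...) {
  cat(sprintf("Weibull AFT/PH model: n = %s, events = %s, loglik = %s\n",
              x$n, x$n_events, format(x$loglik)))
  cat(sprintf("  shape gamma = %.4f%s, scale lambda = %.4g per day^gamma\n",
              x$gamma, if (isTRUE(x$shape_fixed)) " (fixed)" else "",
              x$lambda))
  if (length(x$beta) > 0) {
    se <- sqrt(diag(x$covariance)[-(1:2)])
    tab <- data.frame(coef = x$beta, `se` = se, HR = exp(x$beta),
                      ETR = exp(-x$beta / x$gamma))
    print(round(tab, 4))
  }
  invisible(x)
}
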