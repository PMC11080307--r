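#' Fit a Cox proportional hazards model to a cohort
#'
#' Semiparametric comparator to [fit_weibull_aft()]: maximizes the partial
#' likelihood (Efron tie correction by default, Breslow available) and stores
#' the Breslow baseline cumulative hazard.  The heavy lifting is done by
#' [survival::coxph()]; this wrapper enforces the cohort contract (at least
#' one event, no constant or collinear covariates) and keeps the pieces the
#' rest of the pipeline needs in one place.  The baseline hazard is centred
#' at the covariate means, the usual convention; [predict_survival_cox()]
#' un-centres at prediction time.
#'
#' @param cohort a [survival_cohort()].
#' @param covariates character vector of (already encoded, numeric) covariate
#'   columns; `NULL` fits the null model (no predictors), whose "baseline" is
#'   the marginal hazard.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return Object of class `parasurv_cox`: `beta`, `covariance`,
#'   `baseline_cumhaz` (data.frame `time`, `cumhaz`, at the covariate means),
#'   `means`, `loglik` (partial log-likelihood at the optimum), `n`,
#'   `n_events`, `ties_method`, `covariate_names`, and the underlying
#'   `coxph` fit as `$fit`.
#' @export
fit_cox <- function(cohort, covariates = NULL, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  cohort <- as_survival_cohort(cohort)
  if (sum(cohort$event) < 1) abort_data("no events: cannot fit a Cox model")
  X <- design_matrix(cohort, covariates)
  check_full_rank(X)
  dat <- data.frame(.time = cohort$time, .event = cohort$event)
  if (ncol(X) > 0) {
    dat <- cbind(dat, as.data.frame(X))
    fml <- stats::as.formula(paste(
      "survival::Surv(.time, .event) ~",
      paste(sprintf("`%s`", colnames(X)), collapse = " + ")))
  } else {
    fml <- survival::Surv(.time, .event) ~ 1
  }
  fit <- survival::coxph(fml, data = dat, ties = ties, x = TRUE, model = TRUE,
                         control = survival::coxph.control(
                           eps = 1e-11, toler.chol = 1e-12, iter.max = 50))
  p <- ncol(X)
  beta <- if (p > 0) setNames(coef(fit), colnames(X)) else numeric(0)
  if (any(!is.finite(beta)))
    abort_convergence("Cox partial-likelihood fit did not converge",
                      last_iterate = beta)
  covariance <- if (p > 0) {
    v <- vcov(fit); dimnames(v) <- list(colnames(X), colnames(X)); v
  } else matrix(numeric(0), 0, 0)
  bh <- survival::basehaz(fit, centered = TRUE)
  structure(list(
    beta = beta, covariance = covariance,
    baseline_cumhaz = data.frame(time = bh$time, cumhaz = bh$hazard),
    means = if (p > 0) setNames(fit$means, colnames(X)) else numeric(0),
    loglik = fit$loglik[length(fit$loglik)],
    n = nrow(cohort), n_events = sum(cohort$event),
    ties_method = ties, covariate_names = colnames(X),
    fit = fit), class = "parasurv_cox")
}

check_same_cohort <- function(model, cohort) {
  cohort <- as_survival_cohort(cohort)
  if (nrow(cohort) != model$n ||
      !isTRUE(all.equal(cohort$time, model$fit$model[[1]][, 1],
                        check.attributes = FALSE)))
    abort_data("cohort does not match the one the model was fitted to")
  invisible(cohort)
}

#' Schoenfeld residuals of a fitted Cox model
#'
#' One row per event (in increasing event-time order), one column per
#' covariate: the difference between the covariate of the subject failing at
#' each event time and the risk-set weighted covariate mean.  Their column
#' sums vanish at the partial-likelihood optimum (the score equation).  The
#' scaled version follows the Grambsch-Therneau convention
#' \eqn{s^*_k = \hat\beta + d \, \widehat{Var}(\hat\beta) \, s_k} with
#' \eqn{d} the number of events; a time trend in the scaled residuals
#' indicates a time-varying coefficient, i.e. non-proportional hazards.
#'
#' @param model a `parasurv_cox` fit.
#' @param cohort the cohort it was fitted to (consistency-checked).
#' @return List with `residuals` (d x p matrix), `scaled` (d x p), and
#'   `time` (the d ordered event times).
#' @export
schoenfeld_residuals <- function(model, cohort) {
  check_same_cohort(model, cohort)
  if (length(model$beta) == 0)
    abort_data("Schoenfeld residuals need at least one covariate")
  r <- residuals(model$fit, type = "schoenfeld")
  r <- as.matrix(r)
  colnames(r) <- model$covariate_names
  etimes <- sort(model$fit$model[[1]][model$fit$model[[1]][, 2] == 1, 1])
  d <- nrow(r)
  scaled <- sweep(d * r %*% model$covariance, 2, model$beta, `+`)
  colnames(scaled) <- model$covariate_names
  list(residuals = r, scaled = scaled, time = etimes)
}

#' Proportional-hazards test from scaled Schoenfeld residuals
#'
#' Score test of zero slope of the scaled Schoenfeld residuals against
#' transformed time, per covariate plus a global test — the null hypothesis
#' is that each coefficient does not vary with time.  Delegates to
#' [survival::cox.zph()].
#'
#' @param model a `parasurv_cox` fit.
#' @param transform time transform: `"km"` (default, the Kaplan-Meier
#'   transform), `"identity"` or `"rank"`.
#' @return Object of class `ph_test_result`: data.frame with columns
#'   `covariate`, `chisq`, `df`, `p` (last row `GLOBAL`), plus attribute
#'   `transform`.
#' @export
ph_test <- function(model, transform = c("km", "identity", "rank")) {
  transform <- match.arg(transform)
  if (model$n_events < 3) abort_data("need at least 3 events for the PH test")
  z <- survival::cox.zph(model$fit, transform = transform, global = TRUE)
  tab <- as.data.frame(z$table)
  out <- data.frame(covariate = rownames(tab), chisq = tab$chisq,
                    df = tab$df, p = tab$p, row.names = NULL,
                    stringsAsFactors = FALSE)
  out$covariate[out$covariate != "GLOBAL"] <- model$covariate_names
  structure(out, class = c("ph_test_result", "data.frame"),
            transform = transform)
}

#' Martingale residuals of a fitted Cox model
#'
#' \eqn{r_i = d_i - \hat H_0(t_i) e^{\hat\beta' z_i}}: observed minus
#' expected events per subject.  They sum to zero at the optimum and are
#' bounded above by 1; plotted against a continuous covariate they reveal
#' departures from log-linearity.
#'
#' @param model a `parasurv_cox` fit.
#' @param cohort the cohort it was fitted to.
#' @return Numeric vector, one residual per subject (input order).
#' @export
martingale_residuals <- function(model, cohort) {
  check_same_cohort(model, cohort)
  as.numeric(residuals(model$fit, type = "martingale"))
}

#' Predicted survival from a fitted Cox model
#'
#' \eqn{S(t|z) = \exp(-\hat H_0(t))^{\exp(\hat\beta'(z - \bar z))}} with the
#' Breslow baseline cumulative hazard \eqn{\hat H_0} stored at the covariate
#' means \eqn{\bar z}.  A right-continuous non-increasing step function;
#' times beyond the last observed time carry the last value forward and are
#' flagged in the `"extrapolated"` attribute.
#'
#' @param model a `parasurv_cox` fit.
#' @param z covariate vector on the model's covariate scale.
#' @param times non-negative times in days.
#' @return Vector of survival probabilities with logical attribute
#'   `extrapolated`.
#' @export
predict_survival_cox <- function(model, z = numeric(0), times) {
  if (any(!is.finite(times)) || any(times < 0))
    abort_config("times must be non-negative")
  p <- length(model$beta)
  if (length(z) != p)
    abort_config(sprintf("z must have length %d (model covariates)", p))
  bh <- model$baseline_cumhaz
  H0 <- stepfun(bh$time, c(0, bh$cumhaz))(times)
  lp <- if (p > 0) sum(model$beta * (z - model$means)) else 0
  s <- exp(-H0 * exp(lp))
  attr(s, "extrapolated") <- times > max(bh$time)
  s
}

# survival matrix (n x length(times)) for a whole cohort under a Cox fit
survival_matrix_cox <- function(model, cohort, times) {
  X <- design_matrix(cohort, model$covariate_names)
  bh <- model$baseline_cumhaz
  H0 <- stepfun(bh$time, c(0, bh$cumhaz))(times)
  lp <- if (ncol(X) > 0) drop(sweep(X, 2, model$means) %*% model$beta)
        else rep(0, nrow(cohort))
  exp(-outer(exp(lp), H0))
}

#' @export
print.parasurv_cox <- function(x, ...) {
  cat(sprintf("Cox PH model (%s ties): n = %d, events = %d, loglik = %s\n",
              x$ties_method, x$n, x$n_events, format(x$loglik)))
  if (length(x$beta) > 0) {
    se <- sqrt(diag(x$covariance))
    print(round(data.frame(coef = x$beta, se = se, HR = exp(x$beta)), 4))
  }
  invisible(x)
}
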