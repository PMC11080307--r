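#' Reverse Kaplan-Meier censoring survival function
#'
#' Product-limit estimator with the roles of event and censoring swapped:
#' \eqn{\hat G(t) = \prod_{u \le t} (1 - c_u / r_u)} over distinct censoring
#' times \eqn{u}, with \eqn{c_u} censorings at \eqn{u} and \eqn{r_u} subjects
#' still under observation at \eqn{u}.  At tied times events are taken to
#' precede censorings, and case weights downstream use the left limit
#' \eqn{G(t^-)}, the standard IPCW conventions.  \eqn{G(0) = 1} and `G` is
#' non-increasing.
#'
#' @param cohort a [survival_cohort()] with at least 2 subjects.
#' @return Object of class `censoring_weights`: list with `time` and `surv`
#'   (the step locations/values), and functions `G(t)` (right-continuous)
#'   and `G_minus(t)` (left limit).
#' @export
censoring_weights <- function(cohort) {
  cohort <- as_survival_cohort(cohort)
  if (nrow(cohort) < 2) abort_data("need at least 2 subjects")
  tm <- cohort$time
  cens <- cohort$event == 0
  ct <- sort(unique(tm[cens]))
  if (length(ct) == 0) {
    G <- function(t) rep(1, length(t))
    return(structure(list(time = numeric(0), surv = numeric(0),
                          G = G, G_minus = G), class = "censoring_weights"))
  }
  surv <- cumprod(vapply(ct, function(u)
    1 - sum(tm == u & cens) / sum(tm >= u), numeric(1)))
  structure(list(
    time = ct, surv = surv,
    G = stepfun(ct, c(1, surv)),
    G_minus = stepfun(ct, c(1, surv), right = TRUE)),
    class = "censoring_weights")
}

new_metric_curve <- function(times, values, lower = NA_real_,
                             upper = NA_real_, metric, model_label,
                             undefined = NULL) {
  out <- data.frame(model = model_label, metric = metric, time = times,
                    value = values, lower = lower, upper = upper,
                    stringsAsFactors = FALSE)
  structure(out, class = c("metric_curve", "data.frame"),
            undefined = if (is.null(undefined)) rep(FALSE, length(times))
                        else undefined)
}

# shared IPCW weight computation; errors if G is exhausted where needed
ipcw_weights <- function(cohort, t, cw) {
  tm <- cohort$time
  ev <- cohort$event
  alive <- tm > t
  case <- tm <= t & ev == 1
  g_t <- cw$G(t)
  g_case <- cw$G_minus(tm[case])
  if (g_t <= 0 || any(g_case <= 0))
    abort_data(paste0(
      "censoring survival reaches 0 before t = ", format(t),
      "; truncate the evaluation grid"))
  w <- numeric(length(tm))
  w[alive] <- 1 / g_t
  w[case] <- 1 / g_case
  list(w = w, alive = alive, case = case)
}

#' IPCW Brier score curve
#'
#' Graf-style censoring-corrected prediction error: at each grid time `t`,
#' \deqn{BS(t) = n^{-1} \sum_i w_i(t)\,(1\{T_i > t\} - \hat S(t|z_i))^2}
#' with weights \eqn{w_i(t) = 1\{T_i \le t, d_i = 1\}/\hat G(T_i^-) +
#' 1\{T_i > t\}/\hat G(t)}.  Zero for a perfect forecaster on uncensored
#' data; 0.25 for the constant-1/2 forecaster at the median.
#'
#' @param surv matrix of predicted survival probabilities, one row per
#'   subject and one column per grid time (a single row/vector is recycled
#'   across subjects).
#' @param cohort the evaluation [survival_cohort()].
#' @param times strictly increasing evaluation grid (days).
#' @param model_label label stored in the curve.
#' @param weights optional precomputed [censoring_weights()].
#' @return A `metric_curve` data.frame (`model`, `metric`, `time`, `value`,
#'   `lower`, `upper`).
#' @export
brier_curve <- function(surv, cohort, times, model_label = "model",
                        weights = NULL) {
  cohort <- as_survival_cohort(cohort)
  n <- nrow(cohort)
  times <- check_grid(times)
  surv <- as_pred_matrix(surv, n, length(times))
  cw <- if (is.null(weights)) censoring_weights(cohort) else weights
  vals <- vapply(seq_along(times), function(j) {
    ww <- ipcw_weights(cohort, times[j], cw)
    mean(ww$w * (as.numeric(ww$alive) - surv[, j])^2)
  }, numeric(1))
  new_metric_curve(times, vals, metric = "brier", model_label = model_label)
}

#' IPCW time-dependent AUC curve (cumulative cases / dynamic controls)
#'
#' At each grid time `t`, cases are subjects with an observed event by `t`
#' (weighted \eqn{1/\hat G(T_i^-)}) and controls are subjects still at risk
#' beyond `t`; the curve value is the weighted probability that a random
#' case carries a higher risk score than a random control, ties counting
#' one half.  Times with no cases or no controls get `NA` and are flagged in
#' the `"undefined"` attribute rather than dropped.
#'
#' @param risk matrix of risk scores (higher = riskier), one row per subject
#'   and one column per grid time; a plain vector is treated as a
#'   time-constant score.
#' @inheritParams brier_curve
#' @return A `metric_curve` with attribute `undefined`.
#' @export
auc_curve <- function(risk, cohort, times, model_label = "model",
                      weights = NULL) {
  cohort <- as_survival_cohort(cohort)
  n <- nrow(cohort)
  times <- check_grid(times)
  risk <- as_pred_matrix(risk, n, length(times))
  cw <- if (is.null(weights)) censoring_weights(cohort) else weights
  undef <- logical(length(times))
  vals <- vapply(seq_along(times), function(j) {
    ww <- ipcw_weights(cohort, times[j], cw)
    if (!any(ww$case) || !any(ww$alive)) {
      undef[j] <<- TRUE
      return(NA_real_)
    }
    rc <- risk[ww$case, j]
    rk <- risk[ww$alive, j]
    wi <- ww$w[ww$case]
    conc <- outer(rc, rk, `>`) + 0.5 * outer(rc, rk, `==`)
    sum(wi * rowSums(conc)) / (sum(wi) * length(rk))
  }, numeric(1))
  new_metric_curve(times, vals, metric = "auc", model_label = model_label,
                   undefined = undef)
}

check_grid <- function(times) {
  if (any(!is.finite(times)) || any(times < 0))
    abort_config("grid times must be non-negative and finite")
  if (is.unsorted(times, strictly = TRUE))
    abort_config("grid times must be strictly increasing")
  times
}

as_pred_matrix <- function(x, n, m) {
  if (is.null(dim(x))) {
    if (length(x) == n) x <- matrix(x, n, m)       # time-constant per subject
    else abort_config("prediction vector must have one entry per subject")
  }
  x <- as.matrix(x)
  if (nrow(x) == 1) x <- x[rep(1, n), , drop = FALSE]  # shared curve
  if (nrow(x) != n || ncol(x) != m)
    abort_config("prediction matrix must be n_subjects x n_times")
  x
}

#' Null-model (covariate-free) reference curve
#'
#' Feeds the marginal Kaplan-Meier survival curve through [brier_curve()] as
#' the prediction for every subject.  For `metric = "auc"` a constant score
#' cannot rank subjects, so the curve is all-`NA` with every time flagged
#' undefined.
#'
#' @param cohort the evaluation [survival_cohort()].
#' @param times evaluation grid.
#' @param metric `"brier"` or `"auc"`.
#' @return A `metric_curve` labelled `"null"`.
#' @export
null_model_curve <- function(cohort, times, metric = c("brier", "auc")) {
  metric <- match.arg(metric)
  cohort <- as_survival_cohort(cohort)
  times <- check_grid(times)
  if (metric == "auc")
    return(new_metric_curve(times, rep(NA_real_, length(times)),
                            metric = "auc", model_label = "null",
                            undefined = rep(TRUE, length(times))))
  km <- survival::survfit(survival::Surv(time, event) ~ 1,
                          data = as.data.frame(cohort))
  S <- stepfun(km$time, c(1, km$surv))(times)
  brier_curve(matrix(S, 1), cohort, times, model_label = "null")
}

#' Default metric evaluation grid
#'
#' Quantiles 0.05-0.95 of the observed event times in `n_points` steps,
#' truncated to times where the reverse-KM censoring survival exceeds
#' `g_floor` (weights blow up as G approaches 0).
#'
#' @param cohort a [survival_cohort()].
#' @param n_points number of grid points (default 20).
#' @param probs range of event-time quantiles spanned (default 0.05-0.95).
#' @param g_floor minimum admissible censoring survival (default 0.1).
#' @return Strictly increasing numeric grid.
#' @export
default_time_grid <- function(cohort, n_points = 20, probs = c(0.05, 0.95),
                              g_floor = 0.1) {
  cohort <- as_survival_cohort(cohort)
  et <- cohort$time[cohort$event == 1]
  if (length(et) < 2) abort_data("too few events to build a time grid")
  grid <- unique(as.numeric(quantile(et, seq(probs[1], probs[2],
                                             length.out = n_points))))
  cw <- censoring_weights(cohort)
  keep <- cw$G(grid) > g_floor
  if (!any(keep)) abort_data("censoring exhausts follow-up on the whole grid")
  grid[keep]
}

#' Bootstrap bands for a metric curve
#'
#' Resamples subjects with replacement, refits via `refitter` on each
#' replicate, evaluates the metric on that replicate, and summarizes
#' pointwise as mean +/- sd across replicates.  Replicates that draw zero
#' events are redrawn (total draws capped at `10 * B`).  Deterministic given
#' `seed`.
#'
#' @param refitter `function(cohort, times)` returning the matrix of
#'   predicted survival probabilities (subjects x times) from a model
#'   refitted to `cohort`.
#' @param cohort the [survival_cohort()] to resample.
#' @param times evaluation grid.
#' @param metric `"brier"` or `"auc"` (AUC uses risk `1 - surv`).
#' @param B number of bootstrap replicates (default 10; use 200+ for real
#'   inference — 10 mirrors a quick-look setting and is visibly noisy).
#' @param seed integer seed.
#' @param model_label label stored in the curve.
#' @return A `metric_curve` with `value` = pointwise mean, `lower`/`upper` =
#'   mean -/+ sd, attribute `replicates` (B x n_times matrix) and
#'   `n_redrawn`.
#' @export
bootstrap_curves <- function(refitter, cohort, times,
                             metric = c("brier", "auc"), B = 10, seed = 1,
                             model_label = "model") {
  metric <- match.arg(metric)
  cohort <- as_survival_cohort(cohort)
  times <- check_grid(times)
  if (B < 1) abort_config("B must be at least 1")
  n <- nrow(cohort)
  reps <- matrix(NA_real_, B, length(times))
  redrawn <- 0L
  with_seed(stream_seed(seed, "bootstrap"), {
    b <- 1L
    attempts <- 0L
    while (b <= B) {
      attempts <- attempts + 1L
      if (attempts > 10L * B)
        abort_data("too many all-censored bootstrap replicates; enlarge the cohort")
      idx <- sample.int(n, n, replace = TRUE)
      boot <- survival_cohort(cohort[idx, , drop = FALSE])
      if (sum(boot$event) == 0) {
        redrawn <- redrawn + 1L
        next
      }
      surv <- refitter(boot, times)
      crv <- if (metric == "brier") brier_curve(surv, boot, times)
             else auc_curve(1 - as_pred_matrix(surv, n, length(times)),
                            boot, times)
      reps[b, ] <- crv$value
      b <- b + 1L
    }
  })
  m <- colMeans(reps)
  s <- apply(reps, 2, sd)
  s[is.na(s)] <- 0
  out <- new_metric_curve(times, m, lower = m - s, upper = m + s,
                          metric = metric, model_label = model_label)
  attr(out, "replicates") <- reps
  attr(out, "n_redrawn") <- redrawn
  out
}
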