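#' Fit a two-parameter distribution to uncensored death times
#'
#' Maximum likelihood for one of three candidate families for positive
#' survival times: Weibull (shape/scale), log-normal (meanlog/sdlog) or
#' log-logistic (shape/scale).  Intended for the uncensored-deaths subset of
#' a cohort (censored follow-up times carry different information and are
#' excluded by design from this marginal check).  Weibull fitting delegates
#' to [fitdistrplus::fitdist()]; the log-normal MLE is closed form (note the
#' maximum-likelihood variance uses the n denominator, so an all-equal
#' sample gives sdlog exactly 0); the log-logistic MLE is a two-parameter
#' numerical optimization over log-parameters using the flexsurv density.
#'
#' @param times vector of strictly positive death times (days), `n >= 5`.
#' @param family `"weibull"`, `"lognormal"` or `"loglogistic"`.
#' @return Object of class `univariate_fit`: `family`, `params` (named
#'   pair), `loglik`, `n`.
#' @export
fit_univariate <- function(times,
                           family = c("weibull", "lognormal", "loglogistic")) {
  family <- match.arg(family)
  if (length(times) == 0 || any(!is.finite(times)) || any(times <= 0))
    abort_data("times must be strictly positive and finite")
  n <- length(times)
  if (n < 5 && family != "lognormal")
    abort_data("need at least 5 observations")
  if (family == "lognormal") {
    m <- mean(log(times))
    s <- sqrt(mean((log(times) - m)^2))
    ll <- if (s > 0) sum(dlnorm(times, m, s, log = TRUE)) else Inf
    params <- c(meanlog = m, sdlog = s)
  } else if (family == "weibull") {
    f <- fitdistrplus::fitdist(times, "weibull")
    params <- c(shape = unname(f$estimate["shape"]),
                scale = unname(f$estimate["scale"]))
    ll <- f$loglik
  } else {
    nll <- function(par)
      -sum(flexsurv::dllogis(times, shape = exp(par[1]), scale = exp(par[2]),
                             log = TRUE))
    opt <- optim(c(log(1.5), log(median(times))), nll, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-12))
    params <- c(shape = exp(opt$par[1]), scale = exp(opt$par[2]))
    ll <- -opt$value
  }
  structure(list(family = family, params = params, loglik = ll, n = n),
            class = "univariate_fit")
}

# distribution functions of a univariate_fit
fit_cdf <- function(fit) {
  p <- fit$params
  switch(fit$family,
    weibull = function(x) pweibull(x, p[["shape"]], p[["scale"]]),
    lognormal = function(x) plnorm(x, p[["meanlog"]], p[["sdlog"]]),
    loglogistic = function(x) flexsurv::pllogis(x, shape = p[["shape"]],
                                                scale = p[["scale"]]))
}

fit_quantile <- function(fit) {
  p <- fit$params
  switch(fit$family,
    weibull = function(q) qweibull(q, p[["shape"]], p[["scale"]]),
    lognormal = function(q) qlnorm(q, p[["meanlog"]], p[["sdlog"]]),
    loglogistic = function(q) flexsurv::qllogis(q, shape = p[["shape"]],
                                                scale = p[["scale"]]))
}

#' Kolmogorov-Smirnov statistic against a fitted distribution
#'
#' \eqn{D = \max_i \max\{i/n - F(x_{(i)}),\; F(x_{(i)}) - (i-1)/n\}} over the
#' sorted sample, with the p-value from the asymptotic Kolmogorov
#' distribution (`method = "asymptotic"`).  Because the parameters were
#' estimated from the same data, this plain KS p-value is anti-conservative
#' (the Lilliefors effect); `method = "bootstrap"` refits on parametric
#' resamples to calibrate it.
#'
#' @param times positive sample.
#' @param fit a [fit_univariate()] result.
#' @param method `"asymptotic"` (default) or `"bootstrap"`.
#' @param n_boot bootstrap replicates when `method = "bootstrap"`.
#' @param seed seed for the bootstrap draw.
#' @return List with `D` and `p_value`.
#' @export
ks_statistic <- function(times, fit, method = c("asymptotic", "bootstrap"),
                         n_boot = 500, seed = 1) {
  method <- match.arg(method)
  if (length(times) == 0) abort_data("empty sample")
  if (any(!is.finite(times)) || any(times <= 0))
    abort_data("times must be strictly positive and finite")
  n <- length(times)
  Fx <- fit_cdf(fit)(sort(times))
  i <- seq_len(n)
  D <- max(pmax(i / n - Fx, Fx - (i - 1) / n))
  if (method == "asymptotic") {
    p <- kolmogorov_pvalue(D, n)
  } else {
    qf <- fit_quantile(fit)
    p <- with_seed(stream_seed(seed, "ks_boot"), {
      d_star <- vapply(seq_len(n_boot), function(b) {
        x <- qf(runif(n))
        f <- fit_univariate(x, fit$family)
        Fb <- fit_cdf(f)(sort(x))
        max(pmax(i / n - Fb, Fb - (i - 1) / n))
      }, numeric(1))
      mean(d_star >= D)
    })
  }
  list(D = D, p_value = p)
}

# asymptotic Kolmogorov tail probability P(sqrt(n) D > x)
kolmogorov_pvalue <- function(D, n) {
  x <- sqrt(n) * D
  if (x < 1e-8) return(1)
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * x^2))
  min(max(p, 0), 1)
}

#' Q-Q and P-P plot coordinates against a fitted distribution
#'
#' Plotting positions \eqn{(i - 0.5)/n}.  Q-Q: theoretical quantiles at the
#' plotting positions against the sorted sample.  P-P: fitted CDF at the
#' sorted sample against the plotting positions.  Both coordinate sets are
#' sorted ascending; points near the 1:1 line indicate a good fit.
#'
#' @param times positive sample.
#' @param fit a [fit_univariate()] result.
#' @return List of two data.frames, `qq` and `pp`, each with columns
#'   `theoretical` and `empirical`.
#' @export
qq_pp_points <- function(times, fit) {
  if (length(times) == 0) abort_data("empty sample")
  if (any(!is.finite(times)) || any(times <= 0))
    abort_data("times must be strictly positive and finite")
  n <- length(times)
  pos <- (seq_len(n) - 0.5) / n
  x <- sort(times)
  list(qq = data.frame(theoretical = fit_quantile(fit)(pos), empirical = x),
       pp = data.frame(theoretical = fit_cdf(fit)(x), empirical = pos))
}

#' @export
print.univariate_fit <- function(x, ...) {
  cat(sprintf("%s fit (n = %d): %s; loglik = %s\n", x$family, x$n,
              paste(names(x$params), signif(x$params, 6), sep = " = ",
                    collapse = ", "), format(x$loglik)))
  invisible(x)
}
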