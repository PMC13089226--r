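#' Ordinary least squares fit of a log-linear allometry
#'
#' Fits `y = slope * x + intercept` by OLS, where `x` and `y` are already
#' log10-transformed by the caller. The Gaussian maximum-likelihood
#' log-likelihood (sigma^2 = RSS/n) feeds the AICc with k = 3 parameters
#' (slope, intercept, residual variance).
#'
#' @param x,y Numeric vectors of equal length >= 3 (log10 scale).
#' @return A list of class `log_linear_fit`: `slope`, `intercept`, `n`,
#'   `r_squared`, `loglik`, `aicc`, `method = "OLS"`, `predict` (a function
#'   of new x), and the underlying `lm` fit.
#' @export
fit_log_linear_ols <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L,
            all(is.finite(x)), all(is.finite(y)))
  if (stats::var(x) == 0) stop("zero variance in x; slope is unidentifiable")
  fit <- stats::lm(y ~ x, data = data.frame(x = x, y = y))
  co <- stats::coef(fit)
  ll <- as.numeric(stats::logLik(fit))
  n <- length(x)
  # summary.lm warns on noiseless data ("essentially perfect fit"); exact
  # recovery is an intended use here
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(list(slope = unname(co[2L]), intercept = unname(co[1L]), n = n,
                 r_squared = r2, loglik = ll,
                 aicc = aicc(ll, k = 3L, n = n), method = "OLS",
                 predict = function(xnew) unname(co[1L] + co[2L] * xnew),
                 lm_fit = fit),
            class = "log_linear_fit")
}

#' @export
print.log_linear_fit <- function(x, ...) {
  cat(sprintf("<log_linear_fit %s> slope %.4f, intercept %.4f, n = %d",
              x$method, x$slope, x$intercept, x$n))
  if (!is.null(x$r_squared)) cat(sprintf(", R^2 = %.4f", x$r_squared))
  cat(sprintf(", AICc = %.2f\n", x$aicc))
  invisible(x)
}

#' Sample-size corrected Akaike Information Criterion
#'
#' `AICc = -2 loglik + 2k + 2k(k + 1)/(n - k - 1)`; requires
#' `n - k - 1 > 0`. Straight-line Gaussian models count k = 3 parameters
#' (slope, intercept, residual variance); the four-parameter log-logistic
#' counts k = 5.
#'
#' @param loglik Maximized log-likelihood.
#' @param k Number of estimated parameters (including residual variance).
#' @param n Sample size.
#' @return The AICc value.
#' @export
aicc <- function(loglik, k, n) {
  if (n - k - 1 <= 0) {
    stop(sprintf("AICc undefined: n - k - 1 = %d must be positive", n - k - 1))
  }
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Four-parameter log-logistic fit
#'
#' Fits `y = c + (d - c) / (1 + (x/e)^b)` by least squares, reported in the
#' form used for the skull-to-neck ratio curve: `numerator = d - c` (the
#' logistic rise), `scale = e` (the predictor value at the midpoint),
#' `exponent = b` (steepness), and `offset = c` (the lower asymptote added
#' outside the fraction). Optimization runs a fixed, documented multi-start
#' grid (scale at the x quantiles 0.25/0.5/0.75, exponent in
#' 1, 2, 5, 10, 20) through box-constrained BFGS, then polishes the best
#' start with Levenberg-Marquardt, making fits deterministic.
#'
#' @param x Positive predictor values (e.g. log10 cervical count), n >= 6.
#' @param y Response values.
#' @param starts Optional data frame of start points with columns `e`, `b`
#'   (overrides the default grid).
#' @return A list of class `log_logistic_fit`: `numerator`, `scale`,
#'   `exponent`, `offset`, `d` (upper asymptote `offset + numerator`), `n`,
#'   `loglik`, `aicc`, `rss`, `degenerate` flag, and `predict`.
#' @export
fit_log_logistic <- function(x, y, starts = NULL) {
  stopifnot(length(x) == length(y), length(x) >= 6L, all(x > 0),
            all(is.finite(x)), all(is.finite(y)))
  n <- length(x)
  ll4 <- function(x, c, d, e, b) c + (d - c) / (1 + (x / e)^b)
  obj <- function(p) {
    r <- y - ll4(x, p[1L], p[2L], exp(p[3L]), exp(p[4L]))
    sum(r * r)
  }
  if (is.null(starts)) {
    starts <- expand.grid(e = stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE),
                          b = c(1, 2, 5, 10, 20))
  }
  c0 <- y[which.max(x)]
  d0 <- y[which.min(x)]
  if (abs(d0 - c0) < .Machine$double.eps) d0 <- c0 + 1
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    p0 <- c(c0, d0, log(starts$e[i]), log(starts$b[i]))
    res <- tryCatch(
      stats::optim(p0, obj, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-14)),
      error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$value < best$value)) best <- res
  }
  if (is.null(best)) stop("log-logistic fit failed to converge from any start")
  p <- best$par
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ c + (d - c) / (1 + (x / e)^b),
      data = data.frame(x = x, y = y),
      start = list(c = p[1L], d = p[2L], e = exp(p[3L]), b = exp(p[4L])),
      lower = c(-Inf, -Inf, 1e-10, 1e-10),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-15,
                                           ptol = 1e-15)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    co <- stats::coef(fit)
    rss <- sum(stats::resid(fit)^2)
    if (rss > best$value) { # keep whichever route found the lower RSS
      co <- c(c = p[1L], d = p[2L], e = exp(p[3L]), b = exp(p[4L]))
      rss <- best$value
    }
  } else {
    co <- c(c = p[1L], d = p[2L], e = exp(p[3L]), b = exp(p[4L]))
    rss <- best$value
  }
  sigma2 <- rss / n
  loglik <- if (sigma2 > 0) {
    -n / 2 * (log(2 * pi * sigma2) + 1)
  } else {
    Inf
  }
  # flat over the observed range: either d ~ c, or the transition sits
  # entirely outside the data so the rise is unidentifiable
  yhat <- co[["c"]] + (co[["d"]] - co[["c"]]) / (1 + (x / co[["e"]])^co[["b"]])
  degenerate <- (max(yhat) - min(yhat)) <
    1e-8 * max(1, abs(co[["d"]]), abs(co[["c"]]))
  if (degenerate) warning("degenerate log-logistic fit: d ~ c (flat curve)")
  structure(list(numerator = co[["d"]] - co[["c"]], scale = co[["e"]],
                 exponent = co[["b"]], offset = co[["c"]],
                 d = co[["d"]], n = n, rss = rss, loglik = loglik,
                 aicc = if (is.finite(loglik)) aicc(loglik, 5L, n) else -Inf,
                 degenerate = degenerate,
                 predict = function(xnew) {
                   co[["c"]] + (co[["d"]] - co[["c"]]) / (1 + (xnew / co[["e"]])^co[["b"]])
                 }),
            class = "log_logistic_fit")
}

#' @export
print.log_logistic_fit <- function(x, ...) {
  cat(sprintf(
    "<log_logistic_fit> y = %.4f + %.4f / (1 + (x/%.4f)^%.4f), n = %d, RSS = %.3g\n",
    x$offset, x$numerator, x$scale, x$exponent, x$n, x$rss))
  invisible(x)
}

#' Leave-one-out percent prediction error
#'
#' Each sample is iteratively removed; the model is refitted on the
#' remaining n - 1 samples and used to predict the removed one. Observed
#' and predicted values are compared on the antilog (arithmetic) scale:
#' `|%PE| = |(observed - predicted)/predicted| * 100`. The summary reports
#' the mean |%PE| and its standard deviation (N - 1 denominator).
#'
#' @param x Predictor (model scale, e.g. log10).
#' @param y Response (model scale).
#' @param fitter Function `(x_train, y_train)` returning a prediction
#'   function of new x on the model scale. Defaults to the OLS fitter.
#' @param back_transform Function mapping model scale to the comparison
#'   scale (default antilog10; use `identity` for untransformed responses).
#' @return A list of class `prediction_error_summary`: `mean_abs_pe`,
#'   `sd_abs_pe`, `per_sample_pe`, `n`.
#' @export
loo_prediction_error <- function(x, y,
                                 fitter = function(xt, yt) fit_log_linear_ols(xt, yt)$predict,
                                 back_transform = function(v) 10^v) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 3L)
  pe <- vapply(seq_len(n), function(i) {
    pred_fun <- fitter(x[-i], y[-i])
    predicted <- back_transform(pred_fun(x[i]))
    observed <- back_transform(y[i])
    if (!is.finite(predicted) || predicted <= 0) {
      stop(sprintf("non-positive predicted value for sample %d on the antilog scale", i))
    }
    abs((observed - predicted) / predicted) * 100
  }, numeric(1))
  structure(list(mean_abs_pe = mean(pe),
                 sd_abs_pe = if (n > 1L) stats::sd(pe) else 0,
                 per_sample_pe = pe, n = n),
            class = "prediction_error_summary")
}

#' @export
print.prediction_error_summary <- function(x, ...) {
  cat(sprintf("<prediction_error_summary> mean |%%PE| = %.2f, sd = %.2f, N = %d\n",
              x$mean_abs_pe, x$sd_abs_pe, x$n))
  invisible(x)
}

#' Symmetric back-transformed prediction interval
#'
#' On the antilog scale the mean |%PE| defines a symmetric error range
#' around a prediction: `point * (1 +/- mean_abs_pe/100)`.
#'
#' @param point_antilog Predicted value on the antilog scale (> 0).
#' @param mean_abs_pe Mean absolute percent prediction error (>= 0).
#' @return A list of class `prediction_interval`: `point`, `lower`, `upper`.
#' @export
prediction_interval <- function(point_antilog, mean_abs_pe) {
  stopifnot(point_antilog > 0, mean_abs_pe >= 0)
  structure(list(point = point_antilog,
                 lower = point_antilog * (1 - mean_abs_pe / 100),
                 upper = point_antilog * (1 + mean_abs_pe / 100)),
            class = "prediction_interval")
}

#' @export
print.prediction_interval <- function(x, ...) {
  cat(sprintf("%.4g  [%.4g, %.4g]\n", x$point, x$lower, x$upper))
  invisible(x)
}
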