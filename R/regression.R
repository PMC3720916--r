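#' Fit a log-linear or log-log line to a colony-size distribution
#'
#' Fits one of the two regression families used to smooth colony-size
#' frequency data by ordinary least squares on base-10 log-transformed
#' frequencies:
#' \describe{
#'   \item{`log_linear`}{\eqn{\log_{10} y = a\,n + b} (exponential decay
#'     of frequency with size),}
#'   \item{`log_log`}{\eqn{\log_{10} y = a \log_{10} n + b} (power-law
#'     decay).}
#' }
#' \eqn{R^2} is computed on the transformed scale. The AIC is the
#' least-squares form \eqn{N \ln(\mathrm{RSS}/N) + 2K} with \eqn{K = 3}
#' (slope, intercept, residual variance); an inferred 1-cell point may be
#' included in the fit (`include_f1 = TRUE`) but is always excluded from
#' the AIC, which is meant to compare families on observed data only.
#'
#' @param dist A [colony_size_distribution()] with at least 3 strictly
#'   positive frequencies.
#' @param family `"log_log"` or `"log_linear"`.
#' @param include_f1 Include the estimated `n = 1` point in the fit?
#'   (Ignored when the distribution has no estimated 1-cell class.)
#' @return An object of class `regression_fit` with elements `family`, `a`
#'   (slope), `b` (intercept), `r2`, `aic`, `n_points`, `aic_sizes` (the
#'   sizes entering the AIC), `model` (the underlying `lm`), and `data`.
#' @examples
#' d <- colony_size_distribution("0", n = 1:15,
#'        frequency = 10^(1.02 - 1.28 * log10(1:15)))
#' fit <- fit_size_distribution(d, "log_log")
#' c(fit$a, fit$b, fit$r2)  # -1.28, 1.02, 1
#' @export
fit_size_distribution <- function(dist, family = c("log_log", "log_linear"),
                                  include_f1 = TRUE) {
  stopifnot(inherits(dist, "colony_dist"))
  family <- match.arg(family)
  est <- dist$f1_estimated & dist$n == 1L
  keep <- rep(TRUE, length(dist$n))
  if (!include_f1) keep <- keep & !est
  n <- dist$n[keep]
  f <- dist$frequency[keep]
  if (any(f <= 0)) stop("all frequencies entering a log fit must be > 0")
  if (length(n) < 3L) stop("at least 3 points are required for a fit")
  x <- if (family == "log_log") log10(n) else n
  y <- log10(f)
  df <- data.frame(x = x, y = y)
  model <- lm(y ~ x, data = df)
  r2 <- suppressWarnings(summary(model)$r.squared)  # exact fits are legitimate here
  if (all(abs(y - mean(y)) < 1e-12)) r2 <- 0   # flat-data convention
  # AIC over observed points only (estimated f1 never contributes)
  aic_keep <- !est[keep]
  res <- y[aic_keep] - predict(model, newdata = data.frame(x = x[aic_keep]))
  N <- sum(aic_keep)
  aic <- N * log(sum(res^2) / N) + 2 * 3
  structure(list(family = family, a = unname(coef(model)[2L]),
                 b = unname(coef(model)[1L]), r2 = r2, aic = aic,
                 n_points = length(n), aic_sizes = n[aic_keep],
                 model = model,
                 data = data.frame(n = n, frequency = f, estimated = est[keep]),
                 dose = dist$dose, include_f1 = include_f1),
            class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  eq <- if (x$family == "log_log") "log y = a log x + b" else "log y = a x + b"
  cat("Regression fit (", x$family, "): ", eq, "\n", sep = "")
  cat(sprintf("  a = %.4g, b = %.4g, R2 = %.4g, AIC = %.4g (%d points)\n",
              x$a, x$b, x$r2, x$aic, x$n_points))
  invisible(x)
}

#' Predicted mean frequency of a fit at given colony sizes
#'
#' @param object A `regression_fit`.
#' @param n Colony sizes (cells) at which to evaluate the fitted line.
#' @param ... Unused.
#' @return Predicted frequencies (percent), back-transformed from the log
#'   scale.
#' @export
predict.regression_fit <- function(object, n, ...) {
  x <- if (object$family == "log_log") log10(n) else n
  10^unname(predict(object$model, newdata = data.frame(x = x)))
}

#' 95% confidence limits of the mean response of a fit
#'
#' Confidence band for the mean log-frequency at each size, using the
#' t-distribution with `N - 2` degrees of freedom, back-transformed to the
#' frequency (percent) scale. The band is symmetric on the transformed
#' scale and narrowest at the centroid of the design points.
#'
#' @param fit A `regression_fit` built from at least 3 points.
#' @param n Colony sizes at which to evaluate the band.
#' @param level Confidence level (default 0.95).
#' @return A data frame with columns `n`, `fit`, `lower`, `upper`
#'   (frequencies in percent).
#' @export
confidence_band <- function(fit, n, level = 0.95) {
  stopifnot(inherits(fit, "regression_fit"))
  if (fit$n_points < 3L) stop("a confidence band requires at least 3 fitted points")
  if (any(n < 1)) stop("colony sizes must be >= 1")
  x <- if (fit$family == "log_log") log10(n) else n
  ci <- predict(fit$model, newdata = data.frame(x = x),
                interval = "confidence", level = level)
  data.frame(n = n, fit = 10^ci[, "fit"], lower = 10^ci[, "lwr"],
             upper = 10^ci[, "upr"])
}

#' Select the better regression family by AIC
#'
#' Compares fits of the same observation set and returns the one with the
#' minimal AIC. Fits must have been computed on identical observed sizes
#' (the AIC point sets must match), otherwise their AICs are not
#' comparable. Exact ties are resolved in favour of the first fit supplied
#' and flagged.
#'
#' @param fits A list of two or more `regression_fit` objects.
#' @return A list with `selected` (the winning fit), `family`, `aic`
#'   (named vector of AIC values) and `tie` (logical).
#' @examples
#' # Table-style comparison: smaller AIC wins
#' @export
aic_compare <- function(fits) {
  if (length(fits) < 2L) stop("at least two fits are required")
  stopifnot(all(vapply(fits, inherits, logical(1), "regression_fit")))
  sizes <- lapply(fits, function(f) f$aic_sizes)
  if (!all(vapply(sizes, identical, logical(1), sizes[[1L]])))
    stop("fits were computed on different observation sets; AICs are not comparable")
  aics <- vapply(fits, function(f) f$aic, numeric(1))
  names(aics) <- vapply(fits, function(f) f$family, character(1))
  best <- which.min(aics)                     # first minimum wins on ties
  tie <- sum(abs(aics - aics[best]) < 1e-12) > 1L
  list(selected = fits[[best]], family = fits[[best]]$family, aic = aics,
       tie = tie)
}
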