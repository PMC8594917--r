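#' Gamma log-likelihood of positive signal samples
#'
#' Sum of log gamma densities `log P(z; k, theta)` with shape `k` and
#' scale `theta` over the samples.  Used to model the distribution of
#' FM1-43 readily-releasable-pool signals, a proxy for presynaptic
#' release probability.
#'
#' @param samples positive signal values.
#' @param k shape parameter (`> 0`).
#' @param theta scale parameter (`> 0`).
#' @return The log-likelihood (finite for valid inputs).
#' @export
#' @examples
#' gamma_loglik(1, k = 1, theta = 1)  # exponential density at 1: -1
gamma_loglik <- function(samples, k, theta) {
  if (length(samples) < 1 || any(!is.finite(samples)) || any(samples <= 0))
    stop("samples must be positive and finite")
  if (!is.finite(k) || k <= 0 || !is.finite(theta) || theta <= 0)
    stop("k and theta must be positive")
  sum(stats::dgamma(samples, shape = k, scale = theta, log = TRUE))
}

new_gamma_fit <- function(k, theta, loglik, n, fixed_mean = NULL) {
  structure(list(k = k, theta = theta, loglik = loglik, n = n,
                 fixed_mean = fixed_mean),
            class = "gamma_fit")
}

#' Gamma distribution from known parameters
#'
#' Wraps a `(k, theta)` pair as a `gamma_fit` object so that known
#' release-probability distributions can be fed to the samplers and
#' protocols without refitting.
#'
#' @param k,theta gamma shape and scale.
#' @return An object of class `"gamma_fit"` (with `loglik = NA`).
#' @seealso [fm_gamma_fits()] for the three fitted FM1-43 distributions.
#' @export
gamma_fit <- function(k, theta) {
  stopifnot(k > 0, theta > 0)
  new_gamma_fit(k, theta, NA_real_, NA_integer_)
}

#' The fitted FM1-43 release-probability distributions
#'
#' The three gamma distributions fitted to FM1-43
#' readily-releasable-pool signal measurements in cultured hippocampal
#' neurons: `control` (CNQX only), `AP5` (CNQX + AP5, a narrower
#' distribution), and `AP5_with_control_mean` (the AP5 data refit with
#' the mean constrained to the control mean, isolating the variance
#' change).  Signals divided by 140 (the maximal observed signal) give
#' release probabilities.
#'
#' @return A named list of three [gamma_fit] objects.
#' @export
#' @examples
#' sapply(fm_gamma_fits(), function(f) f$k * f$theta / 140)  # mean U_SE
fm_gamma_fits <- function() {
  list(control = gamma_fit(k = 1.40, theta = 26.5),
       AP5 = gamma_fit(k = 3.12, theta = 10.1),
       AP5_with_control_mean = gamma_fit(k = 2.94, theta = 12.6))
}

# profile log-likelihood in k (theta profiled out analytically or fixed
# by the mean constraint)
profile_loglik_k <- function(k, samples, fixed_mean = NULL) {
  theta <- if (is.null(fixed_mean)) mean(samples) / k else fixed_mean / k
  gamma_loglik(samples, k, theta)
}

fit_gamma_core <- function(samples, fixed_mean = NULL) {
  if (length(samples) < 10)
    stop("at least 10 samples are required for a stable gamma fit")
  if (any(!is.finite(samples)) || any(samples <= 0))
    stop("samples must be positive and finite")
  if (stats::var(samples) == 0)
    stop("degenerate sample: all values equal")
  # method-of-moments start, then 1-D profile-likelihood maximisation
  k_mom <- mean(samples)^2 / stats::var(samples)
  lo <- k_mom / 100
  hi <- k_mom * 100
  opt <- stats::optimize(profile_loglik_k, interval = c(lo, hi),
                         samples = samples, fixed_mean = fixed_mean,
                         maximum = TRUE, tol = 1e-10)
  k <- opt$maximum
  theta <- if (is.null(fixed_mean)) mean(samples) / k else fixed_mean / k
  new_gamma_fit(k, theta, opt$objective, length(samples), fixed_mean)
}

#' Maximum-likelihood gamma fit
#'
#' Fits a gamma distribution to positive signal samples by maximising
#' the likelihood.  The scale is profiled out analytically
#' (`theta = mean(samples)/k` at the optimum), leaving a robust
#' one-dimensional maximisation in the shape `k`.
#'
#' @param samples positive signal values (`n >= 10`).
#' @return A [gamma_fit] object with elements `k`, `theta`, `loglik`,
#'   `n` and `fixed_mean` (`NULL` here).
#' @seealso [fit_gamma_mle_fixed_mean()], [gamma_loglik()]
#' @export
#' @examples
#' set.seed(1)
#' fit_gamma_mle(rgamma(500, shape = 2, scale = 5))
fit_gamma_mle <- function(samples) {
  fit_gamma_core(samples, fixed_mean = NULL)
}

#' Mean-constrained maximum-likelihood gamma fit
#'
#' Fits a gamma distribution under the constraint `k * theta = mean`,
#' maximising the likelihood over the one-parameter family
#' `theta = mean / k`.  Used to refit a condition's signal distribution
#' while pinning its mean to the control mean, so that only the
#' distribution's width differs.
#'
#' @inheritParams fit_gamma_mle
#' @param mean the fixed distribution mean (`> 0`), signal units.
#' @return A [gamma_fit] object; `k * theta` equals `mean` exactly.
#' @export
fit_gamma_mle_fixed_mean <- function(samples, mean) {
  stopifnot(is.numeric(mean), length(mean) == 1L, mean > 0)
  fit_gamma_core(samples, fixed_mean = mean)
}

#' Sample release probabilities from a fitted signal distribution
#'
#' Draws signals `z ~ gamma(k, theta)` and maps them to release
#' probabilities `U_SE = z / z_max`, with `z_max = 140` (the maximal
#' observed FM1-43 signal).  Draws exceeding `z_max` are clipped to
#' `U_SE = 1` by default (the tail mass is tiny for the fitted
#' distributions); `tail = "resample"` redraws them instead.
#'
#' @param fit a [gamma_fit].
#' @param n number of draws (`>= 1`).
#' @param seed optional integer seed (applied with `set.seed`); when
#'   `NULL` the current RNG state is used.
#' @param z_max normalising maximal signal.
#' @param tail `"clip"` (default) or `"resample"`.
#' @return A vector of `n` release probabilities in `[0, 1]`.
#' @export
#' @examples
#' u <- sample_release_prob(fm_gamma_fits()$control, 5, seed = 1)
sample_release_prob <- function(fit, n, seed = NULL, z_max = 140,
                                tail = c("clip", "resample")) {
  stopifnot(inherits(fit, "gamma_fit"), n >= 1, z_max > 0)
  tail <- match.arg(tail)
  if (!is.null(seed)) set.seed(seed)
  z <- stats::rgamma(n, shape = fit$k, scale = fit$theta)
  if (tail == "resample") {
    while (any(bad <- z > z_max))
      z[bad] <- stats::rgamma(sum(bad), shape = fit$k, scale = fit$theta)
  }
  pmin(z / z_max, 1)
}

#' @export
print.gamma_fit <- function(x, ...) {
  cat("Gamma fit")
  if (!is.null(x$fixed_mean))
    cat(sprintf(" (mean constrained to %.4g)", x$fixed_mean))
  cat("\n")
  cat(sprintf("  shape k = %.4g, scale theta = %.4g (mean %.4g)\n",
              x$k, x$theta, x$k * x$theta))
  if (is.finite(x$loglik))
    cat(sprintf("  log-likelihood %.4f on n = %d samples\n", x$loglik, x$n))
  invisible(x)
}

#' @export
coef.gamma_fit <- function(object, ...) {
  c(shape = object$k, scale = object$theta)
}

#' @export
logLik.gamma_fit <- function(object, ...) {
  ll <- object$loglik
  attr(ll, "df") <- if (is.null(object$fixed_mean)) 2L else 1L
  attr(ll, "nobs") <- object$n
  class(ll) <- "logLik"
  ll
}

#' @export
simulate.gamma_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  stats::rgamma(nsim, shape = object$k, scale = object$theta)
}

#' Read a one-column CSV of signal values
#'
#' @param path CSV file with one numeric column (header optional).
#' @return A numeric vector.
#' @export
read_signals_csv <- function(path) {
  x <- utils::read.csv(path, header = FALSE,
                       stringsAsFactors = FALSE)[[1]]
  suppressWarnings(v <- as.numeric(x))
  v[!is.na(v)]
}

#' Write a gamma fit record as JSON
#'
#' @param fit a [gamma_fit].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gamma_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "gamma_fit"))
  rec <- list(k = fit$k, theta = fit$theta, loglik = fit$loglik,
              fixed_mean = fit$fixed_mean, n = fit$n)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
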