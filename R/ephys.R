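#' Assemble a paired-pulse sweep series
#'
#' A tidy record of a paired-pulse experiment for one or more inputs:
#' per sweep, the amplitudes (positive magnitudes, pA) of the two EPSCs
#' evoked 50 ms apart, the input label and the period
#' (`"baseline"`/`"drug"`).  Sweeps are sampled every 30 s, so a
#' 20-sweep period spans 10 min.
#'
#' @param sweep sweep index within the period.
#' @param epsc1,epsc2 EPSC amplitudes, pA (`> 0`).
#' @param input_id input label.
#' @param period `"baseline"` or `"drug"`.
#' @return A data frame of class `"sweep_series"`.
#' @export
sweep_series <- function(sweep, epsc1, epsc2, input_id = "input1",
                         period = "baseline") {
  stopifnot(all(epsc1 > 0), all(epsc2 > 0))
  df <- data.frame(sweep = sweep, epsc1 = epsc1, epsc2 = epsc2,
                   input_id = input_id, period = period,
                   stringsAsFactors = FALSE)
  class(df) <- c("sweep_series", "data.frame")
  df
}

#' Paired-pulse ratios from binned sweeps
#'
#' PPR per bin of `bin_size` consecutive sweeps within each period:
#' `mean(epsc2) / mean(epsc1)` over the bin.  The period summaries are
#' the averages of the last four complete bins of each period (with 20
#' sweeps per period that is exactly the four bins spanning 10 min),
#' and `delta_ppr` is the drug-period average minus the baseline
#' average.  An incomplete final bin is dropped with a warning.
#'
#' @param series a [sweep_series()] for a single input.
#' @param bin_size sweeps per bin.
#' @return A list with `bins` (data frame `period`, `bin`, `ppr`),
#'   `baseline_ppr`, `post_ppr` and `delta_ppr` (`NA` when a period is
#'   absent).
#' @export
#' @examples
#' s <- sweep_series(1:20, rep(100, 20), rep(150, 20))
#' compute_ppr(s)$baseline_ppr  # 1.5
compute_ppr <- function(series, bin_size = 5) {
  stopifnot(is.data.frame(series), bin_size >= 1)
  if (length(unique(series$input_id)) > 1)
    stop("compute_ppr() expects a single input; see ppr_stats()")
  per_period <- function(period) {
    d <- series[series$period == period, , drop = FALSE]
    if (!nrow(d)) return(NULL)
    if (nrow(d) < bin_size)
      stop("fewer than one full bin of sweeps in period '", period, "'")
    d <- d[order(d$sweep), , drop = FALSE]
    n_bins <- nrow(d) %/% bin_size
    if (nrow(d) %% bin_size != 0)
      warning("dropping incomplete final bin in period '", period, "'")
    idx <- rep(seq_len(n_bins), each = bin_size)
    d <- d[seq_len(n_bins * bin_size), , drop = FALSE]
    ppr <- vapply(seq_len(n_bins), function(b)
      mean(d$epsc2[idx == b]) / mean(d$epsc1[idx == b]), numeric(1))
    data.frame(period = period, bin = seq_len(n_bins), ppr = ppr,
               stringsAsFactors = FALSE)
  }
  bins <- rbind(per_period("baseline"), per_period("drug"))
  avg4 <- function(period) {
    p <- bins$ppr[bins$period == period]
    if (!length(p)) return(NA_real_)
    mean(utils::tail(p, 4))
  }
  baseline <- avg4("baseline")
  post <- avg4("drug")
  list(bins = bins, baseline_ppr = baseline, post_ppr = post,
       delta_ppr = post - baseline)
}

#' Single-Gaussian fit of a PPR sample
#'
#' Maximum-likelihood Gaussian fit of the PPR values (`mu` the sample
#' mean, `sigma` the ML standard deviation with denominator `n`) —
#' equivalent to fitting a single Gaussian to the PPR histogram without
#' bin-width sensitivity.  `method = "binned"` instead least-squares
#' fits a Gaussian curve to histogram counts, for parity with
#' figure-style fits.
#'
#' @param pprs PPR values (`n >= 5`).
#' @param method `"mle"` (default) or `"binned"`.
#' @param breaks histogram breaks for `method = "binned"` (passed to
#'   [hist()]).
#' @return A list with `mu` and `sigma`.
#' @export
fit_gaussian_to_ppr <- function(pprs, method = c("mle", "binned"),
                                breaks = "Sturges") {
  method <- match.arg(method)
  if (length(pprs) < 5) stop("at least 5 PPR values are required")
  if (stats::var(pprs) == 0) stop("degenerate sample: zero variance")
  if (method == "mle") {
    mu <- mean(pprs)
    sigma <- sqrt(mean((pprs - mu)^2))
    return(list(mu = mu, sigma = sigma))
  }
  h <- graphics::hist(pprs, breaks = breaks, plot = FALSE)
  obj <- function(par) {
    sum((h$density - stats::dnorm(h$mids, par[1], exp(par[2])))^2)
  }
  o <- stats::optim(c(mean(pprs), log(stats::sd(pprs))), obj)
  list(mu = o$par[1], sigma = exp(o$par[2]))
}

#' One-tailed F test for reduced variance
#'
#' Tests whether the second sample (the experimental condition) has a
#' smaller variance than the first (the baseline):
#' `F = var(a)/var(b)` with the one-tailed p value
#' `P(F_{na-1, nb-1} >= F)` for the alternative `var(b) < var(a)`.
#'
#' @param pprs_a baseline sample (`n >= 3`).
#' @param pprs_b experimental sample (`n >= 3`).
#' @return A list with `F`, `p` (one-tailed), `df` and the two sample
#'   variances.
#' @export
#' @examples
#' variance_f_test(rnorm(30, sd = 0.4), rnorm(30, sd = 0.2))
variance_f_test <- function(pprs_a, pprs_b) {
  if (length(pprs_a) < 3 || length(pprs_b) < 3)
    stop("both samples need at least 3 values")
  va <- stats::var(pprs_a)
  vb <- stats::var(pprs_b)
  if (va == 0 || vb == 0) stop("zero variance in a sample")
  ft <- stats::var.test(pprs_a, pprs_b, alternative = "greater")
  list(F = unname(ft$statistic), p = ft$p.value,
       df = unname(ft$parameter), var_a = va, var_b = vb)
}

#' One-tailed Brown-Forsythe (Levene) test for reduced variance
#'
#' Robust alternative to [variance_f_test()]: a one-tailed two-sample t
#' test on the absolute deviations from each sample's median, testing
#' whether the second sample's deviations are smaller (its spread
#' reduced).  Less sensitive to non-normal tails than the F test.
#'
#' @inheritParams variance_f_test
#' @return A list with `statistic` (t), `p` (one-tailed) and `df`.
#' @export
variance_levene_test <- function(pprs_a, pprs_b) {
  if (length(pprs_a) < 3 || length(pprs_b) < 3)
    stop("both samples need at least 3 values")
  da <- abs(pprs_a - stats::median(pprs_a))
  db <- abs(pprs_b - stats::median(pprs_b))
  if (stats::var(da) == 0 && stats::var(db) == 0)
    stop("zero spread in both samples")
  tt <- stats::t.test(da, db, alternative = "greater")
  list(statistic = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter))
}

#' Regression of the PPR change on the baseline PPR
#'
#' Least-squares fit of `delta_ppr = post - baseline` against the
#' baseline PPR across inputs, with Pearson's correlation and the
#' x-axis intercept of the fitted line (`-intercept/slope`).  A
#' negative slope with an x-intercept near the baseline mean PPR is the
#' signature of a variance change without a mean change (some inputs
#' strengthen, others weaken, pivoting about the mean).
#'
#' @param baseline_pprs,post_pprs paired per-input PPR values
#'   (`n >= 3`).
#' @return A list with `slope`, `intercept`, `x_intercept`,
#'   `pearson_r`, `p` (correlation test p value) and `n`.  When the
#'   PPR change has zero variance the correlation is undefined and
#'   `pearson_r`/`p` are `NA` with `slope = 0`.
#' @export
delta_ppr_regression <- function(baseline_pprs, post_pprs) {
  n <- length(baseline_pprs)
  if (n < 3 || length(post_pprs) != n)
    stop("need paired baseline/post PPRs for at least 3 inputs")
  if (stats::var(baseline_pprs) == 0)
    stop("zero spread in baseline PPRs")
  d <- post_pprs - baseline_pprs
  if (stats::var(d) == 0) {
    return(list(slope = 0, intercept = unique(d)[1], x_intercept = NA_real_,
                pearson_r = NA_real_, p = NA_real_, n = n))
  }
  fit <- stats::lm(d ~ baseline_pprs)
  ct <- stats::cor.test(baseline_pprs, d)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  list(slope = slope, intercept = intercept,
       x_intercept = -intercept / slope,
       pearson_r = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Inverse squared coefficient of variation of EPSC amplitudes
#'
#' `CV^-2 = (mean/sd)^2` of the first EPSC amplitude over the last 20
#' sweeps of each period, and the post/baseline ratio — a classical
#' indicator of presynaptic change.
#'
#' @param series a [sweep_series()] for a single input with both
#'   periods.
#' @param n_sweeps sweeps per window.
#' @return A list with `cv2_inv_baseline`, `cv2_inv_post` and `ratio`.
#' @export
inverse_cv_squared <- function(series, n_sweeps = 20) {
  stopifnot(is.data.frame(series))
  win <- function(period) {
    d <- series[series$period == period, , drop = FALSE]
    if (nrow(d) < n_sweeps)
      stop("period '", period, "' has fewer than ", n_sweeps, " sweeps")
    x <- utils::tail(d$epsc1[order(d$sweep)], n_sweeps)
    if (stats::sd(x) == 0) stop("zero amplitude SD in period '", period, "'")
    (mean(x) / stats::sd(x))^2
  }
  b <- win("baseline")
  p <- win("drug")
  list(cv2_inv_baseline = b, cv2_inv_post = p, ratio = p / b)
}

#' Paired-pulse ratio disparity between two inputs
#'
#' The absolute PPR difference between two independent inputs
#' converging on the same neuron — a pairwise proxy for presynaptic
#' strength heterogeneity.
#'
#' @param ppr_a,ppr_b PPR values (`> 0`).
#' @return `|ppr_a - ppr_b|`.
#' @export
#' @examples
#' ppr_disparity(1.8, 2.2)  # 0.4
ppr_disparity <- function(ppr_a, ppr_b) {
  stopifnot(all(ppr_a > 0), all(ppr_b > 0))
  abs(ppr_a - ppr_b)
}

#' Full PPR statistics pipeline over a multi-input sweep table
#'
#' Runs the per-input PPR computation ([compute_ppr()]) and CV^-2
#' ([inverse_cv_squared()]) over every input of a sweep table, then the
#' population statistics: Gaussian fits of the baseline and drug PPR
#' samples, the one-tailed F test for reduced variance, the paired t
#' test of the means, and the regression of the PPR change on the
#' baseline PPR.
#'
#' @param sweeps a data frame with columns `sweep`, `epsc1`, `epsc2`,
#'   `input_id`, `period` (as produced by [gen_epsc_experiment()] or
#'   read from CSV).
#' @param bin_size sweeps per PPR bin.
#' @param var_test `"f"` (default) for the one-tailed F test or
#'   `"levene"` for the Brown-Forsythe alternative.
#' @return An object of class `"ppr_summary"`: a list with `per_input`
#'   (data frame of per-input baseline/post PPR, delta PPR and CV^-2
#'   ratio), `gaussian_baseline`, `gaussian_post`, `f_test`,
#'   `mean_test` (paired t test), and `regression`.
#' @export
ppr_stats <- function(sweeps, bin_size = 5, var_test = c("f", "levene")) {
  var_test <- match.arg(var_test)
  stopifnot(is.data.frame(sweeps),
            all(c("sweep", "epsc1", "epsc2", "input_id", "period") %in%
                  names(sweeps)))
  ids <- unique(sweeps$input_id)
  rows <- lapply(ids, function(id) {
    d <- sweeps[sweeps$input_id == id, , drop = FALSE]
    pp <- compute_ppr(d, bin_size = bin_size)
    cv <- tryCatch(inverse_cv_squared(d), error = function(e) NULL)
    data.frame(input_id = id, baseline_ppr = pp$baseline_ppr,
               post_ppr = pp$post_ppr, delta_ppr = pp$delta_ppr,
               cv2_inv_ratio = if (is.null(cv)) NA_real_ else cv$ratio,
               stringsAsFactors = FALSE)
  })
  per_input <- do.call(rbind, rows)
  base <- per_input$baseline_ppr
  post <- per_input$post_ppr
  out <- list(per_input = per_input,
              gaussian_baseline = fit_gaussian_to_ppr(base),
              gaussian_post = fit_gaussian_to_ppr(post),
              f_test = if (var_test == "f") variance_f_test(base, post)
                       else variance_levene_test(base, post),
              mean_test = stats::t.test(base, post, paired = TRUE),
              regression = delta_ppr_regression(base, post))
  class(out) <- "ppr_summary"
  out
}

#' @export
print.ppr_summary <- function(x, ...) {
  n <- nrow(x$per_input)
  cat(sprintf("PPR statistics over %d inputs\n", n))
  cat(sprintf("  baseline: mean %.3f, sd %.3f; post: mean %.3f, sd %.3f\n",
              x$gaussian_baseline$mu, x$gaussian_baseline$sigma,
              x$gaussian_post$mu, x$gaussian_post$sigma))
  if (!is.null(x$f_test$F)) {
    cat(sprintf("  variance F test (one-tailed, reduction): F = %.3f, p = %.4g\n",
                x$f_test$F, x$f_test$p))
  } else {
    cat(sprintf("  variance test (one-tailed, reduction): t = %.3f, p = %.4g\n",
                x$f_test$statistic, x$f_test$p))
  }
  cat(sprintf("  mean change (paired t): p = %.4g\n", x$mean_test$p.value))
  r <- x$regression
  cat(sprintf("  dPPR ~ baseline: slope %.3f, r = %.3f, x-intercept %.3f\n",
              r$slope, r$pearson_r, r$x_intercept))
  invisible(x)
}
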