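# Diagnostic battery: estimator bias under truncation, normalized
# background differences between methods, index-of-dispersion outlier
# selection, Poisson median-bound checks, and the zero-background
# pathology rate.

#' Index of dispersion
#'
#' Sample variance over sample mean.  For Poisson data the expectation
#' is 1 (with variance roughly `2/N` for sample size `N`); values much
#' larger than 1 flag over-dispersion, i.e. pixels not all drawn from
#' one Poisson distribution -- a simple detector for outlier-bearing
#' shoeboxes.
#'
#' @param y Counts, at least 2 values.
#' @return `var(y) / mean(y)`, or `NA` (with a warning) when the mean
#'   is zero.
#' @export
index_of_dispersion <- function(y) {
  if (length(y) < 2) stop("need at least 2 values")
  m <- mean(y)
  if (m == 0) {
    warning("index of dispersion undefined for all-zero data")
    return(NA_real_)
  }
  var(y) / m
}

#' Select shoeboxes with over-dispersed backgrounds
#'
#' Returns the subset of shoeboxes whose background-pixel index of
#' dispersion exceeds `threshold` (all-zero backgrounds never qualify).
#'
#' @param dataset List of shoeboxes.
#' @param threshold Dispersion cut, > 1 (default 5).
#' @return The selected subset, with a logical attribute `"selected"`
#'   marking the original positions.
#' @export
select_outlier_shoeboxes <- function(dataset, threshold = 5) {
  if (threshold <= 1) stop("`threshold` must exceed 1")
  sel <- vapply(dataset, function(sb) {
    y <- background_counts(sb)
    m <- mean(y)
    length(y) >= 2 && m > 0 && var(y) / m > threshold
  }, logical(1))
  out <- dataset[sel]
  class(out) <- class(dataset)
  attr(out, "selected") <- sel
  out
}

#' Exact bias of the symmetrically truncated Poisson mean
#'
#' Expectation of the trimmed mean of `n` i.i.d. Poisson(`lambda`)
#' values with `floor(fraction * n)` order statistics removed from each
#' end, minus `lambda`.  Computed from the order-statistic identity
#' `E[Y_(j)] = sum_t P(Y_(j) > t)` with
#' `P(Y_(j) <= t) = P(Binom(n, F(t)) >= j)` and `F` the Poisson CDF
#' (the regularized incomplete gamma function), summed over a support
#' window with negligible tail.  With no trimming the bias is exactly
#' zero; with trimming it is nonzero because the Poisson distribution is
#' asymmetric, and it shrinks relative to `lambda` as `lambda` grows and
#' the distribution symmetrizes.
#'
#' @param lambda Positive Poisson mean.
#' @param fraction Trim fraction per end, in `[0, 0.5)`.
#' @param n Sample size (>= 3).
#' @return The bias `E[trimmed mean] - lambda`.
#' @export
truncated_estimator_bias <- function(lambda, fraction, n) {
  if (lambda <= 0) stop("`lambda` must be positive")
  if (fraction < 0 || fraction >= 0.5) stop("`fraction` must lie in [0, 0.5)")
  if (n < 3) stop("`n` must be at least 3")
  k <- floor(fraction * n)
  if (k == 0) return(0)
  tmax <- ceiling(lambda + 20 * sqrt(lambda) + 50)
  Ft <- ppois(0:tmax, lambda)
  js <- (k + 1):(n - k)
  # E[Y_(j)] = sum_t (1 - P(Y_(j) <= t)) = sum_t pbinom(j - 1, n, F(t))
  e_order <- vapply(js, function(j) sum(pbinom(j - 1, n, Ft)), numeric(1))
  mean(e_order) - lambda
}

#' Normalized difference between two background estimates
#'
#' `(est_method - est_null) / se` with
#' `se = sqrt(max(est_null, eps) / n_bg)` and `eps = 1/(2 n_bg)`: the
#' Poisson standard error of the no-outlier-handling estimate, floored
#' so empty backgrounds stay finite.  Negative values mean the method
#' estimates a lower background than using all pixels.
#'
#' @param est_method Background estimate under some outlier strategy.
#' @param est_null Background estimate with no outlier handling.
#' @param n_bg Number of background pixels.
#' @return The normalized difference (vectorized).
#' @export
normalized_difference <- function(est_method, est_null, n_bg) {
  if (any(n_bg < 1)) stop("`n_bg` must be at least 1")
  if (any(est_null < 0)) stop("`est_null` must be non-negative")
  eps <- 1 / (2 * n_bg)
  (est_method - est_null) / sqrt(pmax(est_null, eps) / n_bg)
}

#' Poisson median-bound check of a background estimate
#'
#' For Poisson(`lambda`) the median `m` satisfies
#' `lambda - log(2) <= m < lambda + 1/3`, hence a sound estimate of
#' `lambda` must satisfy
#' `estimate - median(y) in [-log(2), 1/3]` up to sampling noise.  The
#' interval is widened by `z` times a plug-in standard error for
#' `estimate - median(y)`:
#' `z * sqrt((1 + pi/2) * max(estimate, eps) / n)`, combining the
#' Poisson variance of the estimate (`lambda/n`) with the asymptotic
#' variance of a sample median (`~ (pi/2) lambda / n`).  A grossly
#' inflated estimate -- e.g. a mean dragged up by a hot pixel -- fails
#' the check.
#'
#' @param estimate Background estimate (counts/pixel).
#' @param y The background pixel counts the estimate was computed from.
#' @param z Widening multiplier (default 3).
#' @return `TRUE` if the estimate is consistent with the median bounds.
#' @export
median_bound_check <- function(estimate, y, z = 3) {
  if (length(y) == 0) stop("empty input")
  n <- length(y)
  d <- estimate - median(y)
  tol <- z * sqrt((1 + pi / 2) * max(estimate, 1 / (2 * n)) / n)
  d >= -log(2) - tol && d <= 1 / 3 + tol
}

#' Background estimate of one shoebox by any method
#'
#' Dispatcher used by the diagnostics and the command line: applies one
#' of the seven strategies to the background pixels of a shoebox and
#' reports a scalar background level (for the plane methods, the value
#' at the peak position, i.e. the mean background).
#'
#' @param sb A `"shoebox"`.
#' @param method One of `"null"`, `"truncated"`, `"nsigma"`, `"tukey"`,
#'   `"plane"`, `"normal"`, `"glm"`.
#' @param params Named list of method parameters (`fraction`, `N`,
#'   `trim_fraction`, `range_factor`, `model`, `config`).
#' @return `list(estimate =, detail =)` where `detail` is the
#'   `"bg_filter"` or `"bg_fit"` object.
#' @export
background_estimate <- function(sb, method = c("glm", "null", "truncated",
                                               "nsigma", "tukey", "plane",
                                               "normal"),
                                params = list()) {
  method <- match.arg(method)
  y <- background_counts(sb)
  p <- params
  detail <- switch(method,
    null = filter_null(y),
    truncated = filter_truncated(y, fraction = p$fraction %||% 0.05),
    nsigma = filter_nsigma(y, N = p$N %||% 3),
    tukey = filter_tukey(y, N = p$N %||% 1.5),
    plane = filter_plane(y, background_coords(sb),
                         trim_fraction = p$trim_fraction %||% 0.1,
                         N = p$N %||% 4),
    normal = filter_normal(y, range_factor = p$range_factor %||% 1),
    glm = {
      model <- p$model %||% "constant"
      config <- p$config %||% robust_fit_config()
      if (identical(model, "constant")) constant_background_fit(y, config)
      else robust_glm_fit(y, model_spec("planar"), background_coords(sb),
                          config)
    })
  estimate <- if (inherits(detail, "bg_fit")) {
    if (detail$degenerate) 0 else exp(detail$beta[1])
  } else if (method == "plane") unname(detail$background["a"])
  else detail$background
  list(estimate = estimate, detail = detail)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fraction of shoeboxes with an exactly zero background estimate
#'
#' Percentage of shoeboxes that contain at least one nonzero background
#' pixel yet whose background estimate is exactly zero -- which can only
#' happen when the outlier strategy rejected every nonzero pixel.  The
#' robust GLM and the no-rejection method are immune by construction;
#' rejection-based methods collapse this way at very low background.
#'
#' @param dataset List of shoeboxes.
#' @param method Method name, as [background_estimate()].
#' @param params Method parameters.
#' @return Percentage in `[0, 100]` (NA if no shoebox has a nonzero
#'   pixel).
#' @export
zero_background_fraction <- function(dataset, method, params = list()) {
  if (length(dataset) == 0) stop("empty dataset")
  est <- vapply(dataset, function(sb)
    background_estimate(sb, method, params)$estimate, numeric(1))
  nonzero <- vapply(dataset, function(sb)
    any(background_counts(sb) > 0), logical(1))
  if (!any(nonzero)) return(NA_real_)
  100 * mean(est[nonzero] == 0)
}

#' Multi-method background comparison experiment
#'
#' Simulates `n_replicates` shoeboxes per scenario and estimates the
#' background of every shoebox with every requested method -- the same
#' shoeboxes are shared across methods, so differences are purely
#' methodological.  Per scenario and method it reports the mean
#' normalized difference against the no-rejection estimate, the
#' zero-background percentage, the percentage of median-bound
#' violations, and the mean bias against the simulation truth.
#'
#' @param scenarios A [shoebox_spec()] or (optionally named) list of
#'   them.
#' @param methods Character vector of method names.
#' @param n_replicates Shoeboxes per scenario.
#' @param seed Master seed; the experiment is fully deterministic given
#'   it.
#' @param params Named list of per-method parameter lists, e.g.
#'   `list(truncated = list(fraction = 0.05))`.
#' @param keep_histograms Attach the per-shoebox normalized differences
#'   as attribute `"normalized_differences"` (a named list of numeric
#'   vectors) for histogramming.
#' @return Data frame with one row per scenario x method:
#'   `scenario`, `method`, `n_shoeboxes`, `mean_normalized_difference`,
#'   `zero_background_pct`, `median_bound_violation_pct`, `mean_bias`.
#' @export
run_comparison <- function(scenarios,
                           methods = c("null", "truncated", "nsigma",
                                       "tukey", "plane", "normal", "glm"),
                           n_replicates = 1000, seed = 1L,
                           params = list(), keep_histograms = FALSE) {
  if (inherits(scenarios, "shoebox_spec")) scenarios <- list(scenarios)
  if (length(scenarios) == 0 || length(methods) == 0)
    stop("need at least one scenario and one method")
  if (is.null(names(scenarios)))
    names(scenarios) <- paste0("scenario", seq_along(scenarios))
  rows <- list()
  hists <- list()
  for (s in seq_along(scenarios)) {
    spec <- scenarios[[s]]
    ds <- simulate_dataset(n_replicates, spec, seed = sub_seed(seed, s))
    ys <- lapply(ds, background_counts)
    n_bg <- lengths(ys)
    est_null <- vapply(ys, mean, numeric(1))
    medians <- vapply(ys, median, numeric(1))
    truth_mean <- if (length(spec$background) == 1) spec$background
                  else mean(background_mean_grid(spec)[build_mask(spec) ==
                                                         MASK_BACKGROUND])
    for (method in methods) {
      p <- params[[method]] %||% list()
      est <- if (method == "glm" &&
                 identical(p$model %||% "constant", "constant")) {
        Y <- do.call(rbind, ys)
        fit_constant_batch(Y, p$config %||% robust_fit_config())$mu
      } else if (method == "null") {
        est_null
      } else {
        vapply(ds, function(sb)
          background_estimate(sb, method, p)$estimate, numeric(1))
      }
      nd <- normalized_difference(est, est_null, n_bg)
      nonzero <- est_null > 0
      viol <- !mapply(median_bound_check, est, ys)
      rows[[length(rows) + 1]] <- data.frame(
        scenario = names(scenarios)[s],
        method = method,
        n_shoeboxes = n_replicates,
        mean_normalized_difference = mean(nd),
        zero_background_pct =
          if (any(nonzero)) 100 * mean(est[nonzero] == 0) else NA_real_,
        median_bound_violation_pct = 100 * mean(viol),
        mean_bias = mean(est) - truth_mean)
      if (keep_histograms)
        hists[[paste(names(scenarios)[s], method, sep = ".")]] <- nd
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (keep_histograms) attr(out, "normalized_differences") <- hists
  out
}
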