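# Traditional background strategies used by integration programs.  Each
# returns a "bg_filter" object: which background pixels were kept, and
# the background estimate computed from the survivors.

new_filter_result <- function(retained, background, method,
                              degenerate = FALSE) {
  structure(list(retained = retained,
                 background = background,
                 method = method,
                 n_rejected = sum(!retained),
                 degenerate = degenerate),
            class = "bg_filter")
}

#' @export
print.bg_filter <- function(x, ...) {
  cat("Background filter '", x$method, "': ", sum(x$retained),
      " pixels retained, ", x$n_rejected, " rejected\n", sep = "")
  if (is.null(names(x$background)))
    cat("  background:", format(x$background, digits = 6), "counts/pixel\n")
  else
    cat("  plane (a, b, c):", format(x$background, digits = 6), "\n")
  invisible(x)
}

#' Background with no outlier handling
#'
#' Retains every pixel; the background is the sample mean.
#'
#' @param y Non-negative counts of the background pixels.
#' @return A `"bg_filter"` result.
#' @export
filter_null <- function(y) {
  if (length(y) == 0) stop("empty input: no background pixels")
  new_filter_result(rep(TRUE, length(y)), mean(y), "null")
}

#' Symmetrically truncated background
#'
#' Sorts the pixel values and discards `floor(fraction * n)` pixels from
#' each end (ties broken by stable sort order), then averages the rest.
#' Because the Poisson distribution is asymmetric, this symmetric trim
#' biases the estimate even on outlier-free data; see
#' [truncated_estimator_bias()].
#'
#' @param y Non-negative counts.
#' @param fraction Fraction trimmed from each end, in `[0, 0.5)`.
#' @return A `"bg_filter"` result.
#' @export
filter_truncated <- function(y, fraction = 0.05) {
  if (length(y) == 0) stop("empty input: no background pixels")
  if (fraction < 0 || fraction >= 0.5)
    stop("`fraction` must lie in [0, 0.5)")
  n <- length(y)
  k <- floor(fraction * n)
  retained <- rep(TRUE, n)
  if (k > 0) {
    ord <- order(y)  # stable
    retained[ord[c(seq_len(k), n + 1 - seq_len(k))]] <- FALSE
  }
  new_filter_result(retained, mean(y[retained]), "truncated")
}

#' Sigma-clipped background
#'
#' Single-pass clip: pixels outside `mean(y) +/- N * sd(y)` are
#' discarded and the survivors averaged.  The sample standard deviation
#' (n - 1 divisor) is used; when it is zero all pixels equal the mean
#' and everything is retained.
#'
#' @param y Non-negative counts, at least 2 pixels.
#' @param N Clip width in standard deviations (default 3).
#' @return A `"bg_filter"` result.
#' @export
filter_nsigma <- function(y, N = 3) {
  if (length(y) < 2) stop("nsigma filter needs at least 2 pixels")
  if (N <= 0) stop("`N` must be positive")
  m <- mean(y)
  s <- sd(y)
  retained <- if (s == 0) y == m else abs(y - m) <= N * s
  degenerate <- FALSE
  if (!any(retained)) {  # only possible for N < 1; keep closest pixel(s)
    retained <- abs(y - m) == min(abs(y - m))
    degenerate <- TRUE
  }
  new_filter_result(retained, mean(y[retained]), "nsigma", degenerate)
}

#' Tukey-fence background
#'
#' Pixels outside `[Q1 - N * IQR, Q3 + N * IQR]` are discarded and the
#' survivors averaged.  Quartiles use linear interpolation between order
#' statistics (R's default type 7); conventions differ between
#' implementations, so this is fixed and documented.  At very low
#' backgrounds the IQR is typically zero, so every nonzero pixel is
#' rejected and the estimate collapses to zero -- the pathology measured
#' by [zero_background_fraction()].
#'
#' @param y Non-negative counts, at least 4 pixels.
#' @param N Fence width in IQR units (default 1.5).
#' @return A `"bg_filter"` result.
#' @export
filter_tukey <- function(y, N = 1.5) {
  if (length(y) < 4) stop("tukey filter needs at least 4 pixels")
  if (N <= 0) stop("`N` must be positive")
  q <- quantile(y, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  retained <- y >= q[1] - N * iqr & y <= q[2] + N * iqr
  new_filter_result(retained, mean(y[retained]), "tukey")
}

#' Plane-fit background with deviation rejection
#'
#' MOSFLM-style strategy: discard the top `trim_fraction` of pixels by
#' value, least-squares fit `background = a + b x + c y` (origin at the
#' peak position, so `a` is the mean background), then re-test every
#' pixel and reject those whose absolute deviation from the plane
#' exceeds `N * sqrt(max(a, 1))` -- the Poisson standard deviation at
#' the plane's mean level, floored at one count so that near-zero planes
#' keep a usable threshold.  The plane is refitted on the survivors.
#'
#' @param y Non-negative counts.
#' @param coords Data frame with `x`, `y` pixel coordinates relative to
#'   the peak position.
#' @param trim_fraction Fraction of highest-valued pixels removed before
#'   the first fit (default 0.1).
#' @param N Rejection threshold in Poisson standard deviations
#'   (default 4).
#' @return A `"bg_filter"` whose `background` is the named coefficient
#'   vector `c(a, b, c)`.
#' @export
filter_plane <- function(y, coords, trim_fraction = 0.1, N = 4) {
  n <- length(y)
  coords <- as.data.frame(coords)
  if (nrow(coords) != n) stop("`coords` must have one row per pixel")
  k <- floor(trim_fraction * n)
  if (n - k < 3) stop("too few pixels to fit a plane after trimming")
  ord <- order(y)
  keep0 <- rep(TRUE, n)
  if (k > 0) keep0[ord[(n - k + 1):n]] <- FALSE

  fit_plane <- function(keep) {
    X <- cbind(1, coords$x[keep], coords$y[keep])
    if (qr(X)$rank < 3)
      stop("degenerate geometry: retained pixels are collinear, ",
           "cannot fit a plane")
    lm.fit(X, y[keep])$coefficients
  }
  ab <- fit_plane(keep0)
  thr <- N * sqrt(max(ab[1], 1))
  pred <- ab[1] + ab[2] * coords$x + ab[3] * coords$y
  retained <- abs(y - pred) <= thr
  if (sum(retained) < 3)
    stop("degenerate geometry: fewer than 3 pixels survive rejection")
  ab <- fit_plane(retained)
  new_filter_result(retained, c(a = unname(ab[1]), b = unname(ab[2]),
                                c = unname(ab[3])), "plane")
}

# Expected range (max - min) of an m-sample from N(0, 1), by quadrature
# of E[max] = int z m phi(z) Phi(z)^(m-1) dz; the range mean is twice
# that by symmetry.  Cached per sample size.
expected_normal_range <- function(m) {
  key <- sprintf("rng_%d", m)
  if (!is.null(.robustbg_cache[[key]])) return(.robustbg_cache[[key]])
  emax <- integrate(function(z) z * m * dnorm(z) * pnorm(z)^(m - 1),
                    -Inf, Inf, rel.tol = 1e-10)$value
  .robustbg_cache[[key]] <- 2 * emax
  2 * emax
}

#' Normality-trimmed background
#'
#' Kabsch-style strategy: the pixels are sorted by increasing value and
#' the largest is removed repeatedly until the retained sample looks
#' approximately normal.  The normality criterion used here is a range
#' test: the retained sample passes when `max - min` does not exceed
#' `range_factor` times the expected range of an equal-sized normal
#' sample with the retained sample's standard deviation (expected range
#' from normal order statistics, by quadrature).  With
#' `range_factor = 1`, a single spike among `m` quiet pixels inflates
#' the sample deviation by roughly `spike/sqrt(m)`, while the observed
#' range grows like the spike itself, so arbitrarily large spikes are
#' always trimmed.  Trimming stops (and the result is flagged
#' degenerate) rather than continuing below 5 survivors.
#'
#' @param y Non-negative counts, at least 5 pixels.
#' @param range_factor Multiplier on the expected normal range
#'   (default 1).
#' @return A `"bg_filter"` result.
#' @export
filter_normal <- function(y, range_factor = 1) {
  if (length(y) < 5) stop("normal filter needs at least 5 pixels")
  if (range_factor <= 0) stop("`range_factor` must be positive")
  n <- length(y)
  ord <- order(y)  # stable: ties removed last-index-first
  m <- n
  repeat {
    kept <- ord[seq_len(m)]
    s <- sd(y[kept])
    rng <- y[kept[m]] - y[kept[1]]
    if (rng <= range_factor * expected_normal_range(m) * s || s == 0) {
      retained <- rep(FALSE, n); retained[kept] <- TRUE
      return(new_filter_result(retained, mean(y[kept]), "normal"))
    }
    if (m - 1 < 5) {
      retained <- rep(FALSE, n); retained[kept] <- TRUE
      return(new_filter_result(retained, mean(y[kept]), "normal",
                               degenerate = TRUE))
    }
    m <- m - 1
  }
}
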