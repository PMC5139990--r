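#' Background model specification
#'
#' The expected background of a shoebox is modelled on the log scale as
#' either a constant or a plane.  For the planar model the design row of
#' pixel i is `(1, x_i - x0, y_i - y0)` with the origin `(x0, y0)` at
#' the peak position, so the intercept is the log-background at the
#' peak.  Pixel centres sit at integer coordinates, `x` (column) before
#' `y` (row).
#'
#' @param kind `"constant"` (1 coefficient) or `"planar"` (3
#'   coefficients).
#' @param origin Length-2 numeric `(x0, y0)`; ignored for the constant
#'   model.
#' @return An object of class `"bg_model_spec"`.
#' @export
model_spec <- function(kind = c("constant", "planar"), origin = c(0, 0)) {
  kind <- match.arg(kind)
  stopifnot(length(origin) == 2, is.numeric(origin))
  structure(list(kind = kind, origin = as.numeric(origin)),
            class = "bg_model_spec")
}

#' Configuration for the robust GLM fit
#'
#' @param c Positive Huber tuning constant.  The default solves
#'   `normal_efficiency(c) = 0.95`, i.e. 95% efficiency at the normal
#'   distribution (approximately 1.345).  `c = Inf` recovers the
#'   classical (non-robust) Poisson GLM, if `allow_infinite_c` is
#'   `TRUE`.
#' @param tol Convergence tolerance on the maximum absolute coefficient
#'   change per iteration.
#' @param max_iter Iteration cap; hitting it flags `converged = FALSE`
#'   on the result rather than throwing.
#' @param allow_infinite_c Whether `c = Inf` is accepted.
#' @return An object of class `"robust_fit_config"`.
#' @export
robust_fit_config <- function(c = huber_tuning_constant(), tol = 1e-6,
                              max_iter = 100L, allow_infinite_c = TRUE) {
  if (!is.numeric(c) || length(c) != 1 || is.na(c) || c <= 0)
    stop("`c` must be a positive scalar")
  if (is.infinite(c) && !allow_infinite_c)
    stop("`c = Inf` is not allowed by this configuration")
  if (tol <= 0) stop("`tol` must be positive")
  max_iter <- as.integer(max_iter)
  if (max_iter < 1) stop("`max_iter` must be at least 1")
  structure(list(c = c, tol = tol, max_iter = max_iter,
                 allow_infinite_c = isTRUE(allow_infinite_c)),
            class = "robust_fit_config")
}

# Build the design matrix for a model over pixel coordinates.
design_matrix <- function(model, coords, n) {
  if (model$kind == "constant") return(matrix(1, n, 1))
  if (is.null(coords)) stop("planar model requires pixel `coords`")
  coords <- as.data.frame(coords)
  if (nrow(coords) != n) stop("`coords` must have one row per pixel")
  cbind(1, coords$x - model$origin[1], coords$y - model$origin[2])
}

degenerate_fit <- function(n, p, model, config) {
  structure(list(beta = c(-Inf, rep(0, p - 1)), mu = rep(0, n),
                 covariance = matrix(NA_real_, p, p),
                 weights = rep(1, n), n_iter = 0L, converged = TRUE,
                 degenerate = TRUE, model = model, config = config,
                 X = NULL),
            class = "bg_fit")
}

# One IRLS pass from beta0 at tuning constant cc; shared by the
# classical initialization (cc = Inf) and the robust phase.
irls_run <- function(y, X, beta, cc, tol, max_iter) {
  n_iter <- 0L
  converged <- FALSE
  while (n_iter < max_iter) {
    n_iter <- n_iter + 1L
    eta <- pmin(50, pmax(-50, drop(X %*% beta)))
    mu <- exp(eta)
    r <- (y - mu) / sqrt(mu)
    w <- huber_weight(r, cc)
    a <- fisher_consistency_correction(mu, cc)
    score <- drop(crossprod(X, w * (y - mu) - a * sqrt(mu)))
    H <- crossprod(X, X * (w * mu))
    delta <- tryCatch(solve(H, score), error = function(e)
      stop("degenerate design: weighted information matrix is singular"))
    beta <- beta + delta
    if (max(abs(delta)) < tol) { converged <- TRUE; break }
  }
  list(beta = beta, n_iter = n_iter, converged = converged)
}

#' Robust Poisson GLM fit of the shoebox background
#'
#' Fits the log-linear background model by solving the robust
#' quasi-likelihood score equations
#' `sum_i (psi_c(r_i) - a_i) sqrt(mu_i) x_i = 0`,
#' where `r_i` is the Pearson residual, `psi_c` the Huber function and
#' `a_i` the Fisher-consistency correction, using iteratively
#' reweighted least squares.  Explanatory-variable weights are 1 and the
#' dispersion is fixed at 1.  With `c = Inf` the solution is the
#' classical Poisson GLM maximum-likelihood fit (for the constant model,
#' the sample mean).
#'
#' Iterations start from the classical fit, itself initialized at
#' `log(mean(y) + 1/(2n))` so that nearly-empty shoeboxes are stable.
#' An all-zero input is reported as the degenerate limit `mu = 0`
#' (`beta[1] = -Inf`, `degenerate = TRUE`, covariance undefined) rather
#' than an error, since empty shoeboxes are routine at very low
#' background.
#'
#' @param y Non-negative integer counts (background pixels).
#' @param model A [model_spec()].
#' @param coords Data frame or list with components `x` and `y`, one row
#'   per pixel (required for the planar model).
#' @param config A [robust_fit_config()].
#' @return An object of class `"bg_fit"`: `beta` (log scale), `mu`
#'   (counts/pixel), `covariance` (sandwich estimate over `beta`),
#'   `weights` (final Huber weights), `n_iter`, `converged`,
#'   `degenerate`.
#' @examples
#' fit <- robust_glm_fit(c(1, 0, 2, 1, 0, 1, 1, 2, 0, 1, 50, 1))
#' fit$mu[1]   # resistant to the outlier pixel
#' @export
robust_glm_fit <- function(y, model = model_spec("constant"),
                           coords = NULL, config = robust_fit_config()) {
  if (length(y) == 0) stop("empty input: no background pixels")
  if (any(y < 0) || any(y != round(y))) stop("`y` must be non-negative integer counts")
  y <- as.numeric(y)
  n <- length(y)
  p <- if (model$kind == "constant") 1L else 3L
  if (n < p) stop("need at least as many pixels as model coefficients")
  X <- design_matrix(model, coords, n)
  if (all(y == 0)) return(degenerate_fit(n, p, model, config))

  beta0 <- c(log(mean(y) + 1 / (2 * n)), rep(0, p - 1))
  init <- irls_run(y, X, beta0, Inf, config$tol, config$max_iter)
  if (is.infinite(config$c)) {
    res <- init
  } else {
    res <- irls_run(y, X, init$beta, config$c, config$tol, config$max_iter)
  }
  mu <- exp(pmin(50, pmax(-50, drop(X %*% res$beta))))
  fit <- structure(list(beta = res$beta, mu = mu, covariance = NULL,
                        weights = huber_weight((y - mu) / sqrt(mu), config$c),
                        n_iter = res$n_iter, converged = res$converged,
                        degenerate = FALSE, model = model, config = config,
                        X = X),
                   class = "bg_fit")
  fit$covariance <- if (res$converged)
    tryCatch(estimator_covariance(fit, X, config),
             error = function(e) matrix(NA_real_, p, p))
  else matrix(NA_real_, p, p)
  fit
}

#' Fast constant-model background fit
#'
#' Specialization of [robust_glm_fit()] to the constant background
#' model, where every design row is identical and the iteration
#' collapses to a scalar update
#' `beta <- beta + (sum_i w_i (y_i - mu) - n a(mu) sqrt(mu)) / (mu sum_i w_i)`.
#' The iterates are arithmetically identical to the general path, so the
#' two agree to floating-point precision on every input.
#'
#' @inheritParams robust_glm_fit
#' @return A `"bg_fit"` object, as [robust_glm_fit()].
#' @export
constant_background_fit <- function(y, config = robust_fit_config()) {
  if (length(y) == 0) stop("empty input: no background pixels")
  if (any(y < 0) || any(y != round(y))) stop("`y` must be non-negative integer counts")
  y <- as.numeric(y)
  n <- length(y)
  model <- model_spec("constant")
  if (all(y == 0)) return(degenerate_fit(n, 1L, model, config))

  scalar_irls <- function(beta, cc) {
    n_iter <- 0L; converged <- FALSE
    while (n_iter < config$max_iter) {
      n_iter <- n_iter + 1L
      mu <- exp(min(50, max(-50, beta)))
      r <- (y - mu) / sqrt(mu)
      w <- huber_weight(r, cc)
      a <- fisher_consistency_correction(mu, cc)
      delta <- (sum(w * (y - mu)) - n * a * sqrt(mu)) / (sum(w) * mu)
      beta <- beta + delta
      if (abs(delta) < config$tol) { converged <- TRUE; break }
    }
    list(beta = beta, n_iter = n_iter, converged = converged)
  }

  init <- scalar_irls(log(mean(y) + 1 / (2 * n)), Inf)
  res <- if (is.infinite(config$c)) init else scalar_irls(init$beta, config$c)
  mu <- exp(min(50, max(-50, res$beta)))
  X <- matrix(1, n, 1)
  fit <- structure(list(beta = res$beta, mu = rep(mu, n), covariance = NULL,
                        weights = huber_weight((y - mu) / sqrt(mu), config$c),
                        n_iter = res$n_iter, converged = res$converged,
                        degenerate = FALSE, model = model, config = config,
                        X = X),
                   class = "bg_fit")
  fit$covariance <- if (res$converged)
    tryCatch(estimator_covariance(fit, X, config),
             error = function(e) matrix(NA_real_, 1, 1))
  else matrix(NA_real_, 1, 1)
  fit
}

# Vectorized constant-model fitter over the rows of a count matrix.
# Same update formula as constant_background_fit, run simultaneously on
# every shoebox; used by the diagnostics on large simulated datasets.
# Returns mu (0 for all-zero rows), beta, converged, degenerate.
fit_constant_batch <- function(Y, config = robust_fit_config()) {
  if (is.vector(Y)) Y <- matrix(Y, nrow = 1)
  n <- ncol(Y)
  rmean <- rowMeans(Y)
  degenerate <- rmean == 0
  beta <- log(rmean + 1 / (2 * n))
  beta[degenerate] <- NA_real_
  active_phase <- function(beta, cc) {
    done <- degenerate
    iter <- 0L
    while (!all(done) && iter < config$max_iter) {
      iter <- iter + 1L
      idx <- which(!done)
      mu <- exp(pmin(50, pmax(-50, beta[idx])))
      Yi <- Y[idx, , drop = FALSE]
      R <- (Yi - mu) / sqrt(mu)
      W <- if (is.infinite(cc)) 1 + 0 * R
           else pmin(cc / pmax(abs(R), 1e-300), 1)  # matrix-shaped
      a <- if (is.infinite(cc)) 0 else fisher_consistency_correction(mu, cc)
      delta <- (rowSums(W * (Yi - mu)) - n * a * sqrt(mu)) /
        (rowSums(W) * mu)
      beta[idx] <- beta[idx] + delta
      done[idx] <- abs(delta) < config$tol
    }
    list(beta = beta, converged = done)
  }
  ph1 <- active_phase(beta, Inf)
  res <- if (is.infinite(config$c)) ph1 else active_phase(ph1$beta, config$c)
  mu <- exp(pmin(50, pmax(-50, res$beta)))
  mu[degenerate] <- 0
  list(mu = mu, beta = res$beta, converged = res$converged | degenerate,
       degenerate = degenerate)
}

#' @export
print.bg_fit <- function(x, ...) {
  cat("Robust Poisson GLM background fit (", x$model$kind, " model)\n",
      sep = "")
  if (x$degenerate) {
    cat("  degenerate: all pixels zero, mu = 0\n")
  } else {
    cat("  beta:", format(x$beta, digits = 6), "\n")
    cat("  background at origin:", format(exp(x$beta[1]), digits = 6),
        "counts/pixel\n")
    cat("  iterations:", x$n_iter,
        if (x$converged) "(converged)" else "(NOT converged)", "\n")
  }
  invisible(x)
}
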