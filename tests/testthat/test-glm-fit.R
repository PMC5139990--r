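test_that("constant-data fit solves the corrected score and degenerate
           input is flagged", {
  # with c = Inf the fit interpolates constant data exactly
  mle <- robust_glm_fit(c(3, 3, 3, 3), config = robust_fit_config(c = Inf))
  expect_equal(unname(mle$mu), rep(3, 4), tolerance = 1e-8)
  expect_equal(mle$beta[1], log(3), tolerance = 1e-8)
  # at finite c the consistency correction a(mu) != 0 shifts the root
  # slightly above the clamp-free value; the estimate must match the
  # brute-force root of the corrected score equation
  fit <- robust_glm_fit(c(3, 3, 3, 3))
  expect_equal(fit$mu[1],
               brute_constant_root(c(3, 3, 3, 3), huber_tuning_constant()),
               tolerance = 1e-5)
  expect_lt(abs(fit$mu[1] - 3), 0.1)
  expect_true(fit$converged)
  expect_equal(unname(fit$weights), rep(1, 4))  # residuals inside the clamp

  z <- robust_glm_fit(rep(0L, 10))
  expect_true(z$degenerate)
  expect_identical(z$beta[1], -Inf)
  expect_equal(z$mu, rep(0, 10))
  expect_true(all(is.na(z$covariance)))

  expect_error(robust_glm_fit(numeric(0)), "empty")
  expect_error(robust_glm_fit(c(1, -2, 3)), "non-negative")
  expect_error(robust_glm_fit(c(1.5, 2)), "integer")
  expect_error(robust_glm_fit(c(1, 2), model_spec("planar")), "pixels")
})

test_that("c = Inf reproduces the classical Poisson MLE (sample mean)", {
  cfg <- robust_fit_config(c = Inf)
  set.seed(42)
  for (i in 1:60) {
    y <- rpois(sample(5:60, 1), runif(1, 0.1, 9))
    if (all(y == 0)) next
    expect_equal(robust_glm_fit(y, config = cfg)$mu[1], mean(y),
                 tolerance = 1e-8)
  }
})

test_that("robust fit solves the score equation and resists an outlier", {
  y <- c(1, 0, 2, 1, 0, 1, 1, 2, 0, 1, 1, 0,
         2, 1, 1, 0, 1, 2, 1, 0, 1, 1, 50, 1)
  cc <- huber_tuning_constant()
  fit <- robust_glm_fit(y)
  oracle <- brute_constant_root(y, cc)
  expect_equal(fit$mu[1], oracle, tolerance = 1e-5)
  expect_lt(fit$mu[1], mean(y))              # sample mean is ~2.96
  se <- sqrt(fit$covariance[1, 1]) * fit$mu[1]  # delta method to mu scale
  expect_lt(abs(fit$mu[1] - 1), 3 * se)
  expect_lt(fit$weights[y == 50], 0.05)
})

test_that("influence of a single corrupted pixel is bounded", {
  set.seed(7)
  y <- rpois(25, 2)
  base <- constant_background_fit(y)$mu[1]
  for (spike in c(1e3, 1e6)) {
    y2 <- y; y2[1] <- spike
    expect_lt(abs(constant_background_fit(y2)$mu[1] - base), 1.5)
    expect_gt(mean(y2), spike / 25 - 1)  # the mean diverges linearly
  }
})

test_that("mean estimate is monotone in the true background level", {
  set.seed(99)
  R <- 2000; n <- 25
  est <- sapply(c(1, 3), function(lam) {
    mu <- robustbg:::fit_constant_batch(matrix(rpois(R * n, lam), R, n))$mu
    c(mean(mu), sd(mu) / sqrt(R))
  })
  expect_gt(est[1, 2] - est[1, 1], 3 * sqrt(est[2, 1]^2 + est[2, 2]^2))
})

test_that("replicate fits are unbiased for the Poisson rate", {
  # Fisher consistency: the mean of mu-hat over many replicate fits of
  # 100-pixel backgrounds stays within 3 Monte-Carlo SEs of the truth
  set.seed(512)
  R <- 10000; n <- 100
  for (lam in c(0.1, 0.5, 1, 2, 5, 10)) {
    mu <- robustbg:::fit_constant_batch(matrix(rpois(R * n, lam), R, n))$mu
    expect_lt(abs(mean(mu) - lam), 3 * sd(mu) / sqrt(R))
  }
})

test_that("planar model recovers simulated log-plane coefficients", {
  set.seed(1234)
  truth <- c(log(2.5), 0.04, -0.03)
  spec <- shoebox_spec(9, 9, background = truth)
  R <- 300
  betas <- sapply(1:R, function(i) {
    sb <- simulate_shoebox(spec, seed = i)
    robust_glm_fit(background_counts(sb), model_spec("planar"),
                   background_coords(sb))$beta
  })
  for (k in 1:3) {
    se <- sd(betas[k, ]) / sqrt(R)
    expect_lt(abs(mean(betas[k, ]) - truth[k]), 3 * se)
  }
})

test_that("fast constant path and batch fitter agree with the general path", {
  set.seed(77)
  cfg <- robust_fit_config()
  ys <- c(list(c(0, 0, 0, 0), c(2, 2, 2), 0:20),
          lapply(1:40, function(i) rpois(sample(8:50, 1), runif(1, 0.05, 8))))
  for (y in ys) {
    a <- constant_background_fit(y, cfg)
    b <- robust_glm_fit(y, model_spec("constant"), config = cfg)
    expect_equal(a$mu[1], b$mu[1], tolerance = 1e-10)
    expect_identical(a$degenerate, b$degenerate)
  }
  Y <- matrix(rpois(200 * 30, 1.7), 200, 30)
  Y[1, ] <- 0
  batch <- robustbg:::fit_constant_batch(Y, cfg)
  single <- apply(Y, 1, function(r) constant_background_fit(r, cfg)$mu[1])
  expect_equal(batch$mu, unname(single), tolerance = 1e-10)
  expect_true(batch$degenerate[1])
})

test_that("fit configuration is validated", {
  expect_error(robust_fit_config(c = -1), "positive")
  expect_error(robust_fit_config(tol = 0), "positive")
  expect_error(robust_fit_config(max_iter = 0), "at least 1")
  expect_error(robust_fit_config(c = Inf, allow_infinite_c = FALSE),
               "not allowed")
  cfg <- robust_fit_config(max_iter = 1)
  fit <- robust_glm_fit(c(0, 5, 1, 2, 9, 0), config = cfg)
  expect_false(fit$converged)   # flagged, not thrown
})
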