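test_that("null filter keeps everything and averages", {
  cases <- list(list(y = c(1, 2, 3), bg = 2),
                list(y = c(0, 0, 0), bg = 0),
                list(y = 5, bg = 5))
  for (cs in cases) {
    f <- filter_null(cs$y)
    expect_true(all(f$retained))
    expect_equal(f$background, cs$bg)
    expect_equal(f$n_rejected, 0L)
  }
  expect_error(filter_null(numeric(0)), "empty")
})

test_that("truncated filter trims floor(fraction n) per end", {
  f <- filter_truncated(1:20, 0.05)
  expect_equal(f$n_rejected, 2L)
  expect_equal(f$background, mean(2:19))
  expect_false(f$retained[1])
  expect_false(f$retained[20])

  y <- rpois(30, 2)
  expect_equal(filter_truncated(y, 0)$background, filter_null(y)$background)
  expect_error(filter_truncated(y, 0.5), "fraction")
  expect_error(filter_truncated(y, -0.1), "fraction")
})

test_that("truncated-mean replicates reproduce the analytic bias", {
  set.seed(61)
  R <- 1e5; n <- 25; lam <- 1
  Y <- matrix(rpois(R * n, lam), R, n)
  lo <- Y[, 1]; hi <- Y[, 1]
  for (j in 2:n) { lo <- pmin(lo, Y[, j]); hi <- pmax(hi, Y[, j]) }
  trimmed <- (rowSums(Y) - lo - hi) / (n - 2)   # floor(0.05*25)=1 per end
  bias <- truncated_estimator_bias(lam, 0.05, n)
  expect_lt(abs(mean(trimmed) - lam - bias), 3 * sd(trimmed) / sqrt(R))
  expect_lt(bias, 0)   # symmetric trim of an asymmetric law biases down
})

test_that("nsigma filter clips once around the mean", {
  f <- filter_nsigma(c(5, 5, 5, 5))
  expect_true(all(f$retained))
  expect_equal(f$background, 5)

  f2 <- filter_nsigma(c(0, 0, 0, 100), N = 3)   # sd = 50, bound = 175
  expect_true(all(f2$retained))
  expect_equal(f2$background, 25)

  f3 <- filter_nsigma(c(0, 0, 0, 0, 0, 0, 0, 0, 0, 100), N = 2)
  expect_false(f3$retained[10])
  expect_equal(f3$background, 0)
  expect_error(filter_nsigma(5), "at least 2")
})

test_that("tukey fences use type-7 quartiles", {
  f <- filter_tukey(c(3, 3, 3, 3, 3))
  expect_equal(f$background, 3)
  expect_true(all(f$retained))

  f2 <- filter_tukey(1:9, N = 1.5)   # Q1=3 Q3=7, fences [-3, 13]
  expect_true(all(f2$retained))
  expect_equal(f2$background, 5)

  f3 <- filter_tukey(c(0, 0, 0, 0, 100), N = 1.5)   # IQR 0 at median 0
  expect_equal(f3$background, 0)
  expect_equal(f3$n_rejected, 1L)
  expect_error(filter_tukey(1:3), "at least 4")
})

test_that("plane filter recovers exact planes and rejects hot pixels", {
  g <- expand.grid(x = -4:4, y = -4:4)
  flat <- rep(4, nrow(g))
  f <- filter_plane(flat, g, trim_fraction = 0, N = 4)
  expect_equal(unname(f$background), c(4, 0, 0), tolerance = 1e-10)
  expect_equal(f$n_rejected, 0L)

  yplane <- 10 + 1 * g$x + 0 * g$y
  f2 <- filter_plane(yplane, g, trim_fraction = 0, N = 100)
  expect_equal(unname(f2$background), c(10, 1, 0), tolerance = 1e-8)

  set.seed(5)
  ests <- replicate(300, {
    y <- rpois(nrow(g), 5)
    y[sample(nrow(g), 1)] <- 1000
    filter_plane(y, g, trim_fraction = 0.1, N = 4)$background["a"]
  })
  expect_lt(abs(mean(ests) - 5), 3 * sd(ests) / sqrt(300))
  expect_true(all(ests < 20))   # the hot pixel never survives

  expect_error(filter_plane(rep(1, 9), data.frame(x = 1:9, y = 1:9),
                            trim_fraction = 0, N = 4), "collinear")
})

test_that("normal filter trims spikes but keeps normal-looking data", {
  f <- filter_normal(rep(7, 10))
  expect_true(all(f$retained))
  expect_equal(f$background, 7)

  set.seed(14)
  hits <- replicate(200, {
    y <- c(round(rnorm(25, 10, sqrt(10))), 200)
    y[y < 0] <- 0
    f <- filter_normal(y)
    c(removed = !f$retained[26], bg = f$background)
  })
  expect_true(all(hits["removed", ] == 1))
  # the range criterion also trims some genuine maxima, leaving a small
  # downward offset well inside one population sigma (~3.2)
  expect_lt(abs(mean(hits["bg", ]) - 10), 1)

  tiny <- filter_normal(c(0, 0, 1, 4, 9, 20, 60))   # keeps trimming to 5
  expect_true(tiny$degenerate)
  expect_equal(sum(tiny$retained), 5L)
})

test_that("rejection filters collapse weak Poisson backgrounds to zero", {
  # at lambda ~ 0.1 the IQR/range criteria reject every nonzero pixel in
  # a sizeable fraction of shoeboxes, while null never does
  set.seed(33)
  res <- replicate(400, {
    y <- rpois(25, 0.1)
    if (!any(y > 0)) return(c(NA, NA))
    c(tukey = filter_tukey(y)$background == 0,
      normal = filter_normal(y)$background == 0)
  })
  res <- res[, !is.na(res[1, ])]
  expect_gt(mean(res[1, ]), 0.5)
  expect_gt(mean(res[2, ]), 0.05)
})

test_that("filters reduce to null in their wide limits and are
           permutation invariant", {
  set.seed(8)
  y <- rpois(40, 1)
  bg0 <- filter_null(y)$background
  expect_equal(filter_truncated(y, 0)$background, bg0)
  expect_equal(filter_nsigma(y, N = 1e6)$background, bg0)
  expect_equal(filter_tukey(y, N = 1e6)$background, bg0)
  p <- sample(40)
  for (f in list(filter_null, filter_truncated, filter_nsigma,
                 filter_tukey, filter_normal))
    expect_equal(f(y[p])$background, f(y)$background)
})

test_that("trim-style filters are biased low on pure Poisson data", {
  set.seed(55)
  R <- 3000; n <- 25; lam <- 1
  sums <- matrix(0, R, 5,
                 dimnames = list(NULL, c("null", "truncated", "nsigma",
                                         "tukey", "normal")))
  for (i in 1:R) {
    y <- rpois(n, lam)
    sums[i, ] <- c(filter_null(y)$background,
                   filter_truncated(y)$background,
                   filter_nsigma(y)$background,
                   filter_tukey(y)$background,
                   filter_normal(y)$background)
  }
  m <- colMeans(sums)
  for (meth in c("truncated", "nsigma", "tukey", "normal"))
    expect_lte(m[[meth]], m[["null"]])
})
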