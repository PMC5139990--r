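#' Pearson residual for a Poisson observation
#'
#' For Poisson counts the variance function equals the mean, so the
#' Pearson residual of observation `y` with expected value `mu` is
#' `(y - mu) / sqrt(mu)` (dispersion fixed at 1).
#'
#' @param y Non-negative observed count(s).
#' @param mu Positive expected value(s).
#' @return Numeric residual(s), recycled to the common length.
#' @examples
#' pearson_residual(9, 4)  # 2.5
#' @export
pearson_residual <- function(y, mu) {
  if (any(mu <= 0)) stop("`mu` must be strictly positive")
  if (any(y < 0)) stop("`y` must be non-negative")
  (y - mu) / sqrt(mu)
}

#' Huber psi (clamped-identity score) function
#'
#' `huber_psi(r, c)` clamps the residual `r` to `[-c, c]`, giving bounded
#' influence to large residuals.  It is odd in `r` and equals the
#' identity inside the linear region `|r| <= c`.
#'
#' @param r Numeric residual(s).
#' @param c Positive tuning constant (may be `Inf`, recovering the
#'   identity and hence the classical estimator).
#' @return Clamped residual(s).
#' @examples
#' huber_psi(10, 1.345)   # 1.345
#' huber_psi(-0.5, 1.345) # -0.5
#' @export
huber_psi <- function(r, c = huber_tuning_constant()) {
  if (c <= 0) stop("`c` must be positive")
  pmax(-c, pmin(c, r))
}

#' Huber robust weight
#'
#' The multiplicative weight `psi_c(r) / r`, i.e. `min(1, c / |r|)`,
#' with the limit value 1 at `r = 0`.  Residuals inside the linear
#' region get full weight; larger residuals are damped.
#'
#' @inheritParams huber_psi
#' @return Weight(s) in `(0, 1]`.
#' @export
huber_weight <- function(r, c = huber_tuning_constant()) {
  if (c <= 0) stop("`c` must be positive")
  pmin(1, c / abs(r))  # c/0 = Inf, so r = 0 correctly maps to weight 1
}

#' Asymptotic efficiency of the Huber estimator at the normal
#'
#' Relative efficiency, at the standard normal distribution, of the
#' Huber-type M-estimator of location with tuning constant `c` versus
#' the sample mean: `(E[psi'])^2 / E[psi^2]` with expectations under
#' N(0, 1).  `E[psi']` has the closed form `2 * pnorm(c) - 1`;
#' `E[psi^2]` is evaluated by numerical quadrature.  The efficiency is
#' strictly increasing in `c` and tends to 1 as `c -> Inf`.
#'
#' @param c Positive tuning constant.
#' @return Efficiency in `(0, 1]`.
#' @examples
#' normal_efficiency(1.345)  # ~0.95
#' @export
normal_efficiency <- function(c) {
  if (c <= 0) stop("`c` must be positive")
  if (is.infinite(c)) return(1)
  e_psi_prime <- 2 * pnorm(c) - 1
  e_psi_sq <- integrate(function(z) huber_psi(z, c)^2 * dnorm(z),
                        -Inf, Inf, rel.tol = 1e-12)$value
  e_psi_prime^2 / e_psi_sq
}

# cache for the default tuning constant (root-finding is cheap but this
# is evaluated inside tight per-shoebox loops)
.robustbg_cache <- new.env(parent = emptyenv())

#' Default Huber tuning constant for a target normal efficiency
#'
#' Solves `normal_efficiency(c) = efficiency` by 1-D root finding.  The
#' package default, `efficiency = 0.95`, gives `c ~= 1.345`, the usual
#' compromise between efficiency at the Poisson/normal model and
#' robustness to outlier pixels.
#'
#' @param efficiency Target efficiency in `(0, 1)`.
#' @return The tuning constant `c > 0`.
#' @examples
#' huber_tuning_constant()        # ~1.345
#' @export
huber_tuning_constant <- function(efficiency = 0.95) {
  if (efficiency <= 0 || efficiency >= 1)
    stop("`efficiency` must lie strictly between 0 and 1")
  key <- sprintf("c_%.12f", efficiency)
  if (!is.null(.robustbg_cache[[key]])) return(.robustbg_cache[[key]])
  root <- uniroot(function(cc) normal_efficiency(cc) - efficiency,
                  interval = c(1e-3, 50), tol = 1e-10)$root
  .robustbg_cache[[key]] <- root
  root
}

#' Fisher-consistency correction for the Huber Poisson score
#'
#' Expectation `E[psi_c(R)]` of the clamped Pearson residual
#' `R = (Y - mu)/sqrt(mu)` under `Y ~ Poisson(mu)`.  Subtracting this
#' constant from `psi_c(r_i)` makes the robust quasi-likelihood score
#' mean-zero at the true parameter, so the estimator is Fisher
#' consistent.  The expectation is evaluated exactly by expanding the
#' sum over the Poisson mass: with `j1 = floor(mu - c*sqrt(mu))` and
#' `j2 = floor(mu + c*sqrt(mu))`,
#' `E[psi] = -c P(Y <= j1) + c P(Y > j2)
#'           + sqrt(mu) * (P(j1-1 < Y <= j2-1) - P(j1 < Y <= j2))`.
#'
#' @param mu Positive Poisson mean(s).
#' @param c Positive tuning constant; `Inf` gives 0 (the untruncated
#'   Pearson residual has mean zero).
#' @return The correction term(s), same length as `mu`.
#' @export
fisher_consistency_correction <- function(mu, c = huber_tuning_constant()) {
  if (any(mu <= 0)) stop("`mu` must be strictly positive")
  if (c <= 0) stop("`c` must be positive")
  if (is.infinite(c)) return(rep(0, length(mu)))
  j1 <- floor(mu - c * sqrt(mu))
  j2 <- floor(mu + c * sqrt(mu))
  # E[Y 1{a < Y <= b}] = mu * (P(Y <= b-1) - P(Y <= a-1)) for Poisson
  -c * ppois(j1, mu) + c * ppois(j2, mu, lower.tail = FALSE) +
    sqrt(mu) * ((ppois(j2 - 1, mu) - ppois(j1 - 1, mu)) -
                  (ppois(j2, mu) - ppois(j1, mu)))
}

# Exact Poisson moments of the clamped residual by direct summation over
# a support window whose truncated tail mass is negligible (< 1e-12 for
# shoebox-scale mu).  Returns, for a single mu:
#   e_psi   = E[psi_c(R)]            (equals fisher_consistency_correction)
#   e_psi2  = E[psi_c(R)^2]
#   d_eta   = E[d/d(eta) {(psi_c(R) - a(mu)) * sqrt(mu)}], eta = log mu,
#             needed for the expected score derivative.
poisson_psi_moments <- function(mu, c) {
  ymax <- ceiling(mu + 10 * sqrt(mu) + 20)
  y <- 0:ymax
  p <- dpois(y, mu)
  r <- (y - mu) / sqrt(mu)
  psi <- pmax(-c, pmin(c, r))
  inside <- abs(r) < c
  e_psi <- sum(p * psi)
  e_psi2 <- sum(p * psi^2)
  # d/dmu of psi_c(r) sqrt(mu) for fixed y: -1 inside, sign(r) c/(2 sqrt(mu))
  # outside the linear region.
  dpsi_term <- ifelse(inside, -1, sign(r) * c / (2 * sqrt(mu)))
  # d/dmu of h(mu) = E[psi_c(R)] sqrt(mu): differentiate mass and value.
  g <- psi * sqrt(mu)
  dh <- sum(p * ((y / mu - 1) * g + dpsi_term))
  d_eta <- mu * (sum(p * dpsi_term) - dh)
  list(e_psi = e_psi, e_psi2 = e_psi2, d_eta = d_eta)
}
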