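#' Asymptotic covariance of the robust GLM estimator
#'
#' Sandwich covariance `M^{-1} Q M^{-T}` of the quasi-likelihood
#' coefficient estimate.  The per-pixel score contribution is
#' `s_i = (psi_c(r_i) - a_i) sqrt(mu_i) x_i`, so
#' `Q = sum_i Var[psi_c(R_i)] mu_i x_i x_i'` and
#' `M = sum_i m_i x_i x_i'` with `m_i` the (negative) expectation of the
#' derivative of the score summand with respect to the linear predictor.
#' Both expectations are taken under `Y_i ~ Poisson(mu_i)` and evaluated
#' by exact summation of the Poisson mass over a support window with
#' negligible tail.  For `c = Inf` the matrix reduces to the inverse
#' Fisher information of the Poisson GLM (`1 / (n mu)` for the
#' intercept-only model).
#'
#' @param fit A converged, non-degenerate `"bg_fit"`.
#' @param X Design matrix used for the fit (defaults to the matrix
#'   stored on the fit).
#' @param config A [robust_fit_config()]; defaults to the fit's own.
#' @return Symmetric positive semi-definite matrix over `beta`.
#' @export
estimator_covariance <- function(fit, X = fit$X, config = fit$config) {
  if (!inherits(fit, "bg_fit")) stop("`fit` must be a bg_fit object")
  if (fit$degenerate)
    stop("covariance undefined for the degenerate all-zero fit")
  if (!fit$converged) stop("fit did not converge; covariance not evaluated")
  mu <- fit$mu
  cc <- config$c
  p <- ncol(X)
  if (is.infinite(cc)) {
    # classical Poisson GLM: sandwich collapses to inverse Fisher info
    M <- crossprod(X, X * mu)
    Q <- M
  } else {
    m_i <- numeric(length(mu))
    v_i <- numeric(length(mu))
    for (k in seq_along(mu)) {
      mom <- poisson_psi_moments(mu[k], cc)
      m_i[k] <- -mom$d_eta
      v_i[k] <- (mom$e_psi2 - mom$e_psi^2) * mu[k]
    }
    M <- crossprod(X, X * m_i)
    Q <- crossprod(X, X * v_i)
  }
  Minv <- tryCatch(solve(M), error = function(e)
    stop("degenerate design: expected score derivative is singular"))
  V <- Minv %*% Q %*% t(Minv)
  (V + t(V)) / 2
}
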