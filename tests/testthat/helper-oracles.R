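# Independent oracles used across tests.

# E[psi_c(R)] under Poisson(mu) by brute-force summation of the mass,
# independent of the closed form shipped in the package.
brute_e_psi <- function(mu, cc, ymax = ceiling(mu + 12 * sqrt(mu) + 40)) {
  y <- 0:ymax
  sum(dpois(y, mu) * pmax(-cc, pmin(cc, (y - mu) / sqrt(mu))))
}

# Solve the 1-D robust score equation for the constant model by
# root-finding (bisection via uniroot), using the brute-force
# expectation above for the consistency correction.
brute_constant_root <- function(y, cc, lower = 1e-6, upper = max(y) + 10) {
  score <- function(mu) {
    r <- (y - mu) / sqrt(mu)
    sum((pmax(-cc, pmin(cc, r)) - brute_e_psi(mu, cc)) * sqrt(mu))
  }
  uniroot(score, c(lower, upper), tol = 1e-12)$root
}

# Closed-form E[psi^2] under N(0,1) for the Huber score, used to
# cross-check the quadrature efficiency.
closed_normal_epsi2 <- function(cc) {
  (2 * pnorm(cc) - 1) - 2 * cc * dnorm(cc) +
    2 * cc^2 * pnorm(cc, lower.tail = FALSE)
}
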