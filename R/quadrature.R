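# Gauss-Hermite machinery for the pseudo-adaptive quadrature used by the EM
# algorithm.  Nodes are centered at the conditional modes of the random
# effects from the initial separate mixed-model fit and scaled by the
# Cholesky factor of their conditional covariance; they stay fixed for the
# whole EM run.

# product Gauss-Hermite rule in d dimensions: nodes (Q x d) and log-weights
# including the exp(||t||^2) reweighting, so that
#   integral g(b) db ~= sum_q exp(logw_q) g(mu + sqrt(2) L t_q) * 2^(d/2) |L|
gh_rule <- function(n_quad, d) {
  gh <- pracma::gaussHermite(n_quad)
  if (d == 1L) {
    nodes <- matrix(gh$x, ncol = 1)
    logw <- log(gh$w) + gh$x^2
  } else {
    idx <- as.matrix(expand.grid(rep(list(seq_len(n_quad)), d)))
    nodes <- matrix(gh$x[idx], ncol = d)
    logw <- rowSums(matrix(log(gh$w[idx]) + gh$x[idx]^2, ncol = d))
  }
  list(nodes = nodes, logw = logw)
}

# pseudo-adaptive transform of a GH rule for one unit: b_q = mu + sqrt(2) L t_q
# where L is the lower Cholesky factor of the conditional covariance.
# Returns node coordinates (Q x d), per-unit log-weights, and the log of the
# Jacobian constant 2^(d/2) |L|.
adapt_grid <- function(rule, mu, Sigma) {
  d <- length(mu)
  L <- t(chol(Sigma))
  B <- sweep(sqrt(2) * rule$nodes %*% t(L), 2L, mu, "+")
  list(B = B, logw = rule$logw,
       logjac = 0.5 * d * log(2) + sum(log(diag(L))))
}

# log multivariate normal density N(0, Sigma) evaluated at rows of B
log_dmvnorm0 <- function(B, Sigma) {
  d <- ncol(B)
  Sinv <- solve(Sigma)
  q <- rowSums((B %*% Sinv) * B)
  -0.5 * (q + d * log(2 * pi) + determinant(Sigma)$modulus[1])
}

# Posterior moments of a 1-d density proportional to exp(logpost(b)) via an
# adapted GH rule centered at (mu, sd).  Used as the building block whose
# accuracy the dense-grid integration tests check.
gh_posterior_moments_1d <- function(logpost, mu, sd, n_quad) {
  rule <- gh_rule(n_quad, 1L)
  b <- mu + sqrt(2) * sd * rule$nodes[, 1]
  lw <- rule$logw + logpost(b)
  mx <- max(lw)
  w <- exp(lw - mx)
  Z <- sum(w)
  list(norm_const = Z * exp(mx) * sqrt(2) * sd,
       mean = sum(w * b) / Z,
       second = sum(w * b^2) / Z)
}
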