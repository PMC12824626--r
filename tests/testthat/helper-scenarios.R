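# Shared fixtures: all inputs are generated in code at test time.

# A small, fast scenario for unit tests (weak-noise, modest dimensions).
tiny_scenario <- function(n_reps = 5, ...) {
  lima_scenario(n_X = 5e3, n_M = 2e3, n_Y = 5e3, m = 20, k = 3,
                p_k = 1, P = 1, n_reps = n_reps, seed = 42L,
                l_per_mediator = c(2L, 3L, 1L), ...)
}

# Noise-free summary statistics for a given truth/architecture: the
# infinite-sample limit in which every estimator must recover the truth.
noiseless_data <- function(truth, arch, n_X = 1e12, n_M = 1e12,
                           n_Y = 1e12) {
  beta <- arch$beta
  theta <- truth$alpha + sum(truth$gamma * truth$delta)
  summary_data(beta_hat = beta,
               C_hat = tcrossprod(beta, truth$gamma),
               B_hat = arch$B,
               c_hat = beta * theta,
               b_hat = drop(arch$B %*% truth$delta),
               n_X = n_X, n_M = n_M, n_Y = n_Y,
               block = arch$block)
}

# Dense multivariate-normal log-density (oracle building block).
mvtnorm_logdens <- function(x, V) {
  U <- chol(V)
  z <- backsolve(U, x, transpose = TRUE)
  -0.5 * (length(x) * log(2 * pi) + 2 * sum(log(diag(U))) + sum(z^2))
}

# Deterministic small truth + architecture used across estimator tests.
fixed_truth_arch <- function(seed = 7, m = 12, k = 3,
                             l_per_mediator = c(2L, 2L, 3L)) {
  set.seed(seed)
  arch <- draw_instrument_effects(0.3, m, h2_M = rep(0.2, k),
                                  l_per_mediator = l_per_mediator)
  truth <- list(alpha = 0.08, gamma = c(0.15, -0.1, 0.2),
                delta = c(0.1, 0.05, -0.12))
  truth$omega <- sum(truth$gamma * truth$delta)
  truth$theta <- truth$alpha + truth$omega
  list(truth = truth, arch = arch)
}
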