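# Generative model: prior-variance algebra, spike-and-slab draws,
# heritabilities, instrument effects, Sigma strategies, noise model,
# mediator selection, determinism.

test_that("prior variances match the closed-form solution and moment identity", {
  # hand-computed single-mediator case
  pv <- solve_prior_variances(mp = 0.15, expected_theta = 0.15,
                              sigma2_YM = 0.01, rho_gd = 0, k_s = 1)
  expect_equal(pv$sigma2_d, 0.01)
  expect_equal(pv$sigma2_g, 0.0225^2 / 0.01)
  expect_equal(pv$sigma_gd, 0)

  # zero mediation forces zero covariance and zero expected omega
  pv0 <- solve_prior_variances(0, 0.15, 0.05, 0.3, 4)
  expect_equal(pv0$sigma_gd, 0)
  expect_equal(4 * pv0$sigma_gd, 0)

  # E(omega)^2 + Var(omega) == (MP * E(theta))^2 over random inputs
  set.seed(1)
  for (i in 1:25) {
    mp <- runif(1, 0.01, 0.9); eth <- runif(1, 0.05, 0.5)
    s2ym <- runif(1, 0.005, 0.5); rho <- runif(1, -0.95, 0.95)
    ks <- sample(1:40, 1)
    pv <- solve_prior_variances(mp, eth, s2ym, rho, ks)
    var_omega <- ks * (pv$sigma2_g * pv$sigma2_d + pv$sigma_gd^2)
    e_omega <- ks * pv$sigma_gd
    expect_equal(e_omega^2 + var_omega, (mp * eth)^2, tolerance = 1e-12)
  }

  expect_error(solve_prior_variances(0.1, 0.1, -1, 0, 2), "positive")
  expect_error(solve_prior_variances(0.1, 0.1, 0.1, 0, 0), "k_s")
})

test_that("spike-and-slab draws have the prescribed support and moments", {
  set.seed(2)
  # sparsity pattern: only the first k_s entries are non-zero
  eff <- draw_mediation_effects(10, 0.3, 0.01, 0.02, 0.005)
  expect_equal(eff$k_s, 3)
  expect_true(all(eff$gamma[4:10] == 0) && all(eff$delta[4:10] == 0))
  expect_true(all(eff$gamma[1:3] != 0))

  # k_s = 0 means all-null
  eff0 <- draw_mediation_effects(5, 0.01, 0.01, 0.02, 0)
  expect_equal(eff0$k_s, 0)
  expect_true(all(eff0$gamma == 0) && all(eff0$delta == 0))

  # law-of-large-numbers checks of E(gamma_i delta_i) = sigma_gd and
  # Var(gamma'delta) = k_s (s2g s2d + sgd^2)
  s2g <- 0.04; s2d <- 0.01; sgd <- 0.012
  n <- 1e5; ks <- 4
  draws <- replicate(n, {
    e <- draw_mediation_effects(ks, 1, s2g, s2d, sgd)
    c(mean(e$gamma * e$delta), sum(e$gamma * e$delta))
  })
  se_mean <- sd(draws[1, ]) / sqrt(n)
  expect_lt(abs(mean(draws[1, ]) - sgd), 4 * se_mean)
  v_target <- ks * (s2g * s2d + sgd^2)
  v_emp <- var(draws[2, ])
  expect_lt(abs(v_emp - v_target) / v_target, 0.05)

  expect_error(draw_mediation_effects(4, 1, 0.01, 0.01, 0.5),
               "positive semi-definite")
})

test_that("direct effect enforces the target MP, or the uniform null law", {
  expect_equal(compute_direct_effect(0.5, c(0.5), c(0.2), 0.15), 0.1)
  # MP = 0.15 with omega = 0.0225 gives alpha = 0.1275 and theta = 0.15
  a <- compute_direct_effect(0.15, c(0.15), c(0.15), 0.15)
  expect_equal(a, (0.85 / 0.15) * 0.0225)
  expect_equal(1 - a / (a + 0.0225), 0.15)
  expect_error(compute_direct_effect(0.3, c(0, 1), c(1, 0), 0.15),
               "degenerate")
  # null law: mean E(theta), support [0.5, 1.5] * E(theta)
  set.seed(3)
  draws <- replicate(4000, compute_direct_effect(0, 0, 0, 0.15))
  expect_true(all(draws >= 0.075 & draws <= 0.225))
  expect_lt(abs(mean(draws) - 0.15), 4 * sd(draws) / sqrt(4000))
})

test_that("mediator heritabilities follow the truncated Weibull law", {
  set.seed(4)
  h <- draw_mediator_heritabilities(2e5)
  expect_true(all(h >= 0 & h <= 1))
  # quadrature oracle for the truncated mean
  trunc_mass <- pweibull(1, 0.5, 0.05)
  mean_oracle <- integrate(function(x) x * dweibull(x, 0.5, 0.05),
                           0, 1)$value / trunc_mass
  expect_lt(abs(mean(h) - mean_oracle), 4 * sd(h) / sqrt(length(h)))
  # CDF at 0.05 against the closed form
  cdf_oracle <- pweibull(0.05, 0.5, 0.05) / trunc_mass
  p_emp <- mean(h <= 0.05)
  se <- sqrt(cdf_oracle * (1 - cdf_oracle) / length(h))
  expect_lt(abs(p_emp - cdf_oracle), 3 * se)
})

test_that("instrument effects are exactly scaled and block-structured", {
  set.seed(5)
  arch <- draw_instrument_effects(0.35, 50, h2_M = c(0.1, 0.02, 0.3),
                                  l_per_mediator = c(3L, 1L, 4L))
  expect_equal(sum(arch$beta^2), 0.35)
  expect_equal(colSums(arch$B^2), c(0.1, 0.02, 0.3))
  # column j non-zero exactly in its own block of rows
  expect_equal(which(arch$B[, 1] != 0), 1:3)
  expect_equal(which(arch$B[, 2] != 0), 4L)
  expect_equal(which(arch$B[, 3] != 0), 5:8)
  expect_equal(arch$block, rep(1:3, c(3, 1, 4)))
  # k = 2 with one instrument each gives a 2x2 diagonal B
  arch2 <- draw_instrument_effects(0.2, 5, c(0.1, 0.1), c(1L, 1L))
  expect_true(all(arch2$B[row(arch2$B) != col(arch2$B)] == 0))
  expect_error(draw_instrument_effects(1.5, 5, c(0.1), 1L), "h2_X")
})

test_that("Sigma strategies give unit-diagonal PD matrices with cached Cholesky", {
  expect_equal(unname(make_sigma("identity", 4))[, ], diag(4),
               ignore_attr = TRUE)
  set.seed(6)
  S <- make_sigma("random_vectors", 50)
  expect_equal(diag(S), rep(1, 50))
  expect_equal(S, t(S), ignore_attr = TRUE)
  # 10-dim vectors give heavy sampling correlation: typical |off-diag|
  # around 0.25, far from zero
  off <- abs(S[upper.tri(S)])
  expect_gt(mean(off), 0.1)
  # cached Cholesky reproduces Sigma, and shrinkage keeps k > dim_v PD
  U <- attr(S, "chol")
  expect_lt(max(abs(crossprod(U) - S)), 1e-10)
  M <- matrix(rnorm(9), 3, 3); M <- cov2cor(crossprod(M))
  S2 <- make_sigma("empirical_matrix", 3, sigma_matrix = M)
  expect_lt(max(abs(S2 - M)), 1e-6)
  expect_error(make_sigma("empirical_matrix", 3), "user-supplied")
})

test_that("summary statistics match the generative noise model", {
  fx <- fixed_truth_arch()
  # noiseless limit: estimates equal the true effect blocks
  d0 <- noiseless_data(fx$truth, fx$arch)
  sig <- make_sigma("identity", 3)
  set.seed(8)
  d_inf <- simulate_summary_stats(fx$truth, fx$arch, sig,
                                  n_X = 1e14, n_M = 1e14, n_Y = 1e14)
  expect_lt(max(abs(d_inf$beta_hat - fx$arch$beta)), 1e-5)
  expect_lt(max(abs(d_inf$C_hat - tcrossprod(fx$arch$beta, fx$truth$gamma))),
            1e-5)
  expect_lt(max(abs(d_inf$c_hat - d0$c_hat)), 1e-5)
  expect_lt(max(abs(d_inf$b_hat - d0$b_hat)), 1e-5)

  # Monte-Carlo covariance of C-hat rows against (1/n_M + s2C) * Sigma
  set.seed(9)
  k <- 3; m <- 4
  arch <- draw_instrument_effects(0.3, m, rep(0.1, k), rep(1L, k))
  truth <- list(alpha = 0.1, gamma = c(0.2, -0.1, 0.05),
                delta = c(0.1, 0.1, -0.2))
  Sig <- make_sigma("random_vectors", k)
  n_M <- 100; s2C <- 0.002
  reps <- 1e4
  Crows <- matrix(0, reps, k)
  cvals <- numeric(reps)
  for (r in seq_len(reps)) {
    d <- simulate_summary_stats(truth, arch, Sig, n_X = 1e3, n_M = n_M,
                                n_Y = 500, pleiotropy = c(s2C, 0.001, 0))
    Crows[r, ] <- d$C_hat[1, ]
    cvals[r] <- d$c_hat[1]
  }
  emp_cov <- cov(Crows)
  target <- (1 / n_M + s2C) * Sig
  expect_lt(max(abs(emp_cov - target)), 0.06 * max(target))
  # Var(c_hat_i - beta_i * theta) = 1/n_Y + s2c
  theta <- truth$alpha + sum(truth$gamma * truth$delta)
  v_emp <- var(cvals - arch$beta[1] * theta)
  expect_lt(abs(v_emp - (1 / 500 + 0.001)) / (1 / 500 + 0.001), 0.06)

  # goodness of fit: standardized residuals of each block are N(0,1)
  set.seed(10)
  z <- replicate(1500, {
    d <- simulate_summary_stats(truth, arch, Sig, 1e3, n_M, 500,
                                pleiotropy = c(s2C, 0.001, 0.002))
    c((d$beta_hat[1] - arch$beta[1]) * sqrt(1e3),
      (d$b_hat[2] - sum(arch$B[2, ] * truth$delta)) /
        sqrt(1 / 500 + 0.002))
  })
  expect_gt(ks.test(z[1, ], "pnorm")$p.value, 0.01)
  expect_gt(ks.test(z[2, ], "pnorm")$p.value, 0.01)
})

test_that("IVW mediator selection keeps everything at P=1 and has correct null size", {
  sc <- tiny_scenario()
  set.seed(11)
  rep <- generate_replicate(sc)
  expect_equal(select_mediators(rep$data, 1), 1:3)

  # null mediator at threshold t is kept with probability <= ~t
  set.seed(12)
  m <- 30; thr <- 0.05
  arch <- draw_instrument_effects(0.3, m, c(0.1, 0.1), c(1L, 1L))
  truth <- list(alpha = 0.1, gamma = c(0.3, 0), delta = c(0.1, 0))
  Sig <- make_sigma("identity", 2)
  kept <- replicate(4000, {
    d <- simulate_summary_stats(truth, arch, Sig, 1e4, 1e3, 1e4)
    2 %in% select_mediators(d, thr)
  })
  p_emp <- mean(kept)
  expect_lt(p_emp, thr + 3 * sqrt(thr * (1 - thr) / 4000))
})

test_that("subsetting mediators keeps blocks consistent", {
  sc <- tiny_scenario()
  set.seed(13)
  rep <- generate_replicate(sc)
  d <- subset_mediators(rep$data, c(1, 3))
  expect_equal(d$k, 2)
  expect_equal(d$l, sum(rep$arch$l_per_mediator[c(1, 3)]))
  expect_equal(d$C_hat, rep$data$C_hat[, c(1, 3)])
  expect_equal(d$block, rep(1:2, rep$arch$l_per_mediator[c(1, 3)]))
})

test_that("replicates conserve theta = alpha + gamma'delta and the target MP", {
  sc <- tiny_scenario()
  for (s in 1:10) {
    set.seed(s)
    rep <- generate_replicate(sc)
    expect_equal(rep$truth$theta,
                 rep$truth$alpha + sum(rep$truth$gamma * rep$truth$delta))
    expect_equal(1 - rep$truth$alpha / rep$truth$theta, sc$mp,
                 tolerance = 1e-12)
  }
  # under the null, E(omega) = 0 but alpha stays near E(theta)
  sc0 <- tiny_scenario(mp = 0)
  set.seed(14)
  om <- replicate(300, generate_replicate(sc0)$truth$omega)
  expect_lt(abs(mean(om)), 4 * sd(om) / sqrt(300))
})

test_that("identical scenario and seed give bit-identical data", {
  sc <- tiny_scenario()
  set.seed(99); r1 <- generate_replicate(sc)
  set.seed(99); r2 <- generate_replicate(sc)
  expect_identical(r1$data, r2$data)
  expect_identical(r1$truth, r2$truth)
})
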