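## Generative model for mediation summary statistics.
##
## Standardized-trait model: the exposure X affects the outcome Y directly
## (alpha) and through k mediators M_j (gamma_j * delta_j). Instruments G
## (m of them, effects beta on X) and F (l of them, block-sparse effects B
## on M) anchor the five summary-statistic blocks
##   beta_hat ~ N(beta, I/n_X)
##   vec(B_hat) ~ N(vec(B), Sigma (x) I / n_M)
##   vec(C_hat) ~ N(vec(beta gamma'), (1/n_M + s2C) Sigma (x) I)
##   c_hat ~ N(beta (alpha + gamma'delta), (1/n_Y + s2c) I)
##   b_hat ~ N(B delta, (1/n_Y + s2b) I)
## where Sigma is the mediator phenotypic correlation matrix.

#' Solve the prior (co)variances of the mediation effects
#'
#' Given the target mediation proportion MP, expected total effect
#' E(theta), outcome variance explained by mediators sigma2_YM, the
#' correlation rho of per-mediator effects and the number of non-null
#' mediators k_s, returns the slab covariance of (gamma_i, delta_i):
#' `sigma2_d = sigma2_YM / k_s`,
#' `sigma2_g = (MP * E(theta))^2 / (k_s * sigma2_d + (k_s^2 + k_s) * rho^2 * sigma2_d)`,
#' `sigma_gd = rho * sigma_g * sigma_d`. These choices make the first two
#' moments of the total indirect effect omega = gamma'delta satisfy
#' `E(omega) = k_s * sigma_gd` and
#' `Var(omega) = k_s * (sigma2_g * sigma2_d + sigma_gd^2)`, hence
#' `E(omega)^2 + Var(omega) = (MP * E(theta))^2`.
#'
#' @param mp Mediation proportion in \[0, 1\].
#' @param expected_theta Expected total causal effect.
#' @param sigma2_YM Outcome variance explained by the mediators (> 0).
#' @param rho_gd Correlation of (gamma_i, delta_i), |rho| < 1.
#' @param k_s Number of non-null mediators (>= 1).
#' @return List with `sigma2_g`, `sigma2_d`, `sigma_gd`.
#' @examples
#' solve_prior_variances(0.15, 0.15, 0.01, 0, 1)
#' @export
solve_prior_variances <- function(mp, expected_theta, sigma2_YM, rho_gd, k_s) {
  if (k_s < 1) stop("`k_s` must be at least 1")
  if (sigma2_YM <= 0) stop("`sigma2_YM` must be positive")
  if (abs(rho_gd) >= 1) stop("`rho_gd` must be strictly inside (-1, 1)")
  sigma2_d <- sigma2_YM / k_s
  sigma2_g <- (mp * expected_theta)^2 /
    (k_s * sigma2_d + (k_s^2 + k_s) * rho_gd^2 * sigma2_d)
  sigma_gd <- rho_gd * sqrt(sigma2_g * sigma2_d)
  list(sigma2_g = sigma2_g, sigma2_d = sigma2_d, sigma_gd = sigma_gd)
}

#' Draw spike-and-slab mediation effects
#'
#' The first `k_s = round(p_k * k)` mediators receive jointly bivariate
#' Gaussian effects (gamma_i, delta_i) with the slab covariance; the
#' remaining mediators are exactly null. Uses the current RNG state.
#'
#' @param k Total number of mediators.
#' @param p_k Fraction of non-null mediators in (0, 1\].
#' @param sigma2_g,sigma2_d,sigma_gd Slab covariance entries.
#' @return List with numeric vectors `gamma` and `delta` of length `k`
#'   and the integer `k_s`.
#' @export
draw_mediation_effects <- function(k, p_k, sigma2_g, sigma2_d, sigma_gd) {
  k_s <- round(p_k * k)
  gamma <- numeric(k)
  delta <- numeric(k)
  if (k_s > 0) {
    V <- matrix(c(sigma2_g, sigma_gd, sigma_gd, sigma2_d), 2, 2)
    if (sigma2_g < 0 || sigma2_d < 0 ||
        sigma_gd^2 > sigma2_g * sigma2_d + 1e-15)
      stop("slab covariance matrix is not positive semi-definite")
    # 2x2 Cholesky-style factor robust to zero variances
    a <- sqrt(sigma2_g)
    b <- if (a > 0) sigma_gd / a else 0
    c2 <- sigma2_d - b^2
    cc <- sqrt(max(c2, 0))
    z1 <- stats::rnorm(k_s)
    z2 <- stats::rnorm(k_s)
    gamma[seq_len(k_s)] <- a * z1
    delta[seq_len(k_s)] <- b * z1 + cc * z2
  }
  list(gamma = gamma, delta = delta, k_s = k_s)
}

#' Direct effect consistent with the target mediation proportion
#'
#' With `mp > 0` the direct effect is fully determined by the realized
#' indirect effect: `alpha = (1 - mp)/mp * sum(gamma * delta)`, so that
#' `MP = 1 - alpha/theta` holds exactly for each replicate. Under the
#' no-mediation null (`mp = 0`) alpha is drawn uniformly around
#' E(theta), on `range * expected_theta`.
#'
#' @param mp Mediation proportion.
#' @param gamma,delta Mediation effect vectors.
#' @param expected_theta Expected total effect (used when `mp = 0`).
#' @param range Support of the uniform law relative to `expected_theta`.
#' @return The direct effect `alpha` (scalar).
#' @export
compute_direct_effect <- function(mp, gamma, delta, expected_theta,
                                  range = c(0.5, 1.5)) {
  if (mp < 0 || mp > 1) stop("`mp` must be in [0, 1]")
  if (mp == 0)
    return(stats::runif(1, range[1] * expected_theta,
                        range[2] * expected_theta))
  omega <- sum(gamma * delta)
  if (omega == 0)
    stop("degenerate model: mp > 0 but the indirect effect is exactly zero")
  (1 - mp) / mp * omega
}

#' Draw mediator heritabilities
#'
#' i.i.d. Weibull(shape 0.5, scale 0.05) truncated to \[0, 1\], mimicking
#' the heavy-right-skewed distribution of variance explained by top
#' cis-QTLs of molecular traits. Truncation is exact (inverse-CDF).
#'
#' @param k Number of mediators.
#' @param shape,scale Weibull parameters.
#' @return Numeric vector of heritabilities in \[0, 1\].
#' @export
draw_mediator_heritabilities <- function(k, shape = 0.5, scale = 0.05) {
  stopifnot(k >= 1)
  u <- stats::runif(k, 0, stats::pweibull(1, shape, scale))
  stats::qweibull(u, shape, scale)
}

#' Draw per-mediator instrument counts
#'
#' Zero-truncated geometric with the given mean (default 3), capturing
#' the right-skewed "effective number of instruments" of cis-QTL data.
#'
#' @param k Number of mediators.
#' @param mean_count Mean instrument count (> 1).
#' @return Integer vector of counts, all >= 1.
#' @export
draw_instrument_counts <- function(k, mean_count = 3) {
  stopifnot(mean_count > 1)
  p <- 1 / mean_count
  stats::rgeom(k, p) + 1L
}

#' Draw true instrument effects for the exposure and mediators
#'
#' Exposure instrument effects are Gaussian and rescaled post hoc so that
#' `sum(beta^2) == h2_X` exactly. Mediator instrument effects live in
#' disjoint row blocks of the l x k matrix B (rows
#' `sum(l_u, u < j) + 1 ... sum(l_u, u <= j)` for mediator j), each column
#' rescaled so its sum of squares equals that mediator's heritability.
#'
#' @param h2_X Exposure heritability in (0, 1).
#' @param m Number of exposure instruments.
#' @param h2_M Vector of k mediator heritabilities.
#' @param l_per_mediator Integer vector of per-mediator instrument counts.
#' @return List with `beta` (length m), `B` (l x k), `h2_M`,
#'   `l_per_mediator` and `block` (length-l integer vector mapping each
#'   mediator instrument to its mediator).
#' @export
draw_instrument_effects <- function(h2_X, m, h2_M, l_per_mediator) {
  if (!(h2_X > 0 && h2_X < 1)) stop("`h2_X` must be in (0, 1)")
  if (any(h2_M < 0) || any(h2_M > 1)) stop("mediator heritabilities must be in [0, 1]")
  if (any(l_per_mediator < 1)) stop("all instrument counts must be >= 1")
  k <- length(h2_M)
  stopifnot(length(l_per_mediator) == k)
  beta <- stats::rnorm(m, 0, sqrt(h2_X / m))
  beta <- beta * sqrt(h2_X / sum(beta^2))
  l <- sum(l_per_mediator)
  B <- matrix(0, l, k)
  offset <- 0L
  for (j in seq_len(k)) {
    lj <- l_per_mediator[j]
    rows <- offset + seq_len(lj)
    bj <- stats::rnorm(lj, 0, sqrt(h2_M[j] / lj))
    ssq <- sum(bj^2)
    if (h2_M[j] > 0 && ssq > 0) bj <- bj * sqrt(h2_M[j] / ssq)
    B[rows, j] <- bj
    offset <- offset + lj
  }
  list(beta = beta, B = B, h2_M = h2_M, l_per_mediator = l_per_mediator,
       block = rep(seq_len(k), l_per_mediator))
}

#' Build the mediator phenotypic correlation matrix
#'
#' Strategies: `"identity"` returns I_k; `"random_vectors"` builds
#' `Sigma[i, j] = cor(V_i, V_j)` from k independent 10-dimensional
#' standard-Gaussian vectors (low dimension on purpose, giving heavy
#' sampling correlations); `"empirical_matrix"` takes a user-supplied
#' correlation matrix (or square TSV file keyed by mediator). Matrices
#' that are not positive definite are shrunk toward identity
#' (`(1 - lambda) * Sigma + lambda * I`, default `lambda = 1e-6`); the
#' Cholesky factor is cached in the `"chol"` attribute.
#'
#' @param strategy One of `"identity"`, `"random_vectors"`,
#'   `"empirical_matrix"`.
#' @param k Number of mediators.
#' @param sigma_matrix Matrix or TSV path for `"empirical_matrix"`.
#' @param lambda Shrinkage weight toward identity.
#' @param dim_v Dimension of the random vectors.
#' @return k x k correlation matrix with attribute `"chol"` (upper
#'   triangular `U` with `Sigma = U'U`).
#' @export
make_sigma <- function(strategy = c("identity", "random_vectors",
                                    "empirical_matrix"),
                       k, sigma_matrix = NULL, lambda = 1e-6, dim_v = 10) {
  strategy <- match.arg(strategy)
  Sigma <- switch(strategy,
    identity = diag(k),
    random_vectors = stats::cor(matrix(stats::rnorm(dim_v * k), dim_v, k)),
    empirical_matrix = {
      if (is.null(sigma_matrix))
        stop("`empirical_matrix` requires a user-supplied correlation matrix")
      if (is.character(sigma_matrix))
        sigma_matrix <- as.matrix(utils::read.table(sigma_matrix, sep = "\t",
                                                    header = TRUE,
                                                    row.names = 1,
                                                    check.names = FALSE))
      sm <- as.matrix(sigma_matrix)
      if (nrow(sm) != k || ncol(sm) != k)
        stop("supplied correlation matrix must be ", k, " x ", k)
      sm
    })
  Sigma <- (Sigma + t(Sigma)) / 2
  diag(Sigma) <- 1
  U <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(U)) {
    Sigma <- (1 - lambda) * Sigma + lambda * diag(k)
    U <- tryCatch(chol(Sigma), error = function(e)
      stop("Sigma is not positive definite even after shrinkage; ",
           "increase `lambda`"))
  }
  attr(Sigma, "chol") <- U
  Sigma
}

#' Construct a summary-statistics container
#'
#' The five estimate blocks plus the sample sizes, per-element outcome
#' variances and pleiotropy components that every estimator consumes.
#'
#' @param beta_hat Length-m exposure instrument effects on the exposure.
#' @param C_hat m x k exposure instrument effects on the mediators.
#' @param B_hat l x k mediator instrument effects on the mediators.
#' @param c_hat Length-m exposure instrument effects on the outcome.
#' @param b_hat Length-l mediator instrument effects on the outcome.
#' @param n_X,n_M,n_Y Study sample sizes.
#' @param pleiotropy Vector `(sigma2_C, sigma2_c, sigma2_b)`.
#' @param var_c,var_b Per-element variances of `c_hat`/`b_hat`; default
#'   `1/n_Y + sigma2_c` and `1/n_Y + sigma2_b`.
#' @param block Optional length-l integer vector assigning each mediator
#'   instrument to the mediator it instruments.
#' @param mediator_ids Optional mediator names.
#' @return An object of class `"summary_data"`.
#' @export
summary_data <- function(beta_hat, C_hat, B_hat, c_hat, b_hat,
                         n_X, n_M, n_Y,
                         pleiotropy = c(sigma2_C = 0, sigma2_c = 0,
                                        sigma2_b = 0),
                         var_c = NULL, var_b = NULL,
                         block = NULL, mediator_ids = NULL) {
  beta_hat <- as.numeric(beta_hat); c_hat <- as.numeric(c_hat)
  b_hat <- as.numeric(b_hat)
  C_hat <- as.matrix(C_hat); B_hat <- as.matrix(B_hat)
  m <- length(beta_hat); l <- length(b_hat); k <- ncol(C_hat)
  if (length(c_hat) != m || nrow(C_hat) != m)
    stop("`c_hat` and rows of `C_hat` must match `beta_hat`")
  if (nrow(B_hat) != l || ncol(B_hat) != k)
    stop("`B_hat` must be length(b_hat) x ncol(C_hat)")
  pleiotropy <- as.numeric(pleiotropy)
  names(pleiotropy) <- c("sigma2_C", "sigma2_c", "sigma2_b")
  if (is.null(var_c)) var_c <- rep(1 / n_Y + pleiotropy["sigma2_c"], m)
  if (is.null(var_b)) var_b <- rep(1 / n_Y + pleiotropy["sigma2_b"], l)
  if (any(var_c <= 0) || any(var_b <= 0))
    stop("all outcome-effect variances must be positive")
  if (!is.null(block)) {
    block <- as.integer(block)
    if (length(block) != l) stop("`block` must have one entry per row of B_hat")
  }
  mediator_ids <- mediator_ids %||% paste0("M", seq_len(k))
  if (k > 0) {
    colnames(C_hat) <- mediator_ids
    colnames(B_hat) <- mediator_ids
  }
  structure(list(beta_hat = beta_hat, C_hat = C_hat, B_hat = B_hat,
                 c_hat = c_hat, b_hat = b_hat,
                 n_X = n_X, n_M = n_M, n_Y = n_Y,
                 pleiotropy = pleiotropy,
                 var_c = as.numeric(var_c), var_b = as.numeric(var_b),
                 block = block,
                 mediator_ids = mediator_ids,
                 m = m, l = l, k = k),
            class = "summary_data")
}

#' @export
print.summary_data <- function(x, ...) {
  cat(sprintf(
    "Mediation summary statistics: m=%d exposure instruments, l=%d mediator instruments, k=%d mediators\n",
    x$m, x$l, x$k))
  cat(sprintf("  n_X=%g n_M=%g n_Y=%g; pleiotropy=(%g,%g,%g)\n",
              x$n_X, x$n_M, x$n_Y, x$pleiotropy[1], x$pleiotropy[2],
              x$pleiotropy[3]))
  invisible(x)
}

#' Simulate noisy summary statistics from a true mediation model
#'
#' Adds Gaussian estimation noise at the scale implied by the study
#' sample sizes (and pleiotropy components) to the true effect blocks.
#' Rows of the B-hat and C-hat noise are correlated across mediators via
#' the Cholesky factor of Sigma.
#'
#' @param truth List with `alpha`, `gamma`, `delta` (see
#'   [generate_replicate()]).
#' @param arch Genetic architecture from [draw_instrument_effects()].
#' @param Sigma Mediator correlation matrix from [make_sigma()].
#' @param n_X,n_M,n_Y Study sample sizes.
#' @param pleiotropy Vector `(sigma2_C, sigma2_c, sigma2_b)`.
#' @return A [summary_data()] object.
#' @export
simulate_summary_stats <- function(truth, arch, Sigma, n_X, n_M, n_Y,
                                   pleiotropy = c(0, 0, 0)) {
  beta <- arch$beta; B <- arch$B
  m <- length(beta); l <- nrow(B); k <- ncol(B)
  stopifnot(length(truth$gamma) == k, length(truth$delta) == k,
            nrow(Sigma) == k)
  U <- attr(Sigma, "chol") %||% chol(Sigma)
  s2C <- pleiotropy[1]; s2c <- pleiotropy[2]; s2b <- pleiotropy[3]
  theta <- truth$alpha + sum(truth$gamma * truth$delta)

  beta_hat <- beta + stats::rnorm(m, 0, sqrt(1 / n_X))
  B_hat <- B + sqrt(1 / n_M) *
    (matrix(stats::rnorm(l * k), l, k) %*% U)
  C_hat <- tcrossprod(beta, truth$gamma) + sqrt(1 / n_M + s2C) *
    (matrix(stats::rnorm(m * k), m, k) %*% U)
  c_hat <- beta * theta + stats::rnorm(m, 0, sqrt(1 / n_Y + s2c))
  b_hat <- drop(B %*% truth$delta) +
    stats::rnorm(l, 0, sqrt(1 / n_Y + s2b))

  summary_data(beta_hat, C_hat, B_hat, c_hat, b_hat,
               n_X = n_X, n_M = n_M, n_Y = n_Y,
               pleiotropy = pleiotropy, block = arch$block)
}

#' Univariable IVW screen of exposure -> mediator effects
#'
#' For each mediator j, runs inverse-variance weighted MR of the exposure
#' on mediator j using `(beta_hat, C_hat[, j])` and keeps mediators whose
#' two-sided p-value passes the threshold.
#'
#' @param data A [summary_data()] object.
#' @param threshold p-value threshold in (0, 1\]; `threshold = 1` keeps
#'   all mediators.
#' @return Integer vector of retained mediator indices (possibly empty).
#' @export
select_mediators <- function(data, threshold) {
  stopifnot(inherits(data, "summary_data"), threshold > 0, threshold <= 1)
  var_C <- 1 / data$n_M + data$pleiotropy["sigma2_C"]
  ssq <- sum(data$beta_hat^2)
  est <- drop(crossprod(data$C_hat, data$beta_hat)) / ssq
  se <- sqrt(var_C / ssq)
  p <- 2 * stats::pnorm(-abs(est / se))
  unname(which(p <= threshold))
}

#' Restrict summary data to a subset of mediators
#'
#' Keeps the selected columns of B-hat/C-hat and drops the rows of B-hat
#' (and entries of b-hat) belonging to instruments of dropped mediators.
#'
#' @param data A [summary_data()] object with a `block` mapping.
#' @param keep Integer vector of mediator indices to retain.
#' @return A [summary_data()] object with `length(keep)` mediators.
#' @export
subset_mediators <- function(data, keep) {
  stopifnot(inherits(data, "summary_data"), length(keep) >= 1)
  if (is.null(data$block))
    stop("summary data carries no instrument-to-mediator mapping")
  rows <- data$block %in% keep
  new_block <- match(data$block[rows], keep)
  summary_data(data$beta_hat, data$C_hat[, keep, drop = FALSE],
               data$B_hat[rows, keep, drop = FALSE],
               data$c_hat, data$b_hat[rows],
               n_X = data$n_X, n_M = data$n_M, n_Y = data$n_Y,
               pleiotropy = data$pleiotropy,
               var_c = data$var_c, var_b = data$var_b[rows],
               block = new_block,
               mediator_ids = data$mediator_ids[keep])
}

#' Generate one full simulation replicate
#'
#' Draws a complete fictional study from a scenario: slab covariance via
#' [solve_prior_variances()], spike-and-slab mediation effects, the
#' direct effect, Weibull mediator heritabilities, instrument counts and
#' effects, the mediator correlation matrix, and finally the noisy
#' summary statistics. Uses the current RNG state; seed externally for
#' reproducibility.
#'
#' @param scenario A [lima_scenario()].
#' @return List with `truth` (alpha, gamma, delta, omega, theta, mp,
#'   k_s), `arch`, `Sigma` and `data` (a [summary_data()]).
#' @export
generate_replicate <- function(scenario) {
  stopifnot(inherits(scenario, "lima_scenario"))
  sc <- scenario
  if (sc$mp > 0) {
    k_s <- max(1L, round(sc$p_k * sc$k))
    pv <- solve_prior_variances(sc$mp, sc$expected_theta, sc$sigma2_YM,
                                sc$rho_gd, k_s)
    eff <- draw_mediation_effects(sc$k, sc$p_k, pv$sigma2_g, pv$sigma2_d,
                                  pv$sigma_gd)
    # guard against a zero indirect effect (probability-zero event)
    while (sum(eff$gamma * eff$delta) == 0)
      eff <- draw_mediation_effects(sc$k, sc$p_k, pv$sigma2_g, pv$sigma2_d,
                                    pv$sigma_gd)
  } else if (round(sc$p_k * sc$k) >= 1) {
    # no-mediation null: mediators look like typical candidates (same
    # marginal effect scales as a null_slab_mp alternative) but with the
    # gamma-delta coupling removed, so E(omega) = 0 while per-replicate
    # indirect effects fluctuate around zero
    k_s <- round(sc$p_k * sc$k)
    pv <- solve_prior_variances(sc$null_slab_mp, sc$expected_theta,
                                sc$sigma2_YM, sc$rho_gd, k_s)
    eff <- draw_mediation_effects(sc$k, sc$p_k, pv$sigma2_g, pv$sigma2_d,
                                  sigma_gd = 0)
  } else {
    eff <- list(gamma = numeric(sc$k), delta = numeric(sc$k), k_s = 0L)
  }
  alpha <- compute_direct_effect(sc$mp, eff$gamma, eff$delta,
                                 sc$expected_theta, sc$alpha_null_range)
  omega <- sum(eff$gamma * eff$delta)
  truth <- list(alpha = alpha, gamma = eff$gamma, delta = eff$delta,
                omega = omega, theta = alpha + omega, mp = sc$mp,
                k_s = eff$k_s)
  h2_M <- draw_mediator_heritabilities(sc$k)
  l_j <- scenario$l_per_mediator %||% draw_instrument_counts(sc$k, sc$l_mean)
  arch <- draw_instrument_effects(sc$h2_X, sc$m, h2_M, l_j)
  Sigma <- make_sigma(sc$sigma_strategy, sc$k, sc$sigma_matrix)
  data <- simulate_summary_stats(truth, arch, Sigma,
                                 sc$n_X, sc$n_M, sc$n_Y, sc$pleiotropy)
  list(truth = truth, arch = arch, Sigma = Sigma, data = data)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
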