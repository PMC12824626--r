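## LiMA: joint maximum-likelihood estimation of (alpha, gamma, delta).
##
## The joint likelihood factorizes over the three outcome-side blocks,
## conditioning on the estimated instrument effects. Substituting the
## noisy regressors inflates each conditional variance by the regressor
## measurement error:
##   b_hat_i | B_hat_i., delta ~ N(B_hat_i. delta,
##                                 1/n_Y + s2b + delta' Sigma delta / n_M)
##   c_hat_i | beta_hat_i      ~ N(beta_hat_i (alpha + gamma'delta),
##                                 1/n_Y + s2c + (alpha + gamma'delta)^2 / n_X)
##   C_hat_i. | beta_hat_i     ~ N(beta_hat_i gamma,
##                                 (1/n_M + s2C) Sigma + gamma gamma' / n_X)
## Averaged over the Gaussian prior on (gamma, delta) these variances
## reproduce the marginal moments used by I-LiMA, which is the internal
## consistency check applied in the test suite.

#' LiMA joint log-likelihood
#'
#' Evaluates the log-likelihood of the five summary-statistic blocks at
#' parameters (alpha, gamma, delta). The mediator correlation matrix
#' defaults to the identity; a user-supplied `Sigma` is honoured via
#' dense k x k solves.
#'
#' @param params List with numeric `alpha`, `gamma` (length k), `delta`
#'   (length k).
#' @param data A [summary_data()] object.
#' @param Sigma Optional k x k mediator correlation matrix (default
#'   identity).
#' @return Scalar log-likelihood.
#' @export
lima_loglik <- function(params, data, Sigma = NULL) {
  alpha <- params$alpha; gamma <- params$gamma; delta <- params$delta
  if (!all(is.finite(c(alpha, gamma, delta))))
    stop("non-finite parameters")
  k <- data$k
  stopifnot(length(gamma) == k, length(delta) == k)
  s2C <- data$pleiotropy[["sigma2_C"]]
  theta <- alpha + sum(gamma * delta)
  sM2 <- 1 / data$n_M + s2C

  # b-hat block: homoscedastic after conditioning on B-hat
  dSd <- if (is.null(Sigma)) sum(delta^2) else drop(crossprod(delta, Sigma %*% delta))
  sb2 <- mean(data$var_b) + dSd / data$n_M
  ll_b <- if (data$l > 0) {
    r_b <- data$b_hat - drop(data$B_hat %*% delta)
    sum(stats::dnorm(r_b, 0, sqrt(sb2), log = TRUE))
  } else 0

  # c-hat block
  sc2 <- mean(data$var_c) + theta^2 / data$n_X
  r_c <- data$c_hat - data$beta_hat * theta
  ll_c <- sum(stats::dnorm(r_c, 0, sqrt(sc2), log = TRUE))

  # C-hat block: common row covariance sM2 * Sigma + gamma gamma' / n_X
  ll_C <- 0
  if (k > 0) {
    R <- data$C_hat - tcrossprod(data$beta_hat, gamma)
    if (is.null(Sigma)) {
      # rank-1 update of a scaled identity: Sherman-Morrison closed form
      g2 <- sum(gamma^2)
      denom <- sM2 + g2 / data$n_X
      logdet <- (k - 1) * log(sM2) + log(denom)
      q <- (rowSums(R^2) - (drop(R %*% gamma))^2 / (data$n_X * denom)) / sM2
    } else {
      S <- sM2 * Sigma + tcrossprod(gamma) / data$n_X
      U <- chol(S)
      logdet <- 2 * sum(log(diag(U)))
      Z <- backsolve(U, t(R), transpose = TRUE)
      q <- colSums(Z^2)
    }
    ll_C <- -0.5 * data$m * (k * log(2 * pi) + logdet) - 0.5 * sum(q)
  }
  ll_b + ll_c + ll_C
}

#' Fit LiMA by maximizing the joint log-likelihood
#'
#' Quasi-Newton (BFGS) maximization over the 2k+1 free parameters,
#' warm-started at the two-step MR estimates (column-wise IVW for gamma,
#' MVMR for delta and alpha), with jittered restarts if the optimizer
#' reports failure. Non-convergence is returned as a flag, not an error,
#' so replicate drivers can exclude such fits from MP aggregation.
#'
#' @param data A [summary_data()] object.
#' @param init Optional list with starting `alpha`, `gamma`, `delta`.
#' @param Sigma Optional mediator correlation matrix for the likelihood
#'   (defaults to identity regardless of how the data were generated).
#' @param max_restarts Number of jittered restarts after a failed fit.
#' @param warn_k Warn when the mediator count exceeds this (runtime grows
#'   quickly with the parameter count).
#' @return A `"mediation_fit"` list with `alpha`, `gamma`, `delta`,
#'   `omega = gamma'delta`, `theta`, `loglik`, `converged`.
#' @export
fit_lima <- function(data, init = NULL, Sigma = NULL, max_restarts = 3,
                     warn_k = 30) {
  stopifnot(inherits(data, "summary_data"))
  k <- data$k
  if (k > warn_k)
    warning("LiMA optimizes ", 2 * k + 1,
            " parameters; consider I-LiMA for large mediator sets")
  if (is.null(init)) {
    var_C <- 1 / data$n_M + data$pleiotropy[["sigma2_C"]]
    gamma0 <- drop(crossprod(data$C_hat, data$beta_hat)) /
      sum(data$beta_hat^2)
    mv <- tryCatch(mvmr_direct_effect(data), error = function(e) NULL)
    if (is.null(mv)) {
      alpha0 <- ivw_total_effect(data$beta_hat, data$c_hat, data$var_c)$estimate
      delta0 <- numeric(k)
    } else {
      alpha0 <- mv$alpha_hat; delta0 <- mv$delta_hat
    }
    init <- list(alpha = alpha0, gamma = gamma0, delta = delta0)
  }
  pack <- function(p) unname(c(p$alpha, p$gamma, p$delta))
  unpack <- function(x) list(alpha = unname(x[1]),
                             gamma = unname(x[1 + seq_len(k)]),
                             delta = unname(x[1 + k + seq_len(k)]))
  negll <- function(x) {
    v <- -lima_loglik(unpack(x), data, Sigma = Sigma)
    if (!is.finite(v)) 1e12 else v
  }
  best <- NULL
  x0 <- pack(init)
  for (attempt in 0:max_restarts) {
    start <- if (attempt == 0) x0 else
      x0 * (1 + stats::rnorm(length(x0), 0, 0.1)) +
        stats::rnorm(length(x0), 0, 1e-3)
    opt <- tryCatch(
      stats::optim(start, negll, method = "BFGS",
                   control = list(maxit = 1000, reltol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(opt) &&
        (is.null(best) || opt$value < best$value)) best <- opt
    if (!is.null(best) && best$convergence == 0) break
  }
  if (is.null(best))
    return(structure(list(method = "lima", alpha = NA_real_,
                          gamma = rep(NA_real_, k), delta = rep(NA_real_, k),
                          omega = NA_real_, theta = NA_real_,
                          loglik = NA_real_, converged = FALSE),
                     class = "mediation_fit"))
  est <- unpack(best$par)
  structure(list(method = "lima",
                 alpha = est$alpha, gamma = est$gamma, delta = est$delta,
                 omega = sum(est$gamma * est$delta),
                 theta = est$alpha + sum(est$gamma * est$delta),
                 loglik = -best$value,
                 converged = best$convergence == 0),
            class = "mediation_fit")
}

# Outcome-block profile log-likelihood in (alpha, omega); this is the
# only joint-likelihood component that depends on alpha and omega, and
# the basis of the LiMA likelihood-ratio variances.
lima_c_loglik <- function(alpha, omega, data) {
  theta <- alpha + omega
  sc2 <- mean(data$var_c) + theta^2 / data$n_X
  r <- data$c_hat - data$beta_hat * theta
  sum(stats::dnorm(r, 0, sqrt(sc2), log = TRUE))
}
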