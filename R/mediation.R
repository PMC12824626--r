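## Mediation-proportion estimation: likelihood-ratio variances for the
## ML fits, delta-method MP for single exposure-outcome pairs, and
## no-intercept regression MP for groups of pairs.

#' Likelihood-ratio variances of the direct, indirect and total effects
#'
#' For a likelihood fit with estimates (alpha_hat, omega_hat), the LRT
#' statistics `chi2_alpha = -2 log L(0, omega_hat)/L(alpha_hat,
#' omega_hat)` and `chi2_omega = -2 log L(alpha_hat, 0)/L(alpha_hat,
#' omega_hat)` are converted to variances by the standard LRT-Wald
#' correspondence `Var(alpha_hat) = alpha_hat^2 / chi2_alpha` (similarly
#' for omega), with `Var(theta_hat) = Var(alpha_hat) + Var(omega_hat)`.
#' For LiMA the profile likelihood is the outcome block of the joint
#' likelihood (the only component depending on alpha and omega); for
#' I-LiMA it is the full marginal likelihood. A fit exactly at the null
#' (`chi2 = 0`) yields an infinite variance, reported as such. For the
#' two-step MR fit the OLS/WLS variances stored on the fit are returned
#' unchanged.
#'
#' @param fit A `"mediation_fit"` from [fit_lima()], [fit_ilima()] or
#'   [mr_mvmr_mediation()].
#' @param data The [summary_data()] the fit was computed from.
#' @return List with `var_alpha`, `var_omega`, `var_theta`.
#' @export
lrt_variances <- function(fit, data) {
  stopifnot(inherits(fit, "mediation_fit"))
  if (fit$method == "mr_mvmr")
    return(list(var_alpha = fit$var_alpha, var_omega = fit$var_omega,
                var_theta = fit$var_theta))
  if (!isTRUE(fit$converged))
    return(list(var_alpha = NA_real_, var_omega = NA_real_,
                var_theta = NA_real_))
  ll <- switch(fit$method,
    lima = function(a, o) lima_c_loglik(a, o, data),
    ilima = function(a, o) ilima_profile_loglik(a, o, fit, data),
    stop("unknown likelihood fit method: ", fit$method))
  ll_full <- ll(fit$alpha, fit$omega)
  chi2_a <- -2 * (ll(0, fit$omega) - ll_full)
  chi2_o <- -2 * (ll(fit$alpha, 0) - ll_full)
  var_alpha <- if (chi2_a > 0) fit$alpha^2 / chi2_a else Inf
  var_omega <- if (chi2_o > 0) fit$omega^2 / chi2_o else Inf
  list(var_alpha = var_alpha, var_omega = var_omega,
       var_theta = var_alpha + var_omega)
}

#' Mediation proportion of a single exposure-outcome pair
#'
#' `MP_hat = 1 - alpha_hat / theta_hat` with the delta-method variance
#' `Var(MP_hat) = (alpha^2/theta^2) * (Var(alpha)/alpha^2 +
#' Var(theta)/theta^2)` (no covariance term). The estimate is flagged as
#' `defined` only when it lies in \[0, 1\] and the direct and total
#' effects share a sign. `theta_hat = 0` yields an undefined result, not
#' an error.
#'
#' @param alpha_hat,theta_hat Direct and total effect estimates.
#' @param var_alpha,var_theta Their variances.
#' @return List of class `"mp_estimate"`: `mp_hat`, `var_mp`, `ci`
#'   (95\% normal), `defined`, `n_pairs = 1`, `method = "single"`.
#' @examples
#' mp_single(0.1275, 0.15, 1e-4, 1e-4)$mp_hat  # 0.15
#' @export
mp_single <- function(alpha_hat, theta_hat, var_alpha, var_theta) {
  if (!is.finite(theta_hat) || theta_hat == 0)
    return(structure(list(mp_hat = NA_real_, var_mp = NA_real_,
                          ci = c(NA_real_, NA_real_), defined = FALSE,
                          n_pairs = 1L, method = "single"),
                     class = "mp_estimate"))
  mp <- 1 - alpha_hat / theta_hat
  var_mp <- if (alpha_hat == 0) 0 else
    (alpha_hat^2 / theta_hat^2) *
      (var_alpha / alpha_hat^2 + var_theta / theta_hat^2)
  se <- sqrt(var_mp)
  structure(list(mp_hat = mp, var_mp = var_mp,
                 ci = c(mp - 1.96 * se, mp + 1.96 * se),
                 defined = (mp >= 0 && mp <= 1 &&
                              sign(alpha_hat) == sign(theta_hat)),
                 n_pairs = 1L, method = "single"),
            class = "mp_estimate")
}

#' Mediation proportion of a group of exposure-outcome pairs
#'
#' No-intercept linear regression of the direct effects on the total
#' effects: `MP_hat = 1 - sum(alpha_i * theta_i) / sum(theta_i^2)`, with
#' `Var(MP_hat) = sigma2 / sum(theta_i^2)` where `sigma2` is the residual
#' variance of the regression (RSS / (n - 1); one slope parameter, no
#' intercept). Non-finite pairs are dropped.
#'
#' @param alpha_hats,theta_hats Equal-length vectors of per-pair direct
#'   and total effect estimates.
#' @return List of class `"mp_estimate"` with `mp_hat`, `var_mp`, `ci`,
#'   `defined`, `n_pairs`, `method = "group"`.
#' @examples
#' mp_group(c(0.05, 0.10), c(0.1, 0.2))$mp_hat  # 0.5
#' @export
mp_group <- function(alpha_hats, theta_hats) {
  ok <- is.finite(alpha_hats) & is.finite(theta_hats)
  a <- alpha_hats[ok]; th <- theta_hats[ok]
  n <- length(a)
  if (n < 2 || all(th == 0))
    return(structure(list(mp_hat = NA_real_, var_mp = NA_real_,
                          ci = c(NA_real_, NA_real_), defined = FALSE,
                          n_pairs = n, method = "group"),
                     class = "mp_estimate"))
  ssq <- sum(th^2)
  slope <- sum(a * th) / ssq
  mp <- 1 - slope
  resid <- a - slope * th
  sigma2 <- sum(resid^2) / (n - 1)
  var_mp <- sigma2 / ssq
  se <- sqrt(var_mp)
  structure(list(mp_hat = mp, var_mp = var_mp,
                 ci = c(mp - 1.96 * se, mp + 1.96 * se),
                 defined = (mp >= 0 && mp <= 1),
                 n_pairs = n, method = "group"),
            class = "mp_estimate")
}

#' @export
print.mp_estimate <- function(x, ...) {
  cat(sprintf("MP estimate (%s, n=%d): %.4f (var %.3g, 95%% CI [%.3f, %.3f])%s\n",
              x$method, x$n_pairs, x$mp_hat, x$var_mp, x$ci[1], x$ci[2],
              if (isTRUE(x$defined)) "" else " [not a defined MP]"))
  invisible(x)
}

#' Per-pair mediation proportion from a fit
#'
#' Convenience wrapper combining [lrt_variances()] and [mp_single()]:
#' returns the MP estimate, its variance and 95\% CI for one fitted
#' mediation model.
#'
#' @inheritParams lrt_variances
#' @param theta_min Optional reporting filter: return an undefined MP
#'   when `|theta_hat|` falls below this threshold (0 disables; a value
#'   of 0.1 on the standardized scale is a reasonable choice when
#'   screening many pairs).
#' @return An `"mp_estimate"`.
#' @export
mp_from_fit <- function(fit, data, theta_min = 0) {
  if (!isTRUE(fit$converged) ||
      (theta_min > 0 && abs(fit$theta) < theta_min))
    return(structure(list(mp_hat = NA_real_, var_mp = NA_real_,
                          ci = c(NA_real_, NA_real_), defined = FALSE,
                          n_pairs = 1L, method = "single"),
                     class = "mp_estimate"))
  v <- lrt_variances(fit, data)
  mp_single(fit$alpha, fit$theta, v$var_alpha, v$var_theta)
}
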