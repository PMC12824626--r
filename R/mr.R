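## Two-step MR baseline: univariable IVW for the total effect theta and
## block-matrix IVW MVMR for the direct effect alpha.

#' Inverse-variance weighted total causal effect
#'
#' Weighted least squares of the instrument-outcome effects on the
#' instrument-exposure effects,
#' `theta_hat = (b' L^-1 b)^-1 b' L^-1 c` with `L = diag(var_c)`,
#' `Var(theta_hat) = (b' L^-1 b)^-1`. With a single instrument this is
#' the Wald ratio `c1/b1` with first-order Taylor variance
#' `Var(c1)/b1^2`. Optionally `L` may be replaced by a full weighting
#' matrix (e.g. an LD correlation matrix) for correlated instruments.
#'
#' @param beta_hat Instrument effects on the exposure (length m).
#' @param c_hat Instrument effects on the outcome (length m).
#' @param var_c Per-instrument variances of `c_hat` (recycled if scalar).
#' @param weight_matrix Optional m x m matrix replacing `diag(var_c)`.
#' @return List of class `"ivw_result"`: `estimate`, `variance`,
#'   `n_instruments`, `p_value`.
#' @examples
#' ivw_total_effect(0.2, 0.1, 0.01)$estimate  # Wald ratio 0.5
#' @export
ivw_total_effect <- function(beta_hat, c_hat, var_c,
                             weight_matrix = NULL) {
  beta_hat <- as.numeric(beta_hat); c_hat <- as.numeric(c_hat)
  m <- length(beta_hat)
  stopifnot(m >= 1, length(c_hat) == m)
  var_c <- rep_len(as.numeric(var_c), m)
  if (any(var_c <= 0)) stop("`var_c` must be strictly positive")
  if (all(beta_hat == 0)) stop("singular design: all instrument effects are zero")
  if (is.null(weight_matrix)) {
    w <- 1 / var_c
    denom <- sum(beta_hat^2 * w)
    est <- sum(beta_hat * c_hat * w) / denom
  } else {
    Wi <- solve(weight_matrix, cbind(beta_hat, c_hat))
    denom <- sum(beta_hat * Wi[, 1])
    est <- sum(beta_hat * Wi[, 2]) / denom
  }
  variance <- 1 / denom
  z <- est / sqrt(variance)
  structure(list(estimate = est, variance = variance, n_instruments = m,
                 p_value = 2 * stats::pnorm(-abs(z))),
            class = "ivw_result")
}

#' Multivariable MR direct effect
#'
#' IVW MVMR on the stacked design `Pi = [[beta_hat, C_hat], [0, B_hat]]`
#' of dimension (m+l) x (k+1) against the stacked outcome effects
#' `pi = [c_hat; b_hat]`, weights `diag(var_c, var_b)`:
#' `(alpha_hat, delta_hat) = (Pi' L^-1 Pi)^-1 Pi' L^-1 pi`, with
#' covariance `(Pi' L^-1 Pi)^-1`. The zero block encodes the framework
#' assumption that mediator instruments have no effect on the exposure.
#'
#' @param data A [summary_data()] object (`k = 0` reduces to
#'   [ivw_total_effect()] on the exposure instruments).
#' @param weight_matrix Optional (m+l) x (m+l) matrix replacing the
#'   diagonal variance weighting (correlated instruments).
#' @return List of class `"mvmr_result"`: `alpha_hat`, `delta_hat`,
#'   `var_alpha`, `covariance` (the full (k+1) x (k+1) matrix).
#' @export
mvmr_direct_effect <- function(data, weight_matrix = NULL) {
  stopifnot(inherits(data, "summary_data"))
  k <- data$k
  if (k == 0) {
    fit <- ivw_total_effect(data$beta_hat, data$c_hat, data$var_c)
    return(structure(list(alpha_hat = fit$estimate, delta_hat = numeric(0),
                          var_alpha = fit$variance,
                          covariance = matrix(fit$variance, 1, 1)),
                     class = "mvmr_result"))
  }
  Pi <- rbind(cbind(data$beta_hat, data$C_hat),
              cbind(0, data$B_hat))
  pi_hat <- c(data$c_hat, data$b_hat)
  if (is.null(weight_matrix)) {
    w <- 1 / c(data$var_c, data$var_b)
    XtWX <- crossprod(Pi, Pi * w)
    XtWy <- crossprod(Pi, pi_hat * w)
  } else {
    Wi <- solve(weight_matrix, cbind(Pi, pi_hat))
    XtWX <- crossprod(Pi, Wi[, seq_len(k + 1)])
    XtWy <- crossprod(Pi, Wi[, k + 2])
  }
  qr_x <- qr(XtWX)
  if (qr_x$rank < k + 1) {
    bad <- data$mediator_ids[setdiff(seq_len(k), qr_x$pivot[seq_len(qr_x$rank)] - 1L)]
    stop("singular MVMR design; offending columns: ",
         paste(bad, collapse = ", "))
  }
  covariance <- solve(XtWX)
  coefs <- drop(covariance %*% XtWy)
  names(coefs) <- c("alpha", data$mediator_ids)
  structure(list(alpha_hat = unname(coefs[1]), delta_hat = coefs[-1],
                 var_alpha = covariance[1, 1], covariance = covariance),
            class = "mvmr_result")
}

#' Two-step MR+MVMR mediation fit
#'
#' The classical baseline: total effect from univariable IVW on the
#' exposure instruments, direct effect from MVMR, indirect effect by
#' subtraction, `omega_hat = theta_hat - alpha_hat`. The two steps are
#' separate regressions, so `Var(omega_hat)` is taken as
#' `Var(theta_hat) + Var(alpha_hat)` (their covariance is ignored; this
#' is a documented limitation of the two-step design).
#'
#' @inheritParams mvmr_direct_effect
#' @return A `"mediation_fit"` list: `method`, `alpha`, `omega`, `theta`,
#'   `delta`, `var_alpha`, `var_theta`, `var_omega`, `converged`.
#' @export
mr_mvmr_mediation <- function(data, weight_matrix = NULL) {
  ivw <- ivw_total_effect(data$beta_hat, data$c_hat, data$var_c)
  mv <- mvmr_direct_effect(data, weight_matrix = weight_matrix)
  structure(list(method = "mr_mvmr",
                 alpha = mv$alpha_hat,
                 omega = ivw$estimate - mv$alpha_hat,
                 theta = ivw$estimate,
                 delta = mv$delta_hat,
                 var_alpha = mv$var_alpha,
                 var_theta = ivw$variance,
                 var_omega = ivw$variance + mv$var_alpha,
                 converged = TRUE),
            class = "mediation_fit")
}

#' @export
print.mediation_fit <- function(x, ...) {
  cat(sprintf("%s fit: alpha=%.4f omega=%.4f theta=%.4f (converged: %s)\n",
              x$method, x$alpha, x$omega, x$theta, x$converged))
  invisible(x)
}
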