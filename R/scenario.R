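#' Define a simulation scenario
#'
#' A scenario bundles every parameter of the generative model for one
#' simulated mediation study: sample sizes of the exposure, mediator and
#' outcome GWAS, the genetic architecture of the exposure and mediators,
#' the strength and shape of the mediation signal, the mediator-selection
#' threshold, pleiotropy variance components and replication settings.
#' All traits are taken to be standardized (zero mean, unit variance), so
#' effect sizes are on the per-SD scale and estimation noise scales as the
#' reciprocal of the study sample size.
#'
#' The defaults describe the canonical study design the simulator is built
#' around: a well-powered complex-trait exposure and outcome
#' (`n_X = n_Y = 3e5`) with molecular mediators measured in a much smaller
#' QTL study (`n_M = 1e4`), a total causal effect of `E(theta) = 0.15` of
#' which `MP = 0.15` is mediated, exposure heritability 0.35 spread over
#' `m = 100` independent instruments, `k = 10` mediators all carrying
#' signal (`p_k = 1`), mediators jointly explaining `sigma2_YM = 0.05` of
#' the outcome variance, uncorrelated mediation effects (`rho_gd = 0`), an
#' identity mediator correlation matrix, no pleiotropy, and Bonferroni
#' mediator selection (`P = 0.05/k`).
#'
#' @param n_X,n_M,n_Y Positive integer sample sizes of the exposure,
#'   mediator and outcome studies.
#' @param m Number of exposure instruments.
#' @param k Number of candidate mediators.
#' @param p_k Fraction in (0, 1] of mediators with non-zero mediation
#'   effects; `k_s = round(p_k * k)` (at least 1 when `mp > 0`).
#' @param P Mediator-selection p-value threshold in (0, 1]. `P = 1`
#'   bypasses selection (the "oracle" design).
#' @param expected_theta Expected total causal effect E(theta).
#' @param mp Target mediation proportion in \[0, 1\].
#' @param h2_X Exposure heritability in (0, 1).
#' @param sigma2_YM Outcome variance explained by the mediators.
#' @param rho_gd Correlation of the per-mediator effects (gamma_i, delta_i),
#'   strictly inside (-1, 1).
#' @param sigma_strategy Mediator correlation matrix strategy: one of
#'   `"identity"`, `"random_vectors"`, `"empirical_matrix"`.
#' @param sigma_matrix Correlation matrix (or path to a square TSV) used
#'   when `sigma_strategy = "empirical_matrix"`.
#' @param pleiotropy Named or positional numeric vector
#'   `(sigma2_C, sigma2_c, sigma2_b)` of non-negative pleiotropy variance
#'   components inflating the estimation noise of C-hat, c-hat and b-hat.
#' @param l_mean Mean of the zero-truncated geometric distribution of
#'   per-mediator instrument counts.
#' @param l_per_mediator Optional fixed integer vector of per-mediator
#'   instrument counts, overriding the geometric draw.
#' @param alpha_null_range Support of the uniform law for the direct
#'   effect when `mp = 0`, as multiples of `expected_theta`.
#' @param null_slab_mp Reference mediation proportion setting the scale
#'   of the candidate-mediator effect slab under the no-mediation null
#'   (`mp = 0`): the k mediators draw (gamma_i, delta_i) from the same
#'   spike-and-slab an alternative with this MP would use, but with the
#'   gamma-delta coupling removed, so the expected indirect effect is
#'   exactly zero while per-replicate indirect effects fluctuate — the
#'   regime in which type-I error of the MP test is meaningful.
#' @param n_reps Number of simulation replicates.
#' @param seed Integer base seed.
#'
#' @return An object of class `"lima_scenario"` (a named list).
#' @seealso [generate_replicate()], [run_scenario()]
#' @examples
#' sc <- lima_scenario(k = 5, n_reps = 10)
#' sc$P  # Bonferroni default 0.05/k
#' @export
lima_scenario <- function(n_X = 3e5, n_M = 1e4, n_Y = 3e5,
                          m = 100, k = 10, p_k = 1,
                          P = 0.05 / k,
                          expected_theta = 0.15, mp = 0.15,
                          h2_X = 0.35, sigma2_YM = 0.05, rho_gd = 0,
                          sigma_strategy = c("identity", "random_vectors",
                                             "empirical_matrix"),
                          sigma_matrix = NULL,
                          pleiotropy = c(sigma2_C = 0, sigma2_c = 0,
                                         sigma2_b = 0),
                          l_mean = 3, l_per_mediator = NULL,
                          alpha_null_range = c(0.5, 1.5),
                          null_slab_mp = 0.15,
                          n_reps = 300, seed = 1L) {
  sigma_strategy <- match.arg(sigma_strategy)
  stopifnot(n_X >= 1, n_M >= 1, n_Y >= 1, m >= 1, k >= 1)
  if (!(p_k > 0 && p_k <= 1)) stop("`p_k` must be in (0, 1]")
  if (!(P > 0 && P <= 1)) stop("`P` must be in (0, 1]")
  if (mp < 0 || mp > 1) stop("`mp` must be in [0, 1]")
  if (!(h2_X > 0 && h2_X < 1)) stop("`h2_X` must be in (0, 1)")
  if (sigma2_YM <= 0) stop("`sigma2_YM` must be positive")
  if (abs(rho_gd) >= 1) stop("`rho_gd` must be strictly inside (-1, 1)")
  pleiotropy <- as.numeric(pleiotropy)
  if (length(pleiotropy) != 3 || any(pleiotropy < 0))
    stop("`pleiotropy` must be three non-negative variances")
  names(pleiotropy) <- c("sigma2_C", "sigma2_c", "sigma2_b")
  if (mp > 0 && round(p_k * k) < 1)
    stop("`p_k * k` must round to at least 1 when `mp` > 0")
  if (!is.null(l_per_mediator)) {
    l_per_mediator <- as.integer(l_per_mediator)
    if (length(l_per_mediator) != k || any(l_per_mediator < 1))
      stop("`l_per_mediator` must give a positive count for each of k mediators")
  }
  structure(list(
    n_X = n_X, n_M = n_M, n_Y = n_Y, m = m, k = k, p_k = p_k, P = P,
    expected_theta = expected_theta, mp = mp, h2_X = h2_X,
    sigma2_YM = sigma2_YM, rho_gd = rho_gd,
    sigma_strategy = sigma_strategy, sigma_matrix = sigma_matrix,
    pleiotropy = pleiotropy, l_mean = l_mean,
    l_per_mediator = l_per_mediator, alpha_null_range = alpha_null_range,
    null_slab_mp = null_slab_mp,
    n_reps = as.integer(n_reps), seed = as.integer(seed)
  ), class = "lima_scenario")
}

#' @export
print.lima_scenario <- function(x, ...) {
  cat("Mediation simulation scenario\n")
  cat(sprintf("  samples: n_X=%g n_M=%g n_Y=%g\n", x$n_X, x$n_M, x$n_Y))
  cat(sprintf("  genetics: m=%d exposure instruments, h2_X=%g, k=%d mediators (p_k=%g)\n",
              x$m, x$h2_X, x$k, x$p_k))
  cat(sprintf("  mediation: E(theta)=%g MP=%g sigma2_YM=%g rho_gd=%g\n",
              x$expected_theta, x$mp, x$sigma2_YM, x$rho_gd))
  cat(sprintf("  selection P=%g, Sigma=%s, pleiotropy=(%g,%g,%g)\n",
              x$P, x$sigma_strategy, x$pleiotropy[1], x$pleiotropy[2],
              x$pleiotropy[3]))
  cat(sprintf("  n_reps=%d seed=%d\n", x$n_reps, x$seed))
  invisible(x)
}

#' Read or write a scenario as YAML/JSON
#'
#' Scenario files carry the scalar fields of [lima_scenario()]; a file
#' path stored under `sigma_matrix` is preserved verbatim.
#'
#' @param path File path; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @return `read_scenario()` returns a `"lima_scenario"`;
#'   `write_scenario()` returns `path` invisibly.
#' @export
read_scenario <- function(path) {
  ext <- tolower(tools::file_ext(path))
  lst <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(lima_scenario, lst)
}

#' @param scenario A `"lima_scenario"` object.
#' @rdname read_scenario
#' @export
write_scenario <- function(scenario, path) {
  stopifnot(inherits(scenario, "lima_scenario"))
  lst <- unclass(scenario)
  lst$pleiotropy <- as.list(lst$pleiotropy)
  lst <- lst[!vapply(lst, is.null, logical(1))]
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) yaml::write_yaml(lst, path, precision = 15)
  else jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA,
                            pretty = TRUE)
  invisible(path)
}
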