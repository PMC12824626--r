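## Simulation-study driver: replicate a scenario through the estimators
## and compute the performance metrics (relative MP bias via the group
## regression, per-replicate CI coverage, power / type-I error, estimator
## variance, non-convergence counts), each with Monte-Carlo 95% CIs.

method_fitters <- list(
  mr_mvmr = function(data) mr_mvmr_mediation(data),
  lima = function(data) fit_lima(data),
  ilima = function(data) fit_ilima(data)
)

#' Run all replicates of one scenario
#'
#' For each replicate: generate a fresh ground-truth model and noisy
#' summary statistics, apply IVW mediator selection at the scenario's
#' threshold `P` (re-simulating, with a logged count, if no mediator
#' passes), fit each requested method, and record the per-replicate
#' direct/total effects and delta-method MP with its 95% CI. Replicate
#' r uses a sub-seed derived deterministically from the scenario seed,
#' so results are reproducible and independent of evaluation order.
#'
#' @param scenario A [lima_scenario()].
#' @param methods Subset of `c("mr_mvmr", "lima", "ilima")`.
#' @param progress Print a dot every 25 replicates.
#' @return List of class `"scenario_result"`: `estimates` (long
#'   data.frame, one row per replicate x method), `metrics` (long
#'   data.frame: method, metric, value, ci_lo, ci_hi), `n_resim`,
#'   `scenario`.
#' @export
run_scenario <- function(scenario,
                         methods = c("mr_mvmr", "lima", "ilima"),
                         progress = FALSE) {
  stopifnot(inherits(scenario, "lima_scenario"))
  methods <- match.arg(methods, names(method_fitters), several.ok = TRUE)
  set.seed(scenario$seed)
  subseeds <- sample.int(.Machine$integer.max - 1L, scenario$n_reps)
  n_resim <- 0L
  rows <- vector("list", scenario$n_reps * length(methods))
  ri <- 0L
  for (r in seq_len(scenario$n_reps)) {
    set.seed(subseeds[r])
    repeat {
      rep_data <- generate_replicate(scenario)
      sel <- select_mediators(rep_data$data, scenario$P)
      if (length(sel) > 0) break
      n_resim <- n_resim + 1L
    }
    data_r <- if (length(sel) < scenario$k)
      subset_mediators(rep_data$data, sel) else rep_data$data
    for (meth in methods) {
      fit <- method_fitters[[meth]](data_r)
      mp <- mp_from_fit(fit, data_r)
      ri <- ri + 1L
      rows[[ri]] <- data.frame(
        rep = r, method = meth,
        alpha_hat = fit$alpha, theta_hat = fit$theta,
        mp_hat = mp$mp_hat, var_mp = mp$var_mp,
        ci_lo = mp$ci[1], ci_hi = mp$ci[2],
        converged = isTRUE(fit$converged),
        n_selected = length(sel),
        theta_true = rep_data$truth$theta)
    }
    if (progress && r %% 25 == 0) cat(".")
  }
  if (progress) cat("\n")
  estimates <- do.call(rbind, rows[seq_len(ri)])
  metrics <- compute_scenario_metrics(estimates, scenario)
  structure(list(estimates = estimates, metrics = metrics,
                 n_resim = n_resim, scenario = scenario),
            class = "scenario_result")
}

binom_ci_pct <- function(p_hat, n) {
  se <- sqrt(pmax(p_hat * (1 - p_hat), 0) / n)
  c(100 * (p_hat - 1.96 * se), 100 * (p_hat + 1.96 * se))
}

compute_scenario_metrics <- function(estimates, scenario) {
  mp_true <- scenario$mp
  out <- lapply(split(estimates, estimates$method), function(df) {
    conv <- df[df$converged & is.finite(df$alpha_hat) &
                 is.finite(df$theta_hat), ]
    n_conv <- nrow(conv)
    grp <- mp_group(conv$alpha_hat, conv$theta_hat)
    rows <- list()
    if (mp_true > 0) {
      # reported as 100 * (MP - MP_hat) / MP: positive = downward bias
      bias <- 100 * (mp_true - grp$mp_hat) / mp_true
      bias_se <- 100 * sqrt(grp$var_mp) / mp_true
      rows$relative_bias_pct <- c(bias, bias - 1.96 * bias_se,
                                  bias + 1.96 * bias_se)
    }
    ok <- conv[is.finite(conv$var_mp) & conv$var_mp >= 0, ]
    n_ci <- nrow(ok)
    cover <- mean(ok$ci_lo <= mp_true & mp_true <= ok$ci_hi)
    rows$coverage_pct <- c(100 * cover, binom_ci_pct(cover, n_ci))
    reject <- mean(ok$ci_lo > 0 | ok$ci_hi < 0)
    rej_row <- c(100 * reject, binom_ci_pct(reject, n_ci))
    if (mp_true > 0) rows$power_pct <- rej_row else rows$t1e_pct <- rej_row
    rows$var_mp <- c(stats::var(ok$mp_hat), NA_real_, NA_real_)
    rows$n_nonconverged <- c(nrow(df) - n_conv, NA_real_, NA_real_)
    data.frame(method = df$method[1], metric = names(rows),
               value = vapply(rows, `[`, numeric(1), 1),
               ci_lo = vapply(rows, `[`, numeric(1), 2),
               ci_hi = vapply(rows, `[`, numeric(1), 3),
               row.names = NULL)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("Scenario result (%d replicates, %d re-simulations)\n",
              x$scenario$n_reps, x$n_resim))
  print(x$metrics, digits = 3)
  invisible(x)
}

#' Sweep one scenario parameter over a grid
#'
#' Re-runs [run_scenario()] with the named field set to each value in
#' turn (all other fields held at the base scenario), returning a tidy
#' long table suitable for plotting bias/coverage/power trajectories.
#' Note that fields derived at construction (e.g. the Bonferroni default
#' `P = 0.05/k`) are not re-derived; set them explicitly when sweeping
#' `k`.
#'
#' @param parameter_name A scalar field of [lima_scenario()].
#' @param values Vector of values to sweep.
#' @param base Base scenario.
#' @param ... Passed to [run_scenario()].
#' @return A data.frame: `parameter`, `param_value`, plus the metric columns
#'   of the per-scenario `metrics` tables.
#' @export
sweep_scenario <- function(parameter_name, values, base, ...) {
  stopifnot(inherits(base, "lima_scenario"))
  sweepable <- setdiff(names(base), c("sigma_matrix", "l_per_mediator",
                                      "alpha_null_range"))
  if (!parameter_name %in% sweepable)
    stop("unknown scenario parameter `", parameter_name, "`; valid: ",
         paste(sweepable, collapse = ", "))
  out <- lapply(values, function(v) {
    sc <- base
    sc[[parameter_name]] <- v
    res <- run_scenario(sc, ...)
    cbind(data.frame(parameter = parameter_name, param_value = v),
          res$metrics)
  })
  do.call(rbind, out)
}

#' Write scenario results to a directory
#'
#' Emits `metrics.tsv` (long format) and `estimates.tsv` (per
#' replicate), the on-disk interface of the benchmark driver.
#'
#' @param result A `"scenario_result"` from [run_scenario()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_scenario_result <- function(result, dir) {
  stopifnot(inherits(result, "scenario_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(result$metrics, file.path(dir, "metrics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(result$estimates, file.path(dir, "estimates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
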