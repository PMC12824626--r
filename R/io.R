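## Tab-separated serialization of the summary-statistic container.
## Layout: exposure.tsv (beta_hat), mediators_C.tsv, mediators_B.tsv,
## outcome_c.tsv, outcome_b.tsv, metadata.json (sample sizes, pleiotropy,
## instrument blocks, optional seed and simulation truth).

#' Write summary data to a directory of TSV files
#'
#' @param data A [summary_data()] object.
#' @param dir Output directory (created if missing).
#' @param truth Optional simulation ground truth to record in the
#'   metadata (list with alpha/gamma/delta/...).
#' @param seed Optional seed to record.
#' @return `dir`, invisibly.
#' @export
write_summary_data <- function(data, dir, truth = NULL, seed = NULL) {
  stopifnot(inherits(data, "summary_data"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, name)
    utils::write.table(df, file.path(dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  g_ids <- paste0("G", seq_len(data$m))
  f_ids <- paste0("F", seq_len(data$l))
  tsv(data.frame(instrument = g_ids, beta_hat = data$beta_hat),
      "exposure.tsv")
  C <- as.data.frame(data$C_hat); names(C) <- data$mediator_ids
  tsv(cbind(data.frame(instrument = g_ids), C), "mediators_C.tsv")
  B <- as.data.frame(data$B_hat); names(B) <- data$mediator_ids
  tsv(cbind(data.frame(instrument = f_ids), B), "mediators_B.tsv")
  tsv(data.frame(instrument = g_ids, c_hat = data$c_hat,
                 var_c = data$var_c), "outcome_c.tsv")
  tsv(data.frame(instrument = f_ids, b_hat = data$b_hat,
                 var_b = data$var_b), "outcome_b.tsv")
  meta <- list(n_X = data$n_X, n_M = data$n_M, n_Y = data$n_Y,
               pleiotropy = as.list(data$pleiotropy),
               block = data$block, mediator_ids = data$mediator_ids,
               seed = seed, truth = truth)
  meta <- meta[!vapply(meta, is.null, logical(1))]
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read summary data from a directory written by [write_summary_data()]
#'
#' @param dir Directory containing the five TSV files and
#'   `metadata.json`.
#' @return A [summary_data()] object.
#' @export
read_summary_data <- function(dir) {
  tsv <- function(name)
    utils::read.table(file.path(dir, name), sep = "\t", header = TRUE,
                      check.names = FALSE)
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"),
                              simplifyVector = TRUE)
  exposure <- tsv("exposure.tsv")
  C <- tsv("mediators_C.tsv"); B <- tsv("mediators_B.tsv")
  oc <- tsv("outcome_c.tsv"); ob <- tsv("outcome_b.tsv")
  summary_data(exposure$beta_hat,
               as.matrix(C[, -1, drop = FALSE]),
               as.matrix(B[, -1, drop = FALSE]),
               oc$c_hat, ob$b_hat,
               n_X = meta$n_X, n_M = meta$n_M, n_Y = meta$n_Y,
               pleiotropy = unlist(meta$pleiotropy),
               var_c = oc$var_c, var_b = ob$var_b,
               block = meta$block, mediator_ids = meta$mediator_ids)
}

#' Serialize a mediation fit or MP estimate to JSON
#'
#' @param x A `"mediation_fit"` or `"mp_estimate"`.
#' @param path Optional file path; when `NULL` the JSON string is
#'   returned.
#' @return JSON string (invisibly when written to a file).
#' @export
to_json <- function(x, path = NULL) {
  lst <- unclass(x)
  js <- jsonlite::toJSON(lst, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
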