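## Applied-analysis front end: harmonized association tables in,
## estimator-ready summary data out. LD clumping is out of scope; the
## pipeline expects pre-clumped (approximately independent) variants.

#' Read a harmonized association table
#'
#' Tab-separated, one row per variant, with header
#' `variant_id effect_allele other_allele beta se p n`. Effects are
#' assumed standardized (per-SD on a unit-variance trait).
#'
#' @param path TSV file path.
#' @return A `data.frame` with validated columns.
#' @export
read_assoc_table <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  validate_assoc_table(tab, label = path)
}

validate_assoc_table <- function(tab, label = "association table") {
  need <- c("variant_id", "effect_allele", "other_allele", "beta", "se",
            "p", "n")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop(label, " is missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(tab$variant_id))
    stop(label, " has duplicated variant ids")
  if (any(tab$se <= 0)) stop(label, " has non-positive standard errors")
  tab
}

# Orient `tab`'s effect at `ids` to the reference alleles; sign-flips
# swapped alleles, errors on a mismatch naming the variant.
aligned_effects <- function(ref, tab, ids) {
  i_ref <- match(ids, ref$variant_id)
  i_tab <- match(ids, tab$variant_id)
  if (anyNA(i_ref) || anyNA(i_tab))
    stop("variants absent from one of the tables: ",
         paste(ids[is.na(i_ref) | is.na(i_tab)], collapse = ", "))
  same <- ref$effect_allele[i_ref] == tab$effect_allele[i_tab] &
    ref$other_allele[i_ref] == tab$other_allele[i_tab]
  swap <- ref$effect_allele[i_ref] == tab$other_allele[i_tab] &
    ref$other_allele[i_ref] == tab$effect_allele[i_tab]
  if (any(!(same | swap)))
    stop("allele mismatch for variant(s): ",
         paste(ids[!(same | swap)], collapse = ", "))
  out <- tab[i_tab, c("beta", "se", "p", "n")]
  out$beta <- ifelse(swap, -out$beta, out$beta)
  out
}

#' Steiger filter against reverse causation
#'
#' Removes candidate instruments whose association with the outcome is
#' both nominally significant (p < 0.05) and stronger (smaller p-value)
#' than their association with the exposure — the signature of an
#' instrument acting through the outcome.
#'
#' @param exposure,outcome Association tables (see
#'   [read_assoc_table()]).
#' @param candidate_ids Variant ids to filter; must be present with
#'   matching alleles in both tables.
#' @param p_threshold Outcome-significance condition (default 0.05).
#' @return Character vector of surviving variant ids (a subset of
#'   `candidate_ids`; idempotent).
#' @export
steiger_filter <- function(exposure, outcome, candidate_ids,
                           p_threshold = 0.05) {
  if (!length(candidate_ids)) return(character(0))
  ex <- aligned_effects(exposure, exposure, candidate_ids)
  ou <- aligned_effects(exposure, outcome, candidate_ids)
  drop <- ou$p < p_threshold & ou$p < ex$p
  candidate_ids[!drop]
}

# Univariable IVW MR between two association tables using the exposure's
# genome-wide-significant variants as instruments.
assoc_ivw <- function(exposure, outcome, p_instrument = 5e-8) {
  ids <- exposure$variant_id[exposure$p < p_instrument]
  ids <- intersect(ids, outcome$variant_id)
  if (!length(ids)) return(NULL)
  ex <- aligned_effects(exposure, exposure, ids)
  ou <- aligned_effects(exposure, outcome, ids)
  ivw_total_effect(ex$beta, ou$beta, ou$se^2)
}

#' Select candidate mediators by bidirectional MR evidence
#'
#' A mediator qualifies when (i) it has at least one strong instrument
#' (p < `p_instrument`), (ii) the exposure -> mediator IVW MR p-value
#' passes `p_em`, and (iii) the mediator -> outcome IVW MR p-value passes
#' `p_mo`. Mediators without instruments are excluded with a message.
#'
#' @param exposure,outcome Association tables.
#' @param mediators Named list of mediator association tables.
#' @param p_em,p_mo Selection thresholds for the exposure -> mediator and
#'   mediator -> outcome effects (defaults nominal 0.05; use
#'   `0.05 / length(mediators)` for a strict Bonferroni mode).
#' @param p_instrument Instrument-strength threshold (default 5e-8).
#' @return Character vector of retained mediator names, with the MR
#'   summary as a `"tests"` attribute.
#' @export
select_candidate_mediators <- function(exposure, mediators, outcome,
                                       p_em = 0.05, p_mo = 0.05,
                                       p_instrument = 5e-8) {
  stopifnot(length(mediators) >= 1, !is.null(names(mediators)))
  rows <- lapply(names(mediators), function(id) {
    med <- mediators[[id]]
    if (!any(med$p < p_instrument)) {
      message("mediator ", id, " has no strong instrument; excluded")
      return(data.frame(mediator = id, p_em = NA_real_, p_mo = NA_real_,
                        gamma_hat = NA_real_, delta_hat = NA_real_))
    }
    em <- assoc_ivw(exposure, med, p_instrument)
    mo <- assoc_ivw(med, outcome, p_instrument)
    data.frame(mediator = id,
               p_em = if (is.null(em)) NA_real_ else em$p_value,
               p_mo = if (is.null(mo)) NA_real_ else mo$p_value,
               gamma_hat = if (is.null(em)) NA_real_ else em$estimate,
               delta_hat = if (is.null(mo)) NA_real_ else mo$estimate)
  })
  tests <- do.call(rbind, rows)
  keep <- !is.na(tests$p_em) & !is.na(tests$p_mo) &
    tests$p_em <= p_em & tests$p_mo <= p_mo
  structure(tests$mediator[keep], tests = tests)
}

#' Prune correlated mediators in a forward stepwise manner
#'
#' Greedily admits mediators in decreasing order of mediation-effect
#' strength, rejecting any candidate whose absolute correlation with an
#' already-admitted mediator exceeds `r_max`. The admitted set therefore
#' has pairwise |correlation| <= `r_max` by construction.
#'
#' @param candidates Mediator ids (row/col names of `mediator_corr`).
#' @param mediator_corr Correlation matrix over the candidates.
#' @param strength Numeric ranking, larger = stronger (e.g.
#'   `|gamma_hat * delta_hat|` from univariable MRs).
#' @param r_max Maximum allowed pairwise |correlation| (default 0.1;
#'   0.5 is the relaxed mode).
#' @return Character vector of admitted mediator ids, in admission
#'   order.
#' @export
prune_correlated_mediators <- function(candidates, mediator_corr, strength,
                                       r_max = 0.1) {
  stopifnot(length(candidates) == length(strength))
  if (!length(candidates)) return(character(0))
  ord <- candidates[order(-abs(strength))]
  admitted <- character(0)
  for (id in ord) {
    if (!length(admitted) ||
        all(abs(mediator_corr[id, admitted]) <= r_max))
      admitted <- c(admitted, id)
  }
  admitted
}

#' Assemble estimator-ready summary data from association tables
#'
#' Builds the five-block [summary_data()] container for one
#' exposure/mediators/outcome tuple from harmonized, pre-clumped
#' association tables: exposure instruments are genome-wide-significant
#' exposure variants surviving Steiger filtering against the outcome;
#' each mediator contributes its genome-wide-significant variants
#' (Steiger-filtered against exposure and outcome) as instruments, owned
#' by the mediator in which they are most significant.
#'
#' @param exposure,outcome Association tables.
#' @param mediators Named list of mediator association tables (already
#'   selected, e.g. via [select_candidate_mediators()]).
#' @param p_instrument Instrument-strength threshold.
#' @param steiger Apply Steiger filtering (default TRUE).
#' @return A [summary_data()] object.
#' @export
assemble_mediation_model <- function(exposure, mediators, outcome,
                                     p_instrument = 5e-8, steiger = TRUE) {
  stopifnot(length(mediators) >= 1, !is.null(names(mediators)))
  med_ids <- names(mediators)
  common <- Reduce(intersect, c(list(exposure$variant_id,
                                     outcome$variant_id),
                                lapply(mediators, `[[`, "variant_id")))
  if (!length(common)) stop("no variants shared by all tables")

  g_ids <- exposure$variant_id[exposure$p < p_instrument]
  g_ids <- intersect(g_ids, common)
  if (steiger) g_ids <- steiger_filter(exposure, outcome, g_ids)
  if (!length(g_ids)) stop("no exposure instruments survive filtering")

  # mediator instruments: strongest-owner assignment, Steiger-filtered
  inst <- lapply(med_ids, function(id) {
    med <- mediators[[id]]
    ids <- intersect(med$variant_id[med$p < p_instrument], common)
    ids <- setdiff(ids, g_ids)
    if (steiger && length(ids)) {
      ids <- steiger_filter(med, outcome, ids)
      ids <- steiger_filter(med, exposure, ids)
    }
    ids
  })
  names(inst) <- med_ids
  all_f <- unique(unlist(inst))
  if (!length(all_f)) stop("no mediator instruments survive filtering")
  owner_p <- vapply(med_ids, function(id) {
    med <- mediators[[id]]
    p <- rep(1, length(all_f))
    hit <- all_f %in% inst[[id]]
    p[hit] <- med$p[match(all_f[hit], med$variant_id)]
    p
  }, numeric(length(all_f)))
  owner_p <- matrix(owner_p, nrow = length(all_f))
  owner <- max.col(-owner_p, ties.method = "first")

  beta_hat <- aligned_effects(exposure, exposure, g_ids)$beta
  C_hat <- vapply(med_ids, function(id)
    aligned_effects(exposure, mediators[[id]], g_ids)$beta,
    numeric(length(g_ids)))
  B_hat <- vapply(med_ids, function(id)
    aligned_effects(exposure, mediators[[id]], all_f)$beta,
    numeric(length(all_f)))
  oc <- aligned_effects(exposure, outcome, g_ids)
  ob <- aligned_effects(exposure, outcome, all_f)

  summary_data(beta_hat,
               matrix(C_hat, ncol = length(med_ids)),
               matrix(B_hat, ncol = length(med_ids)),
               oc$beta, ob$beta,
               n_X = stats::median(exposure$n),
               n_M = stats::median(vapply(mediators,
                                          function(t) stats::median(t$n),
                                          numeric(1))),
               n_Y = stats::median(outcome$n),
               var_c = oc$se^2, var_b = ob$se^2,
               block = owner, mediator_ids = med_ids)
}
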