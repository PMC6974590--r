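# Carrier-based case-control burden per gene set and CNV-type stratum.

match_set <- function(annotated, set_name) {
  if (identical(set_name, "any")) rep(TRUE, nrow(annotated))
  else vapply(annotated$sets_hit, function(s) set_name %in% s, TRUE)
}

#' Count case/control carriers for one burden hypothesis
#'
#' A sample is a carrier if it owns at least one annotated call hitting the
#' gene set (the pseudo-set `"any"` matches every call, including calls that
#' overlap no gene) and, for a gain/loss stratum, of the matching CNV type.
#' Each sample is counted once, irrespective of how many qualifying CNVs it
#' carries.
#'
#' @param annotated an [annotate_calls()] result.
#' @param samples the phenotype rows defining the stratum (one cohort, or one
#'   sex within one cohort); must contain both cases and controls.
#' @param set_name a set name known to the annotation, or `"any"`.
#' @param type_stratum `"any"`, `"gain"`, or `"loss"`.
#' @return an integer vector `c(a, b, c, d)`: case carriers, case
#'   non-carriers, control carriers, control non-carriers.
#' @export
count_carriers <- function(annotated, samples, set_name,
                           type_stratum = c("any", "gain", "loss")) {
  type_stratum <- match.arg(type_stratum)
  known <- c("any", attr(annotated, "set_names"))
  if (!set_name %in% known)
    stopf("unknown gene set '%s'", set_name)
  if (nrow(samples) == 0L) stop("empty stratum")
  use <- match_set(annotated, set_name)
  if (type_stratum != "any") use <- use & annotated$type == type_stratum
  carrier_keys <- unique(sample_key(annotated$cohort, annotated$sample_id)[use])
  is_carrier <- sample_key(samples$cohort, samples$sample_id) %in% carrier_keys
  is_case <- samples$status == "case"
  out <- c(a = sum(is_case & is_carrier), b = sum(is_case & !is_carrier),
           c = sum(!is_case & is_carrier), d = sum(!is_case & !is_carrier))
  setNames(as.integer(out), c("a", "b", "c", "d"))
}

#' Run the gene-set burden analysis per cohort
#'
#' For each cohort, tests the `"any"` hypothesis plus every set in the
#' collection, in three CNV-type strata.  The type-combined (`"any"`) family
#' is Bonferroni-adjusted over the number of hypotheses per cohort; the
#' gain/loss strata are reported at the raw `p < 0.05` rule conventionally
#' used when displaying type-resolved burden signals.
#'
#' @param annotated an [annotate_calls()] result (post-QC).
#' @param samples the phenotype table (all cohorts).
#' @param collection the [gene_set_collection()] used for annotation.
#' @param alpha nominal familywise alpha (default 0.05).
#' @return a data frame with one row per cohort x hypothesis x type stratum:
#'   cells `a`..`d`, `p`, conditional-MLE `or` with exact `ci_lo`/`ci_hi`,
#'   `or_crude`, `alpha_adjusted`, and `significant`.
#' @export
run_burden <- function(annotated, samples, collection, alpha = 0.05) {
  stopifnot(inherits(collection, "gene_set_collection"))
  hypotheses <- c("any", names(collection$sets))
  alpha_any <- bonferroni_alpha(alpha, length(hypotheses))
  rows <- list()
  for (co in unique(samples$cohort)) {
    strat <- samples[samples$cohort == co, , drop = FALSE]
    if (!any(strat$status == "case") || !any(strat$status == "control"))
      stopf("cohort %s has no cases or no controls", co)
    for (set_name in hypotheses) {
      for (ts in c("any", "gain", "loss")) {
        tab <- count_carriers(annotated, strat, set_name, ts)
        alpha_adj <- if (ts == "any") alpha_any else alpha
        rows[[length(rows) + 1L]] <- data.frame(
          cohort = co, set_name = set_name, type_stratum = ts,
          a = tab[["a"]], b = tab[["b"]], c = tab[["c"]], d = tab[["d"]],
          alpha_adjusted = alpha_adj, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  ft <- fisher_exact_2x2(out$a, out$b, out$c, out$d)
  out$p <- ft$p; out$or <- ft$or; out$ci_lo <- ft$ci_lo; out$ci_hi <- ft$ci_hi
  out$or_crude <- ft$or_crude
  out$significant <- out$p < out$alpha_adjusted
  rownames(out) <- NULL
  out[, c("cohort", "set_name", "type_stratum", "a", "b", "c", "d", "p",
          "or", "ci_lo", "ci_hi", "or_crude", "alpha_adjusted", "significant")]
}
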