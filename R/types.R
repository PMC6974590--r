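#' Construct a validated CNV call table
#'
#' The central per-call record: one detected gain or loss segment in one
#' sample.  Coordinates are 0-based half-open (`size = end - start`);
#' chromosome labels are normalized to a `chr` prefix.
#'
#' @param sample_id,cohort character vectors identifying the carrier sample.
#' @param chrom chromosome labels (any `chr` prefixing accepted).
#' @param start,end integer base-pair coordinates, 0-based half-open.
#' @param type call type, `"gain"` or `"loss"` (case-insensitive).
#' @param n_probes non-negative integer count of supporting array probes.
#' @param source free-text origin tag (usually the file of origin).
#' @return A `data.frame` with columns `sample_id`, `cohort`, `chrom`,
#'   `start`, `end`, `type`, `n_probes`, `source`.
#' @examples
#' cnv_calls("S1", "POPGEN", "3", 52082780, 53128685, "loss", 120)
#' @export
cnv_calls <- function(sample_id = character(), cohort = character(),
                      chrom = character(), start = integer(), end = integer(),
                      type = character(), n_probes = integer(),
                      source = "memory") {
  n <- length(sample_id)
  df <- data.frame(
    sample_id = as.character(sample_id),
    cohort = rep_len(as.character(cohort), n),
    chrom = if (n) norm_chrom(rep_len(chrom, n)) else character(),
    start = rep_len(as.numeric(start), n),
    end = rep_len(as.numeric(end), n),
    type = rep_len(tolower(as.character(type)), n),
    n_probes = rep_len(as.integer(n_probes), n),
    source = rep_len(as.character(source), n),
    stringsAsFactors = FALSE
  )
  validate_cnv_calls(df)
}

#' @rdname cnv_calls
#' @param calls a CNV call `data.frame` to validate.
#' @export
validate_cnv_calls <- function(calls) {
  need <- c("sample_id", "cohort", "chrom", "start", "end", "type",
            "n_probes", "source")
  miss <- setdiff(need, names(calls))
  if (length(miss)) stopf("call table is missing column(s): %s",
                          paste(miss, collapse = ", "))
  if (any(!calls$type %in% c("gain", "loss")))
    stopf("unknown CNV type token(s): %s",
          paste(unique(setdiff(calls$type, c("gain", "loss"))), collapse = ", "))
  if (any(calls$end <= calls$start))
    stop("CNV call with end <= start")
  if (any(calls$start < 0)) stop("negative CNV start coordinate")
  if (any(calls$n_probes < 0)) stop("negative probe count")
  calls
}

#' Size of each CNV call in base pairs
#' @param calls a CNV call table (see [cnv_calls()]).
#' @return numeric vector of `end - start`.
#' @export
cnv_size <- function(calls) calls$end - calls$start

#' Construct a validated sample phenotype table
#'
#' One row per genotyped individual: case/control status, sex, age, body-mass
#' index and cohort label, plus an optional type-2-diabetes flag that the
#' association models never use (it is unavailable for entire cohorts in the
#' motivating study design).
#'
#' @param sample_id,cohort identifiers; `sample_id` must be unique within a
#'   cohort.
#' @param status `"case"` or `"control"` (case-insensitive).
#' @param sex `"female"` or `"male"` (case-insensitive).
#' @param age years, non-negative.
#' @param bmi kg/m^2, positive.
#' @param t2d `"yes"`, `"no"`, or anything else mapped to `"unknown"`.
#' @return A `data.frame` with columns `sample_id`, `cohort`, `status`,
#'   `sex`, `age`, `bmi`, `t2d`.
#' @export
sample_records <- function(sample_id = character(), cohort = character(),
                           status = character(), sex = character(),
                           age = numeric(), bmi = numeric(),
                           t2d = "unknown") {
  status <- tolower(as.character(status))
  sex <- tolower(as.character(sex))
  t2d <- tolower(as.character(t2d))
  t2d[!t2d %in% c("yes", "no")] <- "unknown"
  n <- length(sample_id)
  df <- data.frame(
    sample_id = as.character(sample_id),
    cohort = rep_len(as.character(cohort), n),
    status = rep_len(status, n), sex = rep_len(sex, n),
    age = rep_len(as.numeric(age), n), bmi = rep_len(as.numeric(bmi), n),
    t2d = rep_len(t2d, n),
    stringsAsFactors = FALSE
  )
  validate_sample_records(df)
}

#' @rdname sample_records
#' @param samples a phenotype `data.frame` to validate.
#' @export
validate_sample_records <- function(samples) {
  need <- c("sample_id", "cohort", "status", "sex", "age", "bmi")
  miss <- setdiff(need, names(samples))
  if (length(miss)) stopf("phenotype table is missing column(s): %s",
                          paste(miss, collapse = ", "))
  if (anyDuplicated(sample_key(samples$cohort, samples$sample_id)))
    stop("duplicate sample_id within a cohort")
  if (any(!samples$status %in% c("case", "control")))
    stop("status must be 'case' or 'control'")
  if (any(!samples$sex %in% c("female", "male")))
    stop("sex must be 'female' or 'male'")
  if (any(samples$age < 0, na.rm = TRUE)) stop("negative age")
  if (any(samples$bmi <= 0, na.rm = TRUE)) stop("non-positive BMI")
  samples
}

#' Construct a validated gene model table
#'
#' Gene spans (full genomic extent, not exon models) used for call-to-gene
#' overlap.  Coordinates are 0-based half-open, as in BED.
#'
#' @param gene_id unique gene identifiers.
#' @param chrom chromosome labels.
#' @param start,end 0-based half-open span.
#' @return A `data.frame` with columns `gene_id`, `chrom`, `start`, `end`.
#' @export
gene_models <- function(gene_id = character(), chrom = character(),
                        start = integer(), end = integer()) {
  df <- data.frame(
    gene_id = as.character(gene_id),
    chrom = if (length(chrom)) norm_chrom(chrom) else character(),
    start = as.numeric(start), end = as.numeric(end),
    stringsAsFactors = FALSE
  )
  if (any(df$end <= df$start)) stop("gene with end <= start")
  if (anyDuplicated(df$gene_id)) stop("duplicate gene_id")
  df
}

#' Construct a gene-set collection
#'
#' Named sets of gene identifiers (burden hypotheses), with a free-text
#' provenance tag per set (e.g. the GO accession or tissue catalogue a real
#' set was taken from).
#'
#' @param sets named list of character vectors of gene ids; duplicate members
#'   within a set are collapsed, empty sets are rejected.
#' @param provenance optional named character vector (same names as `sets`).
#' @return An object of class `gene_set_collection` with elements `sets` and
#'   `provenance`.
#' @export
gene_set_collection <- function(sets, provenance = NULL) {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("every gene set needs a name")
  if (anyDuplicated(names(sets))) stop("duplicate gene set names")
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (any(vapply(sets, length, 1L) == 0L)) stop("empty gene set")
  if (any(vapply(sets, function(g) any(!nzchar(g) | is.na(g)), TRUE)))
    stop("gene set with empty member id")
  if (is.null(provenance)) provenance <- setNames(rep("", length(sets)), names(sets))
  provenance <- provenance[names(sets)]
  structure(list(sets = sets, provenance = provenance),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection with %d sets:\n", length(x$sets)))
  for (nm in names(x$sets))
    cat(sprintf("  %-20s %5d genes  %s\n", nm, length(x$sets[[nm]]),
                x$provenance[[nm]]))
  invisible(x)
}
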