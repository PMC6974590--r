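# Candidate-gene extraction: genes in the lipid set, expressed in the target
# tissue, hit by CNVs in at least one case and in no control.

#' Extract candidate genes through the staged filter chain
#'
#' Stages: (1) the lipid gene set; (2) its genes also in the tissue set;
#' (3) of those, genes overlapped by at least one CNV in at least one case;
#' (4) of those, genes with zero control carriers anywhere — exclusivity is
#' absolute and pooled across cohorts, so one control carrier in any cohort
#' disqualifies a gene.  Output rows are per gene and cohort, sorted by
#' genomic position, with CNV bounds displayed 1-based inclusive.
#'
#' @param annotated an [annotate_calls()] result (post-QC).
#' @param samples the phenotype table.
#' @param lipid_genes character vector: the lipid gene set.
#' @param tissue_genes character vector: the tissue-expression gene set.
#' @return a list with `candidates` (data frame: `gene_id`, `n_gsd_cases`,
#'   `n_controls` (always 0), `case_sex`, `chrom`, `cnv_start`, `cnv_end`,
#'   `cnv_type`, `cohort`) and `stage_counts` (named integer vector
#'   `lipid`, `lipid_tissue`, `case_hit`, `exclusive`).
#' @export
extract_candidates <- function(annotated, samples, lipid_genes, tissue_genes) {
  lipid_genes <- unique(as.character(lipid_genes))
  tissue_genes <- unique(as.character(tissue_genes))
  if (!length(lipid_genes)) stop("empty lipid gene set")
  if (!length(tissue_genes)) stop("empty tissue gene set")
  focus <- intersect(lipid_genes, tissue_genes)

  long <- annotation_long(annotated)
  long <- long[!is.na(long$gene_id) & long$gene_id %in% focus, , drop = FALSE]
  skey <- sample_key(long$cohort, long$sample_id)
  idx <- match(skey, sample_key(samples$cohort, samples$sample_id))
  if (anyNA(idx))
    stop("annotated call carried by a sample absent from the phenotype table")
  long$status <- samples$status[idx]
  long$sex <- samples$sex[idx]

  case_genes <- sort(unique(long$gene_id[long$status == "case"]))
  control_genes <- unique(long$gene_id[long$status == "control"])
  exclusive <- setdiff(case_genes, control_genes)
  stage_counts <- c(lipid = length(lipid_genes),
                    lipid_tissue = length(focus),
                    case_hit = length(case_genes),
                    exclusive = length(exclusive))

  keep <- long$status == "case" & long$gene_id %in% exclusive
  long <- long[keep, , drop = FALSE]
  if (nrow(long)) {
    grp <- split(seq_len(nrow(long)), paste(long$gene_id, long$cohort, sep = "\r"))
    candidates <- do.call(rbind, lapply(grp, function(ix) {
      data.frame(
        gene_id = long$gene_id[ix[1]],
        n_gsd_cases = length(unique(long$sample_id[ix])),
        n_controls = 0L,
        case_sex = paste(sort(unique(long$sex[ix])), collapse = ","),
        chrom = long$chrom[ix[1]],
        cnv_start = min(long$start[ix]) + 1,  # display 1-based inclusive
        cnv_end = max(long$end[ix]),
        cnv_type = paste(sort(unique(long$type[ix])), collapse = ","),
        cohort = long$cohort[ix[1]], stringsAsFactors = FALSE)
    }))
    candidates <- candidates[order(candidates$chrom, candidates$cnv_start,
                                   candidates$gene_id), , drop = FALSE]
    rownames(candidates) <- NULL
  } else {
    candidates <- data.frame(gene_id = character(), n_gsd_cases = integer(),
                             n_controls = integer(), case_sex = character(),
                             chrom = character(), cnv_start = numeric(),
                             cnv_end = numeric(), cnv_type = character(),
                             cohort = character(), stringsAsFactors = FALSE)
  }
  list(candidates = candidates, stage_counts = stage_counts)
}

#' Collapse candidate rows that share one CNV event for display
#'
#' Genes listed from the same cohort with identical CNV bounds and type are
#' merged into one display row with comma-joined gene ids (the layout used
#' when several genes ride on a single multi-gene event).
#'
#' @param candidates the `candidates` data frame from [extract_candidates()].
#' @return the collapsed display table.
#' @export
format_candidate_table <- function(candidates) {
  if (!nrow(candidates)) return(candidates)
  keyv <- paste(candidates$cohort, candidates$chrom, candidates$cnv_start,
                candidates$cnv_end, candidates$cnv_type, sep = "\r")
  out <- do.call(rbind, lapply(split(seq_len(nrow(candidates)), keyv), function(ix) {
    r <- candidates[ix[1], , drop = FALSE]
    r$gene_id <- paste(sort(candidates$gene_id[ix]), collapse = ",")
    r$n_gsd_cases <- max(candidates$n_gsd_cases[ix])
    r$case_sex <- paste(sort(unique(unlist(
      strsplit(candidates$case_sex[ix], ",", fixed = TRUE)))), collapse = ",")
    r
  }))
  out <- out[order(out$chrom, out$cnv_start, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Upper-tail hypergeometric enrichment probability
#'
#' The probability of observing at least `hits_in_set` members of a
#' `set_size`-gene set among `hits_total` genes drawn without replacement
#' from a universe of `universe` genes.
#'
#' @param hits_in_set observed overlap count.
#' @param set_size size of the annotated set within the universe.
#' @param hits_total number of genes drawn (e.g. candidate genes).
#' @param universe total number of genes.
#' @return `P(X >= hits_in_set)` for `X` hypergeometric.
#' @examples
#' hypergeom_enrichment(2, 2, 2, 4)  # 1/6
#' @export
hypergeom_enrichment <- function(hits_in_set, set_size, hits_total, universe) {
  if (any(c(hits_in_set, set_size, hits_total, universe) < 0) ||
      hits_in_set > min(set_size, hits_total) ||
      set_size > universe || hits_total > universe)
    stop("inconsistent hypergeometric counts")
  phyper(hits_in_set - 1, set_size, universe - set_size, hits_total,
         lower.tail = FALSE)
}
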