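# Call-to-gene overlap annotation and derived (compound) gene sets.

#' Build an interval index over gene models
#'
#' Wraps the gene table in a `GRanges`-backed index whose queries return all
#' genes sharing at least 1 bp with a query interval, in deterministic
#' (chromosome, start, gene_id) order.
#'
#' @param genes a [gene_models()] table.
#' @return an object of class `gene_index`.
#' @export
build_gene_index <- function(genes) {
  stopifnot(all(c("gene_id", "chrom", "start", "end") %in% names(genes)))
  genes <- unique(genes[, c("gene_id", "chrom", "start", "end")])
  if (anyDuplicated(genes$gene_id))
    stopf("gene_id '%s' appears with different coordinates",
          genes$gene_id[duplicated(genes$gene_id)][1])
  genes <- genes[order(genes$chrom, genes$start, genes$gene_id), , drop = FALSE]
  rownames(genes) <- NULL
  structure(list(genes = genes,
                 gr = as_granges0(genes$chrom, genes$start, genes$end)),
            class = "gene_index")
}

#' @rdname build_gene_index
#' @param index a `gene_index`.
#' @param chrom,start,end a query interval (0-based half-open).
#' @return for `query_gene_index`, the character vector of overlapping gene
#'   ids.
#' @export
query_gene_index <- function(index, chrom, start, end) {
  hits <- find_overlaps0(
    as_granges0(norm_chrom(chrom), start, end), index$gr)
  index$genes$gene_id[sort(S4Vectors::subjectHits(hits))]
}

#' Annotate CNV calls with overlapped genes and gene sets
#'
#' Each call is annotated with the genes whose genomic span it overlaps by at
#' least 1 bp, and with the names of every gene set containing such a gene.
#' Calls overlapping no gene are retained with empty annotations — they still
#' count for the "any CNV" carrier analysis.  Genes that appear in a set but
#' have no gene model are reported once and ignored.
#'
#' @param calls a CNV call table.
#' @param index a [build_gene_index()] result.
#' @param collection a [gene_set_collection()].
#' @return the call table with list-columns `genes` and `sets_hit`, plus an
#'   attribute `set_names` recording the collection's set names.
#' @export
annotate_calls <- function(calls, index, collection) {
  stopifnot(inherits(index, "gene_index"),
            inherits(collection, "gene_set_collection"))
  calls <- validate_cnv_calls(calls)
  model_ids <- index$genes$gene_id
  orphan <- unique(unlist(lapply(collection$sets, setdiff, y = model_ids)))
  if (length(orphan))
    message(sprintf("%d gene(s) in sets have no gene model and are ignored for overlap (e.g. %s)",
                    length(orphan), orphan[1]))
  # gene -> sets membership
  gene2sets <- new.env(parent = emptyenv())
  for (nm in names(collection$sets))
    for (g in collection$sets[[nm]])
      assign(g, c(get0(g, envir = gene2sets, ifnotfound = character()), nm),
             envir = gene2sets)
  n <- nrow(calls)
  genes_l <- rep(list(character()), n)
  if (n > 0L) {
    hits <- find_overlaps0(
      as_granges0(calls$chrom, calls$start, calls$end), index$gr)
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    ord <- order(qh, sh)
    genes_split <- split(model_ids[sh[ord]], qh[ord])
    genes_l[as.integer(names(genes_split))] <- genes_split
  }
  sets_l <- lapply(genes_l, function(gs) {
    if (!length(gs)) return(character())
    sort(unique(unlist(lapply(gs, get0, envir = gene2sets,
                              ifnotfound = character()))))
  })
  calls$genes <- genes_l
  calls$sets_hit <- sets_l
  attr(calls, "set_names") <- names(collection$sets)
  calls
}

#' Derive compound gene sets from lipid and tissue-expression sets
#'
#' Adds two first-class sets used by the association grid: the genes that are
#' both in the lipid set and in the tissue set (`lipid_and_si`), and the
#' tissue genes outside the lipid set (`si_not_lipid`).
#'
#' @param collection a [gene_set_collection()].
#' @param lipid,tissue names of the base sets (defaults `"lipid"` and
#'   `"small_intestine"`).
#' @return the collection with the two derived sets appended.
#' @export
derive_compound_sets <- function(collection, lipid = "lipid",
                                 tissue = "small_intestine") {
  for (nm in c(lipid, tissue))
    if (!nm %in% names(collection$sets))
      stopf("base set '%s' is missing from the collection", nm)
  both <- intersect(collection$sets[[lipid]], collection$sets[[tissue]])
  only_tissue <- setdiff(collection$sets[[tissue]], collection$sets[[lipid]])
  if (!length(both))
    stopf("sets '%s' and '%s' are disjoint; the derived intersection set would be empty",
          lipid, tissue)
  if (!length(only_tissue))
    stopf("set '%s' is contained in '%s'; the derived difference set would be empty",
          tissue, lipid)
  sets <- c(collection$sets,
            list(lipid_and_si = both, si_not_lipid = only_tissue))
  prov <- c(collection$provenance,
            lipid_and_si = sprintf("%s AND %s", lipid, tissue),
            si_not_lipid = sprintf("%s NOT %s", tissue, lipid))
  gene_set_collection(sets, prov)
}

#' Export annotated calls as a long call-by-gene table
#'
#' @param annotated an [annotate_calls()] result.
#' @return a data frame with one row per call-gene pair (calls without genes
#'   appear once with `gene_id = NA`).
#' @export
annotation_long <- function(annotated) {
  n_genes <- vapply(annotated$genes, length, 1L)
  idx <- rep(seq_len(nrow(annotated)), pmax(n_genes, 1L))
  gene <- unlist(lapply(annotated$genes, function(g) if (length(g)) g else NA_character_))
  out <- annotated[idx, c("sample_id", "cohort", "chrom", "start", "end",
                          "type", "n_probes")]
  out$gene_id <- gene
  rownames(out) <- NULL
  out
}
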