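# Readers and writers for every external format the pipeline touches.
# Internal convention is 0-based half-open; each reader converts on the way
# in and each writer restores the format's native convention.

#' Read a per-sample CNV call table (TSV)
#'
#' The TSV dialect carries one call per row with a header declaring the
#' columns `sample`, `cohort`, `chrom`, `start`, `end`, `type`, `n_probes`.
#' Coordinates in the file are 1-based inclusive (the convention used when
#' CNV bounds are printed in publication tables); they are converted to the
#' package's 0-based half-open convention on input.
#'
#' @param path path to a tab-separated file with the header above.
#' @return a CNV call table (see [cnv_calls()]).
#' @seealso [write_cnv_tsv()] for the inverse operation.
#' @export
read_cnv_tsv <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  raw <- read.delim(path, header = TRUE, colClasses = "character",
                    check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("sample", "cohort", "chrom", "start", "end", "type", "n_probes")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stopf("CNV TSV %s is missing required column(s): %s", path,
          paste(miss, collapse = ", "))
  if (nrow(raw) == 0L)
    return(cnv_calls(source = character()))
  line_no <- seq_len(nrow(raw)) + 1L  # header is line 1
  to_int <- function(col) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) | v != floor(v))
    if (length(bad))
      stopf("non-integer %s at line %d of %s", col, line_no[bad[1]], path)
    v
  }
  start1 <- to_int("start"); end1 <- to_int("end")
  n_probes <- to_int("n_probes")
  type <- tolower(raw$type)
  bad_type <- which(!type %in% c("gain", "loss"))
  if (length(bad_type))
    stopf("unknown CNV type '%s' at line %d of %s",
          raw$type[bad_type[1]], line_no[bad_type[1]], path)
  bad_coord <- which(end1 <= start1)
  if (length(bad_coord))
    stopf("end <= start at line %d of %s", line_no[bad_coord[1]], path)
  cnv_calls(sample_id = raw$sample, cohort = raw$cohort, chrom = raw$chrom,
            start = start1 - 1, end = end1, type = type,
            n_probes = n_probes, source = path)
}

#' @rdname read_cnv_tsv
#' @param calls a CNV call table.
#' @export
write_cnv_tsv <- function(calls, path) {
  calls <- validate_cnv_calls(calls)
  out <- data.frame(sample = calls$sample_id, cohort = calls$cohort,
                    chrom = calls$chrom,
                    start = format(calls$start + 1, scientific = FALSE, trim = TRUE),
                    end = format(calls$end, scientific = FALSE, trim = TRUE),
                    type = calls$type, n_probes = calls$n_probes)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read CNV calls from a VCF with symbolic DUP/DEL records
#'
#' Accepts VCF 4.x files whose records use symbolic structural-variant
#' alleles `<DUP>` / `<DEL>` with an `INFO/END` field (1-based inclusive end).
#' `<DUP>` maps to a gain and `<DEL>` to a loss; records with any other ALT
#' are skipped with a warning.  The carrier sample is taken from an
#' `INFO/SAMPLE` tag if present, otherwise from a single genotype column.
#'
#' @param path path to a VCF file.
#' @param n_probes_key INFO key holding the supporting-probe count; calls
#'   without it get 0 probes, which the probe filter then removes unless that
#'   filter is disabled (fail-closed QC).
#' @param cohort fallback cohort label when no `INFO/COHORT` tag is present.
#' @return a CNV call table (see [cnv_calls()]).
#' @export
read_cnv_vcf <- function(path, n_probes_key = "NPROBES", cohort = "unknown") {
  if (!file.exists(path)) stopf("no such file: %s", path)
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  n <- length(vcf)
  if (n == 0L) return(cnv_calls(source = character()))
  alt <- as.character(unlist(VariantAnnotation::alt(vcf)))
  keep <- alt %in% c("<DUP>", "<DEL>")
  if (any(!keep))
    warning(sprintf("skipped %d non-DUP/DEL record(s) in %s (e.g. ALT %s)",
                    sum(!keep), path, alt[!keep][1]))
  inf <- VariantAnnotation::info(vcf)
  end1 <- inf$END
  if (is.null(end1)) stopf("VCF %s has no INFO/END field", path)
  if (any(is.na(end1[keep]))) {
    bad <- names(vcf)[keep & is.na(end1)][1]
    stopf("record %s in %s lacks INFO/END", bad, path)
  }
  rr <- SummarizedExperiment::rowRanges(vcf)
  sample_id <- if (!is.null(inf$SAMPLE)) as.character(inf$SAMPLE)
  else {
    smp <- colnames(vcf)
    if (length(smp) == 1L) rep(smp, n)
    else stopf("VCF %s needs an INFO/SAMPLE tag or exactly one sample column",
               path)
  }
  cohort_lab <- if (!is.null(inf$COHORT)) as.character(inf$COHORT)
  else rep(cohort, n)
  n_probes <- if (n_probes_key %in% names(inf)) {
    np <- as.integer(inf[[n_probes_key]])
    np[is.na(np)] <- 0L
    np
  } else rep(0L, n)
  cnv_calls(
    sample_id = sample_id[keep], cohort = cohort_lab[keep],
    chrom = as.character(GenomicRanges::seqnames(rr))[keep],
    start = GenomicRanges::start(rr)[keep] - 1, end = end1[keep],
    type = ifelse(alt[keep] == "<DUP>", "gain", "loss"),
    n_probes = n_probes[keep], source = path
  )
}

#' @rdname read_cnv_vcf
#' @param calls a CNV call table.
#' @export
write_cnv_vcf <- function(calls, path) {
  calls <- validate_cnv_calls(calls)
  n <- nrow(calls)
  gr <- GenomicRanges::GRanges(calls$chrom,
                               IRanges::IRanges(start = calls$start + 1, width = 1L))
  names(gr) <- sprintf("cnv%d", seq_len(max(n, 0L)))
  fixed_df <- S4Vectors::DataFrame(
    REF = Biostrings::DNAStringSet(rep("N", n)),
    ALT = IRanges::CharacterList(as.list(
      ifelse(calls$type == "gain", "<DUP>", "<DEL>"))),
    QUAL = rep(NA_real_, n), FILTER = rep(".", n))
  info_df <- S4Vectors::DataFrame(
    END = as.integer(calls$end), SVTYPE = ifelse(calls$type == "gain", "DUP", "DEL"),
    NPROBES = as.integer(calls$n_probes), SAMPLE = calls$sample_id,
    COHORT = calls$cohort)
  hdr <- VariantAnnotation::VCFHeader()
  VariantAnnotation::info(hdr) <- S4Vectors::DataFrame(
    Number = rep("1", 5L),
    Type = c("Integer", "String", "Integer", "String", "String"),
    Description = c("End position, 1-based inclusive",
                    "Structural variant type",
                    "Number of supporting array probes",
                    "Carrier sample identifier", "Cohort label"),
    row.names = c("END", "SVTYPE", "NPROBES", "SAMPLE", "COHORT"))
  VariantAnnotation::meta(hdr) <- IRanges::DataFrameList(
    fileformat = S4Vectors::DataFrame(Value = "VCFv4.2",
                                      row.names = "fileformat"))
  vcf <- VariantAnnotation::VCF(rowRanges = gr, fixed = fixed_df,
                                info = info_df, collapsed = TRUE)
  VariantAnnotation::header(vcf) <- hdr
  VariantAnnotation::writeVcf(vcf, path)
  invisible(path)
}

#' Read a sample phenotype table (TSV)
#'
#' Expects a header with columns `sample`, `cohort`, `status`, `sex`, `age`,
#' `bmi` and optionally `t2d`.  Enum fields are parsed case-insensitively;
#' unrecognized T2D tokens map to `"unknown"`.
#'
#' @param path path to the tab-separated phenotype file.
#' @return a phenotype table (see [sample_records()]).
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  raw <- read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
  need <- c("sample", "cohort", "status", "sex", "age", "bmi")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stopf("phenotype file %s is missing column(s): %s", path,
          paste(miss, collapse = ", "))
  sample_records(sample_id = raw$sample, cohort = raw$cohort,
                 status = raw$status, sex = raw$sex,
                 age = raw$age, bmi = raw$bmi,
                 t2d = if ("t2d" %in% names(raw)) raw$t2d else "unknown")
}

#' @rdname read_phenotypes
#' @param samples a phenotype table.
#' @export
write_phenotypes <- function(samples, path) {
  samples <- validate_sample_records(samples)
  out <- data.frame(sample = samples$sample_id, cohort = samples$cohort,
                    status = samples$status, sex = samples$sex,
                    age = samples$age, bmi = samples$bmi,
                    t2d = if ("t2d" %in% names(samples)) samples$t2d else "unknown")
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene models (or blacklist regions) from BED
#'
#' BED is natively 0-based half-open, matching the internal convention, so
#' coordinates pass through unchanged.  Intervals without a name column get
#' synthetic `region_<i>` identifiers (useful for blacklists).
#'
#' @param path path to a BED file (3+ columns).
#' @return a gene model table (see [gene_models()]).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  gr <- rtracklayer::import(path, format = "BED")
  nm <- if (!is.null(gr$name)) as.character(gr$name) else rep(NA_character_, length(gr))
  nm[is.na(nm) | !nzchar(nm)] <- sprintf("region_%d", which(is.na(nm) | !nzchar(nm)))
  gene_models(gene_id = nm,
              chrom = as.character(GenomicRanges::seqnames(gr)),
              start = GenomicRanges::start(gr) - 1,
              end = GenomicRanges::end(gr))
}

#' @rdname read_bed
#' @param genes a gene model table.
#' @export
write_bed <- function(genes, path) {
  gr <- as_granges0(genes$chrom, genes$start, genes$end)
  gr$name <- genes$gene_id
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a gene-set collection from GMT
#'
#' Standard GMT dialect: one set per line, tab-separated fields
#' `name`, `description`, then member gene ids.  Duplicate members within a
#' set are collapsed; duplicate set names and sets without members are
#' format errors.  The description field is kept as the set's provenance tag,
#' which is why a dedicated reader is used here rather than one of the
#' enrichment packages' GMT loaders (those drop the description).
#'
#' @param path path to a GMT file.
#' @return a [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, 1L) < 3L)
  if (length(short))
    stopf("GMT line %d of %s has fewer than 3 fields", short[1], path)
  nms <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(nms))
    stopf("duplicate gene set name '%s' in %s", nms[duplicated(nms)][1], path)
  sets <- lapply(fields, function(f) unique(f[-c(1L, 2L)]))
  names(sets) <- nms
  prov <- setNames(vapply(fields, `[[`, "", 2L), nms)
  gene_set_collection(sets, prov)
}

#' @rdname read_gmt
#' @param collection a [gene_set_collection()].
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, collection$provenance[[nm]], collection$sets[[nm]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
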