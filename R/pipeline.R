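# One-command orchestration: simulate/load -> QC -> annotate -> burden ->
# GLM grid -> candidates, with result tables, a markdown report and a
# reproducibility manifest.

format_p <- function(p) ifelse(is.na(p), "NA", formatC(p, format = "e", digits = 1))
format_or <- function(x) ifelse(is.na(x), "NA", sprintf("%.2f", x))

#' Run the complete burden pipeline
#'
#' Executes quality control, gene annotation (with derived compound sets when
#' the lipid and small-intestine sets are available), per-cohort burden
#' analysis including gain/loss strata, the 15-model logistic association
#' grid, and candidate-gene extraction; writes all result tables (TSV), a
#' markdown report, and a JSON manifest with configuration snapshot, file
#' checksums and per-stage row counts.  Any stage failure aborts with the
#' stage name after writing a partial manifest.
#'
#' @param config either a [sim_config()] (inputs are simulated and the
#'   fixture bundle written under `out_dir/inputs`) or a named list of file
#'   paths with elements `calls` (TSV), `phenotypes`, `genes`, `gene_sets`,
#'   and optionally `blacklist`.
#' @param out_dir output directory.
#' @param alpha nominal familywise alpha used for both test families.
#' @param qc a [qc_config()]; its blacklist is filled from the inputs when
#'   available.
#' @return invisibly, the manifest (also written to `manifest.json`).
#' @export
run_all <- function(config, out_dir, alpha = 0.05, qc = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(version = as.character(packageVersion("cnvburden")),
                   alpha = alpha, stages = list(), outputs = character())
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      manifest$error <<- sprintf("stage '%s' failed: %s", name,
                                 conditionMessage(e))
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE, force = TRUE)
      stopf("stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  inputs <- stage("inputs", {
    if (inherits(config, "sim_config")) {
      bundle <- write_fixture_bundle(config, file.path(out_dir, "inputs"))
      manifest$seed <- config$seed
      list(calls = bundle$study$calls, samples = bundle$study$samples,
           genes = bundle$study$genome$genes,
           collection = bundle$study$genome$collection,
           blacklist = bundle$study$genome$blacklist,
           min_probes = setNames(
             vapply(config$cohorts, function(co) as.integer(co$min_probes), 1L),
             vapply(config$cohorts, `[[`, "", "name")),
           files = unlist(bundle[names(bundle) != "study"]))
    } else {
      stopifnot(all(c("calls", "phenotypes", "genes", "gene_sets") %in%
                      names(config)))
      list(calls = read_cnv_tsv(config$calls),
           samples = read_phenotypes(config$phenotypes),
           genes = read_bed(config$genes),
           collection = read_gmt(config$gene_sets),
           blacklist = if (!is.null(config$blacklist)) read_bed(config$blacklist),
           min_probes = NULL,
           files = unlist(config))
    }
  })
  manifest$input_checksums <- as.list(tools::md5sum(
    inputs$files[file.exists(inputs$files)]))
  manifest$stages$inputs <- list(n_calls = nrow(inputs$calls),
                                 n_samples = nrow(inputs$samples))

  qc_res <- stage("qc", {
    if (is.null(qc)) {
      mp <- if (!is.null(inputs$min_probes)) inputs$min_probes else c(default = 50L)
      qc <- qc_config(min_probes = mp, blacklist = inputs$blacklist)
    } else if (is.null(qc$blacklist)) qc$blacklist <- inputs$blacklist
    apply_qc(inputs$calls, inputs$samples, qc)
  })
  manifest$stages$qc <- list(counts = qc_res$report$stages$n_calls,
                             n_excluded_samples = nrow(qc_res$report$excluded_samples))

  annotated <- stage("annotate", {
    coll <- inputs$collection
    if (all(c("lipid", "small_intestine") %in% names(coll$sets)))
      coll <- derive_compound_sets(coll)
    index <- build_gene_index(inputs$genes)
    a <- annotate_calls(qc_res$calls, index, coll)
    attr(a, "collection") <- coll
    a
  })
  collection <- attr(annotated, "collection")
  manifest$stages$annotate <- list(
    n_calls = nrow(annotated),
    n_genic = sum(vapply(annotated$genes, length, 1L) > 0))

  # the burden family is the base collection ("any" + the configured sets);
  # the derived compound sets only enter the association grid
  burden <- stage("burden", run_burden(annotated, qc_res$samples,
                                       inputs$collection, alpha))
  manifest$stages$burden <- list(n_tests = nrow(burden),
                                 n_significant = sum(burden$significant))

  glm_res <- stage("glm", {
    if (all(c("lipid_and_si", "si_not_lipid") %in% names(collection$sets)))
      run_glm_grid(qc_res$samples, annotated, alpha)
    else list(grid = NULL, fits = NULL)
  })
  if (!is.null(glm_res$grid))
    manifest$stages$glm <- list(n_models = nrow(glm_res$grid),
                                n_significant = sum(glm_res$grid$significant,
                                                    na.rm = TRUE))

  cand <- stage("candidates", {
    if (all(c("lipid", "small_intestine") %in% names(collection$sets)))
      extract_candidates(annotated, qc_res$samples,
                         collection$sets$lipid,
                         collection$sets$small_intestine)
    else list(candidates = NULL, stage_counts = NULL)
  })
  if (!is.null(cand$stage_counts))
    manifest$stages$candidates <- as.list(cand$stage_counts)

  # result tables
  outs <- c(qc_stages = "qc_stages.tsv", regions = "cnv_regions.tsv",
            burden = "burden.tsv")
  write.table(qc_res$report$stages, file.path(out_dir, "qc_stages.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(qc_res$report$regions, file.path(out_dir, "cnv_regions.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(burden, file.path(out_dir, "burden.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(glm_res$grid)) {
    write.table(glm_res$grid, file.path(out_dir, "glm_grid.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    outs <- c(outs, glm = "glm_grid.tsv")
  }
  if (!is.null(cand$candidates)) {
    write.table(format_candidate_table(cand$candidates),
                file.path(out_dir, "candidate_genes.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    outs <- c(outs, candidates = "candidate_genes.tsv")
  }
  writeLines(render_report(qc_res, burden, glm_res$grid, cand, alpha),
             file.path(out_dir, "report.md"))
  outs <- c(outs, report = "report.md")
  manifest$outputs <- as.list(tools::md5sum(file.path(out_dir, outs)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  invisible(manifest)
}

render_report <- function(qc_res, burden, grid, cand, alpha) {
  out <- c("# CNV burden pipeline report", "", "## Quality control", "")
  st <- qc_res$report$stages
  out <- c(out, sprintf("- %s: %d calls", st$stage, st$n_calls), "")
  if (nrow(qc_res$report$excluded_samples))
    out <- c(out, sprintf("- excluded CNV-outlier samples: %d",
                          nrow(qc_res$report$excluded_samples)), "")
  out <- c(out, "## Burden (type-combined family)", "",
           sprintf("Bonferroni-adjusted alpha: %s",
                   format_alpha(unique(burden$alpha_adjusted[
                     burden$type_stratum == "any"])[1])), "")
  b <- burden[burden$type_stratum == "any", ]
  out <- c(out, "| cohort | set | OR | 95% CI | p | significant |",
           "|---|---|---|---|---|---|",
           sprintf("| %s | %s | %s | %s-%s | %s | %s |", b$cohort, b$set_name,
                   format_or(b$or), format_or(b$ci_lo), format_or(b$ci_hi),
                   format_p(b$p), ifelse(b$significant, "*", "")), "")
  if (!is.null(grid)) {
    out <- c(out, "## Covariate-adjusted association grid", "",
             sprintf("Carrier-term threshold: %s",
                     format_alpha(bonferroni_alpha(alpha, nrow(grid)))), "",
             "| predictor | stratum | OR | 95% CI | p | significant |",
             "|---|---|---|---|---|---|",
             sprintf("| %s | %s | %s | %s-%s | %s | %s |",
                     grid$predictor_set, grid$stratum, format_or(grid$or),
                     format_or(grid$ci_lo), format_or(grid$ci_hi),
                     format_p(grid$p), ifelse(!is.na(grid$significant) &
                                                grid$significant, "*", "")), "")
  }
  if (!is.null(cand$stage_counts))
    out <- c(out, "## Candidate genes", "",
             sprintf("Filter chain: %d lipid -> %d also tissue-expressed -> %d hit in cases -> %d case-exclusive",
                     cand$stage_counts[["lipid"]],
                     cand$stage_counts[["lipid_tissue"]],
                     cand$stage_counts[["case_hit"]],
                     cand$stage_counts[["exclusive"]]), "")
  out
}
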