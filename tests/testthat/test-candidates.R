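# Candidate-gene filter chain and hypergeometric enrichment.

toy_candidate_setup <- function() {
  genes <- gene_models(LETTERS[1:5], "chr1",
                       start = (1:5) * 1e6, end = (1:5) * 1e6 + 5e4)
  collection <- gene_set_collection(list(
    lipid = c("A", "B", "C", "D"), small_intestine = c("B", "C", "D", "E")))
  samples <- sample_records(sprintf("S%02d", 1:20), "TOY",
                            rep(c("case", "control"), each = 10),
                            rep(c("female", "male"), 10),
                            age = 50, bmi = 27)
  # case CNVs over genes B and C; a control CNV over C only
  calls <- cnv_calls(c("S01", "S02", "S11"), "TOY", "chr1",
                     start = c(1.99e6, 2.99e6, 2.99e6),
                     end = c(2.10e6, 3.10e6, 3.10e6),
                     type = c("gain", "gain", "loss"), n_probes = 80L)
  ann <- annotate_calls(calls, build_gene_index(genes), collection)
  list(genes = genes, collection = collection, samples = samples, ann = ann)
}

test_that("the toy filter chain yields stage counts (4,3,2,1) and candidate B", {
  ts <- toy_candidate_setup()
  res <- extract_candidates(ts$ann, ts$samples,
                            ts$collection$sets$lipid,
                            ts$collection$sets$small_intestine)
  expect_equal(unname(res$stage_counts), c(4L, 3L, 2L, 1L))
  expect_true(all(diff(res$stage_counts) <= 0))
  expect_equal(res$candidates$gene_id, "B")
  expect_equal(res$candidates$n_gsd_cases, 1L)
  expect_equal(res$candidates$n_controls, 0L)
  expect_equal(res$candidates$case_sex, "female")
  # display coordinates are 1-based inclusive
  expect_equal(res$candidates$cnv_start, 1.99e6 + 1)
  expect_equal(res$candidates$cnv_end, 2.10e6)
})

test_that("without case calls the chain reports (n, m, 0, 0)", {
  ts <- toy_candidate_setup()
  controls_only <- ts$ann[ts$ann$sample_id == "S11", ]
  attr(controls_only, "set_names") <- attr(ts$ann, "set_names")
  res <- extract_candidates(controls_only, ts$samples,
                            ts$collection$sets$lipid,
                            ts$collection$sets$small_intestine)
  expect_equal(unname(res$stage_counts), c(4L, 3L, 0L, 0L))
  expect_equal(nrow(res$candidates), 0L)
  expect_error(extract_candidates(ts$ann, ts$samples, character(), "E"),
               "empty lipid")
})

test_that("exclusivity is absolute and output is call-order invariant", {
  fx <- tiny_fixture()
  idx <- build_gene_index(fx$genes)
  for (seed in 1:10) {
    calls <- withr::with_seed(seed, {
      k <- 15L
      g <- fx$genes[sample.int(5, k, replace = TRUE), ]
      cnv_calls(sample(fx$samples$sample_id, k, replace = TRUE), "TOY",
                g$chrom, g$start - 1e4, g$end + 1e4,
                sample(c("gain", "loss"), k, replace = TRUE), 80L)
    })
    ann <- annotate_calls(calls, idx, fx$collection)
    res <- extract_candidates(ann, fx$samples, fx$collection$sets$lipid,
                              fx$collection$sets$small_intestine)
    long <- annotation_long(ann)
    long$status <- fx$samples$status[match(long$sample_id, fx$samples$sample_id)]
    control_hit <- unique(long$gene_id[long$status == "control"])
    expect_false(any(res$candidates$gene_id %in% control_hit))
    # permuting the calls leaves the candidate table unchanged
    perm <- withr::with_seed(seed + 100, sample.int(nrow(calls)))
    ann2 <- annotate_calls(calls[perm, ], idx, fx$collection)
    res2 <- extract_candidates(ann2, fx$samples, fx$collection$sets$lipid,
                               fx$collection$sets$small_intestine)
    expect_equal(res2$candidates, res$candidates)
    expect_equal(res2$stage_counts, res$stage_counts)
  }
})

test_that("genes riding one multi-gene event collapse to one display row", {
  genes <- gene_models(c("B", "C"), "chr1", c(2e6, 2.2e6), c(2.05e6, 2.25e6))
  collection <- gene_set_collection(list(lipid = c("B", "C"),
                                         small_intestine = c("B", "C")))
  samples <- sample_records(c("S1", "S2"), "TOY", c("case", "control"),
                            c("male", "female"), 50, 27)
  calls <- cnv_calls("S1", "TOY", "chr1", 1.95e6, 2.30e6, "gain", 80L)
  ann <- annotate_calls(calls, build_gene_index(genes), collection)
  res <- extract_candidates(ann, samples, c("B", "C"), c("B", "C"))
  expect_equal(nrow(res$candidates), 2L)
  disp <- format_candidate_table(res$candidates)
  expect_equal(nrow(disp), 1L)
  expect_equal(disp$gene_id, "B,C")
})

test_that("hypergeometric upper tail matches closed forms and the oracle", {
  expect_equal(hypergeom_enrichment(2, 2, 2, 4), 1 / 6)
  expect_equal(hypergeom_enrichment(0, 5, 3, 20), 1)
  expect_error(hypergeom_enrichment(5, 3, 4, 20), "inconsistent")
  # exhaustive agreement with a binomial-coefficient oracle for N <= 30
  worst <- 0
  for (N in 1:30) for (K in 0:N) for (n in 0:N) {
    ks <- max(0L, n - (N - K)):min(K, n)
    got <- vapply(ks, hypergeom_enrichment, 0, set_size = K,
                  hits_total = n, universe = N)
    want <- vapply(ks, hyper_upper_oracle, 0, K = K, n = n, N = N)
    worst <- max(worst, abs(got - want))
  }
  expect_lt(worst, 1e-12)
})
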