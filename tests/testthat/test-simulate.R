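# Synthetic genome/cohort generator.

test_that("the genome is deterministic, tiled, and set-constrained by construction", {
  cfg <- sim_config("paper_like", seed = 17)
  g1 <- simulate_genome(cfg)
  g2 <- simulate_genome(cfg)
  expect_identical(g1, g2)
  # configured sizes and lipid/SI overlap hold exactly
  sz <- cfg$gene_sets$sizes
  expect_equal(vapply(g1$collection$sets, length, 1L), sz)
  expect_equal(length(intersect(g1$collection$sets$lipid,
                                g1$collection$sets$small_intestine)),
               cfg$gene_sets$lipid_si_overlap)
  # genes never overlap each other, and the blacklist sits in gene-free gaps
  for (chr in unique(g1$genes$chrom)) {
    on <- g1$genes[g1$genes$chrom == chr, ]
    on <- on[order(on$start), ]
    expect_true(all(on$start[-1] >= on$end[-nrow(on)]))
  }
  hits <- GenomicRanges::findOverlaps(
    GenomicRanges::GRanges(g1$blacklist$chrom,
                           IRanges::IRanges(g1$blacklist$start + 1,
                                            g1$blacklist$end)),
    GenomicRanges::GRanges(g1$genes$chrom,
                           IRanges::IRanges(g1$genes$start + 1, g1$genes$end)))
  expect_equal(length(hits), 0L)
  # genes that cannot fit are rejected
  expect_error(
    simulate_genome(sim_config("tiny", seed = 1,
                               overrides = list(genome = list(n_genes = 5000L)))),
    "do not fit")
})

test_that("per-sample call rates match the configured cohort rate", {
  cfg <- sim_config("paper_like", seed = 23)
  genome <- simulate_genome(cfg)
  means <- vapply(1:50, function(i) {
    sim <- simulate_cohort(cfg, genome, "POPGEN", seed = 1000 + i)
    nrow(sim$calls) / nrow(sim$samples)
  }, 0)
  # 821/1957 displays as 0.42; 3-SE band around it
  expect_gte(mean(means), 0.40)
  expect_lte(mean(means), 0.44)
})

test_that("cohort composition is exact and a zero-rate cohort stays empty", {
  cfg <- sim_config("paper_like", seed = 9)
  sim <- simulate_study(cfg)
  expect_equal(as.integer(table(sim$samples$cohort)[c("POPGEN", "SHIP2", "ANCORA")]),
               c(1957L, 1745L, 1076L))
  anc <- sim$samples[sim$samples$cohort == "ANCORA", ]
  expect_equal(sum(anc$status == "case" & anc$sex == "male"), 40L)
  expect_true(all(sim$samples$age >= 18 & sim$samples$age <= 95))
  expect_true(all(sim$samples$bmi >= 15 & sim$samples$bmi <= 60))

  cfg0 <- sim_config("tiny", seed = 2)
  cfg0$cohorts[[1]]$cnv_rate <- 0
  sim0 <- simulate_study(cfg0)
  expect_equal(nrow(sim0$calls), 0L)
  # downstream stages tolerate emptiness
  qc0 <- apply_qc(sim0$calls, sim0$samples, qc_config())
  expect_equal(nrow(qc0$calls), 0L)
})

test_that("gain fraction and size bounds follow the call model", {
  cfg <- sim_config("paper_like", seed = 41)
  sim <- simulate_study(cfg)
  expect_true(all(cnv_size(sim$calls) > 100000))
  expect_true(all(cnv_size(sim$calls) <= 3e6))
  # ~3:1 gains:losses, binomial 4-SE band around 0.742
  p <- mean(sim$calls$type == "gain")
  expect_lt(abs(p - 0.742), 4 * sqrt(0.742 * 0.258 / nrow(sim$calls)))
})

test_that("a null effect injects nothing and infeasible targets error", {
  cfg <- sim_config("paper_like", seed = 13,
                    overrides = list(effect = list(target_or = 1)))
  genome <- simulate_genome(cfg)
  base <- carrier_baseline(cfg, genome)
  expect_equal(nrow(base), 3L)
  expect_true(all(base$q > 0 & base$q < 1))
  sim <- simulate_cohort(cfg, genome, "POPGEN", seed = 77, baseline = base)
  expect_false(any(sim$calls$source == "injected"))

  cfg_bad <- sim_config("paper_like", seed = 13,
                        overrides = list(effect = list(target_or = 0.5)))
  expect_error(simulate_cohort(cfg_bad, genome, "POPGEN", baseline = base),
               "feasible minimum")
})

test_that("injection hits the calibrated carrier probability", {
  # carrier frequency among targeted samples should match the solved p1
  cfg <- sim_config("paper_like", seed = 19,
                    overrides = list(effect = list(target_or = 2.76)))
  genome <- simulate_genome(cfg)
  base <- carrier_baseline(cfg, genome)
  idx <- build_gene_index(genome$genes)
  q <- base$q[base$cohort == "POPGEN"]
  p1 <- 2.76 * q / (1 - q + 2.76 * q)
  carriers <- 0L; eligible <- 0L
  for (i in 1:40) {
    sim <- simulate_cohort(cfg, genome, "POPGEN", seed = 2000 + i,
                           baseline = base)
    ann <- annotate_calls(sim$calls, idx, genome$collection)
    men_cases <- sim$samples[sim$samples$sex == "male" &
                               sim$samples$status == "case", ]
    tab <- count_carriers(ann, men_cases, "lipid")
    carriers <- carriers + tab[["a"]]
    eligible <- eligible + tab[["a"]] + tab[["b"]]
  }
  # exact binomial 99.9% band around p1
  ci <- stats::binom.test(carriers, eligible, p1, conf.level = 0.999)$conf.int
  expect_gte(p1, ci[1])
  expect_lte(p1, ci[2])
})

test_that("the fixture bundle round-trips losslessly and reproducibly", {
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  cfg <- sim_config("tiny", seed = 6)
  b1 <- write_fixture_bundle(cfg, dir1)
  b2 <- write_fixture_bundle(cfg, dir2)
  for (f in c("calls.tsv", "phenotypes.tsv", "genes.bed", "gene_sets.gmt",
              "blacklist.bed", "calls.vcf", "sim_config.yaml"))
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)))
  sim <- b1$study
  back_calls <- read_cnv_tsv(file.path(dir1, "calls.tsv"))
  expect_equal(back_calls[, 1:7], sim$calls[, 1:7], ignore_attr = TRUE)
  back_vcf <- read_cnv_vcf(file.path(dir1, "calls.vcf"))
  expect_equal(back_vcf[order(back_vcf$sample_id, back_vcf$start), 1:7],
               sim$calls[order(sim$calls$sample_id, sim$calls$start), 1:7],
               ignore_attr = TRUE)
  expect_equal(read_phenotypes(file.path(dir1, "phenotypes.tsv")),
               sim$samples, ignore_attr = TRUE)
  expect_equal(read_bed(file.path(dir1, "genes.bed")), sim$genome$genes,
               ignore_attr = TRUE)
  back_sets <- read_gmt(file.path(dir1, "gene_sets.gmt"))
  expect_equal(back_sets$sets, sim$genome$collection$sets)
  cfg_back <- read_sim_config(file.path(dir1, "sim_config.yaml"))
  expect_equal(unclass(cfg_back), unclass(cfg), tolerance = 1e-12)
})
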