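# Call- and sample-level QC chain.

test_that("size filter is strict and probe filter honours per-cohort thresholds", {
  calls <- cnv_calls(
    sample_id = c("S1", "S2", "S3", "S4", "S5"),
    cohort = c("POPGEN", "POPGEN", "SHIP2", "POPGEN", "SHIP2"),
    chrom = "chr1",
    start = c(0, 1e6, 2e6, 3e6, 4e6),
    end = c(100000, 1e6 + 1045905, 2e6 + 2e5, 3e6 + 100001, 4e6 + 2e5),
    type = "gain", n_probes = c(200L, 200L, 80L, 49L, 100L))
  sized <- filter_size(calls, 100000)
  # exactly 100 kb removed (strict >), the 1,045,905 bp call retained
  expect_equal(sized$sample_id, c("S2", "S3", "S4", "S5"))
  expect_equal(filter_size(calls[0, ], 1e5), calls[0, ])

  cfg <- qc_config(min_probes = c(SHIP2 = 100L, default = 50L))
  probed <- filter_probes(calls, cfg)
  # 49 < 50 default removed; SHIP2 call with 80 probes removed at its
  # cohort-specific 100-probe threshold; 100 retained ("at least")
  expect_equal(probed$sample_id, c("S1", "S2", "S5"))
  expect_equal(filter_probes(cnv_calls("S", "X", "chr1", 0, 2e5, "gain", 50L),
                             qc_config())$sample_id, "S")
})

test_that("blacklist filter removes 1 bp overlaps but not half-open abutment", {
  calls <- cnv_calls(c("S1", "S2"), "X", "chr1", c(100, 100), c(200, 200),
                     "gain", 50L)
  bl1 <- gene_models("b", "chr1", 199, 300)
  expect_equal(nrow(filter_blacklist(calls[1, ], bl1)), 0L)
  bl2 <- gene_models("b", "chr1", 200, 300)
  expect_equal(nrow(filter_blacklist(calls[1, ], bl2)), 1L)
  expect_equal(filter_blacklist(calls, NULL), calls)
})

test_that("outlier exclusion uses single-pass population SD, upper tail only", {
  # counts [0,0,0,0,20]: mean 4, population SD 8 -> 20 <= 4 + 3*8, none excluded
  samples <- sample_records(sprintf("S%d", 1:5), "C", rep("control", 5),
                            rep("female", 5), 50, 25)
  calls <- cnv_calls(rep("S5", 20), "C", "chr1",
                     start = (0:19) * 1e6, end = (0:19) * 1e6 + 2e5,
                     type = "gain", n_probes = 60L)
  res <- exclude_outlier_samples(calls, samples, 3)
  expect_equal(nrow(res$excluded), 0L)
  expect_equal(nrow(res$samples), 5L)

  # all-equal counts: SD 0, equal counts never above mean -> none excluded
  calls_eq <- cnv_calls(sprintf("S%d", 1:5), "C", "chr1", 0, 2e5, "gain", 60L)
  expect_equal(nrow(exclude_outlier_samples(calls_eq, samples, 3)$excluded), 0L)

  # a cohort with <2 samples is skipped with a warning
  expect_warning(
    exclude_outlier_samples(calls_eq[1, ], samples[1, , drop = FALSE], 3),
    "<2 samples")
})

test_that("an injected extreme sample is excluded from a simulated cohort", {
  withr::with_seed(99, {
    n <- 500
    samples <- sample_records(sprintf("S%03d", 1:n), "SIM", "control",
                              "female", 50, 25)
    counts <- rpois(n, 0.5)
    counts[123] <- 50L  # 100x the mean rate
    calls <- cnv_calls(rep(samples$sample_id, counts), "SIM", "chr1",
                       start = seq_len(sum(counts)) * 1e6,
                       end = seq_len(sum(counts)) * 1e6 + 2e5,
                       type = "gain", n_probes = 60L)
    res <- exclude_outlier_samples(calls, samples, 3)
    # oracle: direct threshold check on the count vector
    m <- mean(counts); s <- sqrt(mean((counts - m)^2))
    expect_equal(sort(res$excluded$sample_id),
                 sort(samples$sample_id[counts > m + 3 * s]))
    expect_true("S123" %in% res$excluded$sample_id)
  })
})

test_that("rarity filter clusters by reciprocal overlap and removes common regions", {
  samples <- sample_records(sprintf("S%03d", 1:100), "C", rep("control", 100),
                            "female", 50, 25)
  # two identical calls in a 100-sample cohort: frequency 0.02 > 0.01
  calls <- cnv_calls(c("S001", "S002"), "C", "chr1", 0, 2e5, "gain", 60L)
  res <- filter_rare(calls, samples, qc_config())
  expect_equal(nrow(res$calls), 0L)
  expect_true(all(res$regions$removed))
  expect_equal(res$regions$n_carriers, 2L)

  # boundary of the reciprocal-overlap rule: [0,100k) vs [50k,150k) -> RO 0.5
  calls2 <- cnv_calls(c("S001", "S002"), "C", "chr1", c(0, 50000),
                      c(100000, 150000), "gain", 60L)
  res2 <- filter_rare(calls2, samples, qc_config())
  expect_equal(nrow(res2$regions), 1L)  # single-linkage merges at RO >= 0.5

  # same intervals, different type: never merged across gain/loss
  calls3 <- cnv_calls(c("S001", "S002"), "C", "chr1", c(0, 50000),
                      c(100000, 150000), c("gain", "loss"), 60L)
  expect_equal(nrow(filter_rare(calls3, samples, qc_config())$regions), 2L)
})

test_that("a singleton in a 1957-sample cohort is retained and flagged", {
  samples <- sample_records(sprintf("S%04d", 1:1957), "POPGEN",
                            rep(c("case", "control"), c(1052, 905)),
                            "female", 50, 25)
  calls <- cnv_calls("S0001", "POPGEN", "chr1", 0, 2e5, "gain", 60L)
  res <- filter_rare(calls, samples, qc_config())
  expect_equal(nrow(res$calls), 1L)
  expect_true(res$regions$singleton)
  expect_equal(res$regions$frequency, 1 / 1957)
})

test_that("the full chain reproduces hand-computed stage counts and is idempotent", {
  fx <- tiny_fixture()
  qc <- apply_qc(fx$calls, fx$samples, fx$config)
  expect_equal(qc$report$stages$stage,
               c("input", "size", "probes", "blacklist", "outlier_samples",
                 "rarity"))
  expect_equal(qc$report$stages$n_calls, c(24L, 23L, 22L, 21L, 11L, 7L))
  expect_equal(qc$report$excluded_samples$sample_id, "S20")
  expect_equal(sort(qc$calls$sample_id),
               sort(c("S01", "S02", "S03", "S06", "S11", "S12", "S13")))
  # stage counts never increase
  expect_true(all(diff(qc$report$stages$n_calls) <= 0))
  # idempotence: re-applying the chain changes nothing
  qc2 <- apply_qc(qc$calls, qc$samples, fx$config)
  expect_equal(qc2$calls, qc$calls, ignore_attr = TRUE)
  expect_equal(qc2$samples, qc$samples, ignore_attr = TRUE)
})

test_that("the chain is the identity on QC-clean synthetic calls", {
  cfg <- sim_config("tiny", seed = 3)
  sim <- simulate_study(cfg)
  # the 1% rarity rule is meaningless in a 6-sample cohort (any carrier is
  # above it); use a region-frequency cap compatible with the cohort size
  qc <- apply_qc(sim$calls, sim$samples,
                 qc_config(blacklist = sim$genome$blacklist,
                           max_frequency = 0.5))
  # all generated calls exceed 100 kb, pass probes, avoid the blacklist and
  # no region or sample trips the rarity/outlier rules at this seed
  expect_equal(qc$calls, sim$calls, ignore_attr = TRUE)
  expect_equal(nrow(qc$samples), nrow(sim$samples))
})
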