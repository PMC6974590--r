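# Hand-written fixtures and independent oracles shared across test files.

# A fully hand-enumerable single-cohort study.  Every QC fate, carrier count
# and candidate-gene stage below is worked out by hand:
#
# Genes on chr1 (50 kb each):
#   A [1.00-1.05 Mb]  lipid + small_intestine
#   B [2.00-2.05 Mb]  small_intestine
#   C [3.00-3.05 Mb]  lipid
#   D [4.00-4.05 Mb]  lipid + small_intestine
#   E [5.00-5.05 Mb]  small_intestine
# Blacklist: chr1 [8.0-8.1 Mb].
# Samples: cases S01-S10 (S01-S05 female), controls S11-S20 (S11-S15 female).
# Calls (fates after the chain size > 100 kb, probes >= 50, blacklist,
# outlier 3 SD, region frequency > 0.15 removed):
#   S01 [0.990-1.140 Mb] gain 80  -> kept, hits A
#   S02 [0.995-1.145 Mb] gain 80  -> kept, hits A (same region as S01's)
#   S03 [2.990-3.100 Mb] loss 60  -> kept, hits C
#   S06 [3.995-4.100 Mb] gain 70  -> kept, hits D
#   S11 [4.990-5.100 Mb] gain 55  -> kept, hits E
#   S12 [6.000-6.200 Mb] gain 90  -> kept, hits no gene
#   S13 [3.990-4.095 Mb] gain 70  -> kept, hits D (control carrier)
#   S04 [0.100-0.200 Mb] gain 99  -> removed: size exactly 100 kb (strict >)
#   S05 [6.500-6.800 Mb] gain 49  -> removed: probes < 50
#   S07 [7.800-8.000001 Mb] gain 60 -> removed: 1 bp blacklist overlap
#   S16-S19 identical [9.000-9.150 Mb] loss 80 -> removed: region frequency
#       4/19 > 0.15 (cohort size after outlier exclusion)
#   S20 10 calls on chr2 -> S20 excluded as CNV outlier (10 > mean + 3 SD)
#
# Stage counts: input 24 -> size 23 -> probes 22 -> blacklist 21 ->
# outlier_samples 11 -> rarity 7.
tiny_fixture <- function() {
  genes <- gene_models(
    gene_id = c("A", "B", "C", "D", "E"),
    chrom = "chr1",
    start = c(1.00e6, 2.00e6, 3.00e6, 4.00e6, 5.00e6),
    end   = c(1.05e6, 2.05e6, 3.05e6, 4.05e6, 5.05e6))
  collection <- gene_set_collection(
    list(lipid = c("A", "C", "D"),
         small_intestine = c("A", "B", "D", "E")),
    c(lipid = "toy lipid set", small_intestine = "toy tissue set"))
  blacklist <- gene_models("bl1", "chr1", 8.0e6, 8.1e6)
  ids <- sprintf("S%02d", 1:20)
  samples <- sample_records(
    sample_id = ids, cohort = "TOY",
    status = rep(c("case", "control"), each = 10),
    sex = rep(rep(c("female", "male"), each = 5), 2),
    age = seq(40, 59, by = 1), bmi = seq(24, 33.5, by = 0.5))
  call_row <- function(s, start, end, type, probes)
    list(s = s, start = start, end = end, type = type, probes = probes)
  rows <- c(list(
    call_row("S01", 0.990e6, 1.140e6, "gain", 80L),
    call_row("S02", 0.995e6, 1.145e6, "gain", 80L),
    call_row("S03", 2.990e6, 3.100e6, "loss", 60L),
    call_row("S06", 3.995e6, 4.100e6, "gain", 70L),
    call_row("S11", 4.990e6, 5.100e6, "gain", 55L),
    call_row("S12", 6.000e6, 6.200e6, "gain", 90L),
    call_row("S13", 3.990e6, 4.095e6, "gain", 70L),
    call_row("S04", 0.100e6, 0.200e6, "gain", 99L),
    call_row("S05", 6.500e6, 6.800e6, "gain", 49L),
    call_row("S07", 7.800e6, 8.000001e6, "gain", 60L)),
    lapply(1:4, function(i)
      call_row(sprintf("S%02d", 15 + i), 9.000e6, 9.150e6, "loss", 80L)),
    lapply(1:10, function(i)
      call_row("S20", 3e5 * i, 3e5 * i + 1.2e5, if (i %% 2) "gain" else "loss",
               60L)))
  rows <- lapply(rows, as.data.frame)
  df <- do.call(rbind, rows)
  calls <- cnv_calls(sample_id = df$s, cohort = "TOY",
                     chrom = rep(c("chr1", "chr2"), c(14, 10)),
                     start = df$start, end = df$end, type = df$type,
                     n_probes = df$probes, source = "fixture")
  config <- qc_config(max_frequency = 0.15, blacklist = blacklist)
  list(genes = genes, collection = collection, blacklist = blacklist,
       samples = samples, calls = calls, config = config)
}

# Random but valid call tables for round-trip properties.
make_random_calls <- function(n, seed) {
  withr::with_seed(seed, {
    start <- sort(sample.int(5e7, n))
    size <- sample(100001:3000000, n, replace = TRUE)
    cnv_calls(
      sample_id = sprintf("S%03d", sample.int(30, n, replace = TRUE)),
      cohort = sample(c("POPGEN", "SHIP2"), n, replace = TRUE),
      chrom = sample(paste0("chr", 1:4), n, replace = TRUE),
      start = start, end = start + size,
      type = sample(c("gain", "loss"), n, replace = TRUE),
      n_probes = sample.int(500, n, replace = TRUE),
      source = "random")
  })
}

# Independent O(n) brute-force interval overlap (0-based half-open).
overlap_scan <- function(genes, chrom, start, end) {
  hit <- genes$chrom == chrom & genes$start < end & genes$end > start
  sort(genes$gene_id[hit])
}

# Independent upper-tail hypergeometric oracle from binomial coefficients.
hyper_upper_oracle <- function(k, K, n, N) {
  kk <- seq(k, min(K, n))
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

annotate_fixture <- function(fx = tiny_fixture()) {
  qc <- apply_qc(fx$calls, fx$samples, fx$config)
  ann <- annotate_calls(qc$calls, build_gene_index(fx$genes), fx$collection)
  list(fx = fx, qc = qc, ann = ann)
}
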