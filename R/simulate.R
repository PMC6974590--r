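# Fully synthetic multi-cohort CNV studies with the statistical structure the
# burden analysis assumes: per-cohort covariate marginals and per-sample call
# rates, a ~3:1 gain:loss mix, 100 kb - 3 Mb call sizes, mostly-singleton
# calls, and an injectable sex-specific carrier-enrichment effect over a
# designated gene set.

AGE_BOUNDS <- c(18, 95)   # years; plausibility truncation for drawn ages
BMI_BOUNDS <- c(15, 60)   # kg/m^2

#' Simulation configuration
#'
#' Builds the full parameter block for [simulate_study()].  The
#' `"paper_like"` preset mirrors a three-cohort array CNV study: two European
#' population cohorts (the second on a higher-density platform, hence a
#' 100-probe threshold) and one Latin American cohort strongly enriched for
#' women; sample sizes, sex/age/BMI marginals and per-sample call rates
#' follow the motivating study design, with per-cohort rates kept as exact
#' call-count/sample-count ratios so expected totals reproduce the printed
#' counts.  The `"tiny"` preset is a 6-sample single-cohort toy for smoke
#' tests.
#'
#' @param preset `"paper_like"` or `"tiny"`.
#' @param seed integer seed; the whole simulated study is a pure function of
#'   the configuration including this seed.
#' @param overrides named list merged (recursively) over the preset, e.g.
#'   `list(effect = list(target_or = 2.76))`.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(preset = c("paper_like", "tiny"), seed = 1L,
                       overrides = list()) {
  preset <- match.arg(preset)
  cfg <- if (preset == "paper_like") {
    list(
      seed = as.integer(seed),
      genome = list(n_chromosomes = 8L, chrom_length = 6e7, n_genes = 2000L,
                    gene_length = 2e4, n_blacklist = 2L,
                    blacklist_length = 5e4),
      gene_sets = list(
        sizes = c(lipid = 156L, inflammatory = 61L, insulin = 29L,
                  glucose = 22L, gallbladder = 379L, liver = 326L,
                  small_intestine = 382L, random = 470L),
        lipid_si_overlap = 37L),
      cohorts = list(
        list(name = "POPGEN", n_cases = 1052L, n_controls = 905L,
             frac_women_cases = 0.615, frac_women_controls = 0.422,
             age_case = c(45.7, 12.3), age_control = c(59.3, 12.8),
             bmi_case = c(27.6, 5.3), bmi_control = c(26.5, 4.1),
             cnv_rate = 821 / 1957, min_probes = 50L),
        list(name = "SHIP2", n_cases = 355L, n_controls = 1390L,
             frac_women_cases = 0.645, frac_women_controls = 0.491,
             age_case = c(48.4, 9.8), age_control = c(47.8, 12.1),
             bmi_case = c(28.6, 5.0), bmi_control = c(26.7, 4.2),
             cnv_rate = 1168 / 1745, min_probes = 100L),
        list(name = "ANCORA", n_cases = 522L, n_controls = 554L,
             frac_women_cases = 0.923, frac_women_controls = 0.924,
             age_case = c(51.3, 10.7), age_control = c(49.8, 9.6),
             bmi_case = c(29.4, 4.3), bmi_control = c(28.6, 3.9),
             cnv_rate = 947 / 1076, min_probes = 50L)),
      calls = list(gain_fraction = 0.742, size_range = c(100001, 3e6),
                   probe_density = 5e-4, probe_fail_fraction = 0),
      effect = NULL,
      calibration_draws = 200000L
    )
  } else {
    list(
      seed = as.integer(seed),
      genome = list(n_chromosomes = 1L, chrom_length = 1e7, n_genes = 3L,
                    gene_length = 2e4, n_blacklist = 1L,
                    blacklist_length = 5e4),
      gene_sets = list(sizes = c(lipid = 2L, small_intestine = 2L),
                       lipid_si_overlap = 1L),
      cohorts = list(
        list(name = "TOY", n_cases = 3L, n_controls = 3L,
             frac_women_cases = 0.5, frac_women_controls = 0.5,
             age_case = c(50, 10), age_control = c(50, 10),
             bmi_case = c(27, 4), bmi_control = c(27, 4),
             cnv_rate = 1.0, min_probes = 50L)),
      calls = list(gain_fraction = 0.742, size_range = c(100001, 1e6),
                   probe_density = 5e-4, probe_fail_fraction = 0),
      effect = NULL,
      calibration_draws = 50000L
    )
  }
  cfg <- utils::modifyList(cfg, overrides)
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  g <- cfg$genome
  stopifnot(g$n_chromosomes >= 1, g$chrom_length > 0, g$n_genes >= 1,
            g$gene_length > 0, g$n_blacklist >= 0, g$blacklist_length > 0)
  if (cfg$calls$size_range[1] < 1 ||
      cfg$calls$size_range[2] > g$chrom_length ||
      cfg$calls$size_range[1] >= cfg$calls$size_range[2])
    stop("call size_range must lie within [1, chromosome length]")
  stopifnot(cfg$calls$gain_fraction >= 0, cfg$calls$gain_fraction <= 1,
            cfg$calls$probe_fail_fraction >= 0,
            cfg$calls$probe_fail_fraction < 1)
  for (co in cfg$cohorts) {
    stopifnot(co$n_cases >= 0, co$n_controls >= 0,
              co$frac_women_cases >= 0, co$frac_women_cases <= 1,
              co$frac_women_controls >= 0, co$frac_women_controls <= 1,
              co$cnv_rate >= 0, co$min_probes >= 1)
  }
  if (!is.null(cfg$effect)) {
    e <- cfg$effect
    if (is.null(e$target_or) || e$target_or <= 0)
      stop("effect$target_or must be positive")
    e$set <- if (is.null(e$set)) "lipid" else e$set
    e$sex <- if (is.null(e$sex)) "male" else e$sex
    e$status <- if (is.null(e$status)) "case" else e$status
    cfg$effect <- e
  }
  structure(cfg, class = "sim_config")
}

#' Simulate a synthetic genome: genes, gene sets and blacklist
#'
#' Genes are tiled into equal slots per chromosome with random offsets, so
#' they never overlap; gene sets are sampled at the configured sizes, with
#' the lipid and small-intestine sets sharing a configured number of genes;
#' blacklist regions are placed in gene-free gaps.  Deterministic given the
#' configuration seed.
#'
#' @param config a [sim_config()].
#' @param seed RNG seed; defaults to a sub-seed derived from `config$seed`.
#' @return a list of class `sim_genome`: `genes` ([gene_models()]),
#'   `collection` ([gene_set_collection()]), `blacklist`, `chrom_lengths`.
#' @export
simulate_genome <- function(config, seed = NULL) {
  g <- config$genome
  if (is.null(seed)) seed <- derive_subseeds(config$seed, 1L)[1]
  with_local_seed(seed, {
    chroms <- paste0("chr", seq_len(g$n_chromosomes))
    chrom_lengths <- setNames(rep(g$chrom_length, g$n_chromosomes), chroms)
    per_chrom <- diff(round(seq(0, g$n_genes, length.out = g$n_chromosomes + 1)))
    gene_rows <- list()
    gid <- 0L
    for (ci in seq_along(chroms)) {
      k <- per_chrom[ci]
      if (k == 0L) next
      slot_w <- floor(g$chrom_length / k)
      if (slot_w < g$gene_length)
        stopf("%d genes of %d bp do not fit chromosome of %d bp",
              k, as.integer(g$gene_length), as.integer(g$chrom_length))
      offs <- floor(runif(k) * (slot_w - g$gene_length + 1))
      starts <- (seq_len(k) - 1) * slot_w + offs
      gene_rows[[ci]] <- data.frame(
        gene_id = sprintf("g%04d", gid + seq_len(k)), chrom = chroms[ci],
        start = starts, end = starts + g$gene_length,
        stringsAsFactors = FALSE)
      gid <- gid + k
    }
    genes <- do.call(rbind, gene_rows)
    rownames(genes) <- NULL

    sizes <- config$gene_sets$sizes
    if (any(sizes > nrow(genes)))
      stop("a gene-set size exceeds the number of genes")
    all_ids <- genes$gene_id
    sets <- list()
    if (all(c("lipid", "small_intestine") %in% names(sizes)) &&
        !is.null(config$gene_sets$lipid_si_overlap)) {
      ov <- config$gene_sets$lipid_si_overlap
      lipid <- sample(all_ids, sizes[["lipid"]])
      si <- c(sample(lipid, ov),
              sample(setdiff(all_ids, lipid), sizes[["small_intestine"]] - ov))
      sets$lipid <- sort(lipid)
      sets$small_intestine <- sort(si)
    }
    for (nm in setdiff(names(sizes), names(sets)))
      sets[[nm]] <- sort(sample(all_ids, sizes[[nm]]))
    sets <- sets[names(sizes)]
    prov <- setNames(sprintf("synthetic set (%d genes)", sizes), names(sizes))

    blacklist <- NULL
    if (g$n_blacklist > 0L) {
      bl_rows <- list()
      for (bi in seq_len(g$n_blacklist)) {
        ci <- ((bi - 1L) %% g$n_chromosomes) + 1L
        on_chrom <- genes[genes$chrom == chroms[ci], , drop = FALSE]
        gap_starts <- c(0, on_chrom$end)
        gap_ends <- c(on_chrom$start, g$chrom_length)
        ok <- which(gap_ends - gap_starts >= g$blacklist_length)
        if (!length(ok)) stop("no gene-free gap large enough for blacklist")
        pick <- sample(ok, 1L)
        s <- gap_starts[pick] +
          floor(runif(1) * (gap_ends[pick] - gap_starts[pick] -
                              g$blacklist_length + 1))
        bl_rows[[bi]] <- data.frame(gene_id = sprintf("blacklist_%d", bi),
                                    chrom = chroms[ci], start = s,
                                    end = s + g$blacklist_length,
                                    stringsAsFactors = FALSE)
      }
      blacklist <- do.call(rbind, bl_rows)
    }
    structure(list(genes = genes,
                   collection = gene_set_collection(sets, prov),
                   blacklist = blacklist, chrom_lengths = chrom_lengths),
              class = "sim_genome")
  })
}

# Vectorized background-call sampler shared by the cohort simulator and the
# carrier-baseline calibration, so the calibrated baseline refers to exactly
# the distribution the cohorts draw from.
draw_background_calls <- function(n, genome, calls_cfg, min_probes) {
  if (n == 0L)
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      type = character(), n_probes = integer(),
                      stringsAsFactors = FALSE))
  sr <- calls_cfg$size_range
  size <- round(exp(runif(n, log(sr[1]), log(sr[2]))))
  chrom <- sample(names(genome$chrom_lengths), n, replace = TRUE)
  len <- genome$chrom_lengths[chrom]
  start <- floor(runif(n) * (len - size + 1))
  type <- ifelse(runif(n) < calls_cfg$gain_fraction, "gain", "loss")
  fail <- runif(n) < calls_cfg$probe_fail_fraction
  n_probes <- min_probes + rpois(n, size * calls_cfg$probe_density)
  if (any(fail))
    n_probes[fail] <- 1L + floor(runif(sum(fail)) * (min_probes - 1L))
  data.frame(chrom = chrom, start = start, end = start + size, type = type,
             n_probes = as.integer(n_probes), stringsAsFactors = FALSE)
}

# Does each call survive the call-level QC predicate (size, probes,
# blacklist)?  Rarity is ignored here: under the mostly-singleton regimes
# simulated, its effect on the carrier baseline is negligible.
qc_predicate <- function(calls_df, genome, min_probes, min_size = 100000L) {
  ok <- (calls_df$end - calls_df$start) > min_size &
    calls_df$n_probes >= min_probes
  if (!is.null(genome$blacklist) && nrow(calls_df)) {
    hits <- find_overlaps0(
      as_granges0(calls_df$chrom, calls_df$start, calls_df$end),
      as_granges0(genome$blacklist$chrom, genome$blacklist$start,
                  genome$blacklist$end))
    ok[unique(S4Vectors::queryHits(hits))] <- FALSE
  }
  ok
}

hits_set <- function(calls_df, genome, set_genes) {
  sel <- genome$genes[genome$genes$gene_id %in% set_genes, , drop = FALSE]
  out <- logical(nrow(calls_df))
  if (!nrow(calls_df) || !nrow(sel)) return(out)
  hits <- find_overlaps0(
    as_granges0(calls_df$chrom, calls_df$start, calls_df$end),
    as_granges0(sel$chrom, sel$start, sel$end))
  out[unique(S4Vectors::queryHits(hits))] <- TRUE
  out
}

#' Calibrate the per-cohort baseline carrier probability for a gene set
#'
#' Monte-Carlo estimate (using the same call sampler as the cohort
#' simulator) of the probability that one background call survives call-level
#' QC and overlaps the target set, converted to the per-sample carrier
#' probability `q = 1 - exp(-rate * pi)` under the Poisson call-count model.
#' This `q` is the baseline against which the injected carrier odds ratio is
#' defined.
#'
#' @param config a [sim_config()] with a non-`NULL` `effect` block (or a
#'   `set` override).
#' @param genome a [simulate_genome()] result.
#' @param set name of the gene set (default: the effect's set).
#' @param seed RNG seed; defaults to a sub-seed derived from `config$seed`.
#' @return a data frame per cohort: `cohort`, `pi` (per-call qualifying
#'   probability), `q` (per-sample baseline carrier probability).
#' @export
carrier_baseline <- function(config, genome, set = NULL, seed = NULL) {
  if (is.null(set)) set <- config$effect$set
  if (is.null(set)) stop("no gene set given and no effect block in config")
  set_genes <- genome$collection$sets[[set]]
  if (is.null(set_genes)) stopf("genome has no gene set '%s'", set)
  if (is.null(seed)) seed <- derive_subseeds(config$seed, 2L)[2]
  with_local_seed(seed, {
    do.call(rbind, lapply(config$cohorts, function(co) {
      draws <- draw_background_calls(config$calibration_draws, genome,
                                     config$calls, co$min_probes)
      qual <- qc_predicate(draws, genome, co$min_probes) &
        hits_set(draws, genome, set_genes)
      pi_hat <- mean(qual)
      data.frame(cohort = co$name, pi = pi_hat,
                 q = 1 - exp(-co$cnv_rate * pi_hat),
                 stringsAsFactors = FALSE)
    }))
  })
}

# Injection probability r solving for the target carrier odds ratio:
# p1 = OR q / (1 - q + OR q) and a sample already carrying with background
# probability q becomes a carrier with probability q + (1-q) r.
injection_prob <- function(target_or, q) {
  p1 <- target_or * q / (1 - q + target_or * q)
  r <- (p1 - q) / (1 - q)
  if (r < 0)
    stopf(paste0("target carrier odds ratio %.3g is below the feasible ",
                 "minimum 1: additive injection cannot remove background ",
                 "carriers"), target_or)
  r
}

#' Simulate one cohort: phenotypes and CNV calls
#'
#' Sex counts are assigned deterministically (rounded group fractions, then
#' shuffled) so cohort composition is exact; ages and BMIs are truncated
#' normals at plausibility bounds (18-95 years, 15-60 kg/m^2); per-sample
#' call counts are Poisson at the cohort rate; calls get a Bernoulli
#' gain/loss type, log-uniform sizes and uniform positions.  If the
#' configuration carries an effect block, samples in the targeted
#' sex-by-status stratum receive one extra call overlapping a random gene of
#' the affected set with the probability that produces the target carrier
#' odds ratio against the calibrated baseline; injected calls always pass
#' the probe filter so the injected odds ratio is the post-QC estimand.
#'
#' @param config a [sim_config()].
#' @param genome a [simulate_genome()] result.
#' @param cohort cohort name (defaults to the first configured cohort).
#' @param seed RNG seed; defaults to the cohort's derived sub-seed.
#' @param baseline optional [carrier_baseline()] result (computed on demand
#'   when an effect is configured).
#' @return a list with `samples` ([sample_records()]) and `calls`
#'   ([cnv_calls()]; injected calls carry `source = "injected"`).
#' @export
simulate_cohort <- function(config, genome, cohort = NULL, seed = NULL,
                            baseline = NULL) {
  cohort_names <- vapply(config$cohorts, `[[`, "", "name")
  if (is.null(cohort)) cohort <- cohort_names[1]
  ci <- match(cohort, cohort_names)
  if (is.na(ci)) stopf("no cohort '%s' in configuration", cohort)
  co <- config$cohorts[[ci]]
  if (is.null(seed)) seed <- derive_subseeds(config$seed, 2L + ci)[2L + ci]
  if (!is.null(config$effect) && is.null(baseline))
    baseline <- carrier_baseline(config, genome)
  with_local_seed(seed, {
    n <- co$n_cases + co$n_controls
    status <- rep(c("case", "control"), c(co$n_cases, co$n_controls))
    sex <- character(n)
    nw_case <- round(co$frac_women_cases * co$n_cases)
    nw_ctrl <- round(co$frac_women_controls * co$n_controls)
    sex[status == "case"] <- sample(rep(c("female", "male"),
                                        c(nw_case, co$n_cases - nw_case)))
    sex[status == "control"] <- sample(rep(c("female", "male"),
                                           c(nw_ctrl, co$n_controls - nw_ctrl)))
    age <- numeric(n); bmi <- numeric(n)
    for (grp in c("case", "control")) {
      mu_a <- co[[paste0("age_", grp)]]; mu_b <- co[[paste0("bmi_", grp)]]
      sel <- status == grp
      if (any(sel)) {
        age[sel] <- rnorm_trunc(sum(sel), mu_a[1], mu_a[2],
                                AGE_BOUNDS[1], AGE_BOUNDS[2])
        bmi[sel] <- rnorm_trunc(sum(sel), mu_b[1], mu_b[2],
                                BMI_BOUNDS[1], BMI_BOUNDS[2])
      }
    }
    samples <- sample_records(
      sample_id = sprintf("%s_%05d", co$name, seq_len(n)), cohort = co$name,
      status = status, sex = sex, age = round(age, 1), bmi = round(bmi, 1),
      t2d = "unknown")

    counts <- rpois(n, co$cnv_rate)
    bg <- draw_background_calls(sum(counts), genome, config$calls,
                                co$min_probes)
    calls <- cnv_calls(
      sample_id = rep(samples$sample_id, counts), cohort = co$name,
      chrom = bg$chrom, start = bg$start, end = bg$end, type = bg$type,
      n_probes = bg$n_probes, source = "background")

    if (!is.null(config$effect)) {
      e <- config$effect
      q <- baseline$q[match(co$name, baseline$cohort)]
      r <- injection_prob(e$target_or, q)
      eligible <- which(samples$sex == e$sex & samples$status == e$status)
      hit <- eligible[runif(length(eligible)) < r]
      if (length(hit)) {
        set_genes <- genome$collection$sets[[e$set]]
        gsel <- genome$genes[match(sample(set_genes, length(hit),
                                          replace = TRUE),
                                   genome$genes$gene_id), , drop = FALSE]
        sr <- config$calls$size_range
        size <- round(exp(runif(length(hit), log(sr[1]), log(sr[2]))))
        chrlen <- genome$chrom_lengths[gsel$chrom]
        lo <- pmax(0, gsel$start - size + 1)
        hi <- pmin(gsel$end - 1, chrlen - size)
        start <- lo + floor(runif(length(hit)) * (hi - lo + 1))
        inj <- cnv_calls(
          sample_id = samples$sample_id[hit], cohort = co$name,
          chrom = gsel$chrom, start = start, end = start + size,
          type = ifelse(runif(length(hit)) < config$calls$gain_fraction,
                        "gain", "loss"),
          n_probes = co$min_probes +
            rpois(length(hit), size * config$calls$probe_density),
          source = "injected")
        calls <- rbind(calls, inj)
      }
    }
    list(samples = samples, calls = calls)
  })
}

#' Simulate a full multi-cohort study
#'
#' Derives one sub-seed per component from `config$seed` (genome first, then
#' the carrier-baseline calibration, then each cohort in configuration
#' order), so the entire study is a pure function of the configuration.
#'
#' @param config a [sim_config()].
#' @param genome optionally, a pre-built [simulate_genome()] (reused across
#'   replicate studies that share a reference genome).
#' @param baseline optionally, a pre-computed [carrier_baseline()].
#' @return a list of class `sim_study`: `genome`, `samples`, `calls`,
#'   `baseline` (or `NULL`), `config`.
#' @export
simulate_study <- function(config, genome = NULL, baseline = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(genome)) genome <- simulate_genome(config)
  if (!is.null(config$effect) && is.null(baseline))
    baseline <- carrier_baseline(config, genome)
  pieces <- lapply(vapply(config$cohorts, `[[`, "", "name"),
                   function(nm) simulate_cohort(config, genome, nm,
                                                baseline = baseline))
  structure(list(
    genome = genome,
    samples = do.call(rbind, lapply(pieces, `[[`, "samples")),
    calls = do.call(rbind, lapply(pieces, `[[`, "calls")),
    baseline = baseline, config = config), class = "sim_study")
}

#' Expected (arithmetic) cohort summaries implied by a configuration
#'
#' The deterministic arithmetic layer over the configured marginals: totals,
#' expected CNV counts (`round(n * rate)`), per-sample rates as displayed
#' (two decimals), and the exact sex composition produced by the
#' deterministic sex assignment.
#'
#' @param config a [sim_config()].
#' @return a data frame, one row per cohort plus a `TOTAL` row.
#' @export
expected_cohort_stats <- function(config) {
  rows <- do.call(rbind, lapply(config$cohorts, function(co) {
    n <- co$n_cases + co$n_controls
    data.frame(
      cohort = co$name, n_cases = co$n_cases, n_controls = co$n_controls,
      n_total = n,
      male_cases = co$n_cases - round(co$frac_women_cases * co$n_cases),
      male_controls = co$n_controls -
        round(co$frac_women_controls * co$n_controls),
      cnvs_per_sample = round(co$cnv_rate, 2),
      expected_cnvs = round(n * co$cnv_rate), stringsAsFactors = FALSE)
  }))
  total <- data.frame(cohort = "TOTAL", n_cases = sum(rows$n_cases),
                      n_controls = sum(rows$n_controls),
                      n_total = sum(rows$n_total),
                      male_cases = sum(rows$male_cases),
                      male_controls = sum(rows$male_controls),
                      cnvs_per_sample = round(sum(rows$expected_cnvs) /
                                                sum(rows$n_total), 2),
                      expected_cnvs = sum(rows$expected_cnvs),
                      stringsAsFactors = FALSE)
  rbind(rows, total)
}

#' Write a complete fixture bundle to disk
#'
#' Simulates a study and writes every artefact the pipeline reads: call TSV
#' and VCF, phenotype TSV, gene BED, gene-set GMT, blacklist BED and the
#' configuration as YAML.  Re-running with the same configuration reproduces
#' identical file contents.
#'
#' @param config a [sim_config()].
#' @param outdir output directory (created if needed).
#' @return invisibly, a named list of file paths plus the simulated study.
#' @export
write_fixture_bundle <- function(config, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_study(config)
  paths <- list(
    calls_tsv = file.path(outdir, "calls.tsv"),
    calls_vcf = file.path(outdir, "calls.vcf"),
    phenotypes = file.path(outdir, "phenotypes.tsv"),
    genes = file.path(outdir, "genes.bed"),
    gene_sets = file.path(outdir, "gene_sets.gmt"),
    blacklist = file.path(outdir, "blacklist.bed"),
    config = file.path(outdir, "sim_config.yaml"))
  write_cnv_tsv(sim$calls, paths$calls_tsv)
  write_cnv_vcf(sim$calls, paths$calls_vcf)
  write_phenotypes(sim$samples, paths$phenotypes)
  write_bed(sim$genome$genes, paths$genes)
  write_gmt(sim$genome$collection, paths$gene_sets)
  if (!is.null(sim$genome$blacklist))
    write_bed(sim$genome$blacklist, paths$blacklist)
  cfg_plain <- unclass(config)
  cfg_plain$gene_sets$sizes <- as.list(cfg_plain$gene_sets$sizes)
  yaml::write_yaml(cfg_plain, paths$config)
  invisible(c(paths, list(study = sim)))
}

#' @rdname write_fixture_bundle
#' @param path a YAML file written by `write_fixture_bundle()`.
#' @export
read_sim_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$gene_sets$sizes <- unlist(cfg$gene_sets$sizes)
  cfg$calls$size_range <- as.numeric(unlist(cfg$calls$size_range))
  for (i in seq_along(cfg$cohorts))
    for (f in c("age_case", "age_control", "bmi_case", "bmi_control"))
      cfg$cohorts[[i]][[f]] <- as.numeric(unlist(cfg$cohorts[[i]][[f]]))
  validate_sim_config(cfg)
}
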