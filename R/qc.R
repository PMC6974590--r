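# Call-level and sample-level quality control for rare-CNV analyses.
# Canonical chain order: size -> probes -> blacklist -> outlier samples ->
# rarity.  Every stage is also exposed on its own.

#' Quality-control configuration
#'
#' @param min_size_bp minimum call size in bp; calls must be strictly larger
#'   than this (default 100 kb).
#' @param min_probes named integer vector of per-cohort minimum supporting
#'   probe counts; the `"default"` entry applies to cohorts not listed
#'   (default 50; high-density platforms conventionally use 100).
#' @param max_frequency maximum tolerated CNV-region carrier frequency within
#'   a cohort; regions strictly above it are removed (default 1%).
#' @param outlier_sd a sample whose call count exceeds the cohort mean by more
#'   than this many (population) standard deviations is excluded (default 3).
#' @param blacklist a [gene_models()]-like table of signal-artifact regions
#'   (0-based half-open); calls sharing at least 1 bp are removed.
#' @param reciprocal_overlap minimum mutual overlap fraction for two calls to
#'   be clustered into the same CNV region (default 0.5).
#' @return an object of class `qc_config`.
#' @export
qc_config <- function(min_size_bp = 100000L,
                      min_probes = c(default = 50L),
                      max_frequency = 0.01,
                      outlier_sd = 3.0,
                      blacklist = NULL,
                      reciprocal_overlap = 0.5) {
  stopifnot(min_size_bp > 0, max_frequency > 0, max_frequency <= 1,
            outlier_sd > 0, reciprocal_overlap > 0, reciprocal_overlap <= 1)
  if (is.null(names(min_probes))) names(min_probes) <- "default"
  if (!"default" %in% names(min_probes))
    min_probes <- c(min_probes, default = 50L)
  structure(list(min_size_bp = min_size_bp, min_probes = min_probes,
                 max_frequency = max_frequency, outlier_sd = outlier_sd,
                 blacklist = blacklist,
                 reciprocal_overlap = reciprocal_overlap),
            class = "qc_config")
}

probe_threshold <- function(config, cohort) {
  thr <- config$min_probes[cohort]
  thr[is.na(thr)] <- config$min_probes[["default"]]
  as.integer(thr)
}

#' Size filter: retain calls strictly larger than a bound
#'
#' "Larger than" is read literally: a call of exactly `min_size_bp` is
#' removed.
#'
#' @param calls a CNV call table.
#' @param min_size_bp size bound in bp.
#' @return the retained calls.
#' @export
filter_size <- function(calls, min_size_bp = 100000L) {
  calls[cnv_size(calls) > min_size_bp, , drop = FALSE]
}

#' Probe-count filter: retain calls with at least the cohort's threshold
#'
#' @param calls a CNV call table.
#' @param config a [qc_config()] carrying per-cohort probe thresholds.
#' @return the retained calls.
#' @export
filter_probes <- function(calls, config = qc_config()) {
  calls[calls$n_probes >= probe_threshold(config, calls$cohort), , drop = FALSE]
}

#' Blacklist filter: remove calls touching artifact regions
#'
#' Any shared base pair (>= 1 bp of overlap, any fraction) disqualifies a
#' call; half-open abutment does not.
#'
#' @param calls a CNV call table.
#' @param blacklist a table with `chrom`, `start`, `end` (0-based half-open),
#'   or `NULL` for no filtering.
#' @return the retained calls.
#' @export
filter_blacklist <- function(calls, blacklist = NULL) {
  if (is.null(blacklist) || nrow(blacklist) == 0L || nrow(calls) == 0L)
    return(calls)
  hits <- find_overlaps0(
    as_granges0(calls$chrom, calls$start, calls$end),
    as_granges0(blacklist$chrom, blacklist$start, blacklist$end))
  bad <- unique(S4Vectors::queryHits(hits))
  if (length(bad)) calls[-bad, , drop = FALSE] else calls
}

#' Exclude CNV-outlier samples
#'
#' Within each cohort, computes the mean and (population) standard deviation
#' of per-sample call counts in a single pass — samples with zero calls count
#' as zero — and excludes samples whose count is strictly greater than
#' `mean + outlier_sd * sd`, together with all their calls.  The exclusion is
#' one-sided and is not re-computed after removal.  Cohorts with fewer than
#' two samples are skipped with a warning.
#'
#' @param calls a CNV call table.
#' @param samples a phenotype table covering all samples of each cohort.
#' @param outlier_sd the exclusion threshold in standard deviations.
#' @return a list with elements `calls`, `samples` (both filtered) and
#'   `excluded` (a data frame with `cohort`, `sample_id`, `n_calls`,
#'   `threshold`).
#' @export
exclude_outlier_samples <- function(calls, samples, outlier_sd = 3.0) {
  key_s <- sample_key(samples$cohort, samples$sample_id)
  key_c <- sample_key(calls$cohort, calls$sample_id)
  counts <- as.integer(table(factor(key_c, levels = key_s)))
  excluded <- data.frame(cohort = character(), sample_id = character(),
                         n_calls = integer(), threshold = numeric(),
                         stringsAsFactors = FALSE)
  drop <- logical(length(key_s))
  for (co in unique(samples$cohort)) {
    in_co <- samples$cohort == co
    n <- sum(in_co)
    if (n < 2L) {
      warning(sprintf("cohort %s has <2 samples; outlier exclusion skipped", co))
      next
    }
    x <- counts[in_co]
    m <- mean(x)
    s <- sqrt(mean((x - m)^2))  # population SD, single pass
    thr <- m + outlier_sd * s
    out <- in_co & counts > thr
    if (any(out)) {
      excluded <- rbind(excluded, data.frame(
        cohort = co, sample_id = samples$sample_id[out],
        n_calls = counts[out], threshold = thr, stringsAsFactors = FALSE))
      drop <- drop | out
    }
  }
  keep_keys <- key_s[!drop]
  list(calls = calls[key_c %in% keep_keys, , drop = FALSE],
       samples = samples[!drop, , drop = FALSE],
       excluded = excluded)
}

# Cluster same-type calls of one cohort into CNV regions by single-linkage at
# a minimum reciprocal overlap.  Returns an integer region label per call.
cluster_regions <- function(calls, reciprocal_overlap = 0.5) {
  n <- nrow(calls)
  labels <- integer(n)
  next_id <- 0L
  for (grp in split(seq_len(n),
                    paste(calls$cohort, calls$type, calls$chrom, sep = "\r"))) {
    gr <- as_granges0(calls$chrom[grp], calls$start[grp], calls$end[grp])
    hits <- find_overlaps0(gr, gr)
    qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
    keep <- qi < si
    qi <- qi[keep]; si <- si[keep]
    if (length(qi)) {
      ov <- pmin(calls$end[grp][qi], calls$end[grp][si]) -
        pmax(calls$start[grp][qi], calls$start[grp][si])
      len_q <- calls$end[grp][qi] - calls$start[grp][qi]
      len_s <- calls$end[grp][si] - calls$start[grp][si]
      ro <- pmin(ov / len_q, ov / len_s)
      link <- ro >= reciprocal_overlap
      edges <- cbind(qi[link], si[link])
    } else edges <- cbind(integer(), integer())
    comp <- union_find_components(length(grp), edges)
    labels[grp] <- comp + next_id
    next_id <- next_id + max(comp, 0L)
  }
  labels
}

#' Rarity filter: remove common CNV regions
#'
#' Within each cohort and CNV type, calls are clustered into CNV regions by
#' single-linkage at a minimum reciprocal overlap.  A region's frequency is
#' the number of distinct carrier samples divided by the cohort sample count;
#' calls in regions with frequency strictly above `max_frequency` are
#' removed.
#'
#' @param calls a CNV call table (already size/probe/blacklist filtered).
#' @param samples the phenotype table giving cohort sizes.
#' @param config a [qc_config()].
#' @return a list with `calls` (retained calls) and `regions` (one row per
#'   region: `cohort`, `type`, `chrom`, `start`, `end`, `n_calls`,
#'   `n_carriers`, `frequency`, `singleton`, `removed`).
#' @export
filter_rare <- function(calls, samples, config = qc_config()) {
  if (nrow(calls) == 0L)
    return(list(calls = calls,
                regions = data.frame(cohort = character(), type = character(),
                                     chrom = character(), start = numeric(),
                                     end = numeric(), n_calls = integer(),
                                     n_carriers = integer(), frequency = numeric(),
                                     singleton = logical(), removed = logical())))
  cohort_n <- table(samples$cohort)
  region <- cluster_regions(calls, config$reciprocal_overlap)
  key <- sample_key(calls$cohort, calls$sample_id)
  region_levels <- sort(unique(region))
  first <- which(!duplicated(region))
  first <- first[order(region[first])]
  rf <- factor(region, levels = region_levels)
  n_carriers <- as.integer(tapply(key, rf, function(k) length(unique(k))))
  ntot <- as.integer(cohort_n[calls$cohort[first]])
  if (anyNA(ntot) || any(ntot == 0L))
    stopf("cohort %s present in calls but absent from samples",
          calls$cohort[first][which(is.na(ntot) | ntot == 0L)][1])
  regions <- data.frame(
    cohort = calls$cohort[first], type = calls$type[first],
    chrom = calls$chrom[first],
    start = as.numeric(tapply(calls$start, rf, min)),
    end = as.numeric(tapply(calls$end, rf, max)),
    n_calls = as.integer(tabulate(rf)),
    n_carriers = n_carriers, frequency = n_carriers / ntot,
    singleton = n_carriers == 1L, stringsAsFactors = FALSE)
  regions$removed <- regions$frequency > config$max_frequency
  keep_labels <- region_levels[!regions$removed]
  list(calls = calls[region %in% keep_labels, , drop = FALSE],
       regions = regions[order(regions$cohort, regions$chrom, regions$start), ,
                         drop = FALSE])
}

#' Run the full QC chain
#'
#' Applies size, probe-count, blacklist, CNV-outlier-sample and rarity
#' filters in that canonical order and assembles a staged report.
#'
#' @param calls a CNV call table.
#' @param samples a phenotype table for the same cohorts.
#' @param config a [qc_config()].
#' @return a list of class `qc_result` with `calls`, `samples`, and `report`;
#'   the report carries `stages` (non-increasing call counts per filter
#'   stage), `excluded_samples`, `regions`, and per-cohort gain/loss totals
#'   in `cohort_totals`.
#' @export
apply_qc <- function(calls, samples, config = qc_config()) {
  samples <- validate_sample_records(samples)
  calls <- validate_cnv_calls(calls)
  stages <- data.frame(stage = "input", n_calls = nrow(calls),
                       stringsAsFactors = FALSE)
  note <- function(stage, calls) {
    stages <<- rbind(stages, data.frame(stage = stage, n_calls = nrow(calls)))
    calls
  }
  calls <- note("size", filter_size(calls, config$min_size_bp))
  calls <- note("probes", filter_probes(calls, config))
  calls <- note("blacklist", filter_blacklist(calls, config$blacklist))
  outl <- exclude_outlier_samples(calls, samples, config$outlier_sd)
  calls <- note("outlier_samples", outl$calls)
  samples <- outl$samples
  rare <- filter_rare(calls, samples, config)
  calls <- note("rarity", rare$calls)
  totals <- if (nrow(calls)) {
    t <- as.data.frame(table(cohort = calls$cohort, type = calls$type),
                       stringsAsFactors = FALSE)
    names(t)[3] <- "n_calls"
    t
  } else data.frame(cohort = character(), type = character(),
                    n_calls = integer(), stringsAsFactors = FALSE)
  structure(list(calls = calls, samples = samples,
                 report = list(stages = stages,
                               excluded_samples = outl$excluded,
                               regions = rare$regions,
                               cohort_totals = totals)),
            class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  cat("QC chain:\n")
  print(x$report$stages, row.names = FALSE)
  if (nrow(x$report$excluded_samples))
    cat(sprintf("excluded %d CNV-outlier sample(s)\n",
                nrow(x$report$excluded_samples)))
  invisible(x)
}
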