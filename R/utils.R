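# Internal helpers shared across modules.

# Normalize chromosome labels to a "chr"-prefixed form ("1" -> "chr1",
# "CHR1"/"Chr1" -> "chr1").  Sources disagree on the prefix; one internal
# spelling avoids silent non-overlap between files.
norm_chrom <- function(x) {
  x <- as.character(x)
  if (any(!nzchar(x) | is.na(x))) stop("empty chromosome label")
  paste0("chr", sub("^chr", "", x, ignore.case = TRUE))
}

# Globally unique sample key: sample ids are only guaranteed unique within a
# cohort, so every sample-level join goes through this key.
sample_key <- function(cohort, sample_id) paste(cohort, sample_id, sep = "\r")

# Evaluate expr with a temporary RNG state seeded at `seed`, restoring the
# caller's stream afterwards.
with_local_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Draw k sub-seeds (< 2^31) from the stream seeded at `seed`.
derive_subseeds <- function(seed, k) {
  with_local_seed(seed, sample.int(.Machine$integer.max, k))
}

# Union-find with path compression; `pairs` is a 2-column integer matrix of
# edges over 1..n.  Returns component labels 1..n (renumbered consecutively).
union_find_components <- function(n, pairs) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (length(pairs)) {
    for (e in seq_len(nrow(pairs))) {
      ri <- find(pairs[e, 1L]); rj <- find(pairs[e, 2L])
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# Truncated-normal draws by rejection; bounds are plausibility limits, not
# distribution parameters, so the acceptance rate is always high here.
rnorm_trunc <- function(n, mean, sd, lower, upper) {
  out <- rnorm(n, mean, sd)
  bad <- which(out < lower | out > upper)
  guard <- 0L
  while (length(bad)) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lower | out[bad] > upper]
    guard <- guard + 1L
    if (guard > 1000L) stop("truncated-normal bounds incompatible with mean/sd")
  }
  out
}

# GRanges on 1-based closed coordinates from internal 0-based half-open ones.
as_granges0 <- function(chrom, start0, end0) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start = start0 + 1L, end = end0))
}

# findOverlaps over possibly disjoint chromosome sets; disjoint seqlevels are
# an expected situation (e.g. calls on gene-free chromosomes), not a warning.
find_overlaps0 <- function(query, subject) {
  suppressWarnings(GenomicRanges::findOverlaps(query, subject))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
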