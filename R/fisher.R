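# Exact inference for 2x2 carrier tables.

#' Two-sided Fisher exact test with conditional-MLE odds ratio
#'
#' For a 2x2 table `(a, b; c, d)` with `a` = case carriers, `b` = case
#' non-carriers, `c` = control carriers, `d` = control non-carriers, computes
#' (conditioning on both margins):
#'
#' * the two-sided p-value as the sum of hypergeometric probabilities of all
#'   tables whose probability does not exceed that of the observed table
#'   (masses within a relative factor `1e-7` are treated as tied, the usual
#'   guard against floating-point ties);
#' * the conditional maximum-likelihood odds ratio, i.e. the root of the
#'   conditional score equation of the noncentral hypergeometric model;
#' * the exact conditional confidence interval obtained by inverting the two
#'   one-sided tests at `(1 - conf_level)/2` per tail.
#'
#' This is the estimator semantics of classical exact-test software, computed
#' here to full floating-point precision.  Zero cells give odds-ratio or
#' interval bounds of 0 or `Inf`; a table whose support is a single point
#' (a degenerate margin) returns `p = 1`, `or = NA`, interval `(0, Inf)`.
#' All arguments are vectorized.
#'
#' @param a,b,c,d non-negative integer cell counts (recycled to a common
#'   length).
#' @param conf_level confidence level for the exact interval (default 0.95).
#' @return a data frame with columns `a`, `b`, `c`, `d`, `p`, `or`
#'   (conditional MLE), `ci_lo`, `ci_hi`, and `or_crude` (the cross-product
#'   estimate `ad/bc`, reported for transparency).
#' @examples
#' fisher_exact_2x2(10, 90, 5, 95)
#' @export
fisher_exact_2x2 <- function(a, b, c, d, conf_level = 0.95) {
  n <- max(length(a), length(b), length(c), length(d))
  a <- as.integer(rep_len(a, n)); b <- as.integer(rep_len(b, n))
  c <- as.integer(rep_len(c, n)); d <- as.integer(rep_len(d, n))
  if (anyNA(a) || anyNA(b) || anyNA(c) || anyNA(d))
    stop("NA cell in 2x2 table")
  res <- .fisher2x2_cpp(a, b, c, d, conf_level)
  data.frame(a = a, b = b, c = c, d = d, p = res$p, or = res$or,
             ci_lo = res$ci_lo, ci_hi = res$ci_hi,
             or_crude = (a * d) / (b * c))
}

#' @rdname fisher_exact_2x2
#' @details `fisher_exact_2x2_bruteforce()` is an independent brute-force
#'   enumeration of the same quantities (its own log-factorial tables,
#'   long-double tail sums over the full hypergeometric support, and plain
#'   bisection), kept free of any code shared with the production routine.
#'   It exists to validate `fisher_exact_2x2()` and is quadratic per table.
#' @export
fisher_exact_2x2_bruteforce <- function(a, b, c, d, conf_level = 0.95) {
  n <- max(length(a), length(b), length(c), length(d))
  a <- as.integer(rep_len(a, n)); b <- as.integer(rep_len(b, n))
  c <- as.integer(rep_len(c, n)); d <- as.integer(rep_len(d, n))
  res <- .fisher2x2_enum_cpp(a, b, c, d, conf_level)
  data.frame(a = a, b = b, c = c, d = d, p = res$p, or = res$or,
             ci_lo = res$ci_lo, ci_hi = res$ci_hi)
}

#' Bonferroni-adjusted alpha threshold
#'
#' @param alpha nominal familywise alpha, in (0, 1).
#' @param n_tests number of tests in the declared family (>= 1).
#' @return `alpha / n_tests`.
#' @examples
#' bonferroni_alpha(0.05, 9)   # prints as 0.0055
#' bonferroni_alpha(0.05, 15)  # prints as 0.0033
#' @export
bonferroni_alpha <- function(alpha, n_tests) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must be in (0, 1)")
  if (!is.numeric(n_tests) || n_tests < 1)
    stop("n_tests must be a positive integer")
  alpha / n_tests
}

#' @rdname bonferroni_alpha
#' @param x a threshold to display.
#' @param digits decimal places kept.
#' @details `format_alpha()` renders thresholds the way they are customarily
#'   printed alongside burden results: truncated (not rounded) to `digits`
#'   decimal places, so `0.05/9` prints as `"0.0055"` and `0.05/15` as
#'   `"0.0033"`.
#' @export
format_alpha <- function(x, digits = 4L) {
  sprintf(paste0("%.", digits, "f"), trunc(x * 10^digits) / 10^digits)
}
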