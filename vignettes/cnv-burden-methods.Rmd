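---
title: "Methods: rare CNV carrier burden in case-control cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rare CNV carrier burden in case-control cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvburden)
```

## The problem

Large, rare copy-number variants (CNVs) — gains and losses of 100 kb to a
few Mb — are individually too rare for variant-level association, so
case-control studies aggregate them: for a hypothesis defined by a gene set
(for example, lipid-metabolism genes, or genes expressed in the small
intestine), a sample is a **carrier** if it harbours at least one qualifying
CNV overlapping a member of the set, counted once regardless of how many
such CNVs it has.  The carrier proportions of cases and controls are then
compared.  `cnvburden` implements this design end to end for multi-cohort
array studies of gallstone disease and similar metabolic phenotypes, where
effects can be sex-specific and cohorts differ in genotyping platform,
ancestry and sex composition.

## Quality control

Calls pass a five-stage chain, in this canonical order:

1. **Size**: only calls strictly larger than `min_size_bp` (default 100 kb)
   are kept — "larger than" is read as a strict inequality on `end - start`.
2. **Probes**: calls need at least the cohort's minimum supporting probe
   count (default 50; 100 is the convention for high-density platforms).
   Probe counts missing from a VCF default to 0, so unsupported calls fail
   closed unless the filter is disabled.
3. **Blacklist**: any call sharing at least 1 bp with a signal-artifact
   region is removed; no overlap fraction is required.  Half-open abutment
   is not an overlap.
4. **CNV-outlier samples**: per cohort, the mean and *population* standard
   deviation of per-sample call counts (zero-call samples included) are
   computed once; samples whose count exceeds `mean + 3 SD` are excluded
   together with their calls.  The rule is one-sided and single-pass — it is
   not iterated after exclusions — and is computed per cohort because
   platforms differ between cohorts.
5. **Rarity**: within each cohort and CNV type, calls are clustered into CNV
   regions by single-linkage at ≥ 50% reciprocal overlap
   (`min(overlap/len_A, overlap/len_B)`).  A region's frequency is its
   number of distinct carriers over the cohort sample count; regions
   strictly above 1% are removed.  The 50%-reciprocal-overlap /
   carriers-per-cohort definition is the standard rare-CNV convention; the
   frequency threshold is applied strictly.

The chain is idempotent, and its stage counts are non-increasing.  Order
matters only for the report: the rules are jointly, not sequentially,
defined, but the canonical order above is what the report tabulates.

## Burden testing

For each cohort, the hypothesis family is "any gene" plus the configured
gene sets (nine hypotheses with the default eight-set collection), each
tested on the 2×2 carrier table with a two-sided Fisher exact test.  The
two-sided p-value sums hypergeometric masses not exceeding the observed
mass, with a `1e-7` relative guard against floating-point ties.  The
reported odds ratio is the **conditional maximum-likelihood estimate** under
the noncentral hypergeometric model (the root of the conditional score
equation), with an exact interval obtained by inverting the one-sided tests
at 2.5% per tail — the estimator semantics of classical exact-test software,
here solved to full floating-point precision in compiled code.  The crude
cross-product ratio is reported alongside for transparency.  An independent
brute-force enumeration (`fisher_exact_2x2_bruteforce()`, separate
log-factorial tables, long-double sums, plain bisection) ships with the
package; the test suite verifies agreement to `1e-12` on **every** 2×2 table
with total `N ≤ 60`.

The type-combined family is Bonferroni-adjusted per cohort
(`0.05/9`, displayed truncated as `0.0055`); gain/loss-stratified results
are flagged at raw `p < 0.05`, mirroring how type-resolved burden signals
are conventionally displayed.

## Covariate-adjusted association

Fifteen binomial GLMs — five carrier predictors (any CNV; lipid;
small-intestine; lipid ∩ small-intestine; small-intestine ∖ lipid) × three
strata (all, women, men) — adjust for age (years), BMI (kg/m²), dataset
(indicators, largest cohort as reference) and, in unstratified fits, sex
(male = 1, so a protective male effect appears as OR < 1).  Sex-specificity
is handled purely by stratification; there are no interaction terms, age and
BMI enter in raw units, and T2D never enters (it is unavailable for entire
cohorts in the motivating design).  Inference is Wald: `z = estimate/SE`,
`p = 2Φ(−|z|)`, CI `exp(estimate ± 1.959964·SE)`.  IRLS convergence is
declared below `1e-8` within 100 iterations; apparent complete separation
(a binary predictor with |estimate| > 15) flags the fit as non-converged
rather than returning a silently absurd estimate.  The carrier term's
familywise threshold is `0.05/15` (displayed `0.0033`).

## Candidate genes

The gene-centric filter chain intersects the lipid set with the
tissue-expression set, keeps genes overlapped by at least one case CNV, and
finally requires **absolute** exclusivity: one control carrier in any cohort
disqualifies a gene.  Stage counts are reported as a non-increasing
quadruple.  Enrichment arithmetic (e.g. of loss-of-function-intolerant genes
among candidates) uses the upper-tail hypergeometric probability; the
intolerant-gene list is user-supplied, as constraint metrics are outside
this package's scope.

## The synthetic cohort generator

Every stage is testable without access to any real genotype data because the
generator produces complete studies with the structure the analysis assumes:

* **Cohorts**: three blocks mirroring the motivating study's cohort table —
  1052/905, 355/1390 and 522/554 cases/controls; women fractions 61.5/42.2,
  64.5/49.1 and 92.3/92.4%; age and BMI normal marginals per group,
  truncated at plausibility bounds (18–95 years, 15–60 kg/m²); per-sample
  call counts Poisson with per-cohort rates stored as exact call/sample
  ratios (821/1957, 1168/1745, 947/1076), so expected totals reproduce the
  printed counts (2936 calls overall) and display as 0.42/0.67/0.88.  Sex
  counts are assigned deterministically (rounded fractions, then shuffled),
  making compositions such as the 40 male cases in the smallest cohort exact
  rather than binomial.
* **Calls**: gain with probability 0.742, log-uniform sizes on
  [100 001, 3 Mb] (the empirical size distribution is only known to be
  modal between 250 and 500 kb; log-uniform is a pragmatic stand-in),
  uniform positions, probe counts at threshold + Poisson(size/2 kb), with a
  configurable fraction drawn below threshold for QC testing (0 in the
  default preset, which emulates the *detected*, QC-surviving call set).
* **Genome**: 8 chromosomes × 60 Mb with 2000 non-overlapping 20 kb genes
  tiled with random offsets (≈ 1 gene / 240 kb, the same order as the human
  genome's gene spacing); eight gene sets sampled at sizes scaled from the
  real sets (156 lipid, 382 small-intestine, 37 shared, …); a small
  blacklist placed in gene-free gaps.
* **Effect injection**: samples in the targeted sex × status stratum receive
  one extra call over a random gene of the affected set with probability
  `r = (p1 − q)/(1 − q)` where `p1 = OR·q/(1 − q + OR·q)` and `q` is the
  baseline carrier probability.  `q` is calibrated by Monte Carlo using the
  *same* call sampler the cohorts use (200 000 draws, including the QC
  predicate), so the injected odds ratio is exactly the estimand of the
  downstream carrier models.  Injection is at the carrier level because the
  burden statistic is carrier-based; odds ratios below 1 are rejected as
  infeasible for an additive injection.  One RNG stream is seeded once per
  study; sub-seeds are derived in a documented order (genome, calibration,
  then each cohort), so the entire bundle is a pure function of the
  configuration.

### What the generator does and does not emulate

It reproduces cohort compositions, covariate marginals, call rates, the
gain:loss mix, call sizes and a mostly-singleton region structure.  It does
**not** model recurrent CNV hotspots, linkage or ancestry structure, or the
empirical anti-correlation between large CNVs and gene-dense regions.  Two
consequences are worth stating plainly.  First, with uniform call placement
the per-call probability of hitting a lipid-set gene is ≈ 0.23, giving
carrier baselines of ≈ 9–18% — several-fold higher than the sparse carrier
counts such a design sees in real cohorts.  Injected-effect simulations
therefore recover the injected *odds ratio* (the calibrated estimand) but
at greater power, so simulated p-values are not comparable to real-data
ones and are not reported as such.  Second, re-applying the 3-SD outlier
rule to an already-clean Poisson cohort always trims the distribution's
natural upper tail (≈ 4% of calls); detected-call totals are therefore
tabulated after the call-level filters, where they correspond to the
generator's configured rates.

## Numerical and design choices

* Internal coordinates are 0-based half-open everywhere; only readers and
  writers convert (TSV call tables are declared 1-based inclusive, matching
  how CNV bounds are printed in publication tables; BED passes through; VCF
  uses POS/END).  Chromosome labels are normalized to a `chr` prefix on
  input because gene, blacklist and call files routinely disagree.
* Gene overlap means ≥ 1 bp of the gene's full genomic span — CNVs of
  hundreds of kb typically swallow whole genes, and no exon-aware rule is
  defined for this design.  X-linked genes are treated like autosomal ones.
* Ties and orderings are resolved by (chromosome, start, gene id) for
  reproducibility; annotation is a pure function of its inputs.
* The exact-test root searches bracket log-odds in [−250, 250] and bisect to
  floating-point resolution; degenerate supports (a margin of zero) return
  `p = 1`, `OR = NA`, CI `(0, ∞)`; boundary tables return 0/∞ bounds.
* Small strata are refused (< 10 cases or controls) rather than fitted
  unstably; the association grid records the refusal and continues.
* Simulation problem sizes in the test suite (200 replicates at full cohort
  scale for the operating-characteristic checks, an exhaustive `N ≤ 60` scan
  for the exact test) were chosen so the whole suite completes in a few
  minutes on one CPU while keeping Monte-Carlo error far below the margins
  being asserted.

## Known limitations

Beyond the generator's simplifications above: no raw intensity processing
or segmentation (inputs are called CNVs), no liftover between genome builds,
no permutation-based null for the burden tests, no ancestry adjustment
(upstream of this design), and no protein-interaction or live-annotation
enrichment services.  The candidate-gene stage reports the filter chain's
counts; reproducing any particular real-data candidate list requires the
corresponding real gene sets and calls as inputs.

## A worked run

```{r run, eval = FALSE}
cfg <- sim_config("paper_like", seed = 1,
                  overrides = list(effect = list(target_or = 2.76)))
manifest <- run_all(cfg, "gsd_run")
grid <- read.delim(file.path("gsd_run", "glm_grid.tsv"))
subset(grid, predictor_set == "lipid", c(stratum, or, ci_lo, ci_hi, p))
```

The men-stratum lipid row recovers the injected carrier odds ratio; the
women-stratum row stays null — the qualitative sex-specific pattern the
design is built to detect.
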