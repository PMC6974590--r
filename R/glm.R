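# Covariate-adjusted logistic association: 5 carrier predictors x 3 sex
# strata = 15 binomial GLMs, each adjusting for age, BMI, dataset and (in the
# unstratified fits) sex.

GLM_PREDICTORS <- c(any_cnv = "any", lipid = "lipid",
                    small_intestine = "small_intestine",
                    lipid_and_si = "lipid_and_si",
                    si_not_lipid = "si_not_lipid")
GLM_STRATA <- c("all", "women", "men")

#' The 15-model association grid specification
#'
#' @return a data frame with one row per model: `predictor_set` (one of
#'   `any_cnv`, `lipid`, `small_intestine`, `lipid_and_si`, `si_not_lipid`)
#'   and `stratum` (`all`, `women`, `men`).
#' @export
glm_specs <- function() {
  expand.grid(predictor_set = names(GLM_PREDICTORS), stratum = GLM_STRATA,
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}

#' Build the design matrix for one association model
#'
#' The response is 1 for cases.  The carrier indicator comes first and uses
#' the same count-once carrier semantics as the burden analysis (any CNV
#' type).  Sex is coded male = 1 / female = 0 (so a protective male effect
#' appears as OR < 1) and is dropped in sex-stratified fits.  Cohort enters
#' as indicator columns with the largest cohort as the reference level.
#' Rows with missing covariates are dropped (and counted).
#'
#' @param samples the phenotype table.
#' @param annotated an [annotate_calls()] result.
#' @param predictor_set one of the names in [glm_specs()].
#' @param stratum `"all"`, `"women"`, or `"men"`.
#' @return a list with `x` (design matrix including intercept), `y`
#'   (response), `n_dropped` (rows lost to missing covariates).
#' @export
make_design <- function(samples, annotated, predictor_set = "any_cnv",
                        stratum = "all") {
  stopifnot(predictor_set %in% names(GLM_PREDICTORS),
            stratum %in% GLM_STRATA)
  if (stratum != "all")
    samples <- samples[samples$sex == c(women = "female", men = "male")[stratum], ,
                       drop = FALSE]
  ok <- complete.cases(samples[, c("age", "bmi")])
  n_dropped <- sum(!ok)
  samples <- samples[ok, , drop = FALSE]
  n_case <- sum(samples$status == "case")
  n_ctrl <- sum(samples$status == "control")
  if (n_case < 10L || n_ctrl < 10L)
    stopf("stratum '%s' has %d cases / %d controls; at least 10 of each are required for a stable fit",
          stratum, n_case, n_ctrl)
  set_name <- GLM_PREDICTORS[[predictor_set]]
  known <- c("any", attr(annotated, "set_names"))
  if (!set_name %in% known)
    stopf("annotation lacks the '%s' set needed for predictor '%s' (derive compound sets before annotating)",
          set_name, predictor_set)
  use <- match_set(annotated, set_name)
  carrier_keys <- unique(sample_key(annotated$cohort, annotated$sample_id)[use])
  carrier <- as.numeric(sample_key(samples$cohort, samples$sample_id) %in% carrier_keys)
  x <- data.frame(`(Intercept)` = rep(1, nrow(samples)),
                  cnv_carrier = carrier, age = samples$age,
                  bmi = samples$bmi, check.names = FALSE)
  if (stratum == "all")
    x$sex_male <- as.numeric(samples$sex == "male")
  cohorts <- names(sort(table(samples$cohort), decreasing = TRUE))
  for (co in cohorts[-1])
    x[[paste0("dataset_", co)]] <- as.numeric(samples$cohort == co)
  x <- as.matrix(x)
  list(x = x, y = as.numeric(samples$status == "case"), n_dropped = n_dropped)
}

#' Fit a binomial GLM and return Wald inference per predictor
#'
#' Maximum-likelihood logistic regression (IRLS, convergence when successive
#' deviances change by less than 1e-8 within 100 iterations) with Wald
#' standard errors; p-values are `2 * pnorm(-|z|)` and confidence intervals
#' `exp(estimate +/- 1.959964 * se)`.  Collinear columns are dropped (with a
#' message) before fitting.  Apparent complete separation — a binary
#' predictor with |estimate| > 15 — is flagged by `converged = FALSE`.
#'
#' @param x design matrix (including an intercept column).
#' @param y 0/1 response vector.
#' @param conf_level confidence level for Wald intervals.
#' @return a list of class `glm_fit_result`: `coefficients` (data frame with
#'   `term`, `estimate`, `se`, `z`, `p`, `or`, `ci_lo`, `ci_hi`), `n`,
#'   `converged`, `diagnostic`.
#' @export
fit_logistic <- function(x, y, conf_level = 0.95) {
  if (length(unique(y)) < 2L)
    stop("degenerate response: all samples share one outcome")
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    drop_cols <- colnames(x)[qx$pivot[(qx$rank + 1L):ncol(x)]]
    message(sprintf("dropping collinear column(s): %s",
                    paste(drop_cols, collapse = ", ")))
    x <- x[, setdiff(colnames(x), drop_cols), drop = FALSE]
    if (qr(x)$rank < ncol(x)) stop("design matrix is rank deficient")
  }
  fit <- glm.fit(x, y, family = binomial(),
                 control = list(epsilon = 1e-8, maxit = 100L))
  est <- fit$coefficients
  w <- fit$weights
  cov <- chol2inv(chol(crossprod(x * sqrt(w))))
  se <- sqrt(diag(cov))
  z <- est / se
  crit <- qnorm(1 - (1 - conf_level) / 2)
  coef_df <- data.frame(term = colnames(x), estimate = est, se = se, z = z,
                        p = 2 * pnorm(-abs(z)), or = exp(est),
                        ci_lo = exp(est - crit * se),
                        ci_hi = exp(est + crit * se),
                        row.names = NULL, stringsAsFactors = FALSE)
  binary <- apply(x, 2, function(col) all(col %in% c(0, 1)))
  separated <- binary & colnames(x) != "(Intercept)" & abs(est) > 15
  diagnostic <- if (any(separated))
    sprintf("apparent complete separation on: %s",
            paste(colnames(x)[separated], collapse = ", "))
  else if (!fit$converged) "IRLS did not converge" else ""
  structure(list(coefficients = coef_df, n = nrow(x),
                 converged = fit$converged && !any(separated),
                 diagnostic = diagnostic),
            class = "glm_fit_result")
}

#' Fit the full 15-model association grid
#'
#' Runs every predictor-set x stratum combination of [glm_specs()].  The
#' carrier term's familywise threshold is `alpha / 15`.  Models that cannot
#' be fitted (e.g. a stratum with too few cases) yield `NA` rows, and the
#' grid continues.
#'
#' @param samples the phenotype table.
#' @param annotated an [annotate_calls()] result whose collection included
#'   the compound sets (see [derive_compound_sets()]).
#' @param alpha nominal familywise alpha (default 0.05).
#' @return a list with `grid` (one row per model: carrier-term estimate,
#'   `or`, `ci_lo`, `ci_hi`, `z`, `p`, `n`, `converged`, `alpha_adjusted`,
#'   `significant`, `error`) and `fits` (the full `glm_fit_result`s).
#' @export
run_glm_grid <- function(samples, annotated, alpha = 0.05) {
  specs <- glm_specs()
  alpha_adj <- bonferroni_alpha(alpha, nrow(specs))
  fits <- vector("list", nrow(specs))
  rows <- vector("list", nrow(specs))
  for (i in seq_len(nrow(specs))) {
    ps <- specs$predictor_set[i]; st <- specs$stratum[i]
    res <- tryCatch({
      des <- make_design(samples, annotated, ps, st)
      fit <- fit_logistic(des$x, des$y)
      fits[[i]] <- fit
      cc <- fit$coefficients[fit$coefficients$term == "cnv_carrier", ]
      data.frame(predictor_set = ps, stratum = st, estimate = cc$estimate,
                 se = cc$se, z = cc$z, p = cc$p, or = cc$or,
                 ci_lo = cc$ci_lo, ci_hi = cc$ci_hi, n = fit$n,
                 converged = fit$converged, error = "",
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(predictor_set = ps, stratum = st, estimate = NA_real_,
                 se = NA_real_, z = NA_real_, p = NA_real_, or = NA_real_,
                 ci_lo = NA_real_, ci_hi = NA_real_, n = NA_integer_,
                 converged = NA, error = conditionMessage(e),
                 stringsAsFactors = FALSE)
    })
    rows[[i]] <- res
  }
  grid <- do.call(rbind, rows)
  grid$alpha_adjusted <- alpha_adj
  grid$significant <- !is.na(grid$p) & grid$p < alpha_adj
  list(grid = grid, fits = setNames(fits, paste(specs$predictor_set,
                                                specs$stratum, sep = ".")))
}
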