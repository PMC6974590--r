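# Design construction and logistic association grid.

# 24 hand-written samples in 3 cohorts; carriers defined by calls over the
# tiny fixture's gene A (lipid + small_intestine).
glm_fixture <- function() {
  fx <- tiny_fixture()
  cohorts <- rep(c("P", "S", "A"), c(10, 8, 6))
  ids <- sprintf("G%02d", 1:24)
  samples <- sample_records(
    sample_id = ids, cohort = cohorts,
    status = rep(c("case", "control"), 12),
    sex = rep(c("female", "female", "male", "male"), 6),
    age = 40 + (1:24), bmi = 22 + (1:24) / 2)
  carriers <- c("G01", "G04", "G11", "G20")
  calls <- cnv_calls(carriers, cohorts[match(carriers, ids)], "chr1",
                     990000, 1140000, "gain", 80L)
  ann <- annotate_calls(calls, build_gene_index(fx$genes), fx$collection)
  list(samples = samples, ann = ann, carriers = carriers)
}

test_that("the design matrix matches its hand-written expectation", {
  gf <- glm_fixture()
  des <- make_design(gf$samples, gf$ann, "lipid", "all")
  expected <- cbind(
    `(Intercept)` = rep(1, 24),
    cnv_carrier = as.numeric(gf$samples$sample_id %in% gf$carriers),
    age = 40 + (1:24), bmi = 22 + (1:24) / 2,
    sex_male = as.numeric(gf$samples$sex == "male"),
    dataset_S = as.numeric(gf$samples$cohort == "S"),
    dataset_A = as.numeric(gf$samples$cohort == "A"))
  expect_equal(des$x, expected)
  expect_equal(des$y, rep(c(1, 0), 12))
  # three cohorts -> two indicator columns, largest cohort as reference
  expect_false(any(grepl("dataset_P", colnames(des$x))))
})

test_that("sex stratification removes the sex column and subsets rows", {
  gf <- glm_fixture()
  # double the fixture to give each sex stratum >= 10 cases and controls
  s2 <- gf$samples
  s2$sample_id <- paste0(s2$sample_id, "b")
  s2$sex <- rev(gf$samples$sex)
  samples <- rbind(gf$samples, s2)
  des <- make_design(samples, gf$ann, "any_cnv", "men")
  expect_false("sex_male" %in% colnames(des$x))
  expect_equal(nrow(des$x), sum(samples$sex == "male"))
  expect_error(make_design(gf$samples, gf$ann, "any_cnv", "men"),
               "at least 10")
})

test_that("a two-column fit reproduces the crude cross-product odds ratio", {
  # 2x2 table (30, 70, 15, 85)
  y <- rep(c(1, 0), c(100, 100))
  carrier <- c(rep(c(1, 0), c(30, 70)), rep(c(1, 0), c(15, 85)))
  fit <- fit_logistic(cbind(`(Intercept)` = 1, cnv_carrier = carrier), y)
  crude <- (30 * 85) / (70 * 15)
  expect_equal(fit$coefficients$or[2], crude, tolerance = 1e-8)
  # permuting rows leaves the estimates unchanged
  perm <- withr::with_seed(4, sample.int(200))
  fit2 <- fit_logistic(cbind(`(Intercept)` = 1, cnv_carrier = carrier[perm]),
                       y[perm])
  expect_equal(fit2$coefficients$estimate, fit$coefficients$estimate,
               tolerance = 1e-10)
})

test_that("degenerate and pathological fits are flagged, not silently returned", {
  x <- cbind(`(Intercept)` = rep(1, 40), cnv_carrier = rep(c(1, 0), 20))
  expect_error(fit_logistic(x, rep(0, 40)), "degenerate response")
  # balanced null: intercept ~ 0, OR ~ 1
  fit <- fit_logistic(x[, 1, drop = FALSE], rep(c(1, 0), 20))
  expect_equal(fit$coefficients$or[1], 1, tolerance = 1e-8)
  # complete separation: carrier == response
  y <- rep(c(1, 0), 20)
  sep <- fit_logistic(cbind(`(Intercept)` = 1, cnv_carrier = y), y)
  expect_false(sep$converged)
  expect_match(sep$diagnostic, "separation")
  # collinear column is dropped with a message
  expect_message(
    fit_logistic(cbind(`(Intercept)` = 1, cnv_carrier = y, dup = y),
                 rep(c(1, 0, 0, 1), 10)), "collinear")
})

test_that("the association grid always spans the 15 declared models", {
  specs <- glm_specs()
  expect_equal(nrow(specs), 15L)
  expect_equal(sort(unique(specs$stratum)), c("all", "men", "women"))
  setup <- annotate_fixture()
  coll <- derive_compound_sets(setup$fx$collection)
  ann <- annotate_calls(setup$qc$calls, build_gene_index(setup$fx$genes), coll)
  res <- run_glm_grid(setup$qc$samples, ann)
  expect_equal(nrow(res$grid), 15L)
  # the tiny cohort is far below the per-stratum minimum: every cell reports
  # its error instead of aborting the grid
  expect_true(all(nzchar(res$grid$error)))
  expect_equal(unique(res$grid$alpha_adjusted), 0.05 / 15)
})

test_that("on cohort-structured data sex is protective and its column matters", {
  cfg <- sim_config("paper_like", seed = 31)
  sim <- simulate_study(cfg)
  coll <- derive_compound_sets(sim$genome$collection)
  ann <- annotate_calls(sim$calls, build_gene_index(sim$genome$genes), coll)
  des <- make_design(sim$samples, ann, "any_cnv", "all")
  fit <- fit_logistic(des$x, des$y)
  sex_row <- fit$coefficients[fit$coefficients$term == "sex_male", ]
  # the configured cohort marginals make men less often cases: OR < 1
  expect_lt(sex_row$or, 1)
  expect_lt(sex_row$p, 1e-6)
  # dropping the sex column is a different model: carrier estimate moves
  no_sex <- fit_logistic(des$x[, colnames(des$x) != "sex_male"], des$y)
  expect_false(isTRUE(all.equal(
    fit$coefficients$estimate[2], no_sex$coefficients$estimate[2],
    tolerance = 1e-6)))
})
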