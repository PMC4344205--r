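step_curves <- function(time, surv_rows, horizon) {
  structure(list(time = time, surv = surv_rows, horizon = horizon),
            class = "survival_curves")
}

test_that("areas under step curves match closed forms", {
  H <- 100
  # S == 1 throughout
  expect_equal(survival_curve_area(step_curves(H, matrix(1, 1, 1), H)), H)
  # S = 1 on [0, H/2), 0 after
  expect_equal(survival_curve_area(step_curves(H / 2, matrix(0, 1, 1), H)), H / 2)
  # single-step Cox curve: Lambda0 jumps to 0.5 at t=40, risk score 1
  s <- exp(-0.5)
  expect_equal(survival_curve_area(step_curves(40, matrix(s, 1, 1), H)),
               40 + (H - 40) * s)
  # increasing curves are invalid
  expect_error(survival_curve_area(step_curves(c(10, 20), matrix(c(0.5, 0.9), 1), H)),
               "non-increasing")
})

test_that("concordance follows the strict area rule on canonical 3-patient cases", {
  day <- c(100, 200, 300)
  status <- rep("dead", 3)
  asc <- concordance_index(c(1, 2, 3), day, status, horizon = 400)
  expect_equal(asc$index, 1)
  expect_equal(asc$n_pairs, 3)
  expect_equal(asc$total, 3)
  # identical curves: strict inequality never satisfied
  expect_equal(concordance_index(c(2, 2, 2), day, status, horizon = 400)$index, 0)
  # anti-concordant areas
  expect_equal(concordance_index(c(3, 2, 1), day, status, horizon = 400)$index, 0)
  expect_error(concordance_index(c(1, 2), day, status), "per patient")
})

test_that("concordance equals brute-force pair enumeration on random cohorts", {
  for (s in 1:20) {
    d <- random_survival_data(n = 10 + (s %% 4) * 10, seed = s)
    if (!any(d$status == "dead")) next
    horizon <- 800
    got <- concordance_index(d$areas, d$day, d$status, horizon)
    want <- brute_concordance(d$areas, d$day, d$status, horizon)
    expect_equal(got$index, want$index)
    expect_equal(got$total, want$total)
    expect_equal(got$n_pairs, want$n_pairs)
  }
})

test_that("a patient censored before the earliest death anchors or joins no pair", {
  day <- c(50, 100, 300)
  status <- c("alive", "dead", "dead")
  r <- concordance_index(c(5, 1, 9), day, status, horizon = 400)
  # pairs: (2,3) only — patient 1 was censored before the first death
  expect_equal(r$n_pairs, 1)
  expect_error(concordance_index(1, 10, "alive"), "no evaluable pairs")
})

test_that("the chi-square comparison matches the textbook formula and is symmetric", {
  a <- structure(list(index = 0.9, total = 900, n_pairs = 1000),
                 class = "concordance_result")
  b <- structure(list(index = 0.5, total = 500, n_pairs = 1000),
                 class = "concordance_result")
  p <- compare_concordance_chisq(a, b)
  tab <- rbind(c(900, 100), c(500, 500))
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(attr(p, "statistic"), sum((tab - E)^2 / E))
  expect_equal(as.numeric(p), as.numeric(compare_concordance_chisq(b, a)))
  # identical results: statistic 0, p = 1
  expect_equal(as.numeric(compare_concordance_chisq(a, a)), 1)
  expect_equal(attr(compare_concordance_chisq(a, a), "statistic"), 0)
  zero <- structure(list(index = 0, total = 0, n_pairs = 10),
                    class = "concordance_result")
  expect_error(compare_concordance_chisq(zero, zero), "degenerate")
})

test_that("cross-validation partitions into near-equal folds and is reproducible", {
  coh <- small_cohort(seed = 20, n = 83)
  r <- cross_validate(coh, "Clinical_Only", model = "cox", year = 5, seed = 2)
  folds <- attr(r, "folds")
  sizes <- table(folds)
  expect_equal(length(sizes), 5)
  expect_lte(max(sizes) - min(sizes), 1)
  r2 <- cross_validate(coh, "Clinical_Only", model = "cox", year = 5, seed = 2)
  expect_identical(r$index, r2$index)
  expect_identical(attr(r, "areas"), attr(r2, "areas"))
  # every patient receives exactly one out-of-fold prediction
  expect_false(anyNA(attr(r, "areas")))
})

test_that("zero-signal cohorts cross-validate at chance concordance", {
  idx <- sapply(1:5, function(s) {
    coh <- generate_cohort(cohort_spec(n_patients = 200, n_genes = 10,
                                       n_informative_genes = 2,
                                       gene_effects = 0, interaction_strength = 0,
                                       clinical_effects = numeric(0), seed = s))
    cross_validate(coh, "Clinical_Only", model = "cox", year = 5, seed = s)$index
  })
  expect_equal(mean(idx), 0.5, tolerance = 0.05)
})

test_that("injecting the true risk score never hurts relative to the clinical-only baseline", {
  wins <- 0L
  for (s in 1:10) {
    coh <- generate_cohort(cohort_spec(n_patients = 150, n_genes = 10,
                                       n_informative_genes = 3,
                                       gene_effects = 0.8, interaction_strength = 0,
                                       seed = s))
    z <- scale(coh$expression[, coh$truth$informative_indices])
    risk <- as.numeric(z %*% coh$truth$gene_effects)
    base <- cross_validate(coh, "Clinical_Only", model = "cox", year = 5, seed = s)$index
    coh2 <- coh
    coh2$clinical$risk_bin <- factor(equal_width_discretize(risk)$codes)
    with_risk <- cross_validate(coh2, "Clinical_Only", model = "cox", year = 5,
                                seed = s)$index
    wins <- wins + (with_risk > base)
  }
  # one-sided sign test at alpha = 0.05: >= 8 of 10 improvements
  expect_gte(wins, 8)
})

test_that("the experiment runner covers the grid schema deterministically", {
  coh <- small_cohort(seed = 22, n = 90, genes = 15)
  grid <- experiment_grid(years = 5, k_grid = 12, methods = c(1, 2),
                          seed = 3)
  res <- run_experiment(coh, grid, rsf_config = rsf_config(n_trees = 15, seed = 1))
  # Clinical_Only / Clinical_PAM: 2 models x 1 run; Clinical_Gene: 2 models x 2 methods
  expect_equal(nrow(res$results), 2 + 2 + 4)
  expect_true(all(res$results$concordance >= 0 & res$results$concordance <= 1))
  expect_true(all(is.na(res$results$k[res$results$variant != "Clinical_Gene"])))
  expect_equal(nrow(res$model_comparisons), 3)  # one Cox-vs-RSF row per variant
  expect_equal(nrow(res$variant_comparisons), 2)  # PAM and Gene vs Clinical_Only
  expect_true(all(res$model_comparisons$p_value >= 0 & res$model_comparisons$p_value <= 1))
  res2 <- run_experiment(coh, grid, rsf_config = rsf_config(n_trees = 15, seed = 1))
  expect_identical(res$results, res2$results)
})

test_that("a training fold with no events is reported with its fold number", {
  coh <- small_cohort(seed = 23, n = 30)
  coh$status <- rep("alive", 30)
  expect_error(cross_validate(coh, "Clinical_Only", model = "cox", year = 5, seed = 1),
               "fold 1")
})
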