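toy_features <- function(values, ordered = FALSE) {
  data.frame(x = factor(values, ordered = ordered))
}

test_that("log-rank split score matches hand computation and is symmetric", {
  # 4 patients, no censoring, disjoint event times: groups {10, 20} vs {30, 40}
  day <- c(10, 20, 30, 40)
  status <- rep("dead", 4)
  grp <- c(1, 1, 0, 0)
  # hand O-E: t=10 (Y=4,Y1=2): 1-0.5; t=20 (Y=3,Y1=1): 1-1/3; t=30 (Y=2,Y1=0): 0-0;
  # t=40: Y=1 no variance. O-E = 7/6
  # V: t=10: .5*.5*3/3=0.25; t=20: (1/3)(2/3)(2/2)=2/9; t=30..40: 0
  ome <- 7 / 6
  v <- 0.25 + 2 / 9
  expect_equal(log_rank_split_score(day, status, grp), ome / sqrt(v))
  expect_equal(log_rank_split_score(day, status, 1 - grp),
               log_rank_split_score(day, status, grp))
  # identical survival in both daughters: duplicated data, score 0
  expect_equal(log_rank_split_score(c(5, 9, 5, 9), c("dead", "dead", "dead", "dead"),
                                    c(1, 1, 0, 0)), 0)
  expect_error(log_rank_split_score(day, status, c(1, 1, 1, 1)), "non-empty")
})

test_that("log-rank score agrees with the reference chi-square on random data", {
  skip_if_not_installed("survival")
  for (s in 1:5) {
    set.seed(s)
    n <- 40
    day <- sample(1:500, n, TRUE)
    status <- ifelse(runif(n) < 0.3, "alive", "dead")
    grp <- sample(0:1, n, TRUE)
    if (sum(status == "dead") == 0 || length(unique(grp)) < 2) next
    score <- log_rank_split_score(day, status, grp)
    sd <- survival::survdiff(survival::Surv(day, status == "dead") ~ grp, rho = 0)
    expect_equal(score^2, unname(sd$chisq), tolerance = 1e-8)
  }
})

test_that("a root-only forest equals the bootstrap-averaged Nelson-Aalen estimator", {
  set.seed(21)
  n <- 40
  day <- sample(1:300, n, TRUE)
  status <- ifelse(runif(n) < 0.3, "alive", "dead")
  feats <- toy_features(sample(c("a", "b"), n, TRUE))
  fit <- fit_rsf(feats, day, status,
                 config = rsf_config(n_trees = 25, min_unique_deaths = 10000, seed = 3))
  pred <- predict_survival_curve_rsf(fit, feats[1, , drop = FALSE])
  ev <- as.integer(status == "dead")
  chf_trees <- sapply(seq_len(ncol(fit$inbag)), function(t) {
    brute_nelson_aalen(day, ev, fit$inbag[, t], fit$grid)
  })
  expect_equal(as.numeric(pred$surv[1, ]), as.numeric(exp(-rowMeans(chf_trees))),
               tolerance = 1e-10)
})

test_that("bootstrap samples exclude about 37% of patients on average", {
  set.seed(2)
  n <- 500
  day <- sample(1:300, n, TRUE)
  fit <- fit_rsf(toy_features(sample(c("a", "b"), n, TRUE)), day,
                 rep("dead", n),
                 config = rsf_config(n_trees = 100, min_unique_deaths = 10000, seed = 9))
  oob_frac <- mean(colMeans(fit$inbag == 0))
  expect_lt(abs(oob_frac - exp(-1)), 0.01)
})

test_that("fits are deterministic under a fixed seed", {
  coh <- small_cohort(seed = 14, n = 60)
  feats <- clinical_wo_subtype(coh)
  cfg <- rsf_config(n_trees = 20, seed = 31)
  a <- fit_rsf(feats, coh$day, coh$status, config = cfg)
  b <- fit_rsf(feats, coh$day, coh$status, config = cfg)
  pa <- predict_survival_curve_rsf(a, feats)
  pb <- predict_survival_curve_rsf(b, feats)
  expect_identical(pa$surv, pb$surv)
  expect_identical(a$inbag, b$inbag)
})

test_that("the ensemble CHF is the mean of per-tree CHFs", {
  coh <- small_cohort(seed = 15, n = 50)
  feats <- clinical_wo_subtype(coh)
  fit <- fit_rsf(feats, coh$day, coh$status, config = rsf_config(n_trees = 8, seed = 5))
  n <- nrow(feats)
  full <- survcompare:::rsf_chf(fit, feats)
  per_tree <- lapply(1:8, function(t) {
    mask <- matrix(0L, n, 8); mask[, t] <- 1L
    survcompare:::rsf_chf(fit, feats, use_tree = mask)$chf
  })
  expect_equal(full$chf, Reduce(`+`, per_tree) / 8, tolerance = 1e-12)
  # mean bound: ensemble within [min, max] across trees at every point
  mn <- Reduce(pmin, per_tree); mx <- Reduce(pmax, per_tree)
  expect_true(all(full$chf >= mn - 1e-12 & full$chf <= mx + 1e-12))
})

test_that("a dominant covariate orders the group survival curves", {
  set.seed(33)
  n <- 150
  g <- sample(c("low", "high"), n, TRUE)
  rate <- ifelse(g == "high", 0.01, 0.001)
  day <- ceiling(rexp(n, rate))
  status <- rep("dead", n)
  feats <- toy_features(g)
  fit <- fit_rsf(feats, day, status, config = rsf_config(n_trees = 50, seed = 7))
  pred <- predict_survival_curve_rsf(
    fit, data.frame(x = factor(c("high", "low"), levels = levels(feats$x))))
  # the high-rate group must lie at or below the low-rate group's curve
  expect_true(mean(pred$surv[1, ] <= pred$surv[2, ]) > 0.95)
  expect_true(all(pred$surv[, 1] <= 1 + 1e-12))
})

test_that("unseen factor levels are routed, never an error, at predict time", {
  coh <- small_cohort(seed = 16, n = 60)
  feats <- clinical_wo_subtype(coh)
  fit <- fit_rsf(feats, coh$day, coh$status, config = rsf_config(n_trees = 10, seed = 2))
  new <- feats[1:2, , drop = FALSE]
  new$grade <- factor(c("9", "1"), levels = c("1", "2", "3", "9"))
  pred <- predict_survival_curve_rsf(fit, new)
  expect_true(all(is.finite(pred$surv)))
})

test_that("out-of-bag error covers only out-of-bag patients and flags the rest", {
  coh <- small_cohort(seed = 17, n = 50)
  feats <- clinical_wo_subtype(coh)
  fit <- fit_rsf(feats, coh$day, coh$status, config = rsf_config(n_trees = 1, seed = 4))
  res <- oob_error(fit, feats, coh$day, coh$status)
  expect_identical(res$excluded, which(fit$inbag[, 1] > 0))
  expect_equal(res$error, 1 - res$concordance$index)
})

test_that("random survival forests round-trip through JSON", {
  coh <- small_cohort(seed = 18, n = 40)
  feats <- clinical_wo_subtype(coh)
  fit <- fit_rsf(feats, coh$day, coh$status, config = rsf_config(n_trees = 4, seed = 6))
  path <- withr::local_tempfile(fileext = ".json")
  write_rsf_fit(fit, path)
  back <- read_rsf_fit(path)
  expect_equal(predict_survival_curve_rsf(back, feats)$surv,
               predict_survival_curve_rsf(fit, feats)$surv,
               tolerance = 1e-12)
})

test_that("invalid forest configurations are rejected", {
  expect_error(rsf_config(n_trees = 0), "n_trees")
  expect_error(rsf_config(min_unique_deaths = 0), "min_unique_deaths")
  expect_error(fit_rsf(data.frame(x = 1:5), 1:5, rep("dead", 5)), "categorical")
})
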