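test_that("test-selection tree routes the canonical cases", {
  # rates frozen from a 200-replicate simulation of the tree's behaviour:
  # two standard normals route to t_eq ~88% (joint AD x2 + F non-rejection),
  # 9x variance routes to t_neq ~91%, shifted exponentials to mw ~83%
  set.seed(42)
  r_null <- replicate(40, select_test(rnorm(200), rnorm(200)))
  expect_gt(mean(r_null == "t_eq"), 0.7)
  r_var <- replicate(40, select_test(rnorm(200), rnorm(200, 0, 3)))
  expect_gt(mean(r_var == "t_neq"), 0.7)
  r_shift <- replicate(40, select_test(rexp(200), rexp(200) + 0.5))
  expect_gt(mean(r_shift == "mw"), 0.6)

  expect_error(select_test(rnorm(3), rnorm(10)), "at least 4")
  expect_warning(sc <- select_test(rep(1, 10), rnorm(10)), "constant")
  expect_identical(sc, "mw")
})

test_that("two_sample_p handles the printed-summary and degenerate cases", {
  # pooled t recomputed from printed group summaries (30 vs 29)
  res <- t_test_summary(1.89, 0.22, 30, 1.72, 0.24, 29)
  expect_equal(round(res$p, 2), 0.01)
  expect_equal(res$p, 0.00628, tolerance = 1e-3)

  x <- c(1.2, 3.4, 2.2, 5.1, 4.4)
  expect_equal(two_sample_p(x, x, "t_eq")$p, 1)
  expect_equal(two_sample_p(x, x, "t_neq")$p, 1)
  expect_equal(two_sample_p(rep(2, 5), rep(2, 6), "t_eq")$p, 1)

  # t from summaries == t from raw data realizing those summaries
  set.seed(1)
  raw <- rnorm(30)
  x1 <- 5 + 2 * (raw - mean(raw)) / stats::sd(raw)   # mean 5 sd 2 exactly
  raw2 <- rnorm(29)
  x2 <- 4 + 1.5 * (raw2 - mean(raw2)) / stats::sd(raw2)
  expect_equal(two_sample_p(x1, x2, "t_eq")$p,
               t_test_summary(5, 2, 30, 4, 1.5, 29)$p, tolerance = 1e-12)
  # and both agree with stats::t.test
  expect_equal(two_sample_p(x1, x2, "t_eq")$p,
               stats::t.test(x1, x2, var.equal = TRUE)$p.value,
               tolerance = 1e-12)
  expect_equal(two_sample_p(x1, x2, "t_neq")$p,
               stats::t.test(x1, x2)$p.value, tolerance = 1e-12)
})

test_that("Mann-Whitney p approximates the exact permutation p", {
  # fully separated 4v4 toy: exact two-sided p = 2/70, normal approx close
  x <- c(1, 2, 3, 4); y <- c(5, 6, 7, 8)
  p_norm <- two_sample_p(x, y, "mw")$p
  expect_lt(abs(p_norm - perm_mw_p(x, y)), 0.02)
  # the approximation stays moderate at this tiny n across random samples
  set.seed(9)
  d <- replicate(20, {
    a <- rnorm(4); b <- rnorm(4, 1.5)
    abs(two_sample_p(a, b, "mw")$p - perm_mw_p(a, b))
  })
  expect_lt(max(d), 0.15)
  # agreement with wilcox.test's tie-corrected normal approximation
  set.seed(10)
  a <- rnorm(30); b <- rnorm(29, 0.4)
  expect_equal(two_sample_p(a, b, "mw")$p,
               suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                                   correct = FALSE))$p.value,
               tolerance = 1e-12)
})

test_that("chi-square independence matches its algebraic identities", {
  res <- chi_square_independence(rbind(c(10, 10), c(10, 10)))
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)

  # printed medication-use counts: 10/30 vs 3/29 users
  res2 <- chi_square_independence(rbind(c(10, 20), c(3, 26)))
  expect_lte(res2$p, 0.05)
  expect_equal(round(res2$p, 2), 0.03)

  # 2x2 statistic equals the squared two-proportion z statistic
  tab <- rbind(c(12, 18), c(5, 24))
  n1 <- 30; n2 <- 29
  p1 <- 12 / n1; p2 <- 5 / n2; pp <- 17 / 59
  z <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  expect_equal(chi_square_independence(tab)$statistic, z^2, tolerance = 1e-12)

  expect_error(chi_square_independence(rbind(c(0, 0), c(3, 26))),
               "degenerate")
})

test_that("leave-k-out enumeration and orientation behave as defined", {
  # strongly separated samples: every resampled p significant -> fdr 0
  set.seed(2)
  x <- rnorm(30, 10); y <- rnorm(29)
  f <- leave_k_out_fdr(x, y, depths = 1)
  expect_equal(as.numeric(f), 0)
  expect_equal(attr(f, "n_subsets"), 59L)

  # null samples: essentially never significant -> fdr near 1
  set.seed(3)
  f0 <- leave_k_out_fdr(rnorm(30), rnorm(29), depths = 1)
  expect_gt(as.numeric(f0), 0.9)

  # borderline full-data p (0.042, seed 36): deletions flip significance
  set.seed(36)
  xb <- rnorm(30, 0.5); yb <- rnorm(29)
  fb <- leave_k_out_fdr(xb, yb, depths = 1)
  expect_gt(as.numeric(fb), 0)
  expect_lt(as.numeric(fb), 1)

  expect_error(leave_k_out_fdr(x, y, depths = 0), ">= 1")
  expect_error(leave_k_out_fdr(rnorm(10), rnorm(10), depths = 10), "smaller group")
  expect_error(leave_k_out_fdr(rnorm(4), rnorm(4), depths = 1), "too few")
})

test_that("leave-k-out fdr is invariant to relabeling within groups", {
  set.seed(4)
  x <- rnorm(12, 0.8); y <- rnorm(11)
  f1 <- leave_k_out_fdr(x, y, depths = c(1, 2))
  f2 <- leave_k_out_fdr(sample(x), sample(y), depths = c(1, 2))
  expect_equal(as.numeric(f1), as.numeric(f2))
})

test_that("roc_auc equals brute-force concordant-pair counting", {
  expect_equal(roc_auc(1:3, 1:3), 0.5)
  expect_equal(roc_auc(c(4, 5, 6), c(1, 2, 3)), 1)
  expect_equal(roc_auc(c(1, 2, 3), c(4, 5, 6)), 1)  # orientation >= 0.5

  brute_auc <- function(x, y) {
    s <- 0
    for (a in x) for (b in y) s <- s + (a > b) + 0.5 * (a == b)
    max(s, length(x) * length(y) - s) / (length(x) * length(y))
  }
  set.seed(5)
  for (rep in 1:5) {
    x <- round(rnorm(30), 1); y <- round(rnorm(29, 0.3), 1)  # forces ties
    expect_equal(roc_auc(x, y), brute_auc(x, y), tolerance = 1e-12)
  }
})

test_that("AUC equals trapezoidal integration of the empirical ROC", {
  set.seed(6)
  x <- round(rnorm(30, 0.5), 1); y <- round(rnorm(29), 1)
  thr <- sort(unique(c(x, y, -Inf, Inf)))
  # sweep thresholds in both orientations; the reported AUC is the larger
  tpr_lo <- vapply(thr, function(t) mean(x <= t), 0)  # "low value = positive"
  fpr_lo <- vapply(thr, function(t) mean(y <= t), 0)
  trap <- function(fpr, tpr) {
    o <- order(fpr, tpr)
    sum(diff(fpr[o]) * (utils::head(tpr[o], -1) + utils::tail(tpr[o], -1)) / 2)
  }
  a <- trap(fpr_lo, tpr_lo)
  expect_equal(roc_auc(x, y), max(a, 1 - a), tolerance = 1e-12)
})

test_that("run_screen assembles, sorts, and applies the joint rule", {
  g <- generate_cohort(small_config(seed = 13, n_features = 30,
                                    n_clusters = 1,
                                    cluster_size_range = c(5, 5),
                                    effect_ratio_range = c(0.5, 0.5),
                                    cv = 0.1))
  m <- impute_below_detection(g$cohort)
  sc <- run_screen(m, depths = 1)
  expect_s3_class(sc, "univariate_screen")
  expect_equal(nrow(sc), ncol(m$values))
  expect_true(!is.unsorted(rev(sc$auc)))          # AUC descending
  expect_identical(sc$significant,
                   sc$p <= 0.05 & sc$fdr <= 0.1)  # joint rule
  # a ratio-0.5 feature at cv 0.1 dominates the AUC ranking
  planted <- names(g$truth$true_ratio)[g$truth$true_ratio != 1]
  expect_true(sc$feature[1] %in% planted)
  expect_equal(sc$auc[1], 1)
  # binary genotype features are tested by chi-square
  expect_true(all(sc$scenario[grepl("mthfr", sc$feature)] == "chi2"))
  # ratio column is the ratio of group means
  j <- match(sc$feature[1], colnames(m$values))
  cmask <- m$groups == "ASD-M"
  expect_equal(sc$ratio[1],
               mean(m$values[cmask, j]) / mean(m$values[!cmask, j]))
})

test_that("an all-constant feature yields p = 1 and auc = 0.5", {
  X <- cbind(const = rep(3, 20), real = rlnorm(20))
  m <- toy_cohort(X, 10)
  sc <- run_screen(m, depths = 1)
  row <- sc[sc$feature == "const", ]
  expect_equal(row$p, 1)
  expect_equal(row$auc, 0.5)
  expect_false(row$significant)
})

test_that("unimputed censored cells are rejected by the screen", {
  X <- cbind(a = c(NA, 2, 4, 3, 5, 2, 4, 1))
  cen <- cbind(c(TRUE, rep(FALSE, 7)))
  m <- toy_cohort(X, 4, censored = cen)
  expect_error(run_screen(m), "impute_below_detection")
})

test_that("the internal AD normality test is calibrated and consistent", {
  # null calibration: p-values approximately uniform under normality
  set.seed(7)
  ps <- replicate(400, metpanel:::ad_normality(rnorm(30))$p)
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
  expect_lt(abs(mean(ps <= 0.05) - 0.05), 0.03)
  # power: strongly skewed samples are rejected nearly always
  ps2 <- replicate(100, metpanel:::ad_normality(rlnorm(50, sdlog = 1.2))$p)
  expect_gt(mean(ps2 <= 0.05), 0.9)
})
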