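test_that("fda_fit reduces to the scalar closed form on one feature", {
  set.seed(1)
  x <- matrix(rnorm(20, 2), ncol = 1); y <- matrix(rnorm(25, 0), ncol = 1)
  colnames(x) <- colnames(y) <- "f"
  mod <- fda_fit(x, y, standardize = FALSE)
  J_direct <- (mean(x) - mean(y))^2 / (stats::var(drop(x)) + stats::var(drop(y)))
  expect_equal(mod$J, J_direct, tolerance = 1e-12)
  expect_equal(unname(abs(mod$direction)), 1)
  # case group projects to the lower scores by sign convention
  expect_lt(mod$mean_scores[["case"]], mod$mean_scores[["control"]])
})

test_that("identical group means give J = 0 with a fallback direction", {
  Xc <- rbind(c(1, 2), c(3, 4), c(2, 3))
  Xt <- Xc[c(3, 1, 2), ]          # same rows, same column means
  colnames(Xc) <- colnames(Xt) <- c("a", "b")
  mod <- fda_fit(Xc, Xt)
  expect_equal(mod$J, 0)
  expect_equal(sum(mod$direction^2), 1)
})

test_that("the fitted direction attains the maximum of J (angle-grid oracle)", {
  # independent oracle: brute-force J over a dense grid of unit directions
  set.seed(2)
  n <- 500
  mu <- c(1, 0.5)
  S <- matrix(c(1, 0.6, 0.6, 2), 2)
  L <- chol(S)
  Xc <- matrix(rnorm(n * 2), n) %*% L + rep(mu, each = n)
  Xt <- matrix(rnorm(n * 2), n) %*% L
  colnames(Xc) <- colnames(Xt) <- c("a", "b")
  mod <- fda_fit(Xc, Xt)
  Jof <- function(p) {
    std <- list(center = mod$center, scale = mod$scale)
    t1 <- drop(metpanel:::.apply_standardizer(Xc, std) %*% p)
    t2 <- drop(metpanel:::.apply_standardizer(Xt, std) %*% p)
    (mean(t1) - mean(t2))^2 / (stats::var(t1) + stats::var(t2))
  }
  th <- seq(0, pi, length.out = 10000)
  Js <- vapply(th, function(a) Jof(c(cos(a), sin(a))), 0)
  best <- c(cos(th[which.max(Js)]), sin(th[which.max(Js)]))
  expect_gt(abs(sum(best * mod$direction)), 0.99)          # collinear
  expect_gte(mod$J + 1e-9, max(Js))                         # attains the max
})

test_that("FDA is scale-equivariant after standardization", {
  g <- gaussian_cohort(15, 15, p = 3, n_sig = 1, delta = 1.5, seed = 3)
  X <- g$values
  cm <- g$groups == "ASD-M"
  m1 <- fda_fit(X[cm, ], X[!cm, ])
  X2 <- X; X2[, 2] <- X2[, 2] * 10
  m2 <- fda_fit(X2[cm, ], X2[!cm, ])
  expect_equal(fda_scores(m1, X), fda_scores(m2, X2), tolerance = 1e-9)
  expect_equal(m1$J, m2$J, tolerance = 1e-9)
})

test_that("kde_boundary recovers Gaussian quantiles and is equivariant", {
  set.seed(4)
  s <- rnorm(1e4)
  expect_lt(abs(kde_boundary(s, 0.975) - stats::qnorm(0.975)), 0.06)
  # translation equivariance
  b <- kde_boundary(s, 0.9)
  expect_equal(kde_boundary(s + 3.7, 0.9), b + 3.7, tolerance = 1e-9)
  # near-total confidence pushes the boundary past the sample maximum
  s2 <- rnorm(200)
  expect_gte(kde_boundary(s2, 0.999), max(s2))
  # degenerate scores collapse to the common value
  expect_equal(kde_boundary(rep(2.5, 10), 0.9), 2.5)
  expect_error(kde_boundary(rnorm(3), 0.9), "at least 5")
  expect_error(kde_boundary(s2, 1), "confidence")
})

test_that("balance_confidence is optimal on its own grid and handles plateaus", {
  # overlapping scores: chosen level minimizes |typeI - typeII| (grid oracle)
  g <- gaussian_cohort(20, 20, p = 2, n_sig = 2, delta = 0.8, seed = 5)
  X <- g$values; cm <- g$groups == "ASD-M"
  mod <- fda_fit(X[cm, ], X[!cm, ])
  mod <- balance_confidence(mod, X[cm, ], X[!cm, ])
  t1 <- fda_scores(mod, X[cm, ]); t2 <- fda_scores(mod, X[!cm, ])
  grid <- seq(0.50, 0.99, by = 0.01)
  gaps <- vapply(grid, function(cf) {
    thr <- kde_boundary(t1, cf)
    abs(mean(t2 <= thr) - mean(t1 > thr))
  }, 0)
  achieved <- abs(mod$train_type1 - mod$train_type2)
  expect_lte(achieved, min(gaps) + 1e-9)
  # training confusion from classify() matches the balanced errors
  pred <- classify(mod, X)
  expect_equal(mean(pred$label[!cm] == "ASD-M"), mod$train_type1)
  expect_equal(mean(pred$label[cm] == "TD-M"), mod$train_type2)

  # perfectly separated scores: 0/0 plateau, smallest confidence wins
  gs <- gaussian_cohort(10, 10, p = 1, n_sig = 1, delta = 50, seed = 6)
  Xs <- gs$values; cms <- gs$groups == "ASD-M"
  ms <- fda_fit(Xs[cms, , drop = FALSE], Xs[!cms, , drop = FALSE])
  ms <- balance_confidence(ms, Xs[cms, , drop = FALSE], Xs[!cms, , drop = FALSE])
  expect_equal(ms$train_type1 + ms$train_type2, 0)
  plateau <- grid[vapply(grid, function(cf) {
    thr <- kde_boundary(fda_scores(ms, Xs[cms, , drop = FALSE]), cf)
    mean(fda_scores(ms, Xs[!cms, , drop = FALSE]) <= thr) == 0 &&
      mean(fda_scores(ms, Xs[cms, , drop = FALSE]) > thr) == 0
  }, NA)]
  expect_equal(ms$confidence, min(plateau))
})

test_that("logistic_fit covers separable, intercept-only, and recovery cases", {
  # perfect separation: ridge fallback, extreme but finite probabilities
  X <- matrix(c(1:10, 21:30), ncol = 1); colnames(X) <- "f"
  lab <- factor(rep(c("TD-M", "ASD-M"), each = 10), levels = c("ASD-M", "TD-M"))
  mod <- logistic_fit(X, lab)
  expect_true(mod$separable)
  pr <- logistic_prob(mod, X)
  expect_true(all(pr[11:20] >= 0.99) && all(pr[1:10] <= 0.01))
  expect_equal(sum((pr > 0.5) != (lab == "ASD-M")), 0)

  # no informative features: predicted probability = empirical prevalence
  X0 <- matrix(1, 59, 1); colnames(X0) <- "const"
  lab0 <- factor(rep(c("ASD-M", "TD-M"), c(30, 29)), levels = c("ASD-M", "TD-M"))
  expect_warning(m0 <- logistic_fit(X0, lab0), "constant")
  expect_equal(unique(round(logistic_prob(m0, X0), 10)), round(30 / 59, 10))

  # parameter recovery on data generated from a known logistic model
  set.seed(7)
  n <- 2000
  Xr <- cbind(x1 = rnorm(n), x2 = rnorm(n))
  eta <- 0.5 + 1.0 * Xr[, 1] - 0.7 * Xr[, 2]
  y <- stats::rbinom(n, 1, stats::plogis(eta)) == 1
  mr <- logistic_fit(Xr, y, standardize = FALSE)
  # exact agreement with the reference MLE, and truth inside 3 SE
  ref <- stats::glm(y ~ Xr, family = stats::binomial())
  expect_equal(unname(mr$coefficients), unname(stats::coef(ref)),
               tolerance = 1e-8)
  se <- sqrt(diag(stats::vcov(ref)))
  expect_true(all(abs(mr$coefficients - c(0.5, 1.0, -0.7)) < 3 * se))
})

test_that("classification tie rules are as documented", {
  # FDA: a score exactly on the boundary is labelled positive
  g <- gaussian_cohort(10, 10, p = 1, n_sig = 1, delta = 3, seed = 8)
  X <- g$values; cm <- g$groups == "ASD-M"
  mod <- fda_fit(X[cm, , drop = FALSE], X[!cm, , drop = FALSE])
  mod <- balance_confidence(mod, X[cm, , drop = FALSE], X[!cm, , drop = FALSE])
  # pin the boundary to a representable score value, then present a point
  # whose computed score is exactly that value
  x_at <- mod$boundary / mod$direction * mod$scale + mod$center
  mod$boundary <- fda_scores(mod, matrix(x_at, 1))   # bitwise-equal score
  expect_identical(classify(mod, matrix(x_at, 1))$label, "ASD-M")

  # logistic: probability exactly 0.5 goes to the negative class
  lmod <- structure(list(coefficients = c("(Intercept)" = 0, f = 1),
                         features = "f", center = 0, scale = 1,
                         separable = FALSE, positive_label = "ASD-M",
                         negative_label = "TD-M"),
                    class = "logistic_model")
  expect_identical(classify(lmod, matrix(0, 1))$label, "TD-M")
  expect_identical(classify(lmod, matrix(1, 1))$label, "ASD-M")
})

test_that("models round-trip through JSON export", {
  g <- gaussian_cohort(12, 12, p = 3, n_sig = 2, delta = 1, seed = 9)
  X <- g$values; cm <- g$groups == "ASD-M"
  mod <- fda_fit(X[cm, ], X[!cm, ])
  mod <- balance_confidence(mod, X[cm, ], X[!cm, ])
  path <- withr::local_tempfile(fileext = ".json")
  export_model(mod, path)
  back <- import_model(path)
  expect_equal(fda_scores(back, X), fda_scores(mod, X), tolerance = 1e-12)
  expect_identical(classify(back, X)$label, classify(mod, X)$label)

  lmod <- logistic_fit(X, g$groups)
  export_model(lmod, path)
  lback <- import_model(path)
  expect_equal(logistic_prob(lback, X), logistic_prob(lmod, X),
               tolerance = 1e-12)
})

test_that("logistic and FDA agree far from the boundary on separable data", {
  g <- gaussian_cohort(15, 15, p = 2, n_sig = 2, delta = 4, seed = 10)
  X <- g$values; cm <- g$groups == "ASD-M"
  fmod <- balance_confidence(fda_fit(X[cm, ], X[!cm, ]), X[cm, ], X[!cm, ])
  lmod <- logistic_fit(X, g$groups)
  expect_identical(classify(fmod, X)$label, classify(lmod, X)$label)
})
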