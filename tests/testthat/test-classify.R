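two_blob_data <- function(n = 20, d = 10, sd = 1, seed = 41) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(2 * n, 0, sd), n, 2),
             matrix(rnorm(2 * n, d, sd), n, 2))
  list(X = X, y = rep(c("p", "q"), each = n))
}

test_that("well-separated classes are learned perfectly and symmetrically", {
  dat <- two_blob_data()
  fit <- lda_fit(dat$X, dat$y)
  pred <- lda_predict(fit, dat$X)
  expect_equal(as.character(pred$labels), dat$y)
  expect_equal(rowSums(pred$posteriors), rep(1, 40), tolerance = 1e-12)

  # swapping the training labels swaps every prediction
  y_swap <- ifelse(dat$y == "p", "q", "p")
  pred2 <- lda_predict(lda_fit(dat$X, y_swap), dat$X)
  expect_equal(as.character(pred2$labels), y_swap)
})

test_that("posteriors equal brute-force Gaussian computation", {
  set.seed(42)
  X <- rbind(matrix(rnorm(60), 20, 3),
             matrix(rnorm(60, 1.2), 20, 3),
             matrix(rnorm(60, -1), 20, 3))
  y <- rep(c("a", "b", "c"), each = 20)
  fit <- lda_fit(X, y)
  Xn <- matrix(rnorm(30), 10, 3)
  post <- lda_predict(fit, Xn)$posteriors
  # oracle: shared-covariance Gaussian densities times priors
  dens <- sapply(fit$classes, function(cl) {
    mu <- fit$class_means[cl, ]
    apply(Xn, 1, function(x) {
      q <- -0.5 * t(x - mu) %*% fit$cov_inv %*% (x - mu)
      exp(q) * fit$priors[cl]
    })
  })
  dens <- dens / rowSums(dens)
  expect_equal(unname(post), unname(dens), tolerance = 1e-10)
})

test_that("predictions agree with an independent LDA implementation", {
  skip_if_not_installed("MASS")
  set.seed(43)
  X <- rbind(matrix(rnorm(80), 40, 2), matrix(rnorm(80, 1.5), 40, 2))
  y <- rep(c("a", "b"), each = 40)
  colnames(X) <- c("v1", "v2")
  fit <- lda_fit(X, y)
  ref <- MASS::lda(X, grouping = y, prior = c(0.5, 0.5))
  Xn <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("v1", "v2")))
  mine <- lda_predict(fit, Xn)
  theirs <- predict(ref, Xn)
  expect_equal(as.character(mine$labels), as.character(theirs$class))
  expect_equal(unname(mine$posteriors), unname(theirs$posterior),
               tolerance = 1e-6)
})

test_that("singular covariance triggers the ridge guard, not a crash", {
  set.seed(44)
  X <- cbind(rnorm(10), rnorm(10))
  X <- cbind(X, X[, 1] + X[, 2])  # exactly collinear third column
  y <- rep(c("a", "b"), each = 5)
  expect_warning(fit <- lda_fit(X, y), "ridge")
  expect_true(all(is.finite(fit$cov_inv)))
})

test_that("training is invariant to row order", {
  dat <- two_blob_data(n = 15, d = 3)
  set.seed(45)
  perm <- sample(30)
  f1 <- lda_fit(dat$X, dat$y)
  f2 <- lda_fit(dat$X[perm, ], dat$y[perm])
  expect_equal(f1$class_means, f2$class_means, tolerance = 1e-12)
  expect_equal(f1$pooled_cov, f2$pooled_cov, tolerance = 1e-12)
  a1 <- loocv_accuracy(dat$X, dat$y)$per_class
  a2 <- loocv_accuracy(dat$X[perm, ], dat$y[perm])$per_class
  expect_equal(a1, a2)
})

test_that("the fast LOOCV path equals the literal refit oracle", {
  set.seed(46)
  X <- rbind(matrix(rnorm(40, 0, 1.2), 10, 4),
             matrix(rnorm(40, 0.8), 10, 4))
  y <- rep(c("a", "b"), each = 10)
  fast <- loocv_accuracy(X, y, method = "downdate")
  slow <- loocv_accuracy(X, y, method = "refit")
  expect_identical(fast$predicted, slow$predicted)
  expect_equal(fast$per_class, slow$per_class)

  # and again with three unbalanced-ish classes and proportional priors
  X3 <- rbind(X, matrix(rnorm(24, -1), 6, 4))
  y3 <- c(y, rep("c", 6))
  expect_identical(loocv_accuracy(X3, y3, priors = "proportional")$predicted,
                   loocv_accuracy(X3, y3, priors = "proportional",
                                  method = "refit")$predicted)
})

test_that("LOOCV is perfect on separated data and chance-level on noise", {
  dat <- two_blob_data(n = 12, d = 20, sd = 0.5)
  expect_equal(unname(loocv_accuracy(dat$X, dat$y)$per_class), c(1, 1))

  set.seed(47)
  Xn <- matrix(rnorm(180), 90, 2)
  yn <- rep(c("a", "b", "c"), 30)
  acc <- loocv_accuracy(Xn, yn)$overall
  band <- qbinom(c(0.025, 0.975), 90, 1 / 3) / 90
  expect_gte(acc, band[1])
  expect_lte(acc, band[2])
})

test_that("balanced benchmarking subsamples over-represented classes only", {
  set.seed(48)
  feats <- data.frame(f1 = rnorm(90), f2 = rnorm(90))
  y <- rep(c("big", "small"), c(60, 30))
  feats$f1 <- feats$f1 + (y == "big") * 3
  b <- balanced_benchmark(feats, y, list(fs = c("f1", "f2")),
                          n_per_class = 30, n_perm = 5, seed = 1)
  expect_equal(nrow(b$accuracy), 5 * 2)
  expect_true(all(b$accuracy$accuracy >= 0 & b$accuracy$accuracy <= 1))
  # contract: every permutation trains on exactly 30 + 30
  idx <- seedmorph:::balance_indices(factor(y), 30)
  expect_length(idx, 60)
  expect_equal(sum(y[idx] == "small"), 30)

  b1 <- balanced_benchmark(feats, y, list(fs = c("f1", "f2")),
                           n_per_class = 30, n_perm = 1, seed = 9)
  b2 <- balanced_benchmark(feats, y, list(fs = c("f1", "f2")),
                           n_per_class = 30, n_perm = 1, seed = 9)
  expect_identical(b1$accuracy, b2$accuracy)
  expect_error(balanced_benchmark(feats, rep(c("a", "b"), c(89, 1)),
                                  list(fs = "f1"), seed = 1), ">= 2 rows")
  expect_error(balanced_benchmark(feats, y, list(fs = "nope"), seed = 1),
               "missing columns")
})

test_that("zero-separation classes score at chance in the benchmark", {
  set.seed(49)
  feats <- data.frame(f1 = rnorm(90), f2 = rnorm(90))
  y <- rep(c("a", "b", "c"), each = 30)
  b <- balanced_benchmark(feats, y, list(fs = c("f1", "f2")),
                          n_per_class = 30, n_perm = 30, seed = 2)
  overall <- mean(b$accuracy$accuracy)
  expect_gt(overall, 1 / 3 - 0.1)
  expect_lt(overall, 1 / 3 + 0.1)
})

test_that("the shuffled-label baseline sits above chance but below skill", {
  set.seed(50)
  feats <- data.frame(f1 = rnorm(90), f2 = rnorm(90))
  y <- rep(c("a", "b", "c"), each = 30)
  base <- shuffled_label_baseline(feats, y, c("f1", "f2"),
                                  n_per_class = 30, n_perm = 100, seed = 3)
  expect_length(base$max_accuracy, 100)
  expect_gt(base$overall_max, 1 / 3)
  expect_lt(base$overall_max, 0.75)

  b1 <- shuffled_label_baseline(feats, y, "f1", n_perm = 1, seed = 4)
  b2 <- shuffled_label_baseline(feats, y, "f1", n_perm = 1, seed = 4)
  expect_identical(b1$max_accuracy, b2$max_accuracy)

  # separated data: the real benchmark clears its own chance ceiling
  feats$f1 <- feats$f1 + c(a = 0, b = 6, c = 12)[y]
  real <- balanced_benchmark(feats, y, list(fs = c("f1", "f2")),
                             n_perm = 10, seed = 5)
  expect_gt(mean(real$accuracy$accuracy), base$overall_max)
})

test_that("unknown seeds are assigned by majority vote with full bookkeeping", {
  dat <- two_blob_data(n = 30, d = 12, sd = 1)
  feats <- data.frame(f1 = dat$X[, 1], f2 = dat$X[, 2])
  unk <- data.frame(f1 = c(0, 12), f2 = c(0, 12))  # at the class means
  res <- assign_unknowns(feats, dat$y, unk, c("f1", "f2"),
                         n_per_class = 30, n_perm = 20, seed = 6)
  expect_equal(res$assignments$predicted, c("p", "q"))
  expect_equal(res$assignments$vote_share, c(1, 1))
  expect_false(any(res$assignments$ambiguous))
  expect_true(all(rowSums(res$votes) == 20))
  expect_equal(as.numeric(res$composition), c(1, 1))
  expect_error(assign_unknowns(feats, dat$y, unk, c("f1", "zz"), seed = 1),
               "zz")
})

test_that("a 50/50 unknown mixture is recovered within the binomial band", {
  set.seed(51)
  n_u <- 34
  X <- rbind(matrix(rnorm(120, 0), 60, 2), matrix(rnorm(120, 4), 60, 2))
  y <- rep(c("a", "b"), each = 60)
  U <- rbind(matrix(rnorm(n_u, 0), n_u / 2, 2),
             matrix(rnorm(n_u, 4), n_u / 2, 2))
  feats <- data.frame(f1 = X[, 1], f2 = X[, 2])
  unk <- data.frame(f1 = U[, 1], f2 = U[, 2])
  res <- assign_unknowns(feats, y, unk, c("f1", "f2"), n_per_class = 30,
                         n_perm = 50, seed = 7)
  n_a <- as.numeric(res$composition["a"])
  band <- qbinom(c(0.025, 0.975), n_u, 0.5)
  expect_gte(n_a, band[1])
  expect_lte(n_a, band[2])
})

test_that("accuracy rises monotonically with synthetic class separation", {
  accs <- vapply(c(0.5, 1.5, 3), function(sep) {
    models <- default_taxon_models(sep)[c("setigerum", "somniferum", "nigrum")]
    pop <- simulate_population(models, noise_spec(0.08, 0.004, 0.008,
                                                  seed = 52),
                               render = FALSE)
    res <- resample_from_ldk2(pop)
    ali <- gpa_align(res, pop$landmarks[names(res)])
    cf <- coeff_matrix(lapply(ali$outlines, efourier, H = 8), H = 2)
    mean(loocv_accuracy(cf, pop$records$taxon)$per_class)
  }, numeric(1))
  expect_true(all(diff(accs) >= 0))
  expect_gt(accs[3], 0.9)
})
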