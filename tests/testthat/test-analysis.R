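makeToyTable <- function(n = 50, seed = 1) {
  set.seed(seed)
  data.frame(step_height = rnorm(n, 25, 1),
             stride_length = rnorm(n, 96, 2),
             cadence = rnorm(n, 2.5, 0.1),
             dragging_pct = pmax(0, rnorm(n, 2, 0.5)))
}

test_that("outlier removal drops exactly the constructed outlier", {
  df <- makeToyTable(50, seed = 2)
  df$step_height[17] <- 100 * median(df$step_height)
  out <- removeOutliers(df, 3.5)
  expect_equal(attr(out, "outliersRemoved"), 1L)
  expect_false(17 %in% as.integer(rownames(out)))
  # output rows are a subset of input rows, order preserved
  expect_true(all(diff(as.integer(rownames(out))) > 0))
  # identical rows: zero MAD everywhere, nothing dropped
  same <- data.frame(a = rep(1, 10), b = rep(2, 10))
  w <- capture_warnings(kept <- removeOutliers(same, 3.5))
  expect_length(w, 2)
  expect_match(w, "zero MAD", all = TRUE)
  expect_equal(nrow(kept), 10)
  expect_error(removeOutliers(df[0, ], 3.5), "empty")
})

test_that("random forest separates a separable two-group dataset perfectly", {
  cfgA <- gaitSimConfig(noiseSd = 1, seed = 100, duration = 3)
  cfgB <- gaitSimConfig(noiseSd = 1, stepHeight = 12.5, seed = 200,
                        duration = 3)
  ds <- generateGroupDataset(cfgA, cfgB, 3)
  res <- runRandomForest(ds, seed = 7)
  expect_equal(res@accuracy, 1.0)
  expect_equal(sum(res@importance), 1, tolerance = 1e-9)
  expect_equal(sum(res@confusion), res@testSize)
  expect_equal(sum(diag(res@confusion)) / sum(res@confusion),
               res@accuracy)
  # reproducible bit-for-bit at a fixed seed
  res2 <- runRandomForest(ds, seed = 7)
  expect_identical(res@accuracy, res2@accuracy)
  expect_identical(res@confusion, res2@confusion)
  expect_identical(res@importance, res2@importance)
})

test_that("randomized labels drive accuracy to chance", {
  df <- makeToyTable(120, seed = 5)
  set.seed(99)
  correct <- 0; total <- 0
  for (s in 1:20) {
    rand <- factor(sample(c("a", "b"), nrow(df), replace = TRUE))
    r <- runRandomForest(df, labels = rand, seed = s)
    correct <- correct + sum(diag(r@confusion))
    total <- total + r@testSize
  }
  ci <- qbinom(c(0.025, 0.975), total, 0.5)
  expect_gte(correct, ci[1])
  expect_lte(correct, ci[2])
})

test_that("the single informative feature ranks first in Gini importance", {
  set.seed(11)
  n <- 60
  df <- data.frame(noise1 = rnorm(n), noise2 = rnorm(n),
                   signal = c(rnorm(n / 2, -3), rnorm(n / 2, 3)),
                   noise3 = rnorm(n))
  labs <- factor(rep(c("a", "b"), each = n / 2))
  r <- runRandomForest(df, labels = labs, seed = 3)
  expect_equal(names(r@importance)[1], "signal")
  expect_equal(sum(r@importance), 1, tolerance = 1e-9)
})

test_that("random forest preconditions are enforced", {
  df <- makeToyTable(10)
  expect_error(runRandomForest(df, labels = factor(rep("a", 10))),
               "2 classes")
  expect_error(runRandomForest(df[1:4, ],
                               labels = factor(c("a", "a", "b", "b"))),
               "8 rows")
  # a class absent from the training split is reported
  labs <- factor(c(rep("a", 11), "b"))
  expect_error(runRandomForest(makeToyTable(12), labels = labs, seed = 1),
               "absent from the training split")
})

test_that("PCA matches an independent eigendecomposition oracle", {
  df <- makeToyTable(80, seed = 21)
  p <- runPCA(df)
  X <- as.matrix(df)
  ev <- eigen(cor(X), symmetric = TRUE)$values
  expect_lt(max(abs(p@explainedVar - ev / sum(ev))), 1e-8)
  # full reconstruction of the standardized data
  Z <- scale(X)
  expect_lt(max(abs(Z - p@scores %*% t(p@rotation))), 1e-8)
  # loadings are eigenvectors scaled by component sd; columns orthogonal
  G <- crossprod(p@rotation)
  expect_equal(G, diag(ncol(G)), tolerance = 1e-8, ignore_attr = TRUE)
  expect_true(all(diff(p@explainedVar) <= 1e-12))
  expect_equal(sum(p@explainedVar), 1, tolerance = 1e-9)
})

test_that("rank-1 data concentrates all variance on the first component", {
  set.seed(2)
  t <- rnorm(30)
  df <- data.frame(a = 2 * t, b = -t, c = 5 + 3 * t, d = rep(1, 30))
  expect_warning(p <- runPCA(df), "zero-variance")
  expect_equal(p@dropped, "d")
  expect_equal(p@explainedVar[1], 1.0, tolerance = 1e-9)
  expect_error(runPCA(df[1, , drop = FALSE]), "2 rows")
})

test_that("PCA scores are invariant to column-wise affine rescaling", {
  df <- makeToyTable(40, seed = 31)
  p1 <- runPCA(df)
  df2 <- df
  df2$step_height <- 100 * df2$step_height - 7
  df2$cadence <- df2$cadence / 50 + 2
  p2 <- runPCA(df2)
  for (k in seq_len(ncol(p1@scores))) {
    expect_equal(abs(p1@scores[, k]), abs(p2@scores[, k]),
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("top factor loadings rank by absolute weight with stable ties", {
  set.seed(12)
  t <- rnorm(40)
  df <- data.frame(step_height = 3 * t + rnorm(40, 0, 1e-3),
                   other = rnorm(40), more = rnorm(40))
  p <- runPCA(df)
  top <- topFactorLoadings(p, 1, 1)
  expect_equal(top$parameter, "step_height")
  # k = all parameters gives a permutation of every name
  all3 <- topFactorLoadings(p, 1, 3)
  expect_setequal(all3$parameter, names(df))
  expect_warning(topFactorLoadings(p, 1, 10), "truncated")
  expect_error(topFactorLoadings(p, 99, 1), "out of range")
})

test_that("shrinking the group effect shrinks held-out accuracy", {
  accs <- vapply(c(0.5, 0.9), function(frac) {
    cfgA <- gaitSimConfig(noiseSd = 1.5, seed = 300, duration = 3)
    cfgB <- gaitSimConfig(noiseSd = 1.5, stepHeight = 25 * frac,
                          seed = 400, duration = 3)
    ds <- generateGroupDataset(cfgA, cfgB, 2)
    mean(vapply(1:5, function(s)
      runRandomForest(ds, seed = s)@accuracy, numeric(1)))
  }, numeric(1))
  expect_gte(accs[1], accs[2] - 0.05)
})
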