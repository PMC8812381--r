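test_that("separable clouds decode perfectly and symmetrically", {
  d <- separableData(n = 40, V = 20, sep = 4, seed = 1)
  m <- trainLinearSvm(d$X, d$y)
  expect_equal(mean(predictLinear(m, d$X) == d$y), 1)
  cv <- crossValidate(d$X, d$y, k = 10, seed = 2)
  expect_equal(cv$meanAccuracy, 1)
  # flipped labels negate the hyperplane
  yFlip <- ifelse(d$y == "ATT", "IMG", "ATT")
  mFlip <- trainLinearSvm(d$X, yFlip)
  expect_equal(modelWeights(mFlip), -modelWeights(m), tolerance = 1e-6)
  expect_equal(modelIntercept(mFlip), -modelIntercept(m), tolerance = 1e-6)
})

test_that("duplicating every trial leaves the decision boundary unchanged", {
  d <- separableData(n = 30, V = 10, sep = 2, seed = 3)
  m1 <- trainLinearSvm(d$X, d$y)
  m2 <- trainLinearSvm(rbind(d$X, d$X), c(d$y, d$y))
  set.seed(4)
  probe <- matrix(rnorm(200 * 10), 200, 10)
  expect_equal(predictLinear(m1, probe), predictLinear(m2, probe))
})

test_that("training requires two classes and clean inputs", {
  d <- separableData(seed = 5)
  expect_error(trainLinearSvm(d$X, rep("ATT", nrow(d$X))), "two classes")
  Xna <- d$X
  Xna[1, 1] <- NA
  expect_error(trainLinearSvm(Xna, d$y), "missing values")
})

test_that("stratified folds preserve class balance (60 trials, 10 folds, 3 per class)", {
  set.seed(6)
  X <- matrix(rnorm(60 * 8), 60, 8)
  y <- rep(c("ATT", "IMG"), each = 30)
  cv <- crossValidate(X, y, k = 10, seed = 7)
  for (f in 1:10) {
    expect_equal(sum(cv$fold == f), 6L)
    expect_equal(sum(cv$fold == f & y == "ATT"), 3L)
  }
  expect_error(crossValidate(X, y, k = 40, seed = 1), "fewer than k")
})

test_that("label-independent features decode at chance on average", {
  set.seed(8)
  accs <- replicate(30, {
    X <- matrix(rnorm(40 * 10), 40, 10)
    y <- sample(rep(c("ATT", "IMG"), 20))
    crossValidate(X, y, k = 5)$meanAccuracy
  })
  expect_lt(abs(mean(accs) - 0.5), 0.05)
})

test_that("cross-validated accuracy is invariant to voxel order", {
  d <- separableData(n = 24, V = 12, sep = 1, seed = 9)
  a1 <- crossValidate(d$X, d$y, k = 4, seed = 10)$meanAccuracy
  a2 <- crossValidate(d$X[, sample(12)], d$y, k = 4, seed = 10)$meanAccuracy
  expect_equal(a1, a2, tolerance = 1e-8)
})

test_that("permutation test: strong signal gives the minimal add-one p-value", {
  d <- separableData(n = 30, V = 10, sep = 4, seed = 11)
  perm <- permutationTestAccuracy(d$X, d$y, k = 5, nPerm = 99, seed = 12)
  expect_equal(perm$observed, 1)
  expect_equal(perm$pValue, 1 / 100)
  expect_lt(abs(mean(perm$nullAccuracies) - 0.5), 0.06)
})

test_that("permutation test: indistinguishable features give p = 1", {
  # identical feature rows: every classifier predicts one class, so observed
  # and all null accuracies equal 0.5 exactly
  X <- matrix(1, 20, 4)
  y <- rep(c("ATT", "IMG"), 10)
  perm <- permutationTestAccuracy(X, y, k = 5, nPerm = 9, seed = 13)
  expect_equal(perm$observed, 0.5)
  expect_true(all(perm$nullAccuracies == 0.5))
  expect_equal(perm$pValue, 1)
})

test_that("permutation p-values are uniform under the null", {
  set.seed(14)
  nPerm <- 39L
  pvals <- replicate(150, {
    X <- matrix(rnorm(24 * 8), 24, 8)
    y <- sample(rep(c("ATT", "IMG"), 12))
    permutationTestAccuracy(X, y, k = 4, nPerm = nPerm)$pValue
  })
  # add-one p on a grid of 40 values; KS against uniform is approximate but
  # sensitive to calibration failures
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_gt(mean(pvals), 0.40)
  expect_lt(mean(pvals), 0.62)
})

test_that("fold-weight averaging equals the brute-force mean", {
  set.seed(15)
  models <- lapply(1:10, function(i)
    new("LinearModel", weights = rnorm(6), intercept = rnorm(1),
        labels = c("ATT", "IMG")))
  avg <- averageFoldWeights(models)
  W <- sapply(models, modelWeights)
  expect_equal(avg$weights, rowMeans(W))
  m <- models[[1]]
  expect_equal(averageFoldWeights(list(m, m))$weights, modelWeights(m))
  neg <- new("LinearModel", weights = -modelWeights(m),
             intercept = -m@intercept, labels = c("ATT", "IMG"))
  expect_equal(averageFoldWeights(list(m, neg))$weights, rep(0, 6))
  expect_error(averageFoldWeights(list()), "at least one")
})

test_that("group weight t-map matches closed-form arithmetic and flags zero variance", {
  W0 <- matrix(0, 5, 4)
  g0 <- groupWeightTtest(W0, gridDim = c(4, 1, 1))
  expect_equal(g0@tValues, rep(0, 4))
  W <- matrix(rnorm(35 * 8), 35, 8)
  g <- groupWeightTtest(W, gridDim = c(8, 1, 1))
  expect_equal(g@df, 34L)
  W3 <- cbind(c(1, 2, 3), c(2, 2, 2))
  g3 <- groupWeightTtest(W3, gridDim = c(2, 1, 1))
  expect_equal(g3@tValues[1], 2 * sqrt(3), tolerance = 1e-12)
  expect_true(is.infinite(g3@tValues[2]) && g3@tValues[2] > 0)
  expect_equal(g3@zeroVariance, c(FALSE, TRUE))
  expect_error(groupWeightTtest(W3[1:2, ]), "at least 3")
})

test_that("cluster extraction on constructed maps", {
  gd <- c(10L, 10L, 10L)
  t0 <- rep(0, 1000)
  expect_equal(thresholdClusters(t0, gridDim = gd)$sizes, integer(0))

  # one 201-voxel block: full 10x10 slabs of z = 1,2 plus one voxel at z = 3
  arr <- array(0, gd)
  arr[, , 1:2] <- 3
  arr[1, 1, 3] <- 3
  cl <- thresholdClusters(as.numeric(arr), tThresh = 1.7, minSize = 200,
                          gridDim = gd)
  expect_equal(cl$sizes, 201L)
  expect_equal(sum(cl$labels == 1), 201L)

  # two 150-voxel blocks separated by a sub-threshold gap: none survive
  arr2 <- array(0, gd)
  arr2[, , 1] <- 3          # 100 voxels
  arr2[, 1:5, 2] <- 3       # +50
  arr2[, , 9] <- 3
  arr2[, 1:5, 10] <- 3
  cl2 <- thresholdClusters(as.numeric(arr2), tThresh = 1.7, minSize = 200,
                           gridDim = gd)
  expect_equal(cl2$sizes, integer(0))

  # diagonal contact merges under 26- but not 6-connectivity
  arr3 <- array(0, c(4L, 4L, 1L))
  arr3[1:2, 1:2, 1] <- 3
  arr3[3:4, 3:4, 1] <- 3
  c26 <- thresholdClusters(as.numeric(arr3), tThresh = 1, minSize = 0,
                           connectivity = 26L, gridDim = c(4L, 4L, 1L))
  c6 <- thresholdClusters(as.numeric(arr3), tThresh = 1, minSize = 0,
                          connectivity = 6L, gridDim = c(4L, 4L, 1L))
  expect_equal(length(c26$sizes), 1L)
  expect_equal(length(c6$sizes), 2L)

  # negative sign picks up the mirrored clusters
  cneg <- thresholdClusters(-as.numeric(arr), tThresh = 1.7, minSize = 200,
                            sign = "negative", gridDim = gd)
  expect_equal(cneg$sizes, 201L)
  expect_error(thresholdClusters(t0, tThresh = -1, gridDim = gd),
               "non-negative")
})

test_that("decoding accuracy is non-decreasing in the generated signal amplitude", {
  accs <- vapply(c(0, 1.5, 4), function(a) {
    cfg <- tinyConfig(nVoxels = 64L, signalAmplitude = a, seed = 21L,
                      nTransferTrials = 6L)
    pats <- trialPatterns(simulateSubject(cfg))
    crossValidate(pats$training, k = 10, seed = 3)$meanAccuracy
  }, numeric(1))
  expect_true(all(diff(accs) >= 0))
  expect_gt(accs[3], 0.9)
})
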