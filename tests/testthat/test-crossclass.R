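# training clouds around the two prototypes plus transfer trials drawn from
# one prototype with configurable noise
protoTransferFixture <- function(V = 30L, nTrain = 40L, nTransfer = 30L,
                                 transferClass = "IMG", transferNoise = 0,
                                 seed = 1) {
  set.seed(seed)
  pA <- rnorm(V); pA <- pA / sqrt(sum(pA^2))
  pB <- rnorm(V); pB <- pB - sum(pB * pA) * pA; pB <- pB / sqrt(sum(pB^2))
  half <- nTrain %/% 2
  Xtr <- rbind(
    matrix(rnorm(half * V, sd = 0.2), half, V) + matrix(3 * pA, half, V, byrow = TRUE),
    matrix(rnorm(half * V, sd = 0.2), half, V) + matrix(3 * pB, half, V, byrow = TRUE)
  )
  ytr <- rep(c("ATT", "IMG"), each = half)
  proto <- if (transferClass == "IMG") pB else pA
  Xte <- matrix(rnorm(nTransfer * V, sd = transferNoise), nTransfer, V) +
    matrix(3 * proto, nTransfer, V, byrow = TRUE)
  list(Xtr = Xtr, ytr = ytr, Xte = Xte,
       outcomes = rep("correct", nTransfer))
}

test_that("a classifier trained on the prototypes labels pure-prototype transfer trials accordingly", {
  f <- protoTransferFixture(transferClass = "IMG")
  m <- fitFullModel(f$Xtr, y = f$ytr)
  expect_equal(predictTransfer(m, f$Xte), rep("IMG", 30))
  fA <- protoTransferFixture(transferClass = "ATT")
  mA <- fitFullModel(fA$Xtr, y = fA$ytr)
  expect_equal(predictTransfer(mA, fA$Xte), rep("ATT", 30))
  # refitting is deterministic
  m2 <- fitFullModel(f$Xtr, y = f$ytr)
  expect_identical(modelWeights(m), modelWeights(m2))
})

test_that("transfer prediction is shape-checked and symmetric", {
  f <- protoTransferFixture()
  m <- fitFullModel(f$Xtr, y = f$ytr)
  expect_length(predictTransfer(m, f$Xte), 30L)
  expect_error(predictTransfer(m, f$Xte[, 1:10]), "dimension mismatch")
  neg <- new("LinearModel", weights = -modelWeights(m),
             intercept = -m@intercept, labels = labelOrder(m))
  p1 <- predictTransfer(m, f$Xte)
  p2 <- predictTransfer(neg, f$Xte)
  expect_true(all(p1 != p2))
  # zero-weight model: every trial takes the deterministic tie-break label
  zm <- new("LinearModel", weights = rep(0, 30), intercept = 0,
            labels = c("ATT", "IMG"))
  expect_equal(predictTransfer(zm, f$Xte), rep("ATT", 30))
})

test_that("IMG proportion arithmetic and degenerate inputs", {
  expect_equal(imgProportion(rep("IMG", 5), rep("correct", 5)), 1)
  preds <- c(rep("IMG", 6), rep("ATT", 4), "IMG", "ATT")
  outc <- c(rep("correct", 10), "incorrect", "incorrect")
  expect_equal(imgProportion(preds, outc), 0.6)
  expect_error(imgProportion(c("IMG", "ATT"), c("incorrect", "incorrect")),
               "no correctly anticipated")
  expect_error(imgProportion("IMG", c("correct", "correct")), "length")
})

test_that("transfer permutation null is centred on chance with calibrated extremes", {
  f <- protoTransferFixture(transferClass = "IMG", transferNoise = 1.5,
                            seed = 2)
  res <- subjectPermutationNull(f$Xtr, f$Xte, y = f$ytr,
                                outcomes = f$outcomes, nPerm = 200,
                                seed = 3)
  expect_lt(abs(mean(nullDistribution(res)) - 0.5), 2 * 0.3 / sqrt(200) + 0.05)
  expect_gt(imgProportionOf(res), 0.8)
  # strong transfer signal beats every shuffled-label null: minimal add-one p
  expect_equal(pValue(res), 1 / 201)

  # observed at the floor: transfer trials are pure ATT, so every shuffled
  # null proportion is >= the observed 0
  fA <- protoTransferFixture(transferClass = "ATT", seed = 4)
  resA <- subjectPermutationNull(fA$Xtr, fA$Xte, y = fA$ytr,
                                 outcomes = fA$outcomes, nPerm = 49, seed = 5)
  expect_equal(imgProportionOf(resA), 0)
  expect_equal(pValue(resA), 1)
})

test_that("group proportion test matches closed-form arithmetic", {
  g <- groupProportionTest(c(0.6, 0.7, 0.8))
  expect_equal(g$t, 0.2 / (0.1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(g$df, 2L)
  g0 <- groupProportionTest(rep(0.5, 10))
  expect_equal(g0$t, 0)
  expect_equal(g0$p, 1)
  g35 <- groupProportionTest(runif(35, 0.3, 0.9))
  expect_equal(g35$df, 34L)
  gInf <- groupProportionTest(rep(0.7, 5))
  expect_true(is.infinite(gInf$t) && gInf$t > 0)
  expect_error(groupProportionTest(c(0.5, 0.6)), "at least 3")
  expect_error(groupProportionTest(c(0.5, 0.6, 1.2)), "\\[0, 1\\]")
})

test_that("significant-subject counting and its null calibration", {
  expect_equal(countSignificantSubjects(c(0.01, 0.2, 0.04), alpha = 0.05), 2)
  expect_equal(countSignificantSubjects(rep(1, 10)), 0)
  expect_error(countSignificantSubjects(c(0.5, 0)), "\\(0, 1\\]")

  # under the global null the expected count is alpha * n; with the add-one
  # p on a grid of 20 values and alpha = 0.05 only p = 1/20 rejects
  set.seed(6)
  nSub <- 40L
  pvals <- vapply(seq_len(nSub), function(s) {
    X <- matrix(rnorm(20 * 6), 20, 6)
    y <- sample(rep(c("ATT", "IMG"), 10))
    Xte <- matrix(rnorm(12 * 6), 12, 6)
    pValue(subjectPermutationNull(X, Xte, y = y,
                                  outcomes = rep("correct", 12),
                                  nPerm = 19L))
  }, numeric(1))
  count <- countSignificantSubjects(pvals, alpha = 0.05)
  expect_lte(abs(count - 0.05 * nSub), 5)
})

test_that("group assembly combines subject results coherently", {
  f <- protoTransferFixture(transferNoise = 2, seed = 7)
  res <- lapply(1:4, function(i)
    subjectPermutationNull(f$Xtr, f$Xte, y = f$ytr, outcomes = f$outcomes,
                           nPerm = 19, seed = i))
  g <- groupCrossClass(res)
  expect_s4_class(g, "CrossClassResult")
  st <- groupStats(g)
  expect_equal(st$df, 3L)
  expect_equal(st$mean, mean(vapply(res, imgProportionOf, numeric(1))))
  expect_true(st$nSignificant <= 4)
})
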