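makeConfounds <- function(nScans, seed = 1) {
  set.seed(seed)
  cf <- matrix(rnorm(nScans * 7, sd = 0.1), nScans, 7)
  colnames(cf) <- c(paste0("motion_", 1:6), "global_signal")
  cf
}

twoTrialEvents <- function(onsets = c(10, 30), durations = c(1.3, 1.4)) {
  data.frame(onset = onsets, duration = durations, trial_type = "ATT",
             run_id = 1L, miniblock_id = 1L,
             trial_id = seq_along(onsets), outcome = NA_character_)
}

test_that("design has one column per trial plus seven confounds", {
  ev <- twoTrialEvents()
  d <- buildDesignMatrix(ev, makeConfounds(60), nScans = 60, trS = 2)
  expect_equal(ncol(d@design), 9L)
  expect_equal(sum(d@roles == "trial"), 2L)
  expect_equal(d@trialIds[1:2], 1:2)
  expect_true(all(is.na(d@trialIds[3:9])))
})

test_that("short-duration trial column approaches a scaled shifted kernel", {
  ev <- twoTrialEvents(onsets = 10, durations = 0.4)
  hrf <- hrfParams()
  d <- buildDesignMatrix(ev, makeConfounds(50), nScans = 50, trS = 2, hrf = hrf)
  col <- d@design[, 1]
  scanTimes <- (0:49) * 2
  lag <- scanTimes - 10
  want <- numeric(50)
  ok <- lag >= 0 & lag <= hrf@kernelLengthS
  want[ok] <- doubleGammaHrf(seq(0, hrf@kernelLengthS, by = 0.01), hrf)[
    round(lag[ok] / 0.01) + 1]
  nz <- want != 0 | col != 0
  expect_gt(cor(col[nz], want[nz]), 0.995)
  # scaled by roughly the boxcar area (within one oversampling step)
  expect_lt(abs(max(col) / (0.4 * max(want)) - 1), 0.3)
})

test_that("trials overlapping within the HRF give correlated but distinct columns", {
  ev <- twoTrialEvents(onsets = c(10, 13), durations = c(1.3, 1.3))
  d <- buildDesignMatrix(ev, makeConfounds(50), nScans = 50, trS = 2)
  r <- cor(d@design[, 1], d@design[, 2])
  expect_gt(r, 0.2)
  expect_lt(r, 0.999)
})

test_that("design construction validates events and confounds", {
  expect_error(
    buildDesignMatrix(twoTrialEvents(onsets = c(10, 120)), makeConfounds(50),
                      nScans = 50, trS = 2),
    "trial_id 2")
  cf <- makeConfounds(50)
  expect_error(
    buildDesignMatrix(twoTrialEvents(), cf[, -7], nScans = 50, trS = 2),
    "global_signal")
  expect_error(
    buildDesignMatrix(twoTrialEvents(), cf[-1, ], nScans = 50, trS = 2),
    "one row per scan")
})
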