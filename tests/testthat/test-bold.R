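test_that("all generative amplitudes at zero give an all-zero run", {
  cfg <- tinyConfig(nVoxels = 27L, signalAmplitude = 0, driftAmplitude = 0,
                    noiseSd = 0)
  ev <- sampleEventSchedule("training", cfg, seed = 1)
  ev <- ev[ev$run_id == 1, ]
  run <- renderBold(ev, matrix(1, nrow(ev), 27), cfg, seed = 2)
  expect_true(all(boldSignal(run) == 0))
})

test_that("residual noise reproduces the configured AR(1) autocorrelation", {
  cfg <- tinyConfig(nVoxels = 5L, signalAmplitude = 0, driftAmplitude = 0,
                    noiseSd = 1.5, ar1Coef = 0.6)
  ev <- data.frame(onset = 10, duration = 1.3, trial_type = "ATT",
                   run_id = 1L, miniblock_id = 1L, trial_id = 1L,
                   outcome = NA_character_)
  run <- renderBold(ev, matrix(0, 1, 5), cfg, nScans = 12000L, seed = 3)
  Y <- boldSignal(run)
  # sample-autocorrelation oracle at long run length
  r1 <- mean(vapply(seq_len(ncol(Y)), function(v) {
    x <- Y[, v]
    cor(x[-1], x[-length(x)])
  }, numeric(1)))
  expect_lt(abs(r1 - 0.6), 0.03)
  expect_lt(abs(sd(as.numeric(Y)) - 1.5), 0.1)
})

test_that("single noise-free trial matches a direct convolution oracle", {
  cfg <- tinyConfig(nVoxels = 12L, signalAmplitude = 2, driftAmplitude = 0,
                    noiseSd = 0)
  onset <- 12.4
  dur <- 1.4
  ev <- data.frame(onset = onset, duration = dur, trial_type = "IMG",
                   run_id = 1L, miniblock_id = 1L, trial_id = 1L,
                   outcome = NA_character_)
  proto <- matrix(rnorm(12), 1, 12)
  hrf <- hrfParams()
  run <- renderBold(ev, proto, cfg, hrf = hrf, nScans = 40L, seed = 5)
  Y <- boldSignal(run)

  # independent oracle: brute-force Riemann convolution of the boxcar with
  # the kernel, evaluated directly at the scan times
  dt <- 0.01
  tFine <- seq(0, 80, by = dt)
  kern <- doubleGammaHrf(seq(0, hrf@kernelLengthS, by = dt), hrf)
  scanTimes <- (seq_len(40) - 1) * cfg@trS
  expectedCourse <- vapply(scanTimes, function(t) {
    u <- seq(onset, onset + dur, by = dt)
    lag <- t - u
    ok <- lag >= 0 & lag <= hrf@kernelLengthS
    sum(kern[round(lag[ok] / dt) + 1]) * dt
  }, numeric(1))
  for (v in c(1, 7)) {
    got <- Y[, v]
    want <- 2 * proto[1, v] * expectedCourse
    expect_gt(abs(cor(got, want)), 0.999)
    expect_lt(max(abs(got - want)), 0.05 * max(abs(want)) + 1e-8)
  }
})

test_that("events beyond the run raise an error naming the trial", {
  cfg <- tinyConfig(nVoxels = 8L)
  ev <- data.frame(onset = c(5, 500), duration = c(1.3, 1.3),
                   trial_type = "ATT", run_id = 1L, miniblock_id = 1L,
                   trial_id = c(1L, 99L), outcome = NA_character_)
  expect_error(renderBold(ev, matrix(0, 2, 8), cfg, nScans = 50L),
               "trial_id 99")
})

test_that("subject simulation is deterministic and stable under added subjects", {
  cfg <- tinyConfig(nVoxels = 27L, nSubjects = 2L)
  s1a <- simulateSubject(cfg, subject = 1L)
  s1b <- simulateSubject(cfg, subject = 1L)
  expect_identical(boldSignal(s1a@trainingRuns[[1]]),
                   boldSignal(s1b@trainingRuns[[1]]))
  expect_identical(s1a@truth, s1b@truth)
  # subject 1 is unchanged whether or not subject 2 is ever generated
  s2 <- simulateSubject(cfg, subject = 2L)
  s1c <- simulateSubject(cfg, subject = 1L)
  expect_identical(s1a@truth, s1c@truth)
  expect_false(identical(s1a@truth, s2@truth))
})
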