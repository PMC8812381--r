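# build a run + design pair from a noise-free forward model so OLS recovery
# can be checked exactly
noiselessRunAndDesign <- function(amp = 1.7, V = 12L, nScans = 80L, seed = 2) {
  cfg <- tinyConfig(nVoxels = V, signalAmplitude = amp, driftAmplitude = 0,
                    noiseSd = 0)
  ev <- data.frame(onset = c(10, 25, 50, 85), duration = c(1.3, 1.4, 1.2, 1.5),
                   trial_type = c("ATT", "IMG", "ATT", "IMG"),
                   run_id = 1L, miniblock_id = 1:4, trial_id = 1:4,
                   outcome = NA_character_)
  proto <- sampleConditionPatterns(cfg, seed = seed)
  run <- renderBold(ev, proto[ev$trial_type, ], cfg, nScans = nScans,
                    seed = seed)
  set.seed(seed)
  cf <- matrix(rnorm(nScans * 7, sd = 0.1), nScans, 7)
  colnames(cf) <- c(paste0("motion_", 1:6), "global_signal")
  design <- buildDesignMatrix(runEvents(run), cf, nScans = nScans, trS = 2)
  list(run = run, design = design, proto = proto, amp = amp)
}

test_that("noise-free OLS recovers the generating amplitudes at machine precision", {
  f <- noiselessRunAndDesign(amp = 1.7)
  tpd <- fitLsaGlm(f$run, f$design)
  beta <- S4Vectors::metadata(tpd)$beta # voxel x trial
  want <- 1.7 * t(f$proto[trialLabels(tpd), ])
  expect_equal(unname(beta), unname(want), tolerance = 1e-9)
  expect_equal(dim(zMatrix(tpd)), c(4L, 12L))
})

test_that("trial betas agree with an independent lm() fit per voxel", {
  f <- noiselessRunAndDesign()
  # add reproducible noise so the fit is non-trivial
  Y <- boldSignal(f$run) + matrix(rnorm(length(boldSignal(f$run)), sd = 0.5,
  ), nrow(boldSignal(f$run)))
  tpd <- fitLsaGlm(f$run, f$design, data = Y)
  beta <- S4Vectors::metadata(tpd)$beta
  for (v in c(1, 5)) {
    ref <- lm(Y[, v] ~ f$design@design)
    expect_equal(unname(beta[v, ]), unname(coef(ref)[2:5]), tolerance = 1e-8)
  }
})

test_that("z-statistics are calibrated under pure noise", {
  cfg <- tinyConfig(nVoxels = 200L, signalAmplitude = 0, driftAmplitude = 0,
                    noiseSd = 1, ar1Coef = 0)
  ev <- sampleEventSchedule("transfer",
                            tinyConfig(nTransferTrials = 60L), seed = 6)
  run <- renderBold(ev, matrix(0, 60, 200), cfg, seed = 7)
  nScans <- ncol(assay(run, "bold"))
  cf <- nuisance(run)
  design <- buildDesignMatrix(ev, cf, nScans = nScans, trS = 2)
  z <- zMatrix(fitLsaGlm(run, design)) # 60 x 200 = 12,000 values
  expect_lt(abs(mean(z)), 0.05)
  expect_lt(abs(sd(z) - 1), 0.05)
})

test_that("rank-deficient designs are rejected with the collinear columns named", {
  f <- noiselessRunAndDesign()
  d <- f$design
  d@design[, 2] <- d@design[, 1]
  expect_error(fitLsaGlm(f$run, d), "collinear")
})

test_that("condition mean patterns recover the generating prototypes at moderate SNR", {
  sh <- sharedSubjectPatterns() # signalAmplitude = 3, defaults otherwise
  z <- zMatrix(sh$pats$training)
  lab <- trialLabels(sh$pats$training)
  proto <- sh$study@prototypes
  for (cl in c("ATT", "IMG")) {
    m <- colMeans(z[lab == cl, ])
    expect_gt(cor(m, proto[cl, ]), 0.9)
  }
})

test_that("the generated drift band is almost entirely removed by the high-pass", {
  cfg <- tinyConfig(nVoxels = 27L, signalAmplitude = 0, noiseSd = 0,
                    driftAmplitude = 1.5)
  ev <- sampleEventSchedule("transfer", tinyConfig(nTransferTrials = 30L),
                            seed = 2)
  run <- renderBold(ev, matrix(0, 30, 27), cfg, seed = 3)
  Y <- boldSignal(run) # pure drift
  filt <- highpass(Y, cutoffS = 100, trS = 2)
  expect_lt(sd(as.numeric(filt)) / sd(as.numeric(Y)), 0.1)
})
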