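test_that("degenerate jitter intervals produce exact gaps", {
  cfg <- tinyConfig(itiRangeS = c(5, 5), breakRangeS = c(4, 4))
  ev <- sampleEventSchedule("training", cfg, seed = 1)
  for (r in unique(ev$run_id)) {
    er <- ev[ev$run_id == r, ]
    gaps <- er$onset[-1] - (er$onset[-nrow(er)] + er$duration[-nrow(er)])
    boundary <- diff(er$miniblock_id) != 0
    expect_equal(gaps[!boundary], rep(5, sum(!boundary)))
    expect_equal(gaps[boundary], rep(4, sum(boundary)))
  }
})

test_that("jittered gaps sit on the 0.1-s grid within their bounds and hit the design means", {
  cfg <- generatorConfig(nVoxels = 8, nTransferTrials = 9000L)
  ev <- sampleEventSchedule("transfer", cfg, seed = 7)
  gaps <- ev$onset[-1] - (ev$onset[-nrow(ev)] + ev$duration[-nrow(ev)])
  boundary <- diff(ev$miniblock_id) != 0
  itis <- gaps[!boundary]
  breaks <- gaps[boundary]
  expect_true(all(itis >= 2 - 1e-9 & itis <= 8 + 1e-9))
  expect_true(all(breaks >= 3 - 1e-9 & breaks <= 8 + 1e-9))
  expect_true(all(abs(itis * 10 - round(itis * 10)) < 1e-6))
  expect_true(all(abs(breaks * 10 - round(breaks * 10)) < 1e-6))
  # design means: 5.0 s intervals, 5.5 s breaks
  expect_lt(abs(mean(itis) - 5.0), 0.1)
  expect_lt(abs(mean(breaks) - 5.5), 0.1)
})

test_that("schedule structure: counts, ordering, durations, balance", {
  cfg <- tinyConfig(trialsPerMiniblock = 3L, miniblocksPerRun = 4L,
                    nTrainingRuns = 4L)
  ev <- sampleEventSchedule("training", cfg, seed = 3)
  expect_equal(nrow(ev), 48L)
  for (r in 1:4) {
    er <- ev[ev$run_id == r, ]
    expect_equal(nrow(er), 12L)
    expect_equal(as.integer(table(er$miniblock_id)), rep(3L, 4))
    expect_false(is.unsorted(er$onset, strictly = TRUE))
  }
  expect_true(all(ev$duration >= 1.2 & ev$duration <= 1.5))
  # balanced classes
  expect_equal(sum(ev$trial_type == "ATT"), sum(ev$trial_type == "IMG"))
  # AABB: first half of runs one instruction, second half the other
  expect_equal(unique(ev$trial_type[ev$run_id <= 2]), "ATT")
  expect_equal(unique(ev$trial_type[ev$run_id >= 3]), "IMG")
  evB <- sampleEventSchedule("training", tinyConfig(instructionOrder = "BBAA"),
                             seed = 3)
  expect_equal(unique(evB$trial_type[evB$run_id <= 2]), "IMG")
})

test_that("interleaved design mixes balanced labels within each run", {
  cfg <- tinyConfig(design = "interleaved")
  ev <- sampleEventSchedule("training", cfg, seed = 5)
  for (r in unique(ev$run_id)) {
    tab <- table(ev$trial_type[ev$run_id == r])
    expect_equal(length(tab), 2L)
    expect_equal(unname(tab[["ATT"]]), unname(tab[["IMG"]]))
  }
})

test_that("schedules are deterministic under a fixed seed and reject invalid ranges", {
  cfg <- tinyConfig()
  expect_identical(sampleEventSchedule("training", cfg, seed = 9),
                   sampleEventSchedule("training", cfg, seed = 9))
  expect_error(generatorConfig(itiRangeS = c(8, 2)), "exceeds upper bound")
})
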