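test_that("spike tables read back with counts, rosters and errors intact", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("u1,0.010", "u1,0.025", "u2,0.011"), f)
  sts <- readSpikeTable(f, duration = 0.1)
  expect_equal(unitIds(sts), c("u1", "u2"))
  expect_equal(lengths(spikeTimes(sts)), c(u1 = 2L, u2 = 1L))
  expect_equal(spikeTimes(sts)$u1, c(0.010, 0.025))

  ## declared roster keeps silent units
  writeLines(character(0), f)
  empty <- readSpikeTable(f, duration = 1, unitIds = "u1")
  expect_equal(nUnits(empty), 1L)
  expect_length(spikeTimes(empty)$u1, 0L)

  ## header auto-detection
  writeLines(c("unit_id,spike_time_s", "u1,0.5"), f)
  expect_equal(lengths(spikeTimes(readSpikeTable(f, duration = 1))),
               c(u1 = 1L))

  writeLines(c("u1,0.010", "u1,-0.5"), f)
  expect_error(readSpikeTable(f, duration = 1), "line 2.*negative")
  writeLines("u1,1.5", f)
  expect_error(readSpikeTable(f, duration = 1), "beyond duration")
  writeLines("u1,abc", f)
  expect_error(readSpikeTable(f, duration = 1), "unparsable")
  writeLines(c("u1,0.2", "u1,0.2"), f)
  expect_error(readSpikeTable(f, duration = 1), "duplicate")
})

test_that("write -> read round-trips spike times at microsecond precision", {
  set.seed(4)
  st <- lapply(setNames(1:4, paste0("u", 1:4)),
               function(i) sort(round(runif(50, 0, 9.99), 6)))
  sts <- SpikeTrainSet(st, duration = 10, condition = "BL")
  f <- withr::local_tempfile(fileext = ".csv")
  writeSpikeTable(sts, f)
  back <- readSpikeTable(f, duration = 10, condition = "BL",
                         unitIds = unitIds(sts))
  expect_equal(spikeTimes(back), spikeTimes(sts), tolerance = 1e-9)
})

test_that("binning places spikes on the half-open grid and conserves counts", {
  sts <- SpikeTrainSet(list(u1 = c(0.0005, 0.0015)), duration = 0.003)
  bc <- binSpikes(sts, 0.001)
  expect_equal(as.vector(counts(bc)), c(1L, 1L, 0L))

  ## one bin spanning the whole trial holds everything
  one <- binSpikes(sts, 0.003)
  expect_equal(nBins(one), 1L)
  expect_equal(sum(counts(one)), 2L)

  set.seed(11)
  big <- SpikeTrainSet(list(u1 = sort(sample(0:999999, 1000)) / 1e6),
                       duration = 1)
  expect_equal(sum(counts(binSpikes(big, 0.001))), 1000L)

  ## boundary spike lands in the bin to its right (half-open convention)
  edge <- SpikeTrainSet(list(u1 = 0.001), duration = 0.003)
  expect_equal(as.vector(counts(binSpikes(edge, 0.001))), c(0L, 1L, 0L))

  expect_error(binSpikes(sts, 0), "binWidth")
  expect_error(binSpikes(sts, 0.004), "duration")
})

test_that("rebinning at 2*width equals direct binning at 2*width", {
  set.seed(21)
  for (rep in 1:5) {
    st <- lapply(setNames(1:3, paste0("u", 1:3)),
                 function(i) sort(round(runif(200, 0, 1.9999), 6)))
    sts <- SpikeTrainSet(st, duration = 2)
    fine <- binSpikes(sts, 0.001)
    expect_equal(counts(rebinCounts(fine, 0.002)),
                 counts(binSpikes(sts, 0.002)))
    expect_equal(counts(rebinCounts(fine, 0.010)),
                 counts(binSpikes(sts, 0.010)))
  }
  ## zero-spike unit survives as an all-zero column
  sil <- SpikeTrainSet(list(u1 = 0.5), duration = 1, unitIds = c("u1", "u2"))
  expect_equal(colSums(counts(binSpikes(sil, 0.01))), c(u1 = 1, u2 = 0))
})

test_that("session manifests resolve condition files against one roster", {
  dir <- withr::local_tempdir()
  sets <- list()
  set.seed(31)
  for (cond in c("BL", "E", "BMI/E")) {
    st <- lapply(setNames(1:3, paste0("u", 1:3)),
                 function(i) sort(round(runif(20, 0, 4.9999), 6)))
    sets[[cond]] <- SpikeTrainSet(st, duration = 5, condition = cond)
  }
  writeSpikeTable(sets$BL, file.path(dir, "bl.csv"))
  writeSpikeTable(sets$E, file.path(dir, "e.csv"))
  writeSpikeTable(sets$`BMI/E`, file.path(dir, "bmi.csv"))
  yaml::write_yaml(list(session_id = "s9", duration = 5,
                        units = paste0("u", 1:3),
                        conditions = list(BL = "bl.csv", E = "e.csv",
                                          `BMI/E` = "bmi.csv")),
                   file.path(dir, "manifest.yaml"))
  sess <- readSessionManifest(file.path(dir, "manifest.yaml"))
  expect_named(sess, c("BL", "E", "BMI/E"))
  expect_equal(conditionLabel(sess$E), "E")
  expect_equal(spikeTimes(sess$BL), spikeTimes(sets$BL), tolerance = 1e-9)
  expect_error(readSessionManifest(file.path(dir, "nope.yaml")), "not found")
})
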