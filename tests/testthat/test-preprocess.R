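makeRecording <- function(nEeg = 22, nEog = 3, nSamp = 5000, fs = 250,
                          events = data.frame(sample = c(500, 2000),
                                              label = c(1, 2))) {
  k <- nEeg + nEog
  RawRecording(matrix(rnorm(k * nSamp), k), fs,
               channelKinds = c(rep("EEG", nEeg), rep("EOG", nEog)),
               events = events)
}

test_that("channel selection keeps EEG channels only, in order", {
  set.seed(1)
  rec <- makeRecording()
  out <- selectChannels(rec)
  expect_equal(nChannels(out), 22)
  expect_identical(out@data, rec@data[1:22, ])

  # no EOG channels: identity
  pure <- makeRecording(nEog = 0)
  expect_identical(selectChannels(pure)@data, pure@data)

  # all channels EOG: empty montage
  allEog <- RawRecording(matrix(rnorm(300), 3), 250,
                         channelKinds = rep("EOG", 3))
  expect_error(selectChannels(allEog), "montage")
})

test_that("band-pass preserves the pass band and rejects the stop band", {
  fs <- 250
  tt <- (0:4999) / fs
  inband <- RawRecording(matrix(sin(2 * pi * 20 * tt), 1), fs)
  out <- bandpass(inband, 8, 30)
  expect_gte(stats::var(out@data[1, ]), 0.9 * stats::var(inband@data[1, ]))

  stopband <- RawRecording(matrix(sin(2 * pi * 50 * tt), 1), fs)
  out2 <- bandpass(stopband, 8, 30)
  expect_lte(stats::var(out2@data[1, ]), 0.01 * stats::var(stopband@data[1, ]))

  zero <- RawRecording(matrix(0, 1, 5000), fs)
  expect_equal(bandpass(zero)@data, zero@data)

  expect_error(bandpass(inband, 8, 130), "fs/2")
})

test_that("epoch extraction uses the half-open post-cue window", {
  fs <- 250
  # channel 1 carries the global sample index so windows are verifiable
  rec <- RawRecording(rbind(1:5000, rnorm(5000)), fs,
                      events = data.frame(sample = c(100, 1000),
                                          label = c(1, 2)))
  es <- extractEpochs(rec, 0.5, 3.5)
  expect_equal(nTrials(es), 2)
  expect_equal(dim(epochData(es))[3], 750)
  # first sample = cue + 0.5 s, last = cue + 3.5 s - one sample
  expect_equal(epochData(es)[1, 1, 1], 100 + 125)
  expect_equal(epochData(es)[1, 1, 750], 100 + 125 + 749)
  expect_equal(trialLabels(es), c(1, 2))

  # out-of-range event names the offender
  bad <- RawRecording(matrix(rnorm(1000), 1), fs,
                      events = data.frame(sample = 900, label = 1))
  expect_error(extractEpochs(bad, 0.5, 3.5), "event 1")

  # zero events are allowed for scaffolding
  none <- RawRecording(matrix(rnorm(1000), 1), fs)
  expect_equal(nTrials(extractEpochs(none, 0.5, 3.5)), 0)
})

test_that("the composed pipeline runs in stage order and rejects epoched input", {
  set.seed(2)
  rec <- makeRecording()
  es <- preprocessRecording(rec)
  expect_s4_class(es, "EpochSet")
  expect_equal(nChannels(es), 22)    # EOG dropped before filtering
  expect_equal(dim(epochData(es))[3], 750)
  expect_error(preprocessRecording(es), "already epoched")
})

test_that("epoch and raw containers round-trip through the text format", {
  set.seed(3)
  cfg <- SyntheticConfig(nSubjects = 1, nTrialsPerClass = 3, nChannels = 4,
                         trialDuration = 0.5, betaBand = c(13, 30), seed = 9)
  es <- generateSubject(cfg, 1)
  pre <- file.path(withr::local_tempdir(), "epochs")
  writeEpochSet(es, pre)
  back <- readEpochSet(pre)
  expect_equal(epochData(back), epochData(es), tolerance = 1e-12)
  expect_equal(trialLabels(back), trialLabels(es))
  expect_equal(samplingRate(back), samplingRate(es))

  rec <- makeRecording(nEeg = 3, nEog = 1, nSamp = 400)
  pre2 <- file.path(withr::local_tempdir(), "raw")
  writeRawRecording(rec, pre2)
  rback <- readRawRecording(pre2)
  expect_equal(rback@data, rec@data, tolerance = 1e-12)
  expect_equal(rback@channelKinds, rec@channelKinds)
  expect_equal(rback@events$sample, rec@events$sample)
  expect_error(readEpochSet(pre2), "does not hold epochs")
})
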