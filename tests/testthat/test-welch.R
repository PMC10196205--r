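test_that("segmentation counts and boundaries follow the overlap rule", {
  x <- rnorm(750)
  cfg0 <- WelchConfig(segmentLength = 250, overlap = 0)
  segs <- segmentSignal(x, cfg0)
  expect_length(segs, 3)
  expect_equal(segs[[2]], x[251:500])

  segs5 <- segmentSignal(x, WelchConfig(segmentLength = 250, overlap = 0.5))
  expect_length(segs5, 5)
  expect_equal(segs5[[2]], x[126:375])

  one <- segmentSignal(x[1:250], cfg0)
  expect_length(one, 1)
  expect_equal(one[[1]], x[1:250])

  expect_error(segmentSignal(x[1:100], cfg0), "shorter")
})

test_that("a bin-aligned sinusoid concentrates its power in its own bin", {
  fs <- 250
  x <- sin(2 * pi * 10 * (0:249) / fs)
  cfg <- WelchConfig(segmentLength = 250, windowKind = "rectangular", fs = fs)
  per <- windowedPeriodogram(x, cfg)
  expect_equal(per$freq[which.max(per$power)], 10)
  # essentially all non-DC power sits in the 10 Hz bin
  expect_gt(per$power[per$freq == 10] / sum(per$power[-1]), 1 - 1e-10)
  # the bin integrates to the sinusoid's mean power (1/2)
  expect_equal(per$power[per$freq == 10] * fs / 250, 0.5, tolerance = 1e-10)

  expect_equal(windowedPeriodogram(numeric(250), cfg)$power, rep(0, 126))
  expect_error(windowedPeriodogram(x[1:100], cfg), "segment length")
})

test_that("window-power normalization keeps the white-noise level taper-independent", {
  set.seed(5)
  lvl <- function(kind) {
    mean(replicate(100, {
      x <- rnorm(250)
      mean(windowedPeriodogram(x, WelchConfig(windowKind = kind))$power)
    }))
  }
  rectLevel <- lvl("rectangular")
  expect_equal(lvl("hamming"), rectLevel, tolerance = 0.05)
  expect_equal(lvl("hann"), rectLevel, tolerance = 0.05)
})

test_that("welchPsd equals the independently coded averaged-periodogram oracle", {
  set.seed(6)
  for (rep in 1:50) {
    x <- rnorm(sample(500:1000, 1))
    cfg <- WelchConfig(segmentLength = 200, overlap = sample(c(0, 0.5), 1),
                       windowKind = sample(c("rectangular", "hamming"), 1))
    got <- welchPsd(x, cfg)
    w <- if (cfg@windowKind == "rectangular") rep(1, 200) else
      0.54 - 0.46 * cos(2 * pi * (0:199) / 199)
    expect_equal(got$power,
                 oracleWelch(x, 200, 250, w, cfg@overlap), tolerance = 1e-10)
  }
  # deterministic input, identical segments: average equals one periodogram
  seg <- sin(2 * pi * 5 * (0:249) / 250)
  x3 <- rep(seg, 3)
  cfg <- WelchConfig(segmentLength = 250, windowKind = "hamming")
  expect_equal(welchPsd(x3, cfg)$power, windowedPeriodogram(seg, cfg)$power,
               tolerance = 1e-12)
})

test_that("the PSD integrates to the signal variance and averaging reduces variance", {
  set.seed(7)
  cfg <- WelchConfig(segmentLength = 250, windowKind = "rectangular")
  # Parseval: sum(power) * df recovers the mean power of white noise
  tot <- replicate(200, {
    x <- rnorm(750)
    sum(welchPsd(x, cfg)$power) * 250 / 250
  })
  expect_equal(mean(tot), 1, tolerance = 0.02)

  # 4-segment estimates fluctuate less than single-segment estimates
  est <- function(n) replicate(200, {
    x <- rnorm(250 * n)
    mean(welchPsd(x, cfg)$power)
  })
  expect_lt(stats::var(est(4)), stats::var(est(1)))
})

test_that("band features isolate rhythm power per channel and band", {
  fs <- 250
  tt <- (0:749) / fs
  # channel 1: mu-band tone; channel 2: beta-band tone
  trial <- rbind(sin(2 * pi * 10 * tt), sin(2 * pi * 20 * tt))
  es <- epochsFromTrials(list(trial, trial), c(1, 2), fs)
  bf <- bandFeatures(es, WelchConfig(windowKind = "rectangular"))
  v <- featureValues(bf)
  expect_equal(dim(v), c(2, 4))
  expect_gt(v[1, 1], 100 * v[1, 2])   # ch1: mu >> beta
  expect_gt(v[1, 4], 100 * v[1, 3])   # ch2: beta >> mu
  expect_equal(v[1, ], v[2, ])        # identical trials, identical rows
  expect_true(all(v >= 0))

  expect_error(
    bandFeatures(es, WelchConfig(segmentLength = 16), list(c(8, 12))),
    "lengthen")
})
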