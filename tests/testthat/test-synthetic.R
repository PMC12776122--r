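test_that("power-law synthesis recovers the programmed exponent (Welch oracle)", {
  set.seed(11)
  for (x in c(0.5, 2)) {
    sl <- mean(replicate(8, welchSlope(synthPowerLawEpoch(x, 512, 2^15), 512)))
    expect_lt(abs(sl - (-x)), 0.1)
  }
  # white-noise limit: flat spectrum
  slWhite <- mean(replicate(8, welchSlope(synthPowerLawEpoch(0, 512, 2^15), 512)))
  expect_lt(abs(slWhite), 0.05)
})

test_that("a step exponent profile produces split-half slopes near each level", {
  set.seed(12)
  sl1 <- sl2 <- numeric(6)
  for (i in 1:6) {
    sig <- synthPowerLawEpoch(c(rep(1, 8192), rep(3, 8192)), 512, 16384)
    sl1[i] <- welchSlope(sig[1:8192], 512)
    sl2[i] <- welchSlope(sig[8193:16384], 512)
  }
  expect_lt(abs(mean(sl1) + 1), 0.2)
  expect_lt(abs(mean(sl2) + 3), 0.2)
})

test_that("synthesis validates its arguments", {
  expect_error(synthPowerLawEpoch(2, fs = -1, nSamples = 1024), "fs")
  expect_error(synthPowerLawEpoch(2, fs = 512, nSamples = 32), "nSamples")
  expect_error(synthPowerLawEpoch(5, fs = 512, nSamples = 1024), "exponent")
  expect_error(synthPowerLawEpoch(-0.5, fs = 512, nSamples = 1024), "exponent")
  expect_error(synthPowerLawEpoch(rep(1, 10), fs = 512, nSamples = 1024),
               "every sample")
})

test_that("signals are zero-mean and unit-scale", {
  sig <- synthPowerLawEpoch(1.5, 512, 4096, seed = 5)
  expect_lt(abs(mean(sig)), 1e-10)
  expect_lt(abs(sd(sig) - 1), 0.05)
})

test_that("dataset generation is deterministic in config + seed", {
  cfg <- tinyConfig()
  a <- generateEEGDataset(cfg, seed = 42)
  b <- generateEEGDataset(cfg, seed = 42)
  expect_identical(epochData(a$epochs), epochData(b$epochs))
  expect_identical(a$trials, b$trials)
  c <- generateEEGDataset(cfg, seed = 43)
  expect_false(identical(epochData(a$epochs), epochData(c$epochs)))
})

test_that("trial sequences are lag-consistent and exactly balanced per cell", {
  cfg <- simConfig(nParticipants = 3, nTrialsPerCell = 7, nBlocks = 2)
  tt <- generateBehaviorTable(cfg, seed = 9)
  for (p in unique(tt$participant)) for (b in unique(tt$block)) {
    sub <- tt[tt$participant == p & tt$block == b, ]
    expect_true(is.na(sub$prev[1]))
    expect_identical(sub$prev[-1], sub$curr[-nrow(sub)])
    tab <- table(sub$prev, sub$curr)
    expect_true(all(tab == 7))
  }
})

test_that("zero-noise behavior reproduces programmed cell means exactly", {
  cfg <- tinyConfig(nParticipants = 2, nTrialsPerCell = 4,
                    rtSdWithin = 0, rtSdParticipant = 0)
  tt <- generateBehaviorTable(cfg, seed = 3)
  tt <- tt[!is.na(tt$prev), ]
  key <- paste0(substr(tt$prev, 1, 1), toupper(substr(tt$curr, 1, 1)))
  got <- tapply(tt$rt, key, mean)
  expect_equal(got[names(cfg@rtModel)], cfg@rtModel,
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("degenerate config gives a pure power-law process per channel", {
  cfg <- tinyConfig(nParticipants = 1, nTrialsPerCell = 2, alphaAmp = 0,
                    erpAmp = c(congruent = 0, incongruent = 0), noiseSd = 0,
                    exponentSdParticipant = 0,
                    exponentEffects = data.frame(prev = character(),
                                                 curr = character(),
                                                 region = character(),
                                                 start = numeric(),
                                                 end = numeric(),
                                                 delta = numeric()))
  ds <- generateEEGDataset(cfg, seed = 21)
  # peak-weight channel of the occipital source is nearly pure 1/f^1.5
  ch <- which.max(sourceWeights(cfg@layout)[, "occipital"])
  sig <- as.vector(t(epochData(ds$epochs)[, ch, ]))
  sl <- welchSlope(sig, 512, seg = 1024)
  expect_lt(abs(sl - (-1.5)), 0.3)
})

test_that("the 10 Hz oscillation stays out of the 2.5/5/25 Hz bins", {
  cfgOn <- tinyConfig(nParticipants = 1, nTrialsPerCell = 3, alphaAmp = 4)
  cfgOff <- tinyConfig(nParticipants = 1, nTrialsPerCell = 3, alphaAmp = 0)
  on <- generateEEGDataset(cfgOn, seed = 8)
  off <- generateEEGDataset(cfgOff, seed = 8)
  ch <- which.max(sourceWeights(cfgOn@layout)[, "occipital"])
  binPower <- function(x, f) {
    n <- length(x)
    Mod(stats::fft(x)[round(f * n / 512) + 1])^2
  }
  for (f in c(2.5, 5, 25)) {
    pOn <- mean(sapply(1:nTrials(on$epochs), function(i)
      binPower(epochData(on$epochs)[i, ch, ], f)))
    pOff <- mean(sapply(1:nTrials(off$epochs), function(i)
      binPower(epochData(off$epochs)[i, ch, ], f)))
    expect_lt(abs(pOn - pOff) / pOff, 0.01)
  }
  # while the 10 Hz bin itself gains the oscillation
  p10On <- mean(sapply(1:nTrials(on$epochs), function(i)
    binPower(epochData(on$epochs)[i, ch, ], 10)))
  p10Off <- mean(sapply(1:nTrials(off$epochs), function(i)
    binPower(epochData(off$epochs)[i, ch, ], 10)))
  expect_gt(p10On / p10Off, 2)
})

test_that("ground truth round-trips the programmed exponent shifts", {
  cfg <- tinyConfig()
  ds <- generateEEGDataset(cfg, seed = 2)
  tm <- c(-200, 50, 500, 1400)
  # frontal source, CSE cell: baseline + stimulus shift + frontal delta
  x <- trueExponent(ds$truth, "congruent", "incongruent", "frontal", tm)
  expect_equal(x, c(1.5, 1.5, 1.5 + 0.25 + 0.3, 1.5))
  # central source never receives the frontal delta
  x2 <- trueExponent(ds$truth, "congruent", "incongruent", "central", tm)
  expect_equal(x2, c(1.5, 1.5, 1.75, 1.5))
})

test_that("invalid configurations are refused", {
  expect_error(simConfig(baselineExponent = 3.9), "0, 4")
  expect_error(simConfig(rtModel = c(cC = -5, cI = 600, iC = 600, iI = 600)),
               "positive")
  expect_error(simConfig(accuracyModel = c(cC = 1, cI = 0, iC = 0, iI = 0)),
               "probabilities")
  badLayout <- scalpLayout()
  badLayout$region <- "frontal"
  expect_error(simConfig(layout = badLayout), "occipital")
})
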