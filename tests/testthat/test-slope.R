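test_that("one-cycle wavelet pairs are quadrature, zero-mean, length round(fs/f)", {
  for (f in c(2.5, 5, 7.5, 15, 25)) {
    p <- waveletPair(f, 512)
    expect_equal(p$length, round(512 / f))
    expect_lt(abs(sum(p$sin)), 1e-12)
    expect_lt(abs(sum(p$cos)), 1e-12)
    expect_lt(abs(sum(p$cos * p$sin)), 1e-12)
  }
})

test_that("frequency grid validates and masks the alpha-adjacent band", {
  g <- frequencyGrid()
  expect_equal(g$freqs, c(2.5, 5, 7.5, 15, 25))
  expect_equal(g$freqs[g$fitMask], c(2.5, 5, 25))
  expect_error(frequencyGrid(c(5, 2.5)), "increasing")
  expect_error(frequencyGrid(c(2.5, 5), fitMask = c(TRUE, FALSE)), "two")
})

test_that("wavelet power responds as the single-cycle DFT oracle dictates", {
  fs <- 512; n <- 1024
  t <- (0:(n - 1)) / fs
  g <- frequencyGrid()
  ep <- eegEpochs(array(sin(2 * pi * 5 * t), c(1, 1, n)), fs, tmin = 0)
  p <- waveletPower(ep, g, normalize = "amplitude")
  # matched 5 Hz kernel: unit sinusoid -> power ~ 1 at interior samples
  expect_lt(abs(p[1, 1, 2, 512] - 1), 0.02)
  # cross-response at 25 Hz equals the direct windowed DFT coefficient
  pair <- waveletPair(25, fs)
  mid <- 512
  idx <- (mid - (pair$length - 1) %/% 2):(mid + pair$length %/% 2)
  x <- sin(2 * pi * 5 * t)[idx]
  oracle <- sum(pair$cos * x)^2 + sum(pair$sin * x)^2
  expect_equal(p[1, 1, 5, mid], oracle, tolerance = 1e-8)
  # DC input: zero-mean kernels -> no power
  epd <- eegEpochs(array(7, c(1, 1, n)), fs, tmin = 0)
  pd <- waveletPower(epd, g, normalize = "amplitude")
  expect_lt(max(pd[1, 1, , 300:700]), 1e-20)
  # amplitude-A sinusoid scales power by A^2
  epA <- eegEpochs(array(3 * sin(2 * pi * 5 * t), c(1, 1, n)), fs, tmin = 0)
  pA <- waveletPower(epA, g, normalize = "amplitude")
  expect_equal(pA[1, 1, 2, 400:600], 9 * p[1, 1, 2, 400:600],
               tolerance = 1e-10)
})

test_that("epochs shorter than the longest kernel are refused", {
  ep <- eegEpochs(array(0, c(1, 1, 100)), 512)
  expect_error(waveletPower(ep, frequencyGrid()), "2.5")
})

test_that("collinear and constant power inputs fit exactly", {
  g <- frequencyGrid()
  pw <- array(0, c(2, 1, 5, 4))
  for (i in 1:5) pw[, , i, ] <- g$freqs[i]^(-2)
  sl <- fitSlopeTimecourse(pw, g, floor = 0)
  expect_equal(max(abs(sl@slope + 2)), 0, tolerance = 1e-12)
  pw1 <- array(1, c(1, 1, 5, 4))
  sl1 <- fitSlopeTimecourse(pw1, g, floor = 0)
  expect_identical(max(abs(sl1@slope)), 0)
  expect_error(fitSlopeTimecourse(-pw, g), "negative")
})

test_that("slope recovery on a known background matches the Welch oracle", {
  fs <- 512; n <- 1024
  set.seed(23)
  nT <- 24
  dat <- array(0, c(nT, 1, n))
  long <- synthPowerLawEpoch(1.5, fs, nT * n)  # one realization, long record
  for (i in 1:nT) dat[i, 1, ] <- long[((i - 1) * n + 1):(i * n)] * 10
  g <- frequencyGrid()
  sl <- smoothAndCensor(fitSlopeTimecourse(waveletPower(eegEpochs(dat, fs), g), g))
  est <- median(sl@slope[, 1, 300:700])
  oracle <- welchSlope(long, fs)
  expect_lt(abs(est - oracle), 0.2)
})

test_that("rescaling the signal shifts the intercept, never the slope", {
  fs <- 512
  set.seed(4)
  dat <- array(synthPowerLawEpoch(2, fs, 1024) * 10, c(1, 1, 1024))
  g <- frequencyGrid()
  s1 <- fitSlopeTimecourse(waveletPower(eegEpochs(dat, fs), g), g)
  s2 <- fitSlopeTimecourse(waveletPower(eegEpochs(dat * 5, fs), g), g)
  mid <- 200:800
  expect_equal(s2@slope[1, 1, mid], s1@slope[1, 1, mid], tolerance = 1e-8)
  expect_equal(s2@intercept[1, 1, mid], s1@intercept[1, 1, mid] + 2 * log10(5),
               tolerance = 1e-8)
})

test_that("moving average spreads an impulse and keeps constants", {
  mkSeries <- function(vals) {
    methods::new("SlopeSeries", slope = vals, intercept = vals * 0,
                 validMask = rep(TRUE, dim(vals)[1]),
                 times = seq_len(dim(vals)[3]),
                 channelLabels = "Ch1",
                 trialLink = seq_len(dim(vals)[1]), smoothed = FALSE,
                 normalization = "amplitude")
  }
  imp <- array(0, c(1, 1, 21)); imp[1, 1, 11] <- 1
  sm <- smoothAndCensor(mkSeries(imp), k = 5, bound = 4)
  expect_equal(sm@slope[1, 1, 9:13], rep(1 / 5, 5))
  expect_equal(sum(sm@slope), 1)  # mass conserved in the interior
  cst <- array(-2, c(1, 1, 21))
  smc <- smoothAndCensor(mkSeries(cst), k = 5, bound = 4)
  expect_equal(smc@slope, cst)
  expect_true(all(smc@validMask))
  # censoring: {-5, -1} at some sample -> first trial censored
  two <- array(-1, c(2, 1, 21)); two[1, 1, 7] <- -5
  smt <- smoothAndCensor(mkSeries(two), k = 1, bound = 4)
  expect_identical(smt@validMask, c(FALSE, TRUE))
  expect_equal(attr(smt, "censored"), 1L)
  expect_error(smoothAndCensor(mkSeries(cst), k = 4), "odd")
})

test_that("density-normalized series are censored on the raw slope scale", {
  vals <- array(-4.5, c(2, 1, 11))  # raw scale -3.5: plausible
  vals[2, 1, 6] <- -5.5             # raw scale -4.5: censored
  s <- methods::new("SlopeSeries", slope = vals, intercept = vals * 0,
                    validMask = c(TRUE, TRUE), times = 1:11,
                    channelLabels = "Ch1", trialLink = 1:2,
                    smoothed = FALSE, normalization = "density")
  out <- smoothAndCensor(s, k = 1, bound = 4)
  expect_identical(out@validMask, c(TRUE, FALSE))
})

test_that("condition averages obey the weighted-mean identity", {
  set.seed(31)
  nT <- 12
  vals <- array(rnorm(nT * 2 * 16), c(nT, 2, 16))
  tt <- data.frame(participant = 1, row = 1:nT,
                   prev = rep(c("congruent", "incongruent"), each = 6),
                   curr = rep(c("congruent", "incongruent"), 6))
  s <- methods::new("SlopeSeries", slope = vals, intercept = vals * 0,
                    validMask = rep(TRUE, nT), times = 1:16,
                    channelLabels = c("a", "b"), trialLink = 1:nT,
                    smoothed = TRUE, normalization = "amplitude")
  cm <- conditionAverage(s, tt)
  key <- paste0(substr(tt$prev, 1, 1), toupper(substr(tt$curr, 1, 1)))
  for (cell in congruencyCells()) {
    idx <- which(key == cell)
    expect_equal(cm[1, cell, , ], colMeans(vals[idx, , , drop = FALSE]),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
  # pooled mean equals the trial-count-weighted mean of cell means
  counts <- table(factor(key, congruencyCells()))
  pooled <- colMeans(vals)
  weighted <- apply(cm[1, , , ] * as.vector(counts), c(2, 3), sum) / nT
  expect_equal(weighted, pooled, tolerance = 1e-12, ignore_attr = TRUE)
  # a single-trial cell equals that trial; invalid trials are excluded
  s@validMask[key == "cC"][-1] <- FALSE
  cm2 <- conditionAverage(s, tt)
  first <- which(key == "cC")[1]
  expect_equal(cm2[1, "cC", , ], vals[first, , ], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("the fused pipeline path matches the composed reference path", {
  cfg <- tinyConfig(nParticipants = 1, nTrialsPerCell = 3)
  ds <- generateEEGDataset(cfg, seed = 7)
  g <- frequencyGrid()
  sl <- smoothAndCensor(fitSlopeTimecourse(waveletPower(ds$epochs, g), g))
  tt <- ds$trials
  tt$row <- seq_len(nrow(tt))
  ref <- conditionAverage(sl, tt)
  fast <- aperiodics:::participantSlopeMaps(ds$epochs, tt, g, 5L, 4, 64L)
  expect_equal(ref[1, , , ], fast, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(attr(fast, "censored"), sum(!sl@validMask))
  # chunking never changes the result
  fast2 <- aperiodics:::participantSlopeMaps(ds$epochs, tt, g, 5L, 4, 5L)
  expect_equal(fast, fast2, tolerance = 1e-12, ignore_attr = TRUE)
})
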