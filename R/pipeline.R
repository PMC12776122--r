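#' @include reduce.R
NULL

#' Run the full slope-dynamics analysis
#'
#' Orchestrates the complete analysis on synthetic data: behavior generation,
#' EEG synthesis streamed one participant at a time, trial exclusion,
#' peak-to-peak artifact rejection, condition-ERP subtraction, one-cycle
#' wavelet power, instantaneous log-log slope fitting, smoothing and
#' censoring, condition averaging, spatial and temporal PCA, window
#' segmentation, windowed component scores, the pre- vs post-stimulus
#' baseline table, the per-window congruency ANOVA table, and the behavioral
#' RT/accuracy ANOVAs. No baseline correction is applied anywhere; slope
#' scores enter the statistics as estimated.
#'
#' Stage defaults reproduce the reference analysis settings: 150 microvolt /
#' 600 ms / 100 ms artifact rejection, the 2.5-25 Hz grid with 7.5-15 Hz
#' excluded from fitting, 5-point smoothing, +-4 censoring, a -300..1300 ms
#' crop, 160-ms windows, alpha = 0.05.
#'
#' @param config a [SimConfig-class] describing the synthetic study.
#' @param seed integer master seed; the whole run is a deterministic
#'   function of \code{config}, \code{seed} and the stage parameters.
#' @param artifactThreshold,artifactWindow,artifactStep peak-to-peak
#'   rejection parameters (microvolts, ms, ms).
#' @param grid a [frequencyGrid()].
#' @param smoothK moving-average length, samples (odd).
#' @param censorBound slope censoring bound.
#' @param crop PCA/statistics span, ms.
#' @param windowWidth statistics window width, ms.
#' @param decimation temporal-PCA decimation factor.
#' @param alpha significance threshold.
#' @param chunkSize trials processed per wavelet/slope batch (memory knob;
#'   does not affect results).
#' @return list with elements \code{trials}, \code{behavior} (RT and
#'   accuracy ANOVA lists), \code{condMaps}, \code{spatialModel},
#'   \code{temporalPCA}, \code{windows}, \code{windowedScores},
#'   \code{baselineTable}, \code{congruencyStats} and \code{manifest}
#'   (parameters, seed, per-participant retained-epoch counts).
#' @examples
#' \donttest{
#' cfg <- simConfig(nParticipants = 4, nTrialsPerCell = 5, nBlocks = 1)
#' res <- runPipeline(cfg, seed = 1)
#' res$baselineTable[1:3, ]
#' }
#' @export
runPipeline <- function(config, seed = 1L,
                        artifactThreshold = 150, artifactWindow = 600,
                        artifactStep = 100,
                        grid = frequencyGrid(),
                        smoothK = 5L, censorBound = 4,
                        crop = c(-300, 1300), windowWidth = 160,
                        decimation = 10L, alpha = 0.05,
                        chunkSize = 64L) {
  stopifnot(methods::is(config, "SimConfig"))
  trials <- generateBehaviorTable(config, seed = childSeed(seed, 0L))
  trials$row <- seq_len(nrow(trials))
  behavior <- list(rt = behavioralAnova(trials, "rt", alpha = alpha),
                   accuracy = behavioralAnova(trials, "accuracy", alpha = alpha))
  eegKeep <- filterTrials(trials, purpose = "eeg")

  weights <- sourceWeights(config@layout)
  nSamples <- as.integer(diff(config@epochSpan) / 1000 * config@fs)
  timesMs <- config@epochSpan[1L] + (seq_len(nSamples) - 1L) * 1000 / config@fs
  expOff <- withSeed(childSeed(seed, 1L),
                     stats::rnorm(config@nParticipants, 0,
                                  config@exponentSdParticipant))
  erps <- erpTemplates(config, weights, timesMs)

  nP <- config@nParticipants
  condMaps <- NULL
  retainedCounts <- integer(nP)
  censoredCounts <- integer(nP)
  for (p in seq_len(nP)) {
    tp <- trials[trials$participant == p, , drop = FALSE]
    data <- generateParticipantEpochs(config, tp, expOff[p], weights, erps,
                                      timesMs, seed = childSeed(seed, 100L + p))
    ep <- eegEpochs(data, sampleRate = config@fs, tmin = config@epochSpan[1L],
                    channelLabels = config@layout$label, trialLink = tp$row)
    ep@rejected <- rejectArtifacts(ep, artifactThreshold, artifactWindow,
                                   artifactStep)
    ep <- selectAnalysisTrials(ep, eegKeep$trials)
    if (nTrials(ep) == 0L) {
      warning("participant ", p, " has no analyzable epochs")
      next
    }
    tl <- trials[ep@trialLink, ]
    ep <- subtractConditionERP(ep, paste(tl$participant, tl$prev, tl$curr))
    # wavelet + slope in chunks to bound memory; statistics are unaffected
    maps <- participantSlopeMaps(ep, trials, grid, smoothK, censorBound,
                                 chunkSize)
    censoredCounts[p] <- attr(maps, "censored")
    retainedCounts[p] <- attr(maps, "nRetained")
    if (is.null(condMaps)) {
      condMaps <- array(NA_real_, c(nP, dim(maps)),
                        dimnames = c(list(participant = as.character(seq_len(nP))),
                                     dimnames(maps)))
      attr(condMaps, "times") <- attr(maps, "times")
    }
    condMaps[p, , , ] <- maps
  }

  spatialModel <- runSpatialPCA(condMaps, config@layout, crop = crop)
  temporalPCA <- runTemporalPCA(condMaps, crop = crop, decimation = decimation)
  windows <- segmentWindows(crop, windowWidth)
  scores <- spatialScores(condMaps, spatialModel, crop = crop)
  ws <- windowScores(scores, windows)
  baselineTable <- baselineContrastTable(ws, alpha = alpha)
  congruencyStats <- congruencyTable(ws, alpha = alpha)

  manifest <- list(
    seed = seed,
    packageVersion = as.character(utils::packageVersion("aperiodics")),
    nParticipants = nP,
    parameters = list(
      artifactThreshold = artifactThreshold, artifactWindow = artifactWindow,
      artifactStep = artifactStep, freqs = grid$freqs,
      fitMask = grid$fitMask, smoothK = smoothK, censorBound = censorBound,
      crop = crop, windowWidth = windowWidth, decimation = decimation,
      alpha = alpha),
    retainedEpochsPerParticipant = retainedCounts,
    censoredEpochsPerParticipant = censoredCounts)

  list(trials = trials, behavior = behavior, condMaps = condMaps,
       spatialModel = spatialModel, temporalPCA = temporalPCA,
       windows = windows, windowedScores = ws,
       baselineTable = baselineTable, congruencyStats = congruencyStats,
       manifest = manifest)
}

# Condition-averaged slope maps for one participant's epochs, computed in
# trial chunks through the fused compiled wavelet/slope/smooth/censor path
# (numerically identical to waveletPower + fitSlopeTimecourse +
# smoothAndCensor; asserted in the test suite).
participantSlopeMaps <- function(ep, trials, grid, smoothK, censorBound,
                                 chunkSize) {
  nT <- nTrials(ep)
  d <- dim(ep@data)
  fs <- ep@sampleRate
  cells <- congruencyCells()
  sel <- which(grid$fitMask)
  lf <- log10(grid$freqs[sel])
  lfc <- lf - mean(lf)
  K <- waveletKernelFFT(grid, fs, d[3L])[, sel, drop = FALSE]
  densDiv <- 2 * fs / round(fs / grid$freqs[sel])
  sums <- array(0, c(4L, d[2L], d[3L]))
  counts <- integer(4L)
  censored <- 0L
  for (start in seq(1L, nT, by = chunkSize)) {
    idx <- start:min(start + chunkSize - 1L, nT)
    nTc <- length(idx)
    X <- t(matrix(ep@data[idx, , , drop = FALSE], nTc * d[2L], d[3L]))
    out <- .slopePipelineCpp(X, K, lfc / sum(lfc^2), mean(lf), densDiv,
                             1e-12, as.integer(smoothK), censorBound,
                             offset = 1)
    exceed <- apply(matrix(out$exceed, nTc, d[2L]), 1L, any)
    valid <- !exceed
    censored <- censored + sum(exceed)
    slope <- array(t(out$slope), c(nTc, d[2L], d[3L]))
    tl <- trials[ep@trialLink[idx], ]
    key <- cellKey(tl$prev, tl$curr)
    for (ci in seq_along(cells)) {
      selT <- which(key == cells[ci] & valid)
      if (!length(selT)) next
      sums[ci, , ] <- sums[ci, , ] +
        colSums(slope[selT, , , drop = FALSE])
      counts[ci] <- counts[ci] + length(selT)
    }
  }
  maps <- sums / ifelse(counts == 0L, NA_real_, counts)
  dimnames(maps) <- list(cell = cells, channel = ep@channelLabels, NULL)
  attr(maps, "times") <- ep@times
  attr(maps, "censored") <- censored
  attr(maps, "nRetained") <- sum(counts)
  maps
}
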