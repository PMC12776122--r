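#' @include synth-signal.R
NULL

#' Build a generator configuration
#'
#' Returns a [SimConfig-class] whose defaults mirror the simulated study:
#' 49 participants, two blocks of \code{4 x 120 + 1} trials with the four
#' Previous x Current congruency sequences exactly balanced, 56 channels at
#' 512 Hz, 2000-ms epochs spanning -500..1500 ms, a 1/f^1.5 background with a
#' stimulus-induced exponent increase of +0.25 everywhere and an additional
#' +0.3 frontal increase for incongruent trials preceded by congruent ones
#' (a programmed congruency-sequence effect), a 10 Hz occipital oscillation,
#' condition ERPs, and a behavioral model whose cell means reproduce a
#' congruency effect only after congruent trials.
#'
#' @param nParticipants,nTrialsPerCell,nBlocks design sizes.
#' @param fs,epochSpan,nChannels recording parameters.
#' @param layout channel layout; defaults to [scalpLayout()].
#' @param baselineExponent ground-truth aperiodic exponent.
#' @param exponentEffects data.frame of programmed exponent shifts
#'   (see [SimConfig-class]); \code{NULL} installs the default stimulus +
#'   sequence-interaction effects.
#' @param alphaAmp,alphaFreq occipital oscillation amplitude (microvolts) and
#'   frequency (Hz).
#' @param erpAmp named ERP peak amplitudes per current congruency, microvolts.
#' @param backgroundSd,noiseSd background source and sensor-noise SD,
#'   microvolts.
#' @param temporalSourceScale relative amplitude of the weak left/right
#'   temporal background sources.
#' @param rtModel named RT cell means (ms), cells \code{cC, cI, iC, iI}.
#' @param rtSdWithin,rtSdParticipant RT noise components, ms.
#' @param accuracyModel named error probabilities per cell.
#' @param exponentSdParticipant between-participant SD of the baseline
#'   exponent.
#' @param rsiLevels response-stimulus intervals, ms.
#' @return a validated [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(nParticipants = 2, nTrialsPerCell = 5)
#' cfg
#' @export
simConfig <- function(nParticipants = 49L,
                      nTrialsPerCell = 120L,
                      nBlocks = 2L,
                      fs = 512,
                      epochSpan = c(-500, 1500),
                      nChannels = 56L,
                      layout = scalpLayout(nChannels),
                      baselineExponent = 1.5,
                      exponentEffects = NULL,
                      alphaAmp = 4,
                      alphaFreq = 10,
                      erpAmp = c(congruent = 4, incongruent = 5),
                      backgroundSd = 10,
                      temporalSourceScale = 0.5,
                      noiseSd = 2,
                      rtModel = c(cC = 630, cI = 662, iC = 648, iI = 654),
                      rtSdWithin = 150,
                      rtSdParticipant = 100,
                      accuracyModel = c(cC = 0.0237, cI = 0.0377,
                                        iC = 0.0257, iI = 0.0276),
                      exponentSdParticipant = 0.1,
                      rsiLevels = c(1000, 2000, 3000, 5000)) {
  if (is.null(exponentEffects))
    exponentEffects <- data.frame(
      prev = c("any", "congruent"),
      curr = c("any", "incongruent"),
      region = c("all", "frontal"),
      start = c(100, 400),
      end = c(1300, 1300),
      delta = c(0.25, 0.3),
      stringsAsFactors = FALSE)
  methods::new("SimConfig",
    nParticipants = as.integer(nParticipants),
    nTrialsPerCell = as.integer(nTrialsPerCell),
    nBlocks = as.integer(nBlocks),
    fs = fs, epochSpan = as.numeric(epochSpan),
    nChannels = as.integer(nChannels), layout = layout,
    baselineExponent = baselineExponent, exponentEffects = exponentEffects,
    alphaAmp = alphaAmp, alphaFreq = alphaFreq, erpAmp = erpAmp,
    backgroundSd = backgroundSd, temporalSourceScale = temporalSourceScale,
    noiseSd = noiseSd,
    rtModel = rtModel, rtSdWithin = rtSdWithin,
    rtSdParticipant = rtSdParticipant, accuracyModel = accuracyModel,
    exponentSdParticipant = exponentSdParticipant, rsiLevels = rsiLevels)
}

# Random Eulerian circuit over the two congruency states with exactly m
# transitions of each of the four Previous x Current types (Hierholzer).
# Returns 4m+1 state labels; the first trial has no defined previous state.
congruencySequence <- function(m) {
  rem <- matrix(as.integer(m), 2L, 2L)
  circuit <- 1L
  while (any(rem > 0L)) {
    i <- which(vapply(circuit, function(v) sum(rem[v, ]) > 0L, logical(1L)))[1L]
    v0 <- circuit[i]
    path <- v0
    v <- v0
    repeat {
      choices <- which(rem[v, ] > 0L)
      if (!length(choices)) break
      nxt <- if (length(choices) == 1L) choices else
        sample(choices, 1L, prob = rem[v, choices])
      rem[v, nxt] <- rem[v, nxt] - 1L
      path <- c(path, nxt)
      v <- nxt
    }
    circuit <- append(circuit, path[-1L], after = i)
  }
  c("congruent", "incongruent")[circuit]
}

#' Generate a behavioral trial table
#'
#' One row per trial with participant, block, trial index, previous and
#' current congruency, reaction time, accuracy and RSI. Sequences are exactly
#' balanced: every block contains \code{nTrialsPerCell} trials of each of the
#' four Previous x Current congruency transitions (plus the first trial of
#' the block, whose previous congruency is undefined). RTs follow the
#' programmed cell mean plus a participant offset and Gaussian residual;
#' accuracy is Bernoulli per cell.
#'
#' @param config a [SimConfig-class].
#' @param seed integer seed; the table is a deterministic function of
#'   \code{config} and \code{seed}.
#' @return data.frame with columns \code{participant}, \code{block},
#'   \code{trial}, \code{prev}, \code{curr}, \code{rt}, \code{correct},
#'   \code{rsi}, \code{practice}. \code{prev} is \code{NA} on the first trial
#'   of each block.
#' @examples
#' tt <- generateBehaviorTable(simConfig(nParticipants = 1, nTrialsPerCell = 3,
#'                                       nBlocks = 1), seed = 1)
#' table(tt$prev, tt$curr)
#' @export
generateBehaviorTable <- function(config, seed = 1L) {
  stopifnot(methods::is(config, "SimConfig"))
  withSeed(seed, {
    m <- config@nTrialsPerCell
    nb <- 4L * m + 1L
    rows <- vector("list", config@nParticipants * config@nBlocks)
    k <- 0L
    for (p in seq_len(config@nParticipants)) {
      rtOff <- stats::rnorm(1L, 0, config@rtSdParticipant)
      for (b in seq_len(config@nBlocks)) {
        curr <- congruencySequence(m)
        prev <- c(NA_character_, curr[-nb])
        cell <- ifelse(is.na(prev), NA_character_, cellKey(prev, curr))
        mu <- ifelse(is.na(cell), mean(config@rtModel), config@rtModel[cell])
        perr <- ifelse(is.na(cell), mean(config@accuracyModel),
                       config@accuracyModel[cell])
        rt <- mu + rtOff + stats::rnorm(nb, 0, config@rtSdWithin)
        rt <- pmax(rt, 100)  # physiological floor
        correct <- stats::runif(nb) >= perr
        k <- k + 1L
        rows[[k]] <- data.frame(
          participant = p, block = b, trial = seq_len(nb),
          prev = prev, curr = curr, rt = rt, correct = correct,
          rsi = sample(config@rsiLevels, nb, replace = TRUE),
          practice = FALSE, stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    # sequence bookkeeping must be internally consistent
    chk <- stats::ave(seq_len(nrow(out)), out$participant, out$block,
                      FUN = function(i) {
                        ok <- all(out$prev[i][-1L] == out$curr[i][-length(i)])
                        rep(ok, length(i))
                      })
    stopifnot(all(as.logical(chk)))
    out
  })
}

# Ground-truth exponent profile for one trial cell and source region.
trueExponentProfile <- function(config, prev, curr, region, timesMs,
                                participantOffset = 0) {
  x <- rep(config@baselineExponent + participantOffset, length(timesMs))
  eff <- config@exponentEffects
  for (i in seq_len(nrow(eff))) {
    okPrev <- eff$prev[i] == "any" || (!is.na(prev) && eff$prev[i] == prev)
    okCurr <- eff$curr[i] == "any" || eff$curr[i] == curr
    okReg <- eff$region[i] == "all" || eff$region[i] == region
    if (okPrev && okCurr && okReg) {
      sel <- timesMs >= eff$start[i] & timesMs <= eff$end[i]
      x[sel] <- x[sel] + eff$delta[i]
    }
  }
  x
}

# Condition ERP templates: channels x samples per current-congruency level.
# Early occipital visual transient plus a later central positivity.
erpTemplates <- function(config, weights, timesMs) {
  lapply(config@erpAmp, function(a) {
    early <- 0.8 * a * exp(-(timesMs - 120)^2 / (2 * 30^2))
    late <- a * exp(-(timesMs - 350)^2 / (2 * 80^2))
    weights[, "occipital"] %o% early + weights[, "central"] %o% late
  })
}

#' Generate a synthetic EEG dataset with known ground truth
#'
#' Produces stimulus-locked epochs for every trial of the behavioral table:
#' three power-law background sources (frontal, central, occipital Gaussian
#' scalp maps) with condition- and time-dependent ground-truth exponents, an
#' occipital alpha-band oscillation with random phase per trial, a
#' phase-locked condition ERP, and white sensor noise.
#'
#' Memory grows as trials x channels x samples; for study-sized configs use
#' [runPipeline()], which generates and processes one participant at a time,
#' or call [generateParticipantEpochs()] directly.
#'
#' @param config a [SimConfig-class]; keep the design small (a few
#'   participants) when materializing all epochs at once.
#' @param seed integer seed; output is a deterministic function of
#'   \code{config} and \code{seed}.
#' @return list with elements \code{epochs} ([EEGEpochs-class]),
#'   \code{trials} (behavior table; epochs link to its rows) and
#'   \code{truth} (a \code{GroundTruth} list recording everything injected).
#' @examples
#' cfg <- simConfig(nParticipants = 1, nTrialsPerCell = 2, nBlocks = 1)
#' ds <- generateEEGDataset(cfg, seed = 1)
#' ds$epochs
#' @export
generateEEGDataset <- function(config, seed = 1L) {
  stopifnot(methods::is(config, "SimConfig"))
  trials <- generateBehaviorTable(config, seed = childSeed(seed, 0L))
  weights <- sourceWeights(config@layout)
  nSamples <- as.integer(diff(config@epochSpan) / 1000 * config@fs)
  timesMs <- config@epochSpan[1L] + (seq_len(nSamples) - 1L) * 1000 / config@fs
  expOff <- withSeed(childSeed(seed, 1L),
                     stats::rnorm(config@nParticipants, 0,
                                  config@exponentSdParticipant))
  erps <- erpTemplates(config, weights, timesMs)
  parts <- lapply(seq_len(config@nParticipants), function(p)
    generateParticipantEpochs(config, trials[trials$participant == p, ],
                              expOff[p], weights, erps, timesMs,
                              seed = childSeed(seed, 100L + p)))
  data <- do.call(abind3, parts)
  epochs <- eegEpochs(data, sampleRate = config@fs,
                      tmin = config@epochSpan[1L],
                      channelLabels = config@layout$label,
                      trialLink = seq_len(nrow(trials)))
  truth <- structure(list(
    baselineExponent = config@baselineExponent,
    participantExponentOffset = expOff,
    exponentEffects = config@exponentEffects,
    erpMap = erps,
    rtTruth = config@rtModel,
    accTruth = config@accuracyModel,
    config = config), class = "GroundTruth")
  list(epochs = epochs, trials = trials, truth = truth)
}

#' Generate the epochs of a single participant
#'
#' Workhorse behind [generateEEGDataset()], exposed so that study-sized
#' simulations can stream one participant at a time.
#'
#' @param config a [SimConfig-class].
#' @param trials the participant's rows of the behavior table.
#' @param exponentOffset the participant's baseline-exponent offset.
#' @param weights channels x 3 source weight matrix ([sourceWeights()]).
#' @param erps list of channels x samples ERP templates per condition.
#' @param timesMs ms time axis.
#' @param seed integer seed.
#' @return trials x channels x samples array (microvolts).
#' @export
generateParticipantEpochs <- function(config, trials, exponentOffset,
                                      weights, erps, timesMs, seed) {
  withSeed(seed, {
    nT <- nrow(trials)
    nC <- config@nChannels
    nS <- length(timesMs)
    srcNames <- c("frontal", "central", "occipital",
                  "left-temporal", "right-temporal")
    srcScale <- config@backgroundSd *
      c(1, 1, 1, config@temporalSourceScale, config@temporalSourceScale)
    data <- array(0, dim = c(nT, nC, nS))
    occW <- weights[, "occipital"]
    for (i in seq_len(nT)) {
      src <- vapply(srcNames, function(s) {
        prof <- trueExponentProfile(config, trials$prev[i], trials$curr[i],
                                    s, timesMs, exponentOffset)
        synthPowerLawEpoch(prof, config@fs, nS)
      }, numeric(nS))
      mat <- (weights[, srcNames] %*% (t(src) * srcScale))
      # phase drawn unconditionally so alpha-on/off runs share RNG streams
      phase <- stats::runif(1L, 0, 2 * pi)
      if (config@alphaAmp > 0) {
        alpha <- config@alphaAmp *
          sin(2 * pi * config@alphaFreq * timesMs / 1000 + phase)
        mat <- mat + occW %o% alpha
      }
      mat <- mat + erps[[trials$curr[i]]]
      if (config@noiseSd > 0)
        mat <- mat + matrix(stats::rnorm(nC * nS, 0, config@noiseSd), nC, nS)
      data[i, , ] <- mat
    }
    data
  })
}

# rbind for trials x channels x samples arrays
abind3 <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1L]])
  out <- array(0, dim = c(sum(vapply(parts, function(p) dim(p)[1L], 0)),
                          d[2L], d[3L]))
  at <- 0L
  for (p in parts) {
    out[at + seq_len(dim(p)[1L]), , ] <- p
    at <- at + dim(p)[1L]
  }
  out
}

#' @export
print.GroundTruth <- function(x, ...) {
  cat("GroundTruth: baseline exponent", x$baselineExponent, "\n")
  cat("  ", nrow(x$exponentEffects), "programmed exponent effect(s)\n")
  cat("  RT cell means:", paste(names(x$rtTruth), round(x$rtTruth),
                                sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Ground-truth exponent at given conditions and times
#'
#' Round-trip accessor: returns the exponent the generator injected for a
#' given trial cell, source region and time, excluding participant offsets.
#'
#' @param truth a \code{GroundTruth} from [generateEEGDataset()].
#' @param prev,curr congruency of previous/current trial
#'   (\code{"congruent"}/\code{"incongruent"}; \code{prev} may be \code{NA}).
#' @param region \code{"frontal"}, \code{"central"} or \code{"occipital"}.
#' @param timesMs times at which to evaluate, ms.
#' @return numeric vector of true exponents.
#' @export
trueExponent <- function(truth, prev, curr, region, timesMs) {
  trueExponentProfile(truth$config, prev, curr, region, timesMs)
}
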