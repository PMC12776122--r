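#' @include AllGenerics.R
NULL

# ---------------------------------------------------------------------------
# EEGEpochs
# ---------------------------------------------------------------------------

#' Stimulus-locked EEG epochs
#'
#' Container for a trials x channels x samples array of stimulus-locked EEG,
#' together with its sampling rate, time axis (ms relative to stimulus onset),
#' channel labels, a link into the behavioral trial table, and a per-trial
#' artifact-rejection flag.
#'
#' @slot data numeric array, trials x channels x samples, in microvolts.
#' @slot sampleRate sampling rate in Hz.
#' @slot times numeric vector of sample times in ms; \code{times[1]} is the
#'   epoch start and successive samples are spaced \code{1000/sampleRate} ms.
#' @slot channelLabels character vector, one label per channel.
#' @slot trialLink integer vector mapping each epoch to a row of the
#'   associated trial table.
#' @slot rejected logical vector; \code{TRUE} marks epochs flagged by
#'   peak-to-peak artifact rejection.
#'
#' @seealso [eegEpochs()], [rejectArtifacts()], [subtractConditionERP()]
#' @export
setClass("EEGEpochs",
  representation(
    data = "array",
    sampleRate = "numeric",
    times = "numeric",
    channelLabels = "character",
    trialLink = "integer",
    rejected = "logical"
  )
)

setValidity("EEGEpochs", function(object) {
  d <- dim(object@data)
  msg <- character()
  if (length(d) != 3L)
    msg <- c(msg, "data must be a trials x channels x samples array")
  else {
    if (length(object@times) != d[3L])
      msg <- c(msg, "length(times) must equal the number of samples")
    if (length(object@channelLabels) != d[2L])
      msg <- c(msg, "channelLabels must have one entry per channel")
    if (length(object@trialLink) != d[1L])
      msg <- c(msg, "trialLink must have one entry per trial")
    if (length(object@rejected) != d[1L])
      msg <- c(msg, "rejected must have one entry per trial")
  }
  if (length(object@sampleRate) != 1L || object@sampleRate <= 0)
    msg <- c(msg, "sampleRate must be a single positive number")
  if (length(object@times) > 1L) {
    step <- diff(object@times)
    if (max(abs(step - 1000 / object@sampleRate)) > 1e-6)
      msg <- c(msg, "times must be spaced 1000/sampleRate ms apart")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an EEGEpochs object
#'
#' @param data trials x channels x samples numeric array (microvolts).
#' @param sampleRate sampling rate in Hz.
#' @param tmin epoch start relative to stimulus onset, in ms.
#' @param channelLabels channel labels; defaults to \code{Ch1..ChK}.
#' @param trialLink integer row indices into the trial table; defaults to
#'   \code{1:nTrials}.
#' @return An [EEGEpochs-class] object.
#' @export
eegEpochs <- function(data, sampleRate = 512, tmin = -500,
                      channelLabels = NULL, trialLink = NULL) {
  d <- dim(data)
  if (is.null(d) || length(d) != 3L)
    stop("'data' must be a trials x channels x samples array")
  if (is.null(channelLabels))
    channelLabels <- paste0("Ch", seq_len(d[2L]))
  if (is.null(trialLink))
    trialLink <- seq_len(d[1L])
  times <- tmin + (seq_len(d[3L]) - 1L) * 1000 / sampleRate
  methods::new("EEGEpochs",
    data = data, sampleRate = sampleRate, times = times,
    channelLabels = as.character(channelLabels),
    trialLink = as.integer(trialLink),
    rejected = logical(d[1L]))
}

#' @describeIn EEGEpochs-class the raw trials x channels x samples array
#' @param x an \code{EEGEpochs} object
#' @export
setMethod("epochData", "EEGEpochs", function(x) x@data)

#' @describeIn EEGEpochs-class sampling rate in Hz
#' @export
setMethod("sampleRate", "EEGEpochs", function(x) x@sampleRate)

#' @describeIn EEGEpochs-class sample times in ms
#' @export
setMethod("epochTimes", "EEGEpochs", function(x) x@times)

#' @describeIn EEGEpochs-class channel labels
#' @export
setMethod("channelLabels", "EEGEpochs", function(x) x@channelLabels)

#' @describeIn EEGEpochs-class row indices into the trial table
#' @export
setMethod("trialLink", "EEGEpochs", function(x) x@trialLink)

#' @describeIn EEGEpochs-class number of epochs
#' @export
setMethod("nTrials", "EEGEpochs", function(x) dim(x@data)[1L])

setMethod("show", "EEGEpochs", function(object) {
  d <- dim(object@data)
  cat("EEGEpochs:", d[1L], "trials x", d[2L], "channels x", d[3L], "samples\n")
  cat("  ", object@sampleRate, "Hz, ", round(object@times[1L]), "..",
      round(object@times[length(object@times)]), " ms\n", sep = "")
  if (any(object@rejected))
    cat("  ", sum(object@rejected), "trial(s) flagged by artifact rejection\n")
})

# ---------------------------------------------------------------------------
# SlopeSeries
# ---------------------------------------------------------------------------

#' Instantaneous aperiodic slope and intercept estimates
#'
#' Per-trial, per-channel, per-sample estimates of the aperiodic (1/f) spectral
#' slope (the log10 power vs log10 frequency regression slope; minus the
#' aperiodic exponent) and intercept (log10 power at 1 Hz). Trials whose
#' smoothed slope exceeds the censoring bound anywhere carry
#' \code{validMask = FALSE}.
#'
#' @slot slope numeric array, trials x channels x samples (dimensionless).
#' @slot intercept numeric array, same shape (log10 microvolts squared).
#' @slot validMask logical per trial; \code{FALSE} marks censored trials.
#' @slot times ms time axis shared with the source epochs.
#' @slot channelLabels channel labels.
#' @slot trialLink row indices into the trial table.
#' @slot smoothed logical; has the moving-average filter been applied.
#' @slot normalization \code{"density"} when the slopes come from
#'   spectral-density-scaled wavelet power (slope estimates the negative
#'   aperiodic exponent), \code{"amplitude"} when they come from raw
#'   quadrature power (slope estimates one minus the exponent); governs the
#'   scale on which the censoring bound is applied.
#'
#' @seealso [fitSlopeTimecourse()], [smoothAndCensor()], [conditionAverage()]
#' @export
setClass("SlopeSeries",
  representation(
    slope = "array",
    intercept = "array",
    validMask = "logical",
    times = "numeric",
    channelLabels = "character",
    trialLink = "integer",
    smoothed = "logical",
    normalization = "character"
  ),
  prototype(normalization = "amplitude")
)

setValidity("SlopeSeries", function(object) {
  ds <- dim(object@slope)
  msg <- character()
  if (length(ds) != 3L)
    msg <- c(msg, "slope must be trials x channels x samples")
  if (!identical(ds, dim(object@intercept)))
    msg <- c(msg, "slope and intercept must have identical dimensions")
  if (length(object@validMask) != ds[1L])
    msg <- c(msg, "validMask must have one entry per trial")
  if (length(object@times) != ds[3L])
    msg <- c(msg, "times must have one entry per sample")
  if (length(object@channelLabels) != ds[2L])
    msg <- c(msg, "channelLabels must have one entry per channel")
  if (length(object@trialLink) != ds[1L])
    msg <- c(msg, "trialLink must have one entry per trial")
  if (length(msg)) msg else TRUE
})

#' @describeIn SlopeSeries-class slope array
#' @param x a \code{SlopeSeries} object
#' @export
setMethod("slopeValues", "SlopeSeries", function(x) x@slope)

#' @describeIn SlopeSeries-class intercept array
#' @export
setMethod("interceptValues", "SlopeSeries", function(x) x@intercept)

#' @describeIn SlopeSeries-class per-trial validity after censoring
#' @export
setMethod("validMask", "SlopeSeries", function(x) x@validMask)

#' @describeIn SlopeSeries-class time axis in ms
#' @export
setMethod("epochTimes", "SlopeSeries", function(x) x@times)

#' @describeIn SlopeSeries-class channel labels
#' @export
setMethod("channelLabels", "SlopeSeries", function(x) x@channelLabels)

#' @describeIn SlopeSeries-class row indices into the trial table
#' @export
setMethod("trialLink", "SlopeSeries", function(x) x@trialLink)

#' @describeIn SlopeSeries-class number of trials
#' @export
setMethod("nTrials", "SlopeSeries", function(x) dim(x@slope)[1L])

setMethod("show", "SlopeSeries", function(object) {
  ds <- dim(object@slope)
  cat("SlopeSeries:", ds[1L], "trials x", ds[2L], "channels x", ds[3L], "samples\n")
  cat("  smoothed:", object@smoothed,
      " censored:", sum(!object@validMask), "trial(s)\n")
})

# ---------------------------------------------------------------------------
# ComponentModel
# ---------------------------------------------------------------------------

#' A spatial or temporal principal-component model
#'
#' Result of a PCA over electrodes (spatial) or timepoints (temporal):
#' covariance-based extraction, Empirical Kaiser Criterion retention, varimax
#' rotation of the retained unstandardized loadings, and the 1/x
#' explained-variance filter.
#'
#' @slot kind \code{"spatial"} or \code{"temporal"}.
#' @slot variables variable labels (electrode names or timepoint ms values).
#' @slot eigenvalues covariance-matrix eigenvalues, non-increasing.
#' @slot eigenvaluesCorr the same eigenvalues rescaled to correlation metric
#'   (summing to the number of variables), used by the EKC test.
#' @slot loadings unrotated unstandardized loadings (eigenvector times
#'   sqrt(eigenvalue)) for the EKC-retained components.
#' @slot loadingsRotated varimax-rotated unstandardized loadings.
#' @slot rotation orthonormal rotation matrix.
#' @slot explainedVariance fraction of total variance per extracted component
#'   (all components; sums to 1).
#' @slot rotatedVariance fraction of total variance per rotated component.
#' @slot retained logical per rotated component; \code{TRUE} when the
#'   component survives the 1/x variance filter.
#' @slot covariance the variables x variables covariance matrix used for
#'   extraction (and for regression-method scoring).
#' @slot nCases number of rows entering the covariance estimate.
#' @slot componentNames names per rotated component (scalp region for spatial
#'   models, peak latency for temporal models).
#'
#' @seealso [runSpatialPCA()], [runTemporalPCA()], [projectScores()]
#' @export
setClass("ComponentModel",
  representation(
    kind = "character",
    variables = "character",
    eigenvalues = "numeric",
    eigenvaluesCorr = "numeric",
    loadings = "matrix",
    loadingsRotated = "matrix",
    rotation = "matrix",
    explainedVariance = "numeric",
    rotatedVariance = "numeric",
    retained = "logical",
    covariance = "matrix",
    nCases = "integer",
    componentNames = "character"
  )
)

setValidity("ComponentModel", function(object) {
  msg <- character()
  ev <- object@eigenvalues
  if (length(ev) && any(diff(ev) > 1e-8))
    msg <- c(msg, "eigenvalues must be non-increasing")
  if (length(ev) && any(ev < -1e-8))
    msg <- c(msg, "eigenvalues must be non-negative")
  if (length(object@explainedVariance) &&
      abs(sum(object@explainedVariance) - 1) > 1e-8)
    msg <- c(msg, "explainedVariance must sum to 1")
  if (nrow(object@loadings) != length(object@variables))
    msg <- c(msg, "loadings rows must match variables")
  if (!identical(dim(object@loadings), dim(object@loadingsRotated)))
    msg <- c(msg, "rotated and unrotated loadings must share dimensions")
  k <- ncol(object@loadings)
  if (length(object@retained) != k)
    msg <- c(msg, "retained must have one flag per extracted component")
  if (length(object@componentNames) != k)
    msg <- c(msg, "componentNames must have one entry per extracted component")
  # varimax is orthogonal: per-variable communalities must be conserved
  if (k > 0) {
    h0 <- rowSums(object@loadings^2)
    h1 <- rowSums(object@loadingsRotated^2)
    if (max(abs(h0 - h1)) > 1e-6 * max(1, max(h0)))
      msg <- c(msg, "rotation must conserve per-variable communalities")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn ComponentModel-class covariance-scale eigenvalues
#' @param x a \code{ComponentModel}
#' @export
setMethod("eigenValues", "ComponentModel", function(x) x@eigenvalues)

#' @describeIn ComponentModel-class loadings matrix; \code{rotated} selects the
#'   varimax-rotated solution, \code{standardized} rescales rows to
#'   correlation metric (loading / variable SD)
#' @param rotated return the varimax-rotated loadings
#' @param standardized rescale rows by 1/SD of each variable
#' @export
setMethod("componentLoadings", "ComponentModel",
  function(x, rotated = TRUE, standardized = FALSE) {
    L <- if (rotated) x@loadingsRotated else x@loadings
    if (standardized) {
      sds <- sqrt(diag(x@covariance))
      sds[sds == 0] <- 1
      L <- L / sds
    }
    L
  })

#' @describeIn ComponentModel-class indices of components surviving both the
#'   EKC and the 1/x variance filter
#' @export
setMethod("retainedComponents", "ComponentModel", function(x) which(x@retained))

#' @describeIn ComponentModel-class per-component fraction of total variance
#' @export
setMethod("explainedVariance", "ComponentModel", function(x) x@explainedVariance)

#' @describeIn ComponentModel-class component names (scalp region or latency)
#' @export
setMethod("componentNames", "ComponentModel", function(x) x@componentNames)

setMethod("show", "ComponentModel", function(object) {
  k <- ncol(object@loadings)
  cat("ComponentModel (", object@kind, "): ", length(object@variables),
      " variables, ", k, " extracted component(s), ",
      sum(object@retained), " retained\n", sep = "")
  if (k > 0) {
    cat("  names: ", paste(object@componentNames, collapse = ", "), "\n", sep = "")
    cat("  rotated variance: ",
        paste(sprintf("%.3f", object@rotatedVariance), collapse = ", "),
        "\n", sep = "")
  }
})

# ---------------------------------------------------------------------------
# SimConfig
# ---------------------------------------------------------------------------

#' Configuration of the synthetic EEG + behavior generator
#'
#' Holds every parameter of the simulated conflict-task study: design sizes,
#' recording parameters, the ground-truth aperiodic exponent model (baseline
#' exponent plus programmed condition- and time-dependent shifts), oscillatory
#' and ERP content, and the behavioral reaction-time / accuracy model over the
#' four Previous x Current congruency cells.
#'
#' @slot nParticipants number of simulated participants.
#' @slot nTrialsPerCell trials per Previous x Current cell per block; every
#'   block has \code{4 * nTrialsPerCell + 1} trials (the extra trial is the
#'   first-of-block trial whose previous congruency is undefined).
#' @slot nBlocks number of blocks per participant.
#' @slot fs sampling rate, Hz.
#' @slot epochSpan epoch limits in ms relative to stimulus onset.
#' @slot nChannels number of scalp channels.
#' @slot layout data.frame with columns \code{label}, \code{x}, \code{y},
#'   \code{region}; see [scalpLayout()].
#' @slot baselineExponent ground-truth aperiodic exponent x of the
#'   \eqn{1/f^x} background, before any programmed shift.
#' @slot exponentEffects data.frame of programmed exponent shifts with columns
#'   \code{prev}, \code{curr} (\code{"congruent"}, \code{"incongruent"} or
#'   \code{"any"}), \code{region} (\code{"frontal"}, \code{"central"},
#'   \code{"occipital"} or \code{"all"}), \code{start}, \code{end} (ms) and
#'   \code{delta} (added to the exponent inside the interval).
#' @slot alphaAmp amplitude (microvolts) of the 10 Hz oscillation added to
#'   occipitally weighted channels.
#' @slot alphaFreq oscillation frequency, Hz.
#' @slot erpAmp named numeric, ERP template peak amplitude (microvolts) per
#'   current-congruency condition.
#' @slot backgroundSd standard deviation (microvolts) of each strong
#'   (frontal/central/occipital) power-law background source.
#' @slot temporalSourceScale amplitude of the weak left/right-temporal
#'   background sources relative to \code{backgroundSd}.
#' @slot noiseSd standard deviation (microvolts) of white sensor noise.
#' @slot rtModel named numeric of length 4 (\code{cC, cI, iC, iI}; first
#'   letter = previous, second = current congruency), mean RT in ms per cell.
#' @slot rtSdWithin within-participant RT standard deviation, ms.
#' @slot rtSdParticipant between-participant SD of the RT offset, ms.
#' @slot accuracyModel named numeric of length 4, error probability per cell.
#' @slot exponentSdParticipant between-participant SD of the baseline
#'   exponent offset.
#' @slot rsiLevels response-stimulus intervals (ms) sampled per trial
#'   (labels only; no signal depends on them).
#'
#' @seealso [simConfig()], [generateEEGDataset()], [generateBehaviorTable()]
#' @export
setClass("SimConfig",
  representation(
    nParticipants = "integer",
    nTrialsPerCell = "integer",
    nBlocks = "integer",
    fs = "numeric",
    epochSpan = "numeric",
    nChannels = "integer",
    layout = "data.frame",
    baselineExponent = "numeric",
    exponentEffects = "data.frame",
    alphaAmp = "numeric",
    alphaFreq = "numeric",
    erpAmp = "numeric",
    backgroundSd = "numeric",
    temporalSourceScale = "numeric",
    noiseSd = "numeric",
    rtModel = "numeric",
    rtSdWithin = "numeric",
    rtSdParticipant = "numeric",
    accuracyModel = "numeric",
    exponentSdParticipant = "numeric",
    rsiLevels = "numeric"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@nParticipants < 1L) msg <- c(msg, "nParticipants must be >= 1")
  if (object@nTrialsPerCell < 1L) msg <- c(msg, "nTrialsPerCell must be >= 1")
  if (object@fs <= 0) msg <- c(msg, "fs must be positive")
  dur <- diff(object@epochSpan)
  if (length(object@epochSpan) != 2L || dur <= 0)
    msg <- c(msg, "epochSpan must be an increasing ms pair")
  else if (abs(object@fs * dur / 1000 - round(object@fs * dur / 1000)) > 1e-9)
    msg <- c(msg, "fs x epoch duration must give an integer sample count")
  need <- c("frontal", "central", "occipital")
  if (!all(need %in% object@layout$region))
    msg <- c(msg, "layout must contain frontal, central and occipital regions")
  if (nrow(object@layout) != object@nChannels)
    msg <- c(msg, "layout must have one row per channel")
  x <- object@baselineExponent
  deltas <- if (nrow(object@exponentEffects)) object@exponentEffects$delta else 0
  # programmed truths must survive the +-4 slope censor, even where shifts stack
  if (x + sum(pmax(deltas, 0)) >= 4 || x + sum(pmin(deltas, 0)) <= 0)
    msg <- c(msg, "baselineExponent plus programmed shifts must stay in (0, 4)")
  cells <- c("cC", "cI", "iC", "iI")
  if (!all(cells %in% names(object@rtModel)))
    msg <- c(msg, "rtModel must name cells cC, cI, iC, iI")
  else if (any(object@rtModel <= 0))
    msg <- c(msg, "rtModel means must be positive")
  if (!all(cells %in% names(object@accuracyModel)))
    msg <- c(msg, "accuracyModel must name cells cC, cI, iC, iI")
  else if (any(object@accuracyModel < 0 | object@accuracyModel >= 1))
    msg <- c(msg, "accuracyModel error probabilities must lie in [0, 1)")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nParticipants, "participants x", object@nBlocks,
      "block(s) x", 4L * object@nTrialsPerCell + 1L, "trials\n")
  cat("  ", object@nChannels, " channels @ ", object@fs, " Hz, epochs ",
      object@epochSpan[1L], "..", object@epochSpan[2L], " ms\n", sep = "")
  cat("  baseline exponent ", object@baselineExponent, ", ",
      nrow(object@exponentEffects), " programmed exponent effect(s)\n", sep = "")
})
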