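#' @include behavior.R
NULL

#' Peak-to-peak artifact rejection
#'
#' Flags an epoch when any channel shows a peak-to-peak (max minus min)
#' voltage excursion above \code{threshold} inside any sliding window of
#' \code{window} ms advanced in \code{step} ms increments from the epoch
#' start. Only full windows are evaluated; a trailing partial window is
#' ignored.
#'
#' @param epochs an [EEGEpochs-class].
#' @param threshold peak-to-peak rejection threshold, microvolts.
#' @param window sliding window width, ms.
#' @param step window step, ms.
#' @return logical vector, one flag per trial (\code{TRUE} = rejected).
#' @examples
#' ep <- eegEpochs(array(0, c(2, 1, 512)), sampleRate = 512, tmin = -500)
#' rejectArtifacts(ep)
#' @export
rejectArtifacts <- function(epochs, threshold = 150, window = 600, step = 100) {
  stopifnot(methods::is(epochs, "EEGEpochs"))
  if (threshold <= 0) stop("'threshold' must be positive")
  if (step <= 0) stop("'step' must be positive")
  fs <- epochs@sampleRate
  d <- dim(epochs@data)
  ws <- as.integer(round(window / 1000 * fs))
  ss <- as.integer(round(step / 1000 * fs))
  if (ws > d[3L]) stop("'window' must not exceed the epoch duration")
  X <- t(matrix(epochs@data, d[1L] * d[2L], d[3L]))
  rng <- .ptpRangeCpp(X, ws, ss)
  apply(matrix(rng, d[1L], d[2L]), 1L, max) > threshold
}

#' Subtract the per-cell average ERP from each epoch
#'
#' Computes the average event-related potential over the retained
#' (non-rejected) trials of each condition cell and subtracts it from every
#' epoch of that cell, removing phase-locked content so it cannot distort
#' aperiodic slope estimates while leaving single-trial non-phase-locked
#' activity untouched.
#'
#' @param epochs an [EEGEpochs-class]; its \code{rejected} slot defines the
#'   retained trials entering each cell average.
#' @param conditionLabels per-trial cell labels (typically
#'   participant x previous x current congruency). Must be non-missing for
#'   every retained trial.
#' @return the epochs with cell means removed; within each cell, the mean of
#'   the retained trials of the returned data is zero at every
#'   channel x sample.
#' @export
subtractConditionERP <- function(epochs, conditionLabels) {
  stopifnot(methods::is(epochs, "EEGEpochs"))
  d <- dim(epochs@data)
  if (length(conditionLabels) != d[1L])
    stop("'conditionLabels' must have one entry per trial")
  keep <- !epochs@rejected
  if (anyNA(conditionLabels[keep]))
    stop("every retained trial must have a condition label")
  labs <- as.character(conditionLabels)
  for (cell in unique(labs)) {
    inCell <- which(labs == cell)
    used <- inCell[keep[inCell]]
    if (!length(used))
      stop("condition cell '", cell, "' has no retained trials")
    erp <- colMeans(epochs@data[used, , , drop = FALSE])
    for (i in inCell)
      epochs@data[i, , ] <- epochs@data[i, , ] - erp
  }
  epochs
}

#' Restrict epochs to analyzable trials
#'
#' Intersects the behavioral EEG-analysis exclusion criteria with the
#' artifact-rejection mask: an epoch is kept when its linked trial survives
#' [filterTrials()] with \code{purpose = "eeg"} and the epoch itself is not
#' artifact-flagged.
#'
#' @param epochs an [EEGEpochs-class] whose \code{rejected} slot holds the
#'   artifact mask.
#' @param trials the retained trial table from
#'   \code{filterTrials(..., purpose = "eeg")} (its \code{row} column indexes
#'   the original table the epochs link to).
#' @return the subsetted [EEGEpochs-class].
#' @export
selectAnalysisTrials <- function(epochs, trials) {
  stopifnot(methods::is(epochs, "EEGEpochs"))
  rows <- if (!is.null(trials$row)) trials$row else seq_len(nrow(trials))
  keep <- (epochs@trialLink %in% rows) & !epochs@rejected
  methods::new("EEGEpochs",
    data = epochs@data[keep, , , drop = FALSE],
    sampleRate = epochs@sampleRate, times = epochs@times,
    channelLabels = epochs@channelLabels,
    trialLink = epochs@trialLink[keep],
    rejected = epochs@rejected[keep])
}
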