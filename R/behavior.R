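#' @include stats.R
NULL

#' Apply the trial-exclusion rules
#'
#' Removes trials according to the purpose of the downstream analysis.
#' Accuracy analyses exclude practice trials and the first trial of each
#' block. RT and EEG analyses additionally exclude error trials, trials
#' following an error, and RT outliers: trials whose RT deviates from the
#' participant's mean by more than \code{sdCut} standard deviations, with
#' mean and SD computed once per participant over all blocks pooled, after
#' the error/post-error/first-trial removals.
#'
#' A filtered table remembers the outlier bounds it was filtered with
#' (attribute \code{rtOutlierBounds}); re-filtering reuses them, so
#' filtering is idempotent unless \code{recomputeBounds = TRUE}.
#'
#' @param trials behavior trial table (see [generateBehaviorTable()]).
#' @param purpose \code{"rt"}, \code{"accuracy"} or \code{"eeg"}.
#' @param sdCut RT outlier cutoff in participant SD units.
#' @param recomputeBounds recompute outlier bounds even for a pre-filtered
#'   table.
#' @return list with \code{trials} (retained rows; a \code{row} column holds
#'   the original row index) and \code{counts}, a named integer vector of
#'   exclusions per reason (\code{practice}, \code{firstOfBlock},
#'   \code{error}, \code{postError}, \code{rtOutlier}); each removed row is
#'   counted under the first applicable reason, so the counts sum to the
#'   number of rows removed. Participants left with fewer than 2 retained
#'   trials trigger a warning.
#' @examples
#' tt <- generateBehaviorTable(simConfig(nParticipants = 1, nTrialsPerCell = 5,
#'                                       nBlocks = 1), seed = 2)
#' filterTrials(tt, "rt")$counts
#' @export
filterTrials <- function(trials, purpose = c("rt", "accuracy", "eeg"),
                         sdCut = 2.5, recomputeBounds = FALSE) {
  purpose <- match.arg(purpose)
  stopifnot(all(c("participant", "block", "trial", "rt", "correct")
                %in% names(trials)))
  if (is.null(trials$practice)) trials$practice <- FALSE
  if (is.null(trials$row)) trials$row <- seq_len(nrow(trials))
  grp <- interaction(trials$participant, trials$block, drop = TRUE)

  practice <- trials$practice
  # a block's first trial has no defined previous-trial label; using that
  # marker (rather than position) keeps filtering idempotent
  if (!is.null(trials$prev)) {
    firstOfBlock <- is.na(trials$prev) & !practice
  } else {
    firstOfBlock <- as.logical(
      stats::ave(practice, grp, FUN = function(pr) {
        first <- rep(FALSE, length(pr))
        idx <- which(!pr)
        if (length(idx)) first[idx[1L]] <- TRUE
        first
      }))
  }
  error <- !trials$correct
  postError <- as.logical(
    stats::ave(error, grp, FUN = function(e) c(FALSE, e[-length(e)])))

  if (purpose == "accuracy") {
    reason <- ifelse(practice, "practice",
              ifelse(firstOfBlock, "firstOfBlock", NA_character_))
  } else {
    base <- practice | firstOfBlock | error | postError
    bounds <- attr(trials, "rtOutlierBounds")
    if (is.null(bounds) || recomputeBounds) {
      keep <- !base
      mu <- tapply(trials$rt[keep], trials$participant[keep], mean)
      sdv <- tapply(trials$rt[keep], trials$participant[keep], stats::sd)
      bounds <- data.frame(participant = names(mu), mean = as.numeric(mu),
                           sd = as.numeric(sdv), stringsAsFactors = FALSE)
    }
    i <- match(as.character(trials$participant), bounds$participant)
    dev <- abs(trials$rt - bounds$mean[i])
    rtOutlier <- !is.na(dev) & !is.na(bounds$sd[i]) &
      dev > sdCut * bounds$sd[i]
    reason <- ifelse(practice, "practice",
              ifelse(firstOfBlock, "firstOfBlock",
              ifelse(error, "error",
              ifelse(postError, "postError",
              ifelse(rtOutlier, "rtOutlier", NA_character_)))))
  }

  reasons <- c("practice", "firstOfBlock", "error", "postError", "rtOutlier")
  counts <- stats::setNames(integer(length(reasons)), reasons)
  tab <- table(factor(reason, levels = reasons))
  counts[names(tab)] <- as.integer(tab)
  out <- trials[is.na(reason), , drop = FALSE]
  rownames(out) <- NULL
  small <- names(which(table(out$participant) < 2L))
  if (length(small))
    warning("participant(s) with < 2 retained trials: ",
            paste(small, collapse = ", "))
  if (purpose != "accuracy") attr(out, "rtOutlierBounds") <- bounds
  list(trials = out, counts = counts)
}

#' Behavioral congruency / congruency-sequence ANOVA
#'
#' Filters the trial table for the requested dependent variable, forms
#' per-participant cell means over the four Previous x Current congruency
#' cells (mean RT in ms, or accuracy as a percentage), and runs the 2 x 2
#' within-subject ANOVA with the four follow-up simple-effect paired t-tests.
#'
#' @param trials behavior trial table.
#' @param dv \code{"rt"} or \code{"accuracy"}.
#' @param alpha significance threshold.
#' @param followUp follow-up gating, as in [congruencyTable()].
#' @return list with \code{table} (StatTable data.frame), \code{cells}
#'   (participants x 4 cell-mean matrix) and \code{counts} (exclusion
#'   counts). Participants missing any cell are dropped with a warning.
#' @examples
#' tt <- generateBehaviorTable(simConfig(nParticipants = 8,
#'                                       nTrialsPerCell = 10, nBlocks = 1),
#'                             seed = 3)
#' behavioralAnova(tt, "rt")$table
#' @export
behavioralAnova <- function(trials, dv = c("rt", "accuracy"), alpha = 0.05,
                            followUp = c("auto", "always", "never")) {
  dv <- match.arg(dv)
  followUp <- match.arg(followUp)
  flt <- filterTrials(trials, purpose = if (dv == "rt") "rt" else "accuracy")
  tt <- flt$trials
  tt <- tt[!is.na(tt$prev), , drop = FALSE]
  tt$score <- if (dv == "rt") tt$rt else 100 * tt$correct
  long <- data.frame(participant = tt$participant, prev = tt$prev,
                     curr = tt$curr, score = tt$score,
                     stringsAsFactors = FALSE)
  cells <- cellMatrix(long)
  tab <- rmAnova2x2(cells, alpha = alpha)
  intSig <- tab$p[tab$effect == "interaction"] < alpha
  if (followUp == "always" || (followUp == "auto" && isTRUE(intSig)))
    tab <- rbind(tab, simpleEffects(cells, alpha = alpha))
  rownames(tab) <- NULL
  list(table = tab, cells = cells, counts = flt$counts)
}
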