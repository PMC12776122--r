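#' @include preprocess.R
NULL

#' Sparse frequency grid for slope estimation
#'
#' The wavelet decomposition runs at a sparse set of frequencies;
#' \code{fitMask} marks the frequencies entering the log-log slope fit. The
#' default grid is 2.5, 5, 7.5, 15 and 25 Hz with the alpha-adjacent
#' 7.5-15 Hz range excluded from fitting, so that narrowband oscillatory
#' power cannot bias the aperiodic estimate.
#'
#' @param freqs strictly increasing positive frequencies, Hz.
#' @param fitMask logical per frequency; at least two must be \code{TRUE}.
#' @return object of class \code{FrequencyGrid}.
#' @examples
#' frequencyGrid()
#' @export
frequencyGrid <- function(freqs = c(2.5, 5, 7.5, 15, 25),
                          fitMask = !(freqs >= 7.5 & freqs <= 15)) {
  if (any(freqs <= 0) || any(diff(freqs) <= 0))
    stop("'freqs' must be strictly increasing and positive")
  if (length(fitMask) != length(freqs))
    stop("'fitMask' must have one flag per frequency")
  if (sum(fitMask) < 2L)
    stop("at least two frequencies must enter the fit")
  structure(list(freqs = freqs, fitMask = fitMask), class = "FrequencyGrid")
}

#' @export
print.FrequencyGrid <- function(x, ...) {
  cat("FrequencyGrid:", paste0(x$freqs, ifelse(x$fitMask, "", "*"),
                               collapse = ", "), "Hz (* = excluded from fit)\n")
  invisible(x)
}

#' One-cycle quadrature wavelet pair
#'
#' A single unweighted cycle of a cosine and a sine at the requested
#' frequency, of length \code{round(fs/freq)} samples, scaled by
#' \code{2/length} so that the combined power response to a unit-amplitude
#' matched sinusoid is 1.
#'
#' @param freq frequency, Hz.
#' @param fs sampling rate, Hz.
#' @return list with \code{cos}, \code{sin} kernels, \code{freq} and the
#'   kernel \code{length}.
#' @export
waveletPair <- function(freq, fs) {
  L <- as.integer(round(fs / freq))
  if (L < 2L) stop("kernel for ", freq, " Hz would be shorter than 2 samples")
  phase <- 2 * pi * (0:(L - 1L)) / L
  list(cos = cos(phase) * 2 / L, sin = sin(phase) * 2 / L,
       freq = freq, length = L)
}

# Complex kernel FFTs, circularly pre-shifted so that the inverse transform
# rows 1..nSamples are the centred 'same' convolution (zero-padded edges).
waveletKernelFFT <- function(grid, fs, nSamples) {
  pairs <- lapply(grid$freqs, waveletPair, fs = fs)
  maxL <- max(vapply(pairs, `[[`, 0L, "length"))
  if (nSamples < maxL)
    stop("epoch shorter than the ", grid$freqs[which.max(
      vapply(pairs, `[[`, 0L, "length"))], " Hz kernel")
  nfft <- nextFastLength(nSamples + maxL)
  K <- vapply(pairs, function(p) {
    L <- p$length
    off <- (L - 1L) %/% 2L
    g <- complex(length.out = nfft)
    pos <- ((off - (0:(L - 1L))) %% nfft) + 1L
    g[pos] <- complex(real = p$cos, imaginary = p$sin)
    stats::fft(g)
  }, complex(nfft))
  attr(K, "nfft") <- nfft
  K
}

#' Instantaneous wavelet power
#'
#' Convolves every trial x channel series with the one-cycle cosine/sine
#' wavelet pair at each grid frequency (centred, zero-padded edges) and
#' combines the quadrature outputs into instantaneous power
#' \eqn{c(t)^2 + s(t)^2}.
#'
#' One-cycle kernels have a fixed number of cycles, so their bandwidth grows
#' proportionally to frequency. Under the default
#' \code{normalize = "density"} the quadrature power is divided by twice the
#' kernel frequency, converting it to a spectral-density scale (microvolts
#' squared per Hz) on which a \eqn{1/f^x} background yields a log-log slope
#' of \eqn{-x}. \code{normalize = "amplitude"} returns the raw quadrature
#' power, whose response to a unit-amplitude matched sinusoid is 1 but whose
#' log-log slope for a \eqn{1/f^x} background is \eqn{-(x-1)}.
#'
#' @param epochs an [EEGEpochs-class] (or trials x channels x samples array
#'   with \code{fs} supplied via \code{sampleRate}).
#' @param grid a [frequencyGrid()].
#' @param sampleRate sampling rate; only used when \code{epochs} is a bare
#'   array.
#' @param normalize \code{"density"} (default; slope-faithful spectral
#'   density) or \code{"amplitude"} (unit response to a matched sinusoid).
#' @return trials x channels x freqs x samples array of power, carrying
#'   \code{times}, \code{channelLabels}, \code{trialLink} and \code{grid}
#'   attributes when available.
#' @examples
#' fs <- 512; t <- (0:511) / fs
#' ep <- eegEpochs(array(sin(2 * pi * 5 * t), c(1, 1, 512)), fs, tmin = 0)
#' p <- waveletPower(ep, frequencyGrid(), normalize = "amplitude")
#' round(p[1, 1, 2, 256], 3)  # 5 Hz power mid-epoch
#' @export
waveletPower <- function(epochs, grid = frequencyGrid(), sampleRate = NULL,
                         normalize = c("density", "amplitude")) {
  normalize <- match.arg(normalize)
  if (methods::is(epochs, "EEGEpochs")) {
    data <- epochs@data
    fs <- epochs@sampleRate
    meta <- list(times = epochs@times, channelLabels = epochs@channelLabels,
                 trialLink = epochs@trialLink)
  } else {
    data <- epochs
    fs <- if (is.null(sampleRate)) stop("'sampleRate' required for bare arrays")
          else sampleRate
    meta <- NULL
  }
  d <- dim(data)
  K <- waveletKernelFFT(grid, fs, d[3L])
  X <- t(matrix(data, d[1L] * d[2L], d[3L]))  # samples x (trials*channels)
  cube <- .waveletPowerCpp(X, K)              # samples x series x freqs
  if (normalize == "density") {
    fKernel <- fs / round(fs / grid$freqs)    # actual one-cycle kernel freqs
    for (j in seq_along(fKernel))
      cube[, , j] <- cube[, , j] / (2 * fKernel[j])
  }
  power <- aperm(array(cube, c(d[3L], d[1L], d[2L], length(grid$freqs))),
                 c(2L, 3L, 4L, 1L))
  attr(power, "grid") <- grid
  attr(power, "sampleRate") <- fs
  attr(power, "normalize") <- normalize
  if (!is.null(meta)) {
    attr(power, "times") <- meta$times
    attr(power, "channelLabels") <- meta$channelLabels
    attr(power, "trialLink") <- meta$trialLink
  }
  power
}

#' Instantaneous aperiodic slope and intercept
#'
#' At every trial, channel and sample, fits ordinary least squares of
#' log10(power + floor) on log10(frequency) over the fit-masked grid
#' frequencies. The slope is the negative of the aperiodic exponent; the
#' intercept is the fitted log10 power at 1 Hz.
#'
#' @param power output of [waveletPower()].
#' @param grid the frequency grid; defaults to the grid the power was
#'   computed with.
#' @param floor power floor guarding \code{log10(0)}, microvolts squared.
#' @return a [SlopeSeries-class] (unsmoothed, all trials valid).
#' @export
fitSlopeTimecourse <- function(power, grid = attr(power, "grid"),
                               floor = 1e-12) {
  d <- dim(power)
  stopifnot(length(d) == 4L)
  if (is.null(grid)) stop("'grid' must be supplied")
  if (min(power) < 0) stop("negative power input; upstream contract violated")
  sel <- which(grid$fitMask)
  lf <- log10(grid$freqs[sel])
  lfc <- lf - mean(lf)
  wts <- lfc / sum(lfc^2)
  slope <- array(0, d[c(1L, 2L, 4L)])
  meanLp <- array(0, d[c(1L, 2L, 4L)])
  for (j in seq_along(sel)) {
    lp <- array(log10(power[, , sel[j], , drop = FALSE] + floor),
                d[c(1L, 2L, 4L)])
    slope <- slope + wts[j] * lp
    meanLp <- meanLp + lp / length(sel)
  }
  intercept <- meanLp - slope * mean(lf)
  times <- attr(power, "times")
  if (is.null(times)) times <- seq_len(d[4L])
  chl <- attr(power, "channelLabels")
  if (is.null(chl)) chl <- paste0("Ch", seq_len(d[2L]))
  tl <- attr(power, "trialLink")
  if (is.null(tl)) tl <- seq_len(d[1L])
  norm <- attr(power, "normalize")
  if (is.null(norm)) norm <- "amplitude"
  methods::new("SlopeSeries",
    slope = slope, intercept = intercept,
    validMask = rep(TRUE, d[1L]), times = as.numeric(times),
    channelLabels = chl, trialLink = as.integer(tl), smoothed = FALSE,
    normalization = norm)
}

#' Temporal smoothing and outlier censoring of slope series
#'
#' Applies a centred k-point moving average along time within each
#' trial x channel (edges use shrinking windows), then censors any trial
#' whose smoothed slope exceeds the plausibility bound at any
#' channel x sample by clearing its validity flag.
#'
#' The bound is defined on the raw-quadrature-power slope scale, the scale
#' on which such plausibility bounds are conventionally stated for this
#' estimator. For a density-normalized series (whose slope is exactly the
#' raw slope minus 1, because the density correction is itself a power law)
#' the censor therefore tests \code{|slope + 1| > bound}; for an
#' amplitude-normalized series it tests \code{|slope| > bound} directly.
#'
#' @param slopes a [SlopeSeries-class].
#' @param k moving-average length in samples; must be odd.
#' @param bound censoring bound on the absolute raw-scale slope.
#' @return the smoothed series; the number of newly censored trials is
#'   attached as attribute \code{censored}.
#' @export
smoothAndCensor <- function(slopes, k = 5L, bound = 4) {
  stopifnot(methods::is(slopes, "SlopeSeries"))
  if (k %% 2L == 0L) stop("'k' must be odd")
  if (bound <= 0) stop("'bound' must be positive")
  d <- dim(slopes@slope)
  sm <- function(a) {
    m <- matrix(aperm(a, c(3L, 1L, 2L)), d[3L], d[1L] * d[2L])
    m <- movingAverageCols(m, k)
    aperm(array(m, c(d[3L], d[1L], d[2L])), c(2L, 3L, 1L))
  }
  slopes@slope <- sm(slopes@slope)
  slopes@intercept <- sm(slopes@intercept)
  off <- if (identical(slopes@normalization, "density")) 1 else 0
  exceed <- apply(abs(slopes@slope + off) > bound, 1L, any)
  newly <- sum(exceed & slopes@validMask)
  slopes@validMask <- slopes@validMask & !exceed
  slopes@smoothed <- TRUE
  attr(slopes, "censored") <- newly
  slopes
}

#' Average slope series across trials per condition cell
#'
#' Arithmetic mean of the retained (valid) trials' slope time courses per
#' participant x Previous x Current congruency cell.
#'
#' @param slopes a [SlopeSeries-class].
#' @param trials the trial table; the slope series' \code{trialLink} indexes
#'   its \code{row} column (or row numbers).
#' @return array participants x 4 cells (\code{cC, cI, iC, iI}) x channels x
#'   samples with dimnames, time axis in attribute \code{times}; cells
#'   without any valid trial are \code{NA} and reported in attribute
#'   \code{missingCells}.
#' @export
conditionAverage <- function(slopes, trials) {
  stopifnot(methods::is(slopes, "SlopeSeries"))
  rows <- if (!is.null(trials$row)) trials$row else seq_len(nrow(trials))
  idx <- match(slopes@trialLink, rows)
  if (anyNA(idx)) stop("every slope trial must link to a trial-table row")
  d <- dim(slopes@slope)
  part <- sort(unique(trials$participant))
  cells <- congruencyCells()
  out <- array(NA_real_, c(length(part), 4L, d[2L], d[3L]),
               dimnames = list(participant = as.character(part),
                               cell = cells,
                               channel = slopes@channelLabels, NULL))
  missing <- character()
  key <- cellKey(trials$prev[idx], trials$curr[idx])
  for (p in seq_along(part)) {
    for (ci in seq_along(cells)) {
      sel <- which(trials$participant[idx] == part[p] & key == cells[ci] &
                   slopes@validMask)
      if (!length(sel)) {
        missing <- c(missing, paste0(part[p], ":", cells[ci]))
        next
      }
      out[p, ci, , ] <- colMeans(slopes@slope[sel, , , drop = FALSE])
    }
  }
  if (length(missing))
    warning("cells with no valid trials: ", paste(missing, collapse = ", "))
  attr(out, "times") <- slopes@times
  attr(out, "missingCells") <- missing
  out
}
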