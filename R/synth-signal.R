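#' @include layout.R
NULL

# One stationary zero-mean power-law segment of length n: frequency-domain
# amplitude shaping |A(f)| ~ f^(-x/2) with uniform random phases, inverse
# transformed and standardized to unit variance. Exact spectral control, no
# filter design.
powerLawSegment <- function(x, fs, n) {
  half <- n %/% 2L
  f <- (1:half) * fs / n
  amp <- f^(-x / 2)
  phase <- stats::runif(half, 0, 2 * pi)
  spec <- complex(modulus = amp, argument = phase)
  # Hermitian spectrum: DC = 0 (zero mean), real Nyquist bin for even n
  if (n %% 2L == 0L) spec[half] <- complex(real = amp[half] * sign(cos(phase[half])))
  full <- c(0, spec, Conj(rev(spec[seq_len(half - 1L + n %% 2L)])))
  sig <- Re(stats::fft(full, inverse = TRUE)) / n
  s <- stats::sd(sig)
  if (s > 0) sig / s else sig
}

#' Synthesize a power-law (1/f^x) signal with a possibly time-varying exponent
#'
#' Generates a zero-mean, unit-variance series whose power spectrum falls as
#' \eqn{f^{-x(t)}}. Stationary signals (constant exponent) are produced in one
#' shot by frequency-domain amplitude shaping with uniform random phases.
#' Time-varying exponents are realized by overlap-adding 500-ms stationary
#' segments under a 50\%-overlap Hann (cosine) crossfade, each segment using
#' the exponent at its center sample.
#'
#' @param exponentProfile either a single exponent \code{x} or a numeric
#'   vector of length \code{nSamples} giving \code{x} at every sample.
#'   Exponents must lie in \code{[0, 4)} (0 is the white-noise limit; values
#'   of 4 or more would not survive the downstream slope censor).
#' @param fs sampling rate, Hz.
#' @param nSamples number of samples (>= 64).
#' @param segmentMs stationary segment length for the time-varying case, ms.
#' @param seed optional integer; when given, the signal is generated under a
#'   private RNG state seeded with it.
#' @return numeric vector of length \code{nSamples}, microvolt-scale after
#'   multiplication by the caller's amplitude.
#' @examples
#' sig <- synthPowerLawEpoch(2, fs = 512, nSamples = 1024, seed = 1)
#' sd(sig)
#' @export
synthPowerLawEpoch <- function(exponentProfile, fs, nSamples,
                               segmentMs = 500, seed = NULL) {
  if (length(fs) != 1L || fs <= 0) stop("'fs' must be a single positive number")
  if (length(nSamples) != 1L || nSamples < 64L)
    stop("'nSamples' must be a single count >= 64")
  nSamples <- as.integer(nSamples)
  if (!length(exponentProfile) %in% c(1L, nSamples))
    stop("'exponentProfile' must be a scalar or define an exponent for every sample")
  if (any(exponentProfile < 0) || any(exponentProfile >= 4))
    stop("exponents must lie in [0, 4); got values outside that range")
  if (!is.null(seed)) return(withSeed(seed, synthPowerLawEpoch(
    exponentProfile, fs, nSamples, segmentMs)))

  if (length(exponentProfile) == 1L ||
      diff(range(exponentProfile)) < 1e-12) {
    sig <- powerLawSegment(exponentProfile[1L], fs, nSamples)
    return(sig - mean(sig))
  }

  L <- 2L * max(32L, as.integer(round(segmentMs / 1000 * fs / 2)))
  hop <- L %/% 2L
  win <- 0.5 * (1 - cos(2 * pi * (0:(L - 1L)) / L))  # periodic Hann: OLA sum 1
  starts <- seq(-hop, nSamples - hop, by = hop)
  out <- numeric(nSamples + 2L * L)
  off <- L  # padding so negative starts index validly
  for (s in starts) {
    center <- min(max(s + hop, 1L), nSamples)
    seg <- powerLawSegment(exponentProfile[center], fs, L) * win
    idx <- (s + off + 1L):(s + off + L)
    out[idx] <- out[idx] + seg
  }
  sig <- out[(off + 1L):(off + nSamples)] / sqrt(0.75)  # Hann 50%: sum w^2 = 3/4
  sig - mean(sig)
}
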