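# Independent oracles and shared fixtures used across the suite.

# Welch PSD log-log slope oracle: Hann-tapered averaged periodograms with
# 50% overlap, OLS of log10 power on log10 frequency over flim. Independent
# of the package's wavelet estimator.
welchSlope <- function(x, fs, flim = c(2, 40), seg = 2048) {
  starts <- seq(1, length(x) - seg + 1, by = seg %/% 2)
  win <- 0.5 * (1 - cos(2 * pi * (0:(seg - 1)) / seg))
  P <- 0
  for (s in starts) {
    X <- stats::fft(x[s:(s + seg - 1)] * win)
    P <- P + Mod(X)^2
  }
  P <- P / length(starts)
  f <- (0:(seg - 1)) * fs / seg
  sel <- f >= flim[1] & f <= flim[2]
  unname(stats::coef(stats::lm(log10(P[sel]) ~ log10(f[sel])))[2])
}

# Brute-force varimax criterion value (sum of per-column variance of squared
# loadings, Kaiser-normalized rows).
varimaxCriterion <- function(L, normalize = TRUE) {
  if (normalize) {
    h <- sqrt(rowSums(L^2))
    h[h == 0] <- 1
    L <- L / h
  }
  sum(apply(L^2, 2, stats::var))
}

# Pairwise-Jacobi varimax oracle: sweeps all column pairs, maximizing the
# criterion by a grid + golden-section refinement of the rotation angle.
varimaxJacobi <- function(L, iter = 50, normalize = TRUE) {
  h <- rep(1, nrow(L))
  if (normalize) {
    h <- sqrt(rowSums(L^2))
    h[h == 0] <- 1
  }
  Ln <- L / h
  k <- ncol(Ln)
  for (it in seq_len(iter)) {
    changed <- FALSE
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      obj <- function(th) {
        R <- diag(k)
        R[c(i, j), c(i, j)] <- matrix(c(cos(th), -sin(th),
                                        sin(th), cos(th)), 2, byrow = TRUE)
        varimaxCriterion(Ln %*% R, normalize = FALSE)
      }
      th <- stats::optimize(obj, c(-pi / 4, pi / 4), maximum = TRUE)$maximum
      if (obj(th) > obj(0) + 1e-12) {
        R <- diag(k)
        R[c(i, j), c(i, j)] <- matrix(c(cos(th), -sin(th),
                                        sin(th), cos(th)), 2, byrow = TRUE)
        Ln <- Ln %*% R
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  Ln * h
}

# 2x2 within-subject ANOVA oracle via stats::aov with an Error() stratum.
aovOracle <- function(cells) {
  n <- nrow(cells)
  df <- data.frame(
    y = as.vector(cells),
    id = factor(rep(seq_len(n), 4)),
    prev = factor(rep(c("c", "c", "i", "i"), each = n)),
    curr = factor(rep(c("C", "I", "C", "I"), each = n)))
  fit <- summary(stats::aov(y ~ prev * curr + Error(id / (prev * curr)),
                            data = df))
  getF <- function(stratum, term) {
    tab <- fit[[stratum]][[1]]
    tab[trimws(rownames(tab)) == term, "F value"]
  }
  c(prev = getF("Error: id:prev", "prev"),
    curr = getF("Error: id:curr", "curr"),
    interaction = getF("Error: id:prev:curr", "prev:curr"))
}

# Small generator configuration for fast tests.
tinyConfig <- function(nParticipants = 2, nTrialsPerCell = 3, nBlocks = 1, ...) {
  simConfig(nParticipants = nParticipants, nTrialsPerCell = nTrialsPerCell,
            nBlocks = nBlocks, ...)
}

# Hand-built 12-trial single-block toy table: one error at position 5.
toyTrialTable <- function() {
  data.frame(
    participant = 1, block = 1, trial = 1:12,
    prev = c(NA, rep(c("congruent", "incongruent"), 6)[1:11]),
    curr = rep(c("congruent", "incongruent"), 6),
    rt = c(600, 610, 620, 630, 640, 650, 660, 670, 680, 690, 700, 710),
    correct = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE,
                TRUE, TRUE, TRUE),
    rsi = 1000, practice = FALSE, stringsAsFactors = FALSE)
}

# Five-source scalp data for PCA recovery tests: three strong midline
# sources, two weak temporal ones, plus white sensor noise. Source
# amplitudes are scaled by the inverse scalp-map norm so each strong source
# projects equal total variance.
fiveSourceData <- function(nCases = 400, noiseSd = 0.3,
                           amps = c(1, 1, 1, 0.5, 0.5), sigma = 0.32) {
  layout <- scalpLayout()
  W <- sourceWeights(layout, sigma = sigma)  # compact maps: little overlap
  amps <- amps * mean(sqrt(colSums(W^2))) / sqrt(colSums(W^2))
  A <- matrix(stats::rnorm(nCases * 5), nCases, 5)
  X <- A %*% (t(W) * amps) +
    matrix(stats::rnorm(nCases * nrow(W), 0, noiseSd), nCases)
  list(data = X, layout = layout, weights = W)
}
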