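#' @include slope.R
NULL

#' Empirical Kaiser Criterion component retention
#'
#' Serial eigenvalue test against sample-size-aware reference values
#' \deqn{l^{ref}_j = \max\left((1+\sqrt{p/n})^2 \cdot
#'   \frac{p - \sum_{i<j}\lambda_i}{p - j + 1},\; 1\right)}
#' on correlation-metric eigenvalues (summing to the number of variables
#' \eqn{p}); components are retained while \eqn{\lambda_j > l^{ref}_j},
#' stopping at the first failure.
#'
#' @param eigenvalues non-increasing correlation-scale eigenvalues.
#' @param nCases number of observations the eigenvalues came from.
#' @param nVars number of variables.
#' @return number of components to retain (possibly 0).
#' @examples
#' ekcRetain(c(3, 1.5, 0.8, 0.4, 0.2, 0.1), nCases = 500, nVars = 6)
#' @export
ekcRetain <- function(eigenvalues, nCases, nVars) {
  if (any(diff(eigenvalues) > 1e-8))
    stop("'eigenvalues' must be non-increasing")
  if (nVars == 1L) return(1L)
  a <- (1 + sqrt(nVars / nCases))^2
  k <- 0L
  used <- 0
  for (j in seq_along(eigenvalues)) {
    lref <- max(a * (nVars - used) / (nVars - j + 1), 1)
    if (eigenvalues[j] > lref) {
      k <- j
      used <- used + eigenvalues[j]
    } else break
  }
  k
}

#' Varimax rotation with a deterministic sign convention
#'
#' Orthogonally rotates a loading matrix to maximize the (Kaiser-normalized)
#' varimax simplicity criterion, then fixes each component's sign so that its
#' largest-magnitude loading is positive. Single-column input is returned
#' sign-fixed with an identity rotation.
#'
#' @param loadings variables x components matrix (>= 1 column).
#' @return list with \code{loadings} (rotated) and \code{rotation}
#'   (orthonormal components x components matrix, sign convention included).
#'   Rank-deficient input triggers a warning and is returned unrotated.
#' @export
varimaxRotate <- function(loadings) {
  loadings <- as.matrix(loadings)
  k <- ncol(loadings)
  fixSigns <- function(L, R) {
    s <- vapply(seq_len(ncol(L)), function(j)
      ifelse(L[which.max(abs(L[, j])), j] < 0, -1, 1), 0)
    list(loadings = sweep(L, 2L, s, `*`),
         rotation = sweep(R, 2L, s, `*`))
  }
  if (k == 1L) return(fixSigns(loadings, diag(1L)))
  if (qr(loadings)$rank < k) {
    warning("rank-deficient loadings; returning input unrotated")
    return(list(loadings = loadings, rotation = diag(k)))
  }
  v <- stats::varimax(loadings, normalize = TRUE, eps = 1e-10)
  L <- matrix(as.numeric(v$loadings), nrow(loadings), k,
              dimnames = dimnames(loadings))
  fixSigns(L, as.matrix(v$rotmat))
}

#' Regression-method component scores
#'
#' Projects data onto a component model with the regression (Thurstone)
#' method: scores = data x covariance^-1 x rotated unstandardized loadings,
#' restricted to the retained components. Data are centred with the variable
#' means implied by the model's covariance construction being irrelevant to
#' within-participant contrasts; centring uses the data's own column means.
#'
#' @param data cases x variables matrix; variables must match the model.
#' @param model a [ComponentModel-class].
#' @param components which components to project on; defaults to the
#'   retained set. Use \code{seq_len(ncol(componentLoadings(model)))} for all
#'   extracted components.
#' @param center subtract column means before projecting.
#' @return cases x components score matrix.
#' @export
projectScores <- function(data, model, components = retainedComponents(model),
                          center = TRUE) {
  data <- as.matrix(data)
  if (ncol(data) != length(model@variables))
    stop("data variables do not match the component model")
  if (center) data <- sweep(data, 2L, colMeans(data, na.rm = TRUE))
  L <- model@loadingsRotated[, components, drop = FALSE]
  Sinv <- tryCatch(solve(model@covariance), error = function(e) {
    message("covariance singular; using pseudo-inverse")
    ev <- eigen(model@covariance, symmetric = TRUE)
    pos <- ev$values > max(ev$values) * 1e-12
    ev$vectors[, pos] %*% (t(ev$vectors[, pos]) / ev$values[pos])
  })
  sc <- data %*% Sinv %*% L
  colnames(sc) <- model@componentNames[components]
  sc
}

# Shared extraction machinery: covariance PCA, EKC on correlation-rescaled
# eigenvalues, varimax, 1/x variance filter.
buildComponentModel <- function(X, kind, varNames) {
  n <- nrow(X)
  p <- ncol(X)
  S <- stats::cov(X)
  ev <- eigen(S, symmetric = TRUE)
  lambda <- pmax(ev$values, 0)
  evCorr <- lambda * p / sum(lambda)
  nEKC <- ekcRetain(evCorr, nCases = n, nVars = p)
  total <- sum(lambda)
  if (nEKC == 0L) {
    empty <- matrix(numeric(), p, 0L)
    return(methods::new("ComponentModel",
      kind = kind, variables = varNames, eigenvalues = lambda,
      eigenvaluesCorr = evCorr, loadings = empty, loadingsRotated = empty,
      rotation = matrix(numeric(), 0L, 0L),
      explainedVariance = lambda / total, rotatedVariance = numeric(),
      retained = logical(), covariance = S, nCases = as.integer(n),
      componentNames = character()))
  }
  L <- ev$vectors[, seq_len(nEKC), drop = FALSE] %*%
    diag(sqrt(lambda[seq_len(nEKC)]), nEKC)
  rownames(L) <- varNames
  rot <- varimaxRotate(L)
  rotVar <- colSums(rot$loadings^2) / total
  ord <- order(rotVar, decreasing = TRUE)
  Lrot <- rot$loadings[, ord, drop = FALSE]
  rotVar <- rotVar[ord]
  # 1/x filter on shares of the extracted variance: varimax redistributes the
  # extracted variance, so shares are compared within the extracted space
  retained <- rotVar / sum(rotVar) >= 1 / nEKC
  methods::new("ComponentModel",
    kind = kind, variables = varNames, eigenvalues = lambda,
    eigenvaluesCorr = evCorr, loadings = L, loadingsRotated = Lrot,
    rotation = rot$rotation[, ord, drop = FALSE],
    explainedVariance = lambda / total, rotatedVariance = rotVar,
    retained = retained, covariance = S, nCases = as.integer(n),
    componentNames = paste0("PC", seq_len(nEKC)))
}

cropIndices <- function(times, crop) {
  which(times >= crop[1L] & times <= crop[2L])
}

#' Spatial PCA over electrodes
#'
#' Runs a covariance-based PCA with electrodes as variables and
#' participant x condition x timepoint rows as cases on condition-averaged
#' slope maps cropped to the analysis span, applies Empirical Kaiser
#' Criterion retention, varimax rotation, and the 1/x variance filter, and
#' names each component after the scalp region of its peak-magnitude
#' loading.
#'
#' @param condMaps participants x cells x channels x samples array from
#'   [conditionAverage()] (attribute \code{times} required).
#' @param layout channel layout data.frame matching the channels.
#' @param crop analysis span in ms (edge samples contaminated by wavelet
#'   edge effects are excluded).
#' @return a [ComponentModel-class] with region component names.
#' @export
runSpatialPCA <- function(condMaps, layout, crop = c(-300, 1300)) {
  times <- attr(condMaps, "times")
  d <- dim(condMaps)
  sel <- cropIndices(times, crop)
  if (!length(sel)) stop("crop span contains no samples")
  X <- matrix(aperm(condMaps[, , , sel, drop = FALSE], c(1L, 2L, 4L, 3L)),
              d[1L] * d[2L] * length(sel), d[3L])
  X <- X[stats::complete.cases(X), , drop = FALSE]
  if (nrow(X) < d[3L])
    warning("fewer cases than electrodes; EKC retention is unreliable")
  model <- buildComponentModel(X, "spatial", dimnames(condMaps)[[3L]])
  k <- ncol(model@loadingsRotated)
  if (k > 0L) {
    regions <- vapply(seq_len(k), function(j) {
      peak <- which.max(abs(model@loadingsRotated[, j]))
      layout$region[peak]
    }, "")
    model@componentNames <- make.unique(regions, sep = ".")
  }
  model
}

#' Temporal PCA over timepoints
#'
#' Runs the same extraction machinery as [runSpatialPCA()] with decimated
#' cropped timepoints as variables and participant x condition x electrode
#' rows as cases, and estimates each retained component's duration as the
#' FWHM of its loading curve.
#'
#' @param condMaps participants x cells x channels x samples array.
#' @param crop analysis span, ms.
#' @param decimation take every \code{decimation}-th sample inside the crop
#'   (default 10, about 51 Hz at a 512 Hz record, so a 160-ms window holds
#'   8-9 points).
#' @return list with \code{model} (a [ComponentModel-class], component names
#'   are peak latencies) and \code{components}, a data.frame of
#'   \code{name}, \code{peakTime} (ms), \code{fwhm} (ms) and
#'   \code{truncated} per retained component.
#' @export
runTemporalPCA <- function(condMaps, crop = c(-300, 1300), decimation = 10L) {
  times <- attr(condMaps, "times")
  d <- dim(condMaps)
  sel <- cropIndices(times, crop)
  sel <- sel[seq(1L, length(sel), by = decimation)]
  if (length(sel) < 2L) stop("crop/decimation leave fewer than 2 timepoints")
  tSel <- times[sel]
  X <- matrix(aperm(condMaps[, , , sel, drop = FALSE], c(1L, 2L, 3L, 4L)),
              d[1L] * d[2L] * d[3L], length(sel))
  X <- X[stats::complete.cases(X), , drop = FALSE]
  model <- buildComponentModel(X, "temporal", sprintf("t%.0f", tSel))
  k <- ncol(model@loadingsRotated)
  comps <- NULL
  if (k > 0L) {
    comps <- do.call(rbind, lapply(seq_len(k), function(j) {
      curve <- model@loadingsRotated[, j]
      peak <- tSel[which.max(curve)]
      fw <- tryCatch(estimateFWHM(tSel, curve),
                     error = function(e) list(fwhm = NA_real_, truncated = TRUE))
      data.frame(name = sprintf("t%.0f", peak), peakTime = peak,
                 fwhm = fw$fwhm, truncated = fw$truncated,
                 retained = model@retained[j], stringsAsFactors = FALSE)
    }))
    model@componentNames <- make.unique(comps$name, sep = ".")
  }
  list(model = model, components = comps)
}

#' Full width at half maximum of a loading curve
#'
#' Finds the unique global maximum of the curve and the linearly
#' interpolated half-maximum crossings nearest the peak on either side. A
#' side that never drops below half maximum is truncated at the curve edge
#' and flagged.
#'
#' @param times x-axis, ms.
#' @param curve loading values (a peaked, roughly non-negative curve).
#' @return list with \code{fwhm} (ms), \code{left}, \code{right} crossing
#'   positions and \code{truncated}.
#' @examples
#' t <- seq(-300, 1300, by = 2)
#' estimateFWHM(t, exp(-(t - 400)^2 / (2 * 68^2)))$fwhm  # ~160 ms
#' @export
estimateFWHM <- function(times, curve) {
  stopifnot(length(times) == length(curve))
  if (diff(range(curve)) == 0) stop("curve has no peak")
  ipk <- which.max(curve)
  half <- curve[ipk] / 2
  truncated <- FALSE
  crossing <- function(idx) {
    below <- which(curve[idx] < half)
    if (!length(below)) {
      truncated <<- TRUE
      return(times[idx[length(idx)]])
    }
    i1 <- idx[below[1L]]                       # first point below half-max
    i0 <- i1 - sign(i1 - ipk)                  # neighbour toward the peak
    times[i0] + (half - curve[i0]) * (times[i1] - times[i0]) /
      (curve[i1] - curve[i0])
  }
  left <- if (ipk == 1L) { truncated <- TRUE; times[1L] } else
    crossing(rev(seq_len(ipk - 1L)))
  right <- if (ipk == length(curve)) { truncated <- TRUE; times[length(curve)] } else
    crossing((ipk + 1L):length(curve))
  list(fwhm = right - left, left = left, right = right, truncated = truncated)
}

#' Segment the analysis span into fixed-width windows anchored at onset
#'
#' Builds consecutive non-overlapping windows of \code{width} ms extending
#' from stimulus onset (0 ms) in both directions; windows that do not fit
#' fully inside the crop span are dropped. Post-stimulus windows are
#' lower-exclusive/upper-inclusive \code{(l, u]}; pre-stimulus windows are
#' closed \code{[l, u]}.
#'
#' @param crop analysis span, ms (must contain 0).
#' @param width window width, ms.
#' @return data.frame with columns \code{label}, \code{lower}, \code{upper},
#'   \code{lowerIncl}, \code{upperIncl}, ordered in time.
#' @examples
#' segmentWindows(c(-300, 1300), 160)$label
#' @export
segmentWindows <- function(crop = c(-300, 1300), width = 160) {
  if (width <= 0) stop("'width' must be positive")
  if (crop[1L] > 0 || crop[2L] < 0) stop("'crop' must contain 0 ms")
  if (width > crop[2L] && width > -crop[1L])
    stop("no full window of ", width, " ms fits inside the crop span")
  post <- if (crop[2L] >= width) seq(0, crop[2L] - width, by = width)
          else numeric()
  pre <- if (-crop[1L] >= width) -seq(width, -crop[1L], by = width)
         else numeric()
  rows <- list()
  for (lo in rev(pre))
    rows[[length(rows) + 1L]] <- data.frame(
      label = sprintf("[%g,%g]", lo, lo + width), lower = lo,
      upper = lo + width, lowerIncl = TRUE, upperIncl = TRUE,
      stringsAsFactors = FALSE)
  for (lo in post)
    rows[[length(rows) + 1L]] <- data.frame(
      label = sprintf("(%g,%g]", lo, lo + width), lower = lo,
      upper = lo + width, lowerIncl = FALSE, upperIncl = TRUE,
      stringsAsFactors = FALSE)
  do.call(rbind, rows)
}

#' Spatial component scores over time
#'
#' Projects the cropped condition-averaged slope maps onto the retained
#' spatial components with the regression method, giving one score time
#' course per participant x condition x component.
#'
#' @param condMaps participants x cells x channels x samples array.
#' @param model spatial [ComponentModel-class].
#' @param crop analysis span, ms.
#' @return array participants x cells x components x cropped samples,
#'   attribute \code{times} carries the cropped axis.
#' @export
spatialScores <- function(condMaps, model, crop = c(-300, 1300)) {
  times <- attr(condMaps, "times")
  d <- dim(condMaps)
  sel <- cropIndices(times, crop)
  comp <- retainedComponents(model)
  X <- matrix(aperm(condMaps[, , , sel, drop = FALSE], c(1L, 2L, 4L, 3L)),
              d[1L] * d[2L] * length(sel), d[3L])
  sc <- projectScores(X, model, components = comp)
  out <- aperm(array(sc, c(d[1L], d[2L], length(sel), length(comp))),
               c(1L, 2L, 4L, 3L))
  dimnames(out) <- list(participant = dimnames(condMaps)[[1L]],
                        cell = dimnames(condMaps)[[2L]],
                        component = model@componentNames[comp], NULL)
  attr(out, "times") <- times[sel]
  out
}

#' Average component scores inside each time window
#'
#' @param scores participants x cells x components x samples array from
#'   [spatialScores()] (attribute \code{times} required).
#' @param windows window definition from [segmentWindows()].
#' @return long data.frame with columns \code{participant},
#'   \code{component}, \code{prev}, \code{curr}, \code{window},
#'   \code{lower}, \code{upper}, \code{score}; boundary timepoints follow
#'   each window's inclusion convention.
#' @export
windowScores <- function(scores, windows) {
  times <- attr(scores, "times")
  d <- dim(scores)
  dn <- dimnames(scores)
  cellPrev <- c(cC = "congruent", cI = "congruent",
                iC = "incongruent", iI = "incongruent")
  cellCurr <- c(cC = "congruent", cI = "incongruent",
                iC = "congruent", iI = "incongruent")
  out <- list()
  for (w in seq_len(nrow(windows))) {
    lo <- windows$lower[w]; hi <- windows$upper[w]
    inWin <- (if (windows$lowerIncl[w]) times >= lo else times > lo) &
             (if (windows$upperIncl[w]) times <= hi else times < hi)
    if (!any(inWin))
      stop("window ", windows$label[w], " contains no timepoints")
    m <- apply(scores[, , , inWin, drop = FALSE], c(1L, 2L, 3L), mean)
    grid <- expand.grid(participant = dn[[1L]], cell = dn[[2L]],
                        component = dn[[3L]], stringsAsFactors = FALSE)
    out[[w]] <- data.frame(
      participant = grid$participant, component = grid$component,
      prev = cellPrev[grid$cell], curr = cellCurr[grid$cell],
      window = windows$label[w], lower = lo, upper = hi,
      score = as.vector(m), stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
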