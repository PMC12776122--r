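#' @include utils.R
NULL

#' Synthetic scalp channel layout
#'
#' Builds a deterministic rectangular-grid approximation of an extended 10-20
#' montage with the frontal-pole row already excluded: channels are placed on
#' an anterior-posterior x left-right grid over the scalp and assigned to one
#' of five regions (frontal, central, occipital, left-temporal,
#' right-temporal) by position. The default 56-channel layout is an 8 x 7
#' grid.
#'
#' @param nChannels number of channels (default 56).
#' @return data.frame with columns \code{label}, \code{x} (left-right, -1..1),
#'   \code{y} (posterior-anterior, -1..1) and \code{region}.
#' @examples
#' head(scalpLayout())
#' table(scalpLayout()$region)
#' @export
scalpLayout <- function(nChannels = 56L) {
  nChannels <- as.integer(nChannels)
  stopifnot(nChannels >= 1L)
  ncols <- 8L
  nrows <- as.integer(ceiling(nChannels / ncols))
  xs <- if (ncols > 1L) seq(-0.875, 0.875, length.out = ncols) else 0
  ys <- if (nrows > 1L) seq(0.9, -0.9, length.out = nrows) else 0
  grid <- expand.grid(x = xs, y = ys)[seq_len(nChannels), ]
  region <- ifelse(grid$y >= 0.4, "frontal",
            ifelse(grid$y <= -0.5, "occipital",
            ifelse(grid$x <= -0.6, "left-temporal",
            ifelse(grid$x >= 0.6, "right-temporal", "central"))))
  abbrev <- c(frontal = "F", central = "C", occipital = "O",
              `left-temporal` = "LT", `right-temporal` = "RT")
  idx <- stats::ave(seq_along(region), region, FUN = seq_along)
  data.frame(
    label = paste0(abbrev[region], idx),
    x = grid$x, y = grid$y, region = region,
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Gaussian scalp weight maps for the simulated background sources
#'
#' Each simulated power-law background source projects to the scalp through a
#' Gaussian weight map: three strong midline sources (frontal, central,
#' occipital) and two weak lateral ones (left- and right-temporal),
#' mirroring a five-component scalp topography in which only the three
#' midline components carry substantial variance.
#'
#' @param layout a layout data.frame from [scalpLayout()].
#' @param sigma Gaussian width of each map in layout units.
#' @return channels x 5 matrix with columns \code{frontal}, \code{central},
#'   \code{occipital}, \code{left-temporal}, \code{right-temporal}; the peak
#'   weight of each map is 1.
#' @export
sourceWeights <- function(layout, sigma = 0.45) {
  centers <- rbind(frontal = c(0, 0.75), central = c(0, 0),
                   occipital = c(0, -0.75),
                   `left-temporal` = c(-0.8, 0),
                   `right-temporal` = c(0.8, 0))
  w <- sapply(rownames(centers), function(s) {
    d2 <- (layout$x - centers[s, 1L])^2 + (layout$y - centers[s, 2L])^2
    exp(-d2 / (2 * sigma^2))
  })
  rownames(w) <- layout$label
  w
}
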