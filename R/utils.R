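#' @include AllClasses.R
NULL

# Centered k-point moving average along the first dimension of a matrix,
# with shrinking windows at the edges (mean over the samples that exist).
movingAverageCols <- function(x, k) {
  stopifnot(k %% 2L == 1L)
  if (k == 1L) return(x)
  n <- nrow(x)
  h <- (k - 1L) %/% 2L
  cs <- apply(x, 2L, cumsum)
  if (is.null(dim(cs))) cs <- matrix(cs, ncol = ncol(x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  upper <- cs[hi, , drop = FALSE]
  lower <- rbind(0, cs)[lo, , drop = FALSE]
  (upper - lower) / (hi - lo + 1L)
}

# Deterministic child seed derived from a base seed and a stream index;
# keeps everything inside 32-bit integer range.
childSeed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 69621) %% 2147483563) + 1L
}

# Evaluate with a private RNG state so callers' streams are untouched.
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# smallest 5-smooth (2^a 3^b 5^c) integer >= n, for fast FFT sizes
nextFastLength <- function(n) {
  if (n <= 6) return(as.integer(n))
  best <- 2^ceiling(log2(n))
  p5 <- 1
  while (p5 < best) {
    p35 <- p5
    while (p35 < best) {
      k <- p35 * 2^ceiling(log2(n / p35))
      if (k >= n && k < best) best <- k
      p35 <- p35 * 3
    }
    p5 <- p5 * 5
  }
  as.integer(best)
}

cellKey <- function(prev, curr) {
  paste0(substr(as.character(prev), 1L, 1L),
         toupper(substr(as.character(curr), 1L, 1L)))
}

#' Default cell order of the 2x2 Previous x Current design
#'
#' Cells are keyed \code{cC, cI, iC, iI}: the lowercase letter is the previous
#' trial's congruency, the uppercase letter the current trial's.
#' @return character vector of the four cell keys.
#' @export
congruencyCells <- function() c("cC", "cI", "iC", "iI")
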