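#' @include utils.R
NULL

statRow <- function(effect, statistic, value, df1, df2, p, epsilonHF = NA_real_,
                    etaP2 = NA_real_, cohensD = NA_real_, alpha = 0.05,
                    component = NA_character_, window = NA_character_) {
  data.frame(component = component, window = window, effect = effect,
             statistic = statistic, value = value, df1 = df1, df2 = df2,
             p = p, epsilonHF = epsilonHF, etaP2 = etaP2, cohensD = cohensD,
             significant = is.finite(p) && p < alpha,
             stringsAsFactors = FALSE)
}

#' Paired t-test with Cohen's d
#'
#' Classical two-tailed paired t-test on participant-matched values, with the
#' paired effect size \eqn{d = \bar{d} / SD(d)}.
#'
#' @param a,b numeric vectors of equal length >= 2, paired by participant.
#' @param alpha significance threshold.
#' @param component,window optional labels copied into the output row.
#' @return one-row data.frame with columns \code{effect}, \code{statistic},
#'   \code{value} (t), \code{df1}, \code{df2} (n-1), \code{p}, \code{etaP2}
#'   (NA), \code{cohensD} and \code{significant}. Zero-variance differences
#'   with nonzero mean yield an infinite t with p = 0; all-identical pairs
#'   yield t = 0, p = 1.
#' @examples
#' pairedT(c(2, 3, 4), c(1, 1, 1))
#' @export
pairedT <- function(a, b, alpha = 0.05, component = NA_character_,
                    window = NA_character_) {
  stopifnot(length(a) == length(b), length(a) >= 2L)
  d <- a - b
  n <- length(d)
  md <- mean(d)
  sdd <- stats::sd(d)
  if (sdd == 0) {
    if (md == 0) {
      t <- 0; p <- 1; cd <- 0
    } else {
      t <- sign(md) * Inf; p <- 0; cd <- sign(md) * Inf
    }
  } else {
    t <- md / (sdd / sqrt(n))
    p <- 2 * stats::pt(-abs(t), n - 1)
    cd <- md / sdd
  }
  statRow("paired", "t", t, NA_real_, n - 1, p, epsilonHF = NA_real_,
          etaP2 = NA_real_, cohensD = cd, alpha = alpha,
          component = component, window = window)
}

#' Huynh-Feldt sphericity correction factor
#'
#' General Huynh-Feldt epsilon for one within-subject factor with k levels,
#' computed from the Greenhouse-Geisser epsilon of the orthonormalized
#' contrast covariance and capped at 1. Two-level factors satisfy sphericity
#' trivially and always return 1.
#'
#' @param x participants x levels matrix of the repeated measure.
#' @return epsilon in (0, 1].
#' @export
hfEpsilon <- function(x) {
  k <- ncol(x)
  if (k <= 2L) return(1)
  n <- nrow(x)
  C <- stats::contr.helmert(k)
  C <- qr.Q(qr(C))  # orthonormal contrasts
  D <- t(C) %*% stats::cov(x) %*% C
  gg <- sum(diag(D))^2 / ((k - 1) * sum(D^2))
  hf <- (n * (k - 1) * gg - 2) / ((k - 1) * (n - 1 - (k - 1) * gg))
  min(1, hf)
}

#' Two-by-two within-subject ANOVA via contrast t-statistics
#'
#' Main effects and interaction of a fully within-subject 2 x 2 design
#' (Previous x Current congruency), each computed exactly as the squared
#' paired t on the corresponding within-participant contrast of cell means:
#' F(1, n-1) = t^2. Reports partial eta squared
#' \eqn{\eta_p^2 = F / (F + df_{err})} and the Huynh-Feldt epsilon (1 for
#' two-level factors).
#'
#' @param cells participants x 4 matrix with columns \code{cC, cI, iC, iI}
#'   (lowercase previous, uppercase current congruency).
#' @param alpha significance threshold.
#' @param component,window optional labels for the output rows.
#' @return data.frame with rows \code{currCongruency},
#'   \code{prevCongruency}, \code{interaction}.
#' @examples
#' set.seed(1)
#' cells <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, congruencyCells()))
#' rmAnova2x2(cells)
#' @export
rmAnova2x2 <- function(cells, alpha = 0.05, component = NA_character_,
                       window = NA_character_) {
  stopifnot(is.matrix(cells), ncol(cells) == 4L)
  if (is.null(colnames(cells))) colnames(cells) <- congruencyCells()
  cells <- cells[, congruencyCells(), drop = FALSE]
  n <- nrow(cells)
  stopifnot(n >= 2L)
  contrasts <- list(
    currCongruency = (cells[, "cC"] + cells[, "iC"]) / 2 -
                     (cells[, "cI"] + cells[, "iI"]) / 2,
    prevCongruency = (cells[, "cC"] + cells[, "cI"]) / 2 -
                     (cells[, "iC"] + cells[, "iI"]) / 2,
    interaction = (cells[, "cC"] - cells[, "cI"]) -
                  (cells[, "iC"] - cells[, "iI"]))
  rows <- lapply(names(contrasts), function(nm) {
    d <- contrasts[[nm]]
    sdd <- stats::sd(d)
    if (sdd == 0) {
      Fv <- if (mean(d) == 0) 0 else Inf
    } else {
      Fv <- (mean(d) / (sdd / sqrt(n)))^2
    }
    p <- if (is.infinite(Fv)) 0 else stats::pf(Fv, 1, n - 1, lower.tail = FALSE)
    statRow(nm, "F", Fv, 1, n - 1, p, epsilonHF = 1,
            etaP2 = if (is.infinite(Fv)) 1 else Fv / (Fv + n - 1),
            alpha = alpha, component = component, window = window)
  })
  do.call(rbind, rows)
}

#' Pre- vs post-stimulus baseline contrasts on windowed component scores
#'
#' For every component and post-stimulus window, runs a paired t-test of the
#' condition-averaged window score against the pre-stimulus window
#' (the window whose upper edge is at 0 ms).
#'
#' @param scores long data.frame from [windowScores()] with columns
#'   \code{participant}, \code{component}, \code{prev}, \code{curr},
#'   \code{window}, \code{lower}, \code{upper}, \code{score}.
#' @param alpha significance threshold.
#' @return StatTable data.frame, one row per component x post-stimulus
#'   window.
#' @export
baselineContrastTable <- function(scores, alpha = 0.05) {
  winInfo <- unique(scores[, c("window", "lower", "upper")])
  preWin <- winInfo$window[winInfo$upper <= 0]
  if (length(preWin) != 1L)
    stop("windowed scores must contain exactly one pre-stimulus window")
  postWin <- winInfo$window[winInfo$lower >= 0]
  if (!length(postWin)) {
    warning("no post-stimulus windows; returning empty table")
    return(statRow("none", "t", NA_real_, NA_real_, NA_real_, NA_real_)[0, ])
  }
  # condition-average per participant x component x window
  agg <- stats::aggregate(score ~ participant + component + window,
                          data = scores, FUN = mean)
  out <- lapply(unique(agg$component), function(comp) {
    sub <- agg[agg$component == comp, ]
    pre <- sub[sub$window == preWin, ]
    pre <- pre[order(pre$participant), ]
    do.call(rbind, lapply(postWin, function(w) {
      post <- sub[sub$window == w, ]
      post <- post[order(post$participant), ]
      stopifnot(identical(pre$participant, post$participant))
      pairedT(post$score, pre$score, alpha = alpha, component = comp,
              window = w)
    }))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$effect <- "postVsPre"
  res
}

#' Congruency and congruency-sequence ANOVA table on windowed scores
#'
#' Per component and time window, a 2 x 2 within-subject ANOVA (Current
#' Congruency, Previous Congruency, interaction) on the windowed component
#' scores; where the interaction is significant, the four follow-up
#' simple-effect paired t-tests are appended (the previous-congruency effect
#' within each current level and the congruency effect within each previous
#' level).
#'
#' @param scores long data.frame from [windowScores()].
#' @param alpha significance threshold.
#' @param followUp \code{"auto"} (follow-ups only where the interaction has
#'   p < alpha), \code{"always"} or \code{"never"}.
#' @param adjust p-adjustment method applied across ANOVA rows
#'   (\code{"none"} by default, mirroring raw-p reporting;
#'   \code{"BH"} available).
#' @return StatTable data.frame.
#' @export
congruencyTable <- function(scores, alpha = 0.05,
                            followUp = c("auto", "always", "never"),
                            adjust = "none") {
  followUp <- match.arg(followUp)
  out <- list()
  for (comp in unique(scores$component)) {
    for (w in unique(scores$window)) {
      sub <- scores[scores$component == comp & scores$window == w, ]
      cells <- cellMatrix(sub)
      tab <- rmAnova2x2(cells, alpha = alpha, component = comp, window = w)
      intSig <- tab$p[tab$effect == "interaction"] < alpha
      if (followUp == "always" || (followUp == "auto" && isTRUE(intSig))) {
        fu <- simpleEffects(cells, alpha = alpha, component = comp, window = w)
        tab <- rbind(tab, fu)
      }
      out[[length(out) + 1L]] <- tab
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (adjust != "none") {
    anova_rows <- res$statistic == "F"
    res$p[anova_rows] <- stats::p.adjust(res$p[anova_rows], method = adjust)
    res$significant <- res$p < alpha
  }
  res
}

# participants x 4 cell-mean matrix from a long score data.frame
cellMatrix <- function(sub) {
  sub$cell <- cellKey(sub$prev, sub$curr)
  agg <- stats::aggregate(score ~ participant + cell, data = sub, FUN = mean)
  wide <- stats::reshape(agg, idvar = "participant", timevar = "cell",
                         direction = "wide")
  wide <- wide[order(wide$participant), ]
  cols <- paste0("score.", congruencyCells())
  if (!all(cols %in% names(wide)))
    stop("each participant must contribute all four congruency cells")
  m <- as.matrix(wide[, cols])
  colnames(m) <- congruencyCells()
  if (anyNA(m)) {
    drop <- which(rowSums(is.na(m)) > 0)
    warning(length(drop), " participant(s) dropped due to missing cells")
    m <- m[-drop, , drop = FALSE]
  }
  m
}

# The four simple-effect paired t-tests of a significant 2x2 interaction.
simpleEffects <- function(cells, alpha = 0.05, component = NA_character_,
                          window = NA_character_) {
  tests <- list(
    prevWithinCongruent = c("iC", "cC"),
    prevWithinIncongruent = c("iI", "cI"),
    congruencyAfterCongruent = c("cI", "cC"),
    congruencyAfterIncongruent = c("iI", "iC"))
  out <- lapply(names(tests), function(nm) {
    ab <- tests[[nm]]
    row <- pairedT(cells[, ab[1L]], cells[, ab[2L]], alpha = alpha,
                   component = component, window = window)
    row$effect <- nm
    row
  })
  do.call(rbind, out)
}
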