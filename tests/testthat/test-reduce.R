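test_that("EKC retention follows the serial reference-value rule", {
  # single variable: trivially one component
  expect_equal(ekcRetain(2.4, nCases = 100, nVars = 1), 1L)
  # hand-computed serial rule on a small spectrum
  lam <- c(3, 1.5, 0.8, 0.4, 0.2, 0.1)
  a <- (1 + sqrt(6 / 500))^2
  l1 <- max(a * 6 / 6, 1)
  l2 <- max(a * (6 - 3) / 5, 1)
  l3 <- max(a * (6 - 4.5) / 4, 1)
  expect_true(lam[1] > l1 && lam[2] > l2 && lam[3] <= l3)
  expect_equal(ekcRetain(lam, nCases = 500, nVars = 6), 2L)
  expect_error(ekcRetain(c(1, 2), 10, 2), "non-increasing")
})

test_that("EKC finds two planted factors and rejects pure noise (Monte Carlo)", {
  set.seed(42)
  hits2 <- hits0 <- 0
  for (i in 1:60) {
    f <- matrix(rnorm(2 * 1000), 1000, 2)
    X <- f[, c(1, 1, 1, 2, 2, 2)] * 0.8 + matrix(rnorm(6000), 1000, 6) * 0.6
    lam <- sort(eigen(cor(X), symmetric = TRUE)$values, decreasing = TRUE)
    hits2 <- hits2 + (ekcRetain(lam, 1000, 6) == 2L)
    N <- matrix(rnorm(6000), 1000, 6)
    lamN <- sort(eigen(cor(N), symmetric = TRUE)$values, decreasing = TRUE)
    hits0 <- hits0 + (ekcRetain(lamN, 1000, 6) == 0L)
  }
  expect_gte(hits2 / 60, 0.95)
  expect_gt(hits0 / 60, 0.5)
})

test_that("varimax matches the pairwise-Jacobi oracle and conserves communality", {
  set.seed(8)
  L <- matrix(rnorm(30), 10, 3)
  out <- varimaxRotate(L)
  expect_equal(crossprod(out$rotation), diag(3), tolerance = 1e-8)
  expect_equal(rowSums(out$loadings^2), rowSums(L^2), tolerance = 1e-8)
  # criterion at least as good as before rotation, and equal to the oracle's
  oracle <- varimaxJacobi(L)
  expect_gte(varimaxCriterion(out$loadings) + 1e-10, varimaxCriterion(L))
  expect_equal(varimaxCriterion(out$loadings), varimaxCriterion(oracle),
               tolerance = 1e-6)
  # block-simple loadings are a fixed point up to permutation and sign
  B <- rbind(matrix(c(1, 0), 4, 2, byrow = TRUE) * 0.9,
             matrix(c(0, 1), 4, 2, byrow = TRUE) * 0.7)
  outB <- varimaxRotate(B)
  recov <- abs(t(outB$loadings) %*% B) / (colSums(B^2))
  expect_true(all(apply(recov, 1, max) > 0.999))
  # single column: identity rotation with positive peak sign
  one <- varimaxRotate(matrix(c(-3, 1, 2), 3, 1))
  expect_equal(one$loadings[, 1], c(3, -1, -2))
})

test_that("regression-method scores reproduce and reconstruct", {
  set.seed(10)
  n <- 300; p <- 5
  X <- matrix(rnorm(n * p), n, p) %*% matrix(rnorm(p * p), p, p)
  S <- cov(X)
  ev <- eigen(S, symmetric = TRUE)
  L <- ev$vectors %*% diag(sqrt(ev$values))
  model <- methods::new("ComponentModel",
    kind = "spatial", variables = paste0("v", 1:p),
    eigenvalues = ev$values, eigenvaluesCorr = ev$values * p / sum(ev$values),
    loadings = L, loadingsRotated = L, rotation = diag(p),
    explainedVariance = ev$values / sum(ev$values),
    rotatedVariance = ev$values / sum(ev$values),
    retained = rep(TRUE, p), covariance = S, nCases = as.integer(n),
    componentNames = paste0("PC", 1:p))
  sc <- projectScores(X, model)
  # full-rank reconstruction to numerical precision
  Xc <- sweep(X, 2, colMeans(X))
  expect_equal(sc %*% t(L), Xc, tolerance = 1e-8, ignore_attr = TRUE)
  # scores of a pure loading pattern: 1 on its component, 0 elsewhere
  sc1 <- projectScores(rbind(L[, 2], 0), model, center = FALSE)
  expect_equal(as.vector(sc1[1, ]), c(0, 1, 0, 0, 0), tolerance = 1e-8)
  expect_equal(as.vector(sc1[2, ]), rep(0, p))
  expect_error(projectScores(X[, 1:3], model), "match")
})

test_that("spatial PCA recovers the planted sources with correct regions", {
  set.seed(19)
  src <- fiveSourceData(nCases = 400)
  maps <- array(src$data, c(10, 4, 10, 56))  # fold cases into p x cell x time
  condMaps <- aperm(maps, c(1, 2, 4, 3))
  attr(condMaps, "times") <- seq(0, 180, by = 20)
  dimnames(condMaps) <- list(participant = as.character(1:10),
                             cell = congruencyCells(),
                             channel = src$layout$label, NULL)
  model <- runSpatialPCA(condMaps, src$layout, crop = c(0, 180))
  kept <- componentNames(model)[retainedComponents(model)]
  expect_setequal(kept, c("frontal", "central", "occipital"))
  # relabeling invariance: permuting electrodes permutes loadings rows only
  perm <- sample(56)
  condMapsP <- condMaps[, , perm, ]
  attr(condMapsP, "times") <- attr(condMaps, "times")
  layoutP <- src$layout[perm, ]
  modelP <- runSpatialPCA(condMapsP, layoutP, crop = c(0, 180))
  expect_setequal(componentNames(modelP)[retainedComponents(modelP)], kept)
  expect_equal(sort(abs(componentLoadings(modelP)[, 1])),
               sort(abs(componentLoadings(model)[, 1])), tolerance = 1e-6)
})

test_that("component model bookkeeping invariants hold", {
  set.seed(20)
  src <- fiveSourceData(nCases = 300)
  model <- aperiodics:::buildComponentModel(src$data, "spatial",
                                            src$layout$label)
  expect_equal(sum(explainedVariance(model)), 1, tolerance = 1e-8)
  expect_true(all(diff(eigenValues(model)) < 1e-8))
  expect_true(all(eigenValues(model) >= -1e-10))
  # retained components each hold at least 1/k of the extracted variance
  k <- ncol(componentLoadings(model))
  shares <- model@rotatedVariance / sum(model@rotatedVariance)
  expect_true(all(shares[model@retained] >= 1 / k - 1e-12))
  expect_true(all(shares[!model@retained] < 1 / k))
  # standardized loadings are loadings over variable SD
  Ls <- componentLoadings(model, standardized = TRUE)
  expect_equal(Ls, componentLoadings(model) / sqrt(diag(model@covariance)),
               tolerance = 1e-12)
})

test_that("temporal PCA localizes bursts and reports their FWHM", {
  set.seed(21)
  times <- seq(-300, 1300, by = 20)
  nT <- length(times)
  burst1 <- exp(-(times - 200)^2 / (2 * 60^2))
  burst2 <- exp(-(times - 900)^2 / (2 * 60^2))
  nCase <- 240
  amp <- matrix(rnorm(nCase * 2), nCase, 2)
  X <- amp %*% rbind(burst1, burst2) * 3 +
    matrix(rnorm(nCase * nT), nCase, nT) * 0.4
  condMaps <- aperm(array(X, c(10, 4, 6, nT)), c(1, 2, 3, 4))
  attr(condMaps, "times") <- times
  dimnames(condMaps) <- list(participant = as.character(1:10),
                             cell = congruencyCells(),
                             channel = paste0("Ch", 1:6), NULL)
  res <- runTemporalPCA(condMaps, crop = c(-300, 1300), decimation = 1L)
  comps <- res$components
  near1 <- comps[abs(comps$peakTime - 200) < 40, ]
  near2 <- comps[abs(comps$peakTime - 900) < 40, ]
  expect_gte(nrow(near1), 1L)
  expect_gte(nrow(near2), 1L)
  # FWHM near the Gaussian closed form, burst intervals disjoint
  fw <- 2 * sqrt(2 * log(2)) * 60
  expect_lt(abs(near1$fwhm[1] - fw), 25)
  expect_lt(abs(near2$fwhm[1] - fw), 25)
  expect_lt(near1$peakTime[1] + near1$fwhm[1] / 2,
            near2$peakTime[1] - near2$fwhm[1] / 2)
})

test_that("FWHM matches closed forms and flags truncation", {
  t <- seq(-300, 1300, by = 2)
  g <- estimateFWHM(t, exp(-(t - 400)^2 / (2 * 68^2)))
  expect_lt(abs(g$fwhm - 2 * sqrt(2 * log(2)) * 68), 0.5)
  expect_false(g$truncated)
  # triangle of half-width 100: linear interpolation is exact
  tri <- pmax(0, 1 - abs(t - 500) / 100)
  expect_equal(estimateFWHM(t, tri)$fwhm, 100, tolerance = 1e-8)
  # peak at the edge: truncated flag set
  edge <- estimateFWHM(t, exp(-(t + 290)^2 / (2 * 68^2)))
  expect_true(edge$truncated)
  expect_error(estimateFWHM(t, rep(1, length(t))), "peak")
})

test_that("window segmentation reproduces the canonical nine windows", {
  w <- segmentWindows(c(-300, 1300), 160)
  expect_equal(nrow(w), 9L)
  expect_equal(w$label,
               c("[-160,0]", "(0,160]", "(160,320]", "(320,480]", "(480,640]",
                 "(640,800]", "(800,960]", "(960,1120]", "(1120,1280]"))
  expect_equal(w$upper[nrow(w)], 1280)
  expect_true(w$lowerIncl[1] && w$upperIncl[1])
  expect_true(all(!w$lowerIncl[-1]))
  # tight crop: exactly two windows
  w2 <- segmentWindows(c(-160, 160), 160)
  expect_equal(nrow(w2), 2L)
  expect_error(segmentWindows(c(-300, 1300), 1600), "no full window")
})

test_that("window means respect boundary conventions (index-set oracle)", {
  set.seed(22)
  times <- seq(-300, 1300, by = 20)
  sc <- array(rnorm(2 * 4 * 1 * length(times)), c(2, 4, 1, length(times)))
  dimnames(sc) <- list(participant = c("1", "2"), cell = congruencyCells(),
                       component = "frontal", NULL)
  attr(sc, "times") <- times
  w <- segmentWindows(c(-300, 1300), 160)
  ws <- windowScores(sc, w)
  # brute-force oracle for one participant x cell x window
  for (wi in c(1, 2, 5)) {
    lo <- w$lower[wi]; hi <- w$upper[wi]
    mask <- if (w$lowerIncl[wi]) times >= lo & times <= hi
            else times > lo & times <= hi
    want <- mean(sc[1, 1, 1, mask])
    got <- ws$score[ws$participant == "1" & ws$prev == "congruent" &
                    ws$curr == "congruent" & ws$window == w$label[wi]]
    expect_equal(got, want, tolerance = 1e-12)
  }
  # t = 160 ms belongs to (0,160], not (160,320]
  i160 <- which(times == 160)
  expect_true(times[i160] <= 160)
  m1 <- ws$score[ws$participant == "1" & ws$prev == "congruent" &
                 ws$curr == "congruent" & ws$window == "(0,160]"]
  expect_equal(m1, mean(sc[1, 1, 1, times > 0 & times <= 160]),
               tolerance = 1e-12)
  # constant series: every window mean equals the constant
  scC <- sc; scC[] <- 3.14
  attr(scC, "times") <- times
  wsC <- windowScores(scC, w)
  expect_true(all(abs(wsC$score - 3.14) < 1e-12))
})
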