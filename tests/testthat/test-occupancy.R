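constTrack <- function(value, len = 20000L, chrom = "chr1") {
  SignalTrack(RleList(setNames(list(Rle(value, len)), chrom),
                      compress = FALSE), totalReads = 1e6)
}

test_that("two-line mark assignment requires a peak in both lines", {
  r <- bedRanges("chr1", c(1000, 5000), c(2000, 6000))
  a <- PeakSet("H1", "H3K9ac", bedRanges("chr1", c(1200, 5100),
                                         c(1400, 5300)))
  b <- PeakSet("H9", "H3K9ac", bedRanges("chr1", 1300, 1500))
  expect_equal(assignMarksTwoLines(r, a, b), c(TRUE, FALSE))
  # equals the composition of two independent overlap queries
  set.seed(60)
  q <- grOn(randomIntervals(100, 50000L))
  pa <- grOn(randomIntervals(60, 50000L))
  pb <- grOn(randomIntervals(60, 50000L))
  expect_equal(assignMarksTwoLines(q, pa, pb),
               overlapsWithin(q, pa) & overlapsWithin(q, pb))
})

test_that("TF occupancy applies the peak FDR filter", {
  r <- bedRanges("chr1", c(0, 5000), c(1000, 6000))
  r$category <- factor(c("bivalent", "K4only"),
                       levels = c("bivalent", "K4only", "K27only"))
  pk <- bedRanges("chr1", c(100, 5100), c(300, 5400))
  pk$fdr <- c(0.01, 0.2)   # second peak fails FDR < 0.05
  occ <- tfOccupancy(r, PeakSet("H1", "EZH2", pk))
  expect_equal(occ[["bivalent"]], 1)
  expect_equal(occ[["K4only"]], 0)
})

test_that("planted occupancy rates are recovered within binomial error", {
  set.seed(61)
  nA <- 300L; nB <- 300L
  startA <- seq(0, by = 5000, length.out = nA)
  startB <- seq(nA * 5000, by = 5000, length.out = nB)
  r <- bedRanges("chr1", c(startA, startB), c(startA, startB) + 1000)
  r$category <- factor(rep(c("bivalent", "K4only"), c(nA, nB)),
                       levels = c("bivalent", "K4only", "K27only"))
  pA <- 0.9; pB <- 0.2
  hitA <- runif(nA) < pA
  hitB <- runif(nB) < pB
  st <- c(startA[hitA], startB[hitB])
  pk <- bedRanges("chr1", st + 200, st + 400)
  pk$fdr <- rep(0.001, length(pk))
  occ <- tfOccupancy(r, pk)
  expect_lt(abs(occ[["bivalent"]] - pA), 3 * sqrt(pA * (1 - pA) / nA))
  expect_lt(abs(occ[["K4only"]] - pB), 3 * sqrt(pB * (1 - pB) / nB))
})

test_that("chi-squared matches the closed form and its symmetry", {
  z <- chiSquared2x2(50, 100, 50, 100)
  expect_equal(z$statistic, 0)
  expect_equal(z$p.value, 1)
  # hand-computed: occupied 90/100 vs 50/100, expected 70/30 per group
  z2 <- chiSquared2x2(90, 100, 50, 100)
  expect_equal(z2$statistic, 400 / 70 + 400 / 30 + 400 / 70 + 400 / 30,
               tolerance = 1e-12)
  expect_equal(z2$statistic, 38.0952380952, tolerance = 1e-9)
  z3 <- chiSquared2x2(50, 100, 90, 100)
  expect_equal(z2$statistic, z3$statistic)
  expect_error(chiSquared2x2(0, 10, 0, 10), "expected cell")
  # closed form on many random tables
  set.seed(62)
  for (i in 1:200) {
    tA <- sample(5:200, 1); tB <- sample(5:200, 1)
    oA <- sample.int(tA, 1); oB <- sample.int(tB, 1)
    tab <- rbind(c(oA, tA - oA), c(oB, tB - oB))
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(E == 0)) next
    want <- sum((tab - E)^2 / E)
    expect_equal(chiSquared2x2(oA, tA, oB, tB)$statistic, want,
                 tolerance = 1e-9)
  }
})

test_that("signal matrices reproduce constant tracks and direct bin averages", {
  r <- bedRanges("chr1", c(4000, 10000), c(5000, 11000))
  sm <- signalMatrix(r, constTrack(3), halfWindow = 1000, nBins = 10)
  expect_true(all(sm$matrix == 3))
  expect_equal(sm$profile, rep(3, 10))
  # zero track -> zero everywhere
  expect_true(all(signalMatrix(r, constTrack(0), 1000, 10)$matrix == 0))
  # random track: cells match direct per-bin averaging
  set.seed(63)
  v <- rpois(20000L, 2)
  tr <- SignalTrack(RleList(list(chr1 = Rle(v)), compress = FALSE),
                    totalReads = 1e6)
  sm2 <- signalMatrix(r, tr, halfWindow = 500, nBins = 5)
  for (i in 1:2) {
    center <- floor((asBed(r)$start[i] + asBed(r)$end[i]) / 2)
    for (b in 1:5) {
      lo <- center - 500 + (b - 1) * 200
      expect_equal(sm2$matrix[i, b], mean(v[(lo + 1):(lo + 200)]))
    }
  }
  # linearity: scaling the track scales every cell
  tr2 <- SignalTrack(RleList(list(chr1 = Rle(v * 4)), compress = FALSE),
                     totalReads = 1e6)
  expect_equal(signalMatrix(r, tr2, 500, 5)$matrix, sm2$matrix * 4)
})

test_that("feature extraction equals direct window sums in RPM", {
  set.seed(64)
  v <- c(rep(0, 5000), rpois(2000, 5), rep(0, 13000))
  tr <- SignalTrack(RleList(list(chr1 = Rle(v)), compress = FALSE),
                    totalReads = 2e6)
  r <- bedRanges("chr1", 5500, 6000)
  r$region_id <- "R1"
  f <- extractFeatures(r, list(X = tr), flank = 1000)
  want <- sum(v[(5500 - 1000 + 1):(6000 + 1000)]) * 1e6 / 2e6
  expect_equal(unname(f[1, "X"]), want)
  # a delta deposit inside the window is conserved
  v2 <- rep(0, 20000); v2[6000] <- 123
  tr2 <- SignalTrack(RleList(list(chr1 = Rle(v2)), compress = FALSE),
                     totalReads = 1e6)
  expect_equal(unname(extractFeatures(r, list(X = tr2), 1000)[1, "X"]), 123)
  # all-zero tracks give all-zero features
  expect_true(all(extractFeatures(r, list(X = constTrack(0)), 1000) == 0))
})

plantedBlobs <- function(n = 240, props = c(0.17, 0.22, 0.61), sep = 6,
                         seed = 65) {
  set.seed(seed)
  sizes <- round(props * n)
  sizes[3] <- n - sum(sizes[1:2])
  lab <- rep(1:3, sizes)
  centers <- rbind(c(1, sep, sep, 1),
                   c(sep, 1, 1, sep / 2),
                   c(sep / 2, sep / 2, sep / 2, sep / 3))
  colnames(centers) <- c("EZH2", "PolII", "TAF1", "TCF12")
  x <- 2^(centers[lab, ] + matrix(rnorm(n * 4, 0, 0.3), n, 4)) - 1
  x[x < 0] <- 0
  colnames(x) <- colnames(centers)
  list(features = x, labels = lab)
}

test_that("K-means recovers well-separated planted clusters with correct labels", {
  pb <- plantedBlobs()
  cl <- labelClusters(kmeansThree(pb$features), pb$features)
  expect_gte(mclust::adjustedRandIndex(cl, pb$labels), 0.95)
  # semantic labels: planted blob 1 is PolII/TAF1-high -> label 1;
  # planted blob 2 is EZH2-high -> label 2
  expect_equal(as.integer(names(which.max(table(cl[pb$labels == 1])))), 1L)
  expect_equal(as.integer(names(which.max(table(cl[pb$labels == 2])))), 2L)
})

test_that("K-means is invariant to duplication and input order under a fixed seed", {
  pb <- plantedBlobs(n = 120, seed = 66)
  base <- labelClusters(kmeansThree(pb$features), pb$features)
  dup <- labelClusters(kmeansThree(rbind(pb$features, pb$features)),
                       rbind(pb$features, pb$features))
  expect_equal(dup[seq_len(nrow(pb$features))], base)
  expect_equal(dup[-seq_len(nrow(pb$features))], base)
  perm <- sample(nrow(pb$features))
  permCl <- labelClusters(kmeansThree(pb$features[perm, ]),
                          pb$features[perm, ])
  expect_equal(permCl[order(perm)], base)
})

test_that("K-means rejects degenerate input", {
  x <- matrix(1, nrow = 10, ncol = 4,
              dimnames = list(NULL, c("EZH2", "PolII", "TAF1", "TCF12")))
  expect_error(kmeansThree(x), "distinct")
})

test_that("semantic labeling follows the stated rules on explicit means", {
  feats <- rbind(matrix(rep(c(1, 10, 10, 1), 5), 5, 4, byrow = TRUE),
                 matrix(rep(c(9, 1, 1, 4), 5), 5, 4, byrow = TRUE),
                 matrix(rep(c(3, 3, 3, 2), 5), 5, 4, byrow = TRUE))
  colnames(feats) <- c("EZH2", "PolII", "TAF1", "TCF12")
  assign <- rep(c(3L, 1L, 2L), each = 5)  # arbitrary k-means ids
  lab <- labelClusters(assign, feats)
  expect_equal(lab[1:5], rep(1L, 5))    # PolII/TAF1-high
  expect_equal(lab[6:10], rep(2L, 5))   # EZH2-high among the rest
  expect_equal(lab[11:15], rep(3L, 5))
})
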