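test_that("per-line bivalent domains are the width-filtered K4/K27 overlap", {
  k4 <- PeakSet("H1", "H3K4me3", bedRanges("chr1", 1000, 5000))
  k27 <- PeakSet("H1", "H3K27me3", bedRanges("chr1", 4000, 9000))
  dom <- callBivalentDomains(k4, k27)
  expect_same_intervals(dom, data.frame(start = 4000, end = 5000))
  expect_equal(dom$cellLine, "H1")

  # containment: two separate K27 peaks inside one broad K4 peak
  k4b <- PeakSet("H1", "H3K4me3", bedRanges("chr1", 0, 10000))
  k27b <- PeakSet("H1", "H3K27me3",
                  bedRanges("chr1", c(2000, 6000), c(3000, 8000)))
  expect_same_intervals(callBivalentDomains(k4b, k27b),
                        data.frame(start = c(2000, 6000),
                                   end = c(3000, 8000)))

  # mismatched cell lines rejected
  expect_error(callBivalentDomains(
    PeakSet("H1", "H3K4me3", bedRanges("chr1", 0, 2000)),
    PeakSet("H9", "H3K27me3", bedRanges("chr1", 0, 2000))),
    "different cell lines")
})

test_that("bivalent calling matches the boolean AND oracle on random peaks", {
  len <- 100000L
  set.seed(43)
  for (rep in 1:10) {
    a <- randomIntervals(400, len, maxW = 1500L)
    b <- randomIntervals(400, len, maxW = 1500L)
    dom <- callBivalentDomains(grOn(a), grOn(b), minOverlap = 1000)
    ma <- maskFromBed(a$start, a$end, len)
    mb <- maskFromBed(b$start, b$end, len)
    expect_same_intervals(dom, bedFromMask(ma & mb, minWidth = 1000L))
  }
})

test_that("cross-line merge records supporting lines", {
  domA <- bedRanges("chr1", 1000, 3000)
  domB <- bedRanges("chr1", 1000, 3000)
  m <- mergeAcrossLines(list(A = domA, B = domB))
  expect_equal(length(m), 1L)
  expect_equal(m$n_lines, 2L)
  expect_equal(m$lines, "A,B")

  mOnly <- mergeAcrossLines(list(A = domA, B = GRanges()))
  expect_equal(mOnly$n_lines, 1L)
  expect_equal(mOnly$lines, "A")

  # jittered domains merge into the union span with full support
  sh <- c(-200L, -100L, 0L, 100L, 200L)
  doms <- lapply(sh, function(s) bedRanges("chr1", 5000 + s, 7000 + s))
  names(doms) <- paste0("L", 1:5)
  mj <- mergeAcrossLines(doms)
  expect_same_intervals(mj, data.frame(start = 4800, end = 7200))
  expect_equal(mj$n_lines, 5L)
})

test_that("high-confidence selection keeps full-support regions only", {
  m <- mergeAcrossLines(list(A = bedRanges("chr1", 0, 2000),
                             B = bedRanges("chr1", c(0, 8000),
                                           c(2000, 10000))))
  hc <- selectHighConfidence(m, 2L)
  expect_equal(length(hc), 1L)
  expect_equal(asBed(hc)$start, 0L)
  expect_equal(length(selectHighConfidence(m, 1L)), 2L)
})

test_that("exclusive regions: consensus, width filter and bivalent exclusion", {
  lines <- paste0("L", 1:5)
  k4 <- setNames(lapply(lines, function(ln)
    PeakSet(ln, "H3K4me3", bedRanges("chr1", 0, 3000))), lines)
  expect_same_intervals(callExclusiveRegions(k4, GRanges()),
                        data.frame(start = 0, end = 3000))
  # one line's bivalent domain discards the entire region, not a trimmed piece
  biv <- bedRanges("chr1", 2500, 3600)
  expect_equal(length(callExclusiveRegions(k4, biv)), 0L)
})

test_that("exclusive-region calling matches the 5-line boolean oracle", {
  len <- 100000L
  set.seed(44)
  for (rep in 1:6) {
    peakDfs <- lapply(1:5, function(i) randomIntervals(150, len, 3000L))
    bivDf <- randomIntervals(20, len, 2000L)
    ps <- lapply(seq_along(peakDfs), function(i)
      PeakSet(paste0("L", i), "H3K4me3", grOn(peakDfs[[i]])))
    names(ps) <- paste0("L", 1:5)
    got <- callExclusiveRegions(ps, grOn(bivDf), minWidth = 1000)

    masks <- lapply(peakDfs, function(d) maskFromBed(d$start, d$end, len))
    common <- Reduce(`&`, masks)
    runs <- bedFromMask(common, minWidth = 1000L)
    mbiv <- maskFromBed(bivDf$start, bivDf$end, len)
    keep <- vapply(seq_len(nrow(runs)), function(i)
      !any(mbiv[(runs$start[i] + 1):runs$end[i]]), logical(1L))
    expect_same_intervals(got, runs[keep, , drop = FALSE])
  }
})

test_that("sex chromosomes are excluded", {
  gr <- bedRanges(c("chr7", "chrX", "chrY"), c(0, 0, 500),
                  c(2000, 2000, 1500))
  out <- excludeChromosomes(gr)
  expect_equal(as.character(seqnames(out)), "chr7")
  expect_equal(length(out), length(gr) - 2L)
})

test_that("planted truth is recovered exactly at zero jitter and dropout", {
  study <- simulateStudy(genomeSpec(seed = 11, nBivalent = 40, nK4only = 40,
                                    nK27only = 30, nGenes = 160),
                         jitterSd = 0, dropout = 0, tracks = FALSE,
                         methylomes = FALSE, expression = FALSE)
  st <- callChromatinStates(study$peaks$k4, study$peaks$k27)
  tr <- truthRegions(study$truth)
  hc <- asBed(regions(st))
  for (cc in c("bivalent", "K4only", "K27only")) {
    got <- hc[hc$category == cc, c("chrom", "start", "end")]
    want <- tr[tr$category == cc, c("chrom", "start", "end")]
    got <- got[order(got$chrom, got$start), ]
    want <- want[order(want$chrom, want$start), ]
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got$chrom, want$chrom)
    expect_equal(got$start, as.integer(want$start))
    expect_equal(got$end, as.integer(want$end))
  }
})

test_that("the three HC lists are pairwise disjoint and respect width floors", {
  study <- simulateStudy(genomeSpec(seed = 12, nBivalent = 40, nK4only = 40,
                                    nK27only = 30, nGenes = 160),
                         jitterSd = 60, dropout = 0.1, tracks = FALSE,
                         methylomes = FALSE, expression = FALSE)
  st <- callChromatinStates(study$peaks$k4, study$peaks$k27)
  gr <- regions(st)
  cov <- coverage(gr)
  expect_true(all(vapply(cov, function(r) all(runValue(r) <= 1L),
                         logical(1L))))
  expect_true(all(width(gr) >= 1000))
  expect_false(any(as.character(seqnames(gr)) %in% c("chrX", "chrY")))
})

test_that("consensus support is monotone: adding a line never adds HC regions", {
  study <- simulateStudy(genomeSpec(seed = 13, nBivalent = 30, nK4only = 20,
                                    nK27only = 20, nGenes = 120),
                         jitterSd = 40, dropout = 0.15, tracks = FALSE,
                         methylomes = FALSE, expression = FALSE)
  k4 <- study$peaks$k4
  k27 <- study$peaks$k27
  st4 <- callChromatinStates(k4[1:4], k27[1:4])
  st5 <- callChromatinStates(k4, k27)
  # every 5-line HC bivalent region lies inside some 4-line HC region
  b5 <- regions(st5, "bivalent")
  b4 <- regions(st4, "bivalent")
  if (length(b5))
    expect_true(all(overlapsWithin(b5, b4)))
  expect_lte(length(b5), length(b4))
})

test_that("dropout yields the binomial full-support fraction", {
  dropout <- 0.2
  study <- simulateStudy(genomeSpec(seed = 14), jitterSd = 0,
                         dropout = dropout, tracks = FALSE,
                         methylomes = FALSE, expression = FALSE)
  st <- callChromatinStates(study$peaks$k4, study$peaks$k27)
  merged <- mergedBivalent(st)
  frac <- mean(merged$n_lines == 5L)
  p <- (1 - dropout)^5
  n <- length(merged)
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(frac - p), 3 * se + 0.01)
})
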