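suppressPackageStartupMessages(library(GenomicRanges))

# Base-wise boolean-array oracles for the interval algebra: a chromosome is a
# logical vector with one slot per base (0-based position i -> slot i + 1).
# These deliberately re-derive every set operation from first principles so
# the GRanges-backed implementation is checked against an independent route.

maskFromBed <- function(start, end, len) {
  m <- logical(len)
  for (i in seq_along(start)) {
    lo <- max(start[i], 0) + 1L
    hi <- min(end[i], len)
    if (hi >= lo) m[lo:hi] <- TRUE
  }
  m
}

# maximal TRUE runs as 0-based half-open intervals, optionally width-filtered
bedFromMask <- function(mask, minWidth = 1L) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values & r$lengths >= minWidth
  data.frame(start = starts[keep], end = ends[keep])
}

randomIntervals <- function(n, len, maxW = 2000L) {
  start <- sample.int(len - 1L, n, replace = TRUE) - 1L
  w <- sample.int(maxW, n, replace = TRUE)
  data.frame(start = start, end = pmin(start + w, len))
}

grOn <- function(df, chrom = "chr1") bedRanges(chrom, df$start, df$end)

bedDf <- function(gr) {
  df <- asBed(gr)[, c("start", "end")]
  rownames(df) <- NULL
  df
}

# a tiny three-category region set used by several files
mkStates <- function() {
  r <- bedRanges("chr1", c(1000, 4000, 8000), c(2000, 5500, 9500))
  r$region_id <- c("BIV_00001", "K4_00001", "K27_00001")
  r$category <- factor(c("bivalent", "K4only", "K27only"),
                       levels = c("bivalent", "K4only", "K27only"))
  r
}

expect_same_intervals <- function(gr, oracleDf) {
  got <- bedDf(gr)
  want <- oracleDf[, c("start", "end")]
  rownames(want) <- NULL
  expect_equal(got$start, as.integer(want$start))
  expect_equal(got$end, as.integer(want$end))
}
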