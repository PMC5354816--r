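# Mark/TF occupancy of the consensus regions, signal matrices, chi-squared
# occupancy comparisons, and the 3-cluster partition of bivalent regions by
# EZH2 / PolII / TAF1 / TCF12 signal.

#' Two-line mark assignment
#'
#' A histone mark is assigned to a region only when an overlapping peak is
#' present in both reference cell lines (H1 and H9 in the original design).
#'
#' @param regionsGr \code{GRanges} of regions.
#' @param peaksA,peaksB \linkS4class{PeakSet}s (or \code{GRanges}) for the
#'   same mark in the two lines.
#' @return Logical vector along \code{regionsGr}.
#' @export
assignMarksTwoLines <- function(regionsGr, peaksA, peaksB) {
  if (is(peaksA, "PeakSet") && is(peaksB, "PeakSet") &&
      mark(peaksA) != mark(peaksB))
    stop("the two peak sets carry different marks: ",
         mark(peaksA), " vs ", mark(peaksB))
  ga <- if (is(peaksA, "PeakSet")) peaks(peaksA) else peaksA
  gb <- if (is(peaksB, "PeakSet")) peaks(peaksB) else peaksB
  overlapsWithin(regionsGr, ga) & overlapsWithin(regionsGr, gb)
}

#' Transcription-factor occupancy per region category
#'
#' Peaks are filtered at \code{fdr < fdrMax} (when a per-peak \code{fdr}
#' column is present) and the fraction of regions in each category overlapping
#' at least one retained peak is returned.
#'
#' @param regionsGr \code{GRanges} with a \code{category} column.
#' @param tfPeaks \linkS4class{PeakSet} (or \code{GRanges}) for one factor,
#'   optionally with an \code{fdr} metadata column.
#' @param fdrMax per-peak FDR threshold.
#' @return Named numeric vector of occupied fractions, one per category
#'   present, plus attributes \code{occupied} and \code{total} (counts).
#' @export
tfOccupancy <- function(regionsGr, tfPeaks, fdrMax = 0.05) {
  stopifnot(!is.null(regionsGr$category))
  g <- if (is(tfPeaks, "PeakSet")) peaks(tfPeaks) else tfPeaks
  if (!is.null(g$fdr)) g <- g[!is.na(g$fdr) & g$fdr < fdrMax]
  hit <- if (length(g)) overlapsWithin(regionsGr, g)
         else rep(FALSE, length(regionsGr))
  cats <- as.factor(regionsGr$category)
  occ <- tapply(hit, cats, sum)
  tot <- tapply(rep(1L, length(hit)), cats, sum)
  occ[is.na(occ)] <- 0L
  tot[is.na(tot)] <- 0L
  frac <- ifelse(tot > 0, occ / tot, NA_real_)
  structure(as.numeric(frac), names = names(frac),
            occupied = as.integer(occ), total = as.integer(tot))
}

#' Pearson chi-squared test on a 2x2 occupancy table
#'
#' Compares occupied/total counts between two region categories with a 1-df
#' Pearson chi-squared test, no continuity correction.
#'
#' @param occupiedA,totalA,occupiedB,totalB counts for the two groups.
#' @return List with \code{statistic}, \code{p.value} and the 2x2
#'   \code{table}.
#' @export
chiSquared2x2 <- function(occupiedA, totalA, occupiedB, totalB) {
  stopifnot(totalA > 0, totalB > 0,
            occupiedA >= 0, occupiedB >= 0,
            occupiedA <= totalA, occupiedB <= totalB)
  tab <- rbind(c(occupiedA, totalA - occupiedA),
               c(occupiedB, totalB - occupiedB))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected == 0))
    stop("chi-squared undefined: an expected cell count is zero")
  ht <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(statistic = unname(ht$statistic), p.value = unname(ht$p.value),
       table = tab)
}

#' Binned signal matrix over anchored windows
#'
#' For each region, a window of \code{2 * halfWindow} bases centered on the
#' region midpoint is split into \code{nBins} equal bins and each cell is the
#' mean track value over the bin (window bins reaching past a chromosome edge
#' average over the available bases). Row order follows the region list.
#'
#' @param regionsGr \code{GRanges}.
#' @param track a \linkS4class{SignalTrack}.
#' @param halfWindow half window width in bp.
#' @param nBins number of bins; \code{2 * halfWindow} must be divisible by
#'   \code{nBins}.
#' @return List with \code{matrix} (regions x bins) and \code{profile}
#'   (column means).
#' @export
signalMatrix <- function(regionsGr, track, halfWindow = 5000, nBins = 100) {
  stopifnot(is(track, "SignalTrack"), nBins >= 1,
            (2 * halfWindow) %% nBins == 0)
  binW <- (2 * halfWindow) / nBins
  n <- length(regionsGr)
  m <- matrix(0, nrow = n, ncol = nBins)
  if (n) {
    center <- floor((start(regionsGr) - 1L + end(regionsGr)) / 2)  # 0-based
    chrom <- as.character(seqnames(regionsGr))
    for (ch in unique(chrom)) {
      if (!ch %in% names(track@cov)) next
      idx <- which(chrom == ch)
      rle <- track@cov[[ch]]
      clen <- length(rle)
      for (b in seq_len(nBins)) {
        lo0 <- center[idx] - halfWindow + (b - 1L) * binW   # 0-based starts
        hi0 <- lo0 + binW
        lo <- pmax(lo0 + 1, 1)                               # 1-based clipped
        hi <- pmin(hi0, clen)
        ok <- hi >= lo
        if (any(ok)) {
          v <- Views(rle, start = lo[ok], end = hi[ok])
          m[idx[ok], b] <- viewMeans(v)
        }
      }
    }
  }
  list(matrix = m, profile = colMeans(m))
}

#' Four-factor feature vectors for bivalent regions
#'
#' Per region, the total signal (RPM) of each factor over the region extended
#' by \code{flank} bases on each side. The factor panel (EZH2, PolII, TAF1,
#' TCF12) is the fixed input of the clustering.
#'
#' @param regionsGr \code{GRanges}.
#' @param tracks named list of \linkS4class{SignalTrack}s, one per factor.
#' @param flank window extension in bp (default 1000).
#' @param stat \code{"sum"} (global signal, default) or \code{"mean"}.
#' @return Numeric matrix, regions x factors; rownames from
#'   \code{region_id} when present.
#' @export
extractFeatures <- function(regionsGr, tracks, flank = 1000,
                            stat = c("sum", "mean")) {
  stat <- match.arg(stat)
  stopifnot(is.list(tracks), length(tracks) >= 1L, !is.null(names(tracks)))
  n <- length(regionsGr)
  out <- matrix(0, nrow = n, ncol = length(tracks),
                dimnames = list(regionsGr$region_id, names(tracks)))
  if (!n) return(out)
  chrom <- as.character(seqnames(regionsGr))
  lo <- pmax(start(regionsGr) - flank, 1L)
  hi <- end(regionsGr) + flank
  for (f in names(tracks)) {
    tr <- rpmScale(tracks[[f]])
    for (ch in unique(chrom)) {
      if (!ch %in% names(tr@cov)) next
      idx <- which(chrom == ch)
      rle <- tr@cov[[ch]]
      l <- lo[idx]
      h <- pmin(hi[idx], length(rle))
      ok <- h >= l
      if (any(ok)) {
        v <- Views(rle, start = l[ok], end = h[ok])
        out[idx[ok], f] <- if (stat == "sum") viewSums(v) else viewMeans(v)
      }
    }
  }
  out
}

#' K-means partition of bivalent regions into three clusters
#'
#' Lloyd K-means on \code{log2(RPM + 1)}, per-factor z-scored features
#' (configurable), best of \code{nStarts} random starts under a fixed seed.
#'
#' @param features numeric matrix from \code{\link{extractFeatures}}.
#' @param k number of clusters (default 3).
#' @param seed RNG seed making the partition reproducible.
#' @param nStarts random starts.
#' @param transform log2/z-score the features before clustering (default
#'   TRUE; raw RPM lets the strongest factor dominate the distances).
#' @return Integer vector of cluster indices (arbitrary labels; see
#'   \code{\link{labelClusters}} for the semantic relabeling).
#' @export
kmeansThree <- function(features, k = 3, seed = 1729, nStarts = 50,
                        transform = TRUE) {
  stopifnot(is.matrix(features), is.numeric(features))
  x <- features
  if (transform) {
    x <- log2(x + 1)
    mu <- colMeans(x)
    sdv <- apply(x, 2L, stats::sd)
    sdv[sdv == 0] <- 1
    x <- sweep(sweep(x, 2L, mu, "-"), 2L, sdv, "/")
  }
  if (nrow(unique(x)) < k)
    stop("fewer than k distinct feature vectors")
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  km <- suppressWarnings(
    kmeans(x, centers = k, nstart = nStarts, iter.max = 200,
           algorithm = "Lloyd"))
  as.integer(km$cluster)
}

#' Semantic relabeling of the three bivalent clusters
#'
#' Cluster 1 = highest mean PolII + TAF1 signal (sharp, strong initiation
#' machinery); cluster 2 = highest mean EZH2 among the remaining two (PRC2
#' defined); cluster 3 = the rest. Ties are broken by cluster size,
#' descending.
#'
#' @param assignment integer cluster indices from \code{\link{kmeansThree}}.
#' @param features the raw feature matrix; must have columns \code{EZH2},
#'   \code{PolII} and \code{TAF1} (a \code{TCF12} column is allowed and
#'   ignored by the rule).
#' @return Integer vector with semantic labels 1, 2, 3.
#' @export
labelClusters <- function(assignment, features) {
  stopifnot(length(assignment) == nrow(features),
            all(c("EZH2", "PolII", "TAF1") %in% colnames(features)))
  ids <- sort(unique(assignment))
  stopifnot(length(ids) == 3L)
  sizes <- as.numeric(table(factor(assignment, levels = ids)))
  polMean <- vapply(ids, function(i)
    mean(features[assignment == i, "PolII"] +
           features[assignment == i, "TAF1"]), numeric(1L))
  ezhMean <- vapply(ids, function(i)
    mean(features[assignment == i, "EZH2"]), numeric(1L))
  ord1 <- order(-polMean, -sizes)
  c1 <- ids[ord1[1L]]
  rest <- setdiff(ids, c1)
  restOrd <- order(-ezhMean[match(rest, ids)], -sizes[match(rest, ids)])
  c2 <- rest[restOrd[1L]]
  c3 <- setdiff(rest, c2)
  out <- integer(length(assignment))
  out[assignment == c1] <- 1L
  out[assignment == c2] <- 2L
  out[assignment == c3] <- 3L
  out
}

#' Cluster bivalent regions by four-factor occupancy
#'
#' Convenience wrapper: extract features over region +/- 1 kb, run K-means
#' (k = 3) and apply the semantic labeling.
#'
#' @param regionsGr bivalent region \code{GRanges}.
#' @param tracks named list of \linkS4class{SignalTrack}s including
#'   \code{EZH2}, \code{PolII}, \code{TAF1} and \code{TCF12}.
#' @param ... passed to \code{\link{kmeansThree}}.
#' @return A \code{data.frame} with \code{region_id} and \code{cluster}.
#' @export
clusterBivalentRegions <- function(regionsGr, tracks, ...) {
  feat <- extractFeatures(regionsGr, tracks, flank = 1000)
  cl <- labelClusters(kmeansThree(feat, ...), feat)
  data.frame(region_id = regionsGr$region_id, cluster = cl,
             stringsAsFactors = FALSE)
}
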