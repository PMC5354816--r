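# Interval algebra. Internally everything is a GRanges (1-based closed, the
# Bioconductor convention); BED-convention coordinates (0-based half-open)
# cross the boundary only through bedRanges()/asBed() and the file readers.
# Strand is ignored throughout the region algebra: peaks are unstranded.

#' Build a GRanges from BED-convention coordinates
#'
#' Constructs a \link[GenomicRanges]{GRanges} from 0-based half-open
#' coordinates, the convention of all BED-family peak and annotation files.
#' Each interval must satisfy \code{0 <= start < end}.
#'
#' @param chrom character vector of chromosome names.
#' @param start integer vector, 0-based inclusive start positions.
#' @param end integer vector, exclusive end positions.
#' @param strand optional strand vector (\code{"+"}, \code{"-"} or \code{"*"}).
#' @return A \code{GRanges} with the same widths (\code{end - start}).
#' @examples
#' bedRanges("chr1", 100, 200)  # the 100 bases 100..199
#' @export
bedRanges <- function(chrom, start, end, strand = "*") {
  start <- as.numeric(start)
  end <- as.numeric(end)
  bad <- which(!is.finite(start) | !is.finite(end) | start < 0 | end <= start)
  if (length(bad)) {
    stop("invalid interval(s) at position(s) ", paste(utils::head(bad, 5L), collapse = ", "),
         ": require 0 <= start < end (first offender: ",
         chrom[bad[1L]], ":", start[bad[1L]], "-", end[bad[1L]], ")")
  }
  if (any(!nzchar(chrom))) stop("empty chromosome name")
  GRanges(chrom, IRanges(start + 1, end), strand = strand)
}

#' Convert a GRanges to a BED-convention data.frame
#'
#' @param x a \code{GRanges}.
#' @return A \code{data.frame} with columns \code{chrom}, \code{start}
#'   (0-based), \code{end} (exclusive), plus any metadata columns.
#' @export
asBed <- function(x) {
  df <- data.frame(chrom = as.character(seqnames(x)),
                   start = start(x) - 1L,
                   end = end(x),
                   stringsAsFactors = FALSE)
  mc <- as.data.frame(mcols(x))
  if (ncol(mc)) df <- cbind(df, mc)
  rownames(df) <- NULL
  df
}

#' Normalize an interval set
#'
#' Sorts and merges overlapping or book-ended (zero-gap) intervals per
#' chromosome, ignoring strand. Idempotent; the total number of covered bases
#' is preserved.
#'
#' @param x a \code{GRanges}.
#' @return A sorted, disjoint \code{GRanges}.
#' @export
normalizeIntervals <- function(x) {
  stopifnot(is(x, "GRanges"))
  reduce(sortSeqlevels(x), ignore.strand = TRUE, min.gapwidth = 1L)
}

#' Intersect two interval sets with a minimum piece width
#'
#' Per-chromosome intersection keeping only pieces of at least
#' \code{minWidth} bases. With the default \code{minWidth = 1000} this is the
#' "overlapped for at least 1 kb" rule used for bivalent-domain calling.
#'
#' @param a,b \code{GRanges}; normalized internally.
#' @param minWidth minimum width (bp) of retained intersection pieces;
#'   must be >= 1. A piece of exactly \code{minWidth} bases is kept.
#' @return A normalized \code{GRanges} of the filtered intersection.
#' @export
intersectIntervals <- function(a, b, minWidth = 1L) {
  if (!is.numeric(minWidth) || length(minWidth) != 1L || minWidth < 1)
    stop("minWidth must be a single number >= 1")
  r <- GenomicRanges::intersect(normalizeIntervals(a), normalizeIntervals(b),
                                ignore.strand = TRUE)
  r[width(r) >= minWidth]
}

#' Total overlap of each query interval with a set
#'
#' @param query a \code{GRanges} of query intervals.
#' @param set a \code{GRanges}; normalized internally.
#' @return Integer vector: for each query, the number of its bases covered by
#'   \code{set}.
#' @export
overlapBases <- function(query, set) {
  set <- normalizeIntervals(set)
  hits <- findOverlaps(query, set, ignore.strand = TRUE)
  ov <- pmin(end(query)[queryHits(hits)], end(set)[subjectHits(hits)]) -
    pmax(start(query)[queryHits(hits)], start(set)[subjectHits(hits)]) + 1L
  out <- integer(length(query))
  if (length(hits)) {
    agg <- tapply(ov, queryHits(hits), sum)
    out[as.integer(names(agg))] <- as.integer(agg)
  }
  out
}

#' Does each query overlap a set by at least \code{minBp} bases?
#'
#' @inheritParams overlapBases
#' @param minBp minimum total shared bases, >= 1.
#' @return Logical vector along \code{query}.
#' @export
overlapsWithin <- function(query, set, minBp = 1L) {
  if (minBp < 1) stop("minBp must be >= 1")
  overlapBases(query, set) >= minBp
}

#' Subtract one interval set from another
#'
#' @param a,b \code{GRanges}; normalized internally.
#' @return Bases of \code{a} not covered by \code{b}, as a normalized
#'   \code{GRanges}.
#' @export
subtractIntervals <- function(a, b) {
  GenomicRanges::setdiff(normalizeIntervals(a), normalizeIntervals(b),
                         ignore.strand = TRUE)
}
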