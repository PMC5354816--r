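#' PeakSet: one peak list for one mark in one cell line
#'
#' Thin container pairing a peak \code{GRanges} with the cell line and the
#' histone mark or transcription factor it was called for. Optional metadata
#' columns \code{score} and \code{fdr} on the ranges are preserved and used by
#' downstream FDR filtering.
#'
#' @slot cellLine single character, e.g. \code{"H1"}.
#' @slot mark single character, e.g. \code{"H3K4me3"} or \code{"EZH2"}.
#' @slot peaks a \code{GRanges} of peak intervals.
#' @exportClass PeakSet
setClass("PeakSet",
         representation(cellLine = "character", mark = "character",
                        peaks = "GRanges"))

setValidity("PeakSet", function(object) {
  msg <- character()
  if (length(object@cellLine) != 1L || !nzchar(object@cellLine))
    msg <- c(msg, "cellLine must be a single non-empty string")
  if (length(object@mark) != 1L || !nzchar(object@mark))
    msg <- c(msg, "mark must be a single non-empty string")
  if (length(object@peaks) && any(width(object@peaks) < 1L))
    msg <- c(msg, "all peaks must have width >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct a PeakSet
#'
#' @param cellLine cell-line identifier.
#' @param mark histone mark or factor name.
#' @param peaks a \code{GRanges} (metadata columns \code{score}, \code{fdr}
#'   optional).
#' @return A \linkS4class{PeakSet}.
#' @export
PeakSet <- function(cellLine, mark, peaks) {
  new("PeakSet", cellLine = as.character(cellLine), mark = as.character(mark),
      peaks = peaks)
}

#' @describeIn PeakSet-class the peak intervals
#' @param x,object a \code{PeakSet}.
#' @export
setMethod("peaks", "PeakSet", function(x) x@peaks)

#' @describeIn PeakSet-class the cell-line identifier
#' @export
setMethod("cellLine", "PeakSet", function(x) x@cellLine)

#' @describeIn PeakSet-class the mark / factor name
#' @export
setMethod("mark", "PeakSet", function(x) x@mark)

setMethod("length", "PeakSet", function(x) length(x@peaks))

setMethod("show", "PeakSet", function(object) {
  cat("PeakSet:", object@mark, "in", object@cellLine, "-",
      length(object@peaks), "peaks\n")
})

#' ChromatinStates: the consensus chromatin-state region lists
#'
#' Holds the high-confidence bivalent, H3K4me3-only and H3K27me3-only regions
#' produced by \code{\link{callChromatinStates}} as one sorted \code{GRanges}
#' with metadata columns \code{region_id}, \code{category} (factor with levels
#' \code{bivalent}, \code{K4only}, \code{K27only}), \code{n_lines} and
#' \code{lines} (comma-separated supporting cell lines), plus the full merged
#' bivalent list (all support levels) used to derive them.
#'
#' @slot regions the high-confidence region \code{GRanges}.
#' @slot mergedBivalent merged cross-line bivalent regions at every support
#'   level (the "12,402-list" analogue).
#' @slot cellLines the cell lines that entered the consensus.
#' @slot params named list of calling parameters.
#' @exportClass ChromatinStates
setClass("ChromatinStates",
         representation(regions = "GRanges", mergedBivalent = "GRanges",
                        cellLines = "character", params = "list"))

setValidity("ChromatinStates", function(object) {
  msg <- character()
  need <- c("region_id", "category", "n_lines", "lines")
  if (!all(need %in% names(mcols(object@regions))))
    msg <- c(msg, paste("regions must carry metadata columns:",
                        paste(need, collapse = ", ")))
  else {
    if (anyDuplicated(object@regions$region_id))
      msg <- c(msg, "region_id must be unique")
    if (!all(levels(object@regions$category) ==
             c("bivalent", "K4only", "K27only")))
      msg <- c(msg, "category levels must be bivalent, K4only, K27only")
    if (length(object@regions) > 1L) {
      cov <- coverage(object@regions)
      if (any(vapply(cov, function(r) any(runValue(r) > 1L), logical(1L))))
        msg <- c(msg, "state regions must be pairwise disjoint")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Extract regions from a ChromatinStates object
#'
#' @param x a \linkS4class{ChromatinStates}.
#' @param category optional: one of \code{"bivalent"}, \code{"K4only"},
#'   \code{"K27only"} to subset.
#' @return A \code{GRanges}.
#' @export
regions <- function(x, category = NULL) {
  stopifnot(is(x, "ChromatinStates"))
  r <- x@regions
  if (!is.null(category)) {
    category <- match.arg(category, c("bivalent", "K4only", "K27only"))
    r <- r[r$category == category]
  }
  r
}

#' Merged bivalent regions at every support level
#' @param x a \linkS4class{ChromatinStates}.
#' @return A \code{GRanges} with \code{n_lines} and \code{lines} columns.
#' @export
mergedBivalent <- function(x) {
  stopifnot(is(x, "ChromatinStates"))
  x@mergedBivalent
}

setMethod("length", "ChromatinStates", function(x) length(x@regions))

setMethod("show", "ChromatinStates", function(object) {
  tb <- table(object@regions$category)
  cat("ChromatinStates consensus over", length(object@cellLines),
      "cell line(s):", paste(object@cellLines, collapse = ", "), "\n")
  cat("  high-confidence regions:", length(object@regions), "\n")
  for (nm in names(tb)) cat("    ", nm, ": ", tb[[nm]], "\n", sep = "")
  cat("  merged bivalent regions (all support levels):",
      length(object@mergedBivalent), "\n")
})

#' SignalTrack: genome-wide binned signal coverage
#'
#' Per-chromosome run-length-encoded signal, optionally scaled to reads per
#' million (RPM = value x 1e6 / totalReads).
#'
#' @slot cov a \code{SimpleRleList}, one numeric \code{Rle} per chromosome.
#' @slot totalReads total read count used for RPM scaling.
#' @slot rpm logical; whether values are already RPM-scaled.
#' @exportClass SignalTrack
setClass("SignalTrack",
         representation(cov = "SimpleRleList", totalReads = "numeric",
                        rpm = "logical"))

setValidity("SignalTrack", function(object) {
  msg <- character()
  if (length(object@totalReads) != 1L || object@totalReads <= 0)
    msg <- c(msg, "totalReads must be a single positive number")
  if (any(vapply(object@cov, function(r) any(runValue(r) < 0), logical(1L))))
    msg <- c(msg, "signal values must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a SignalTrack
#'
#' @param cov an \code{RleList} of per-chromosome signal, or a \code{GRanges}
#'   with a \code{score} column (bedGraph-style), which is converted with
#'   \code{\link[GenomicRanges]{coverage}}.
#' @param totalReads total read count for RPM scaling; if \code{NULL} it is
#'   taken as the total signal area (sum of value x width), a proxy suitable
#'   when the track is in per-base read units.
#' @param rpm whether \code{cov} is already RPM-scaled.
#' @return A \linkS4class{SignalTrack}.
#' @export
SignalTrack <- function(cov, totalReads = NULL, rpm = FALSE) {
  if (is(cov, "GRanges")) {
    if (is.null(cov$score)) stop("GRanges input must carry a 'score' column")
    cov <- coverage(cov, weight = cov$score)
  }
  cov <- as(cov, "SimpleRleList")
  if (is.null(totalReads))
    totalReads <- sum(vapply(cov, function(r) sum(as.numeric(runValue(r)) *
                                                    runLength(r)), numeric(1L)))
  if (totalReads <= 0) totalReads <- 1
  new("SignalTrack", cov = cov, totalReads = as.numeric(totalReads), rpm = rpm)
}

#' RPM-scale a SignalTrack
#' @param x a \linkS4class{SignalTrack}.
#' @return The track with values multiplied by \code{1e6 / totalReads}
#'   (a no-op if already scaled).
#' @export
rpmScale <- function(x) {
  stopifnot(is(x, "SignalTrack"))
  if (x@rpm) return(x)
  new("SignalTrack", cov = x@cov * (1e6 / x@totalReads),
      totalReads = x@totalReads, rpm = TRUE)
}

setMethod("show", "SignalTrack", function(object) {
  cat("SignalTrack over", length(object@cov), "chromosome(s);",
      if (object@rpm) "RPM-scaled;" else "raw;",
      "totalReads =", format(object@totalReads), "\n")
})

#' AnnotationBundle: genome annotations used for region classification
#'
#' @slot genes \code{GRanges} of transcript/gene bodies with strand and a
#'   \code{gene_id} metadata column (a gene may appear with several
#'   transcripts, i.e. several TSS).
#' @slot cgis \code{GRanges} of CpG islands.
#' @slot repeats \code{GRanges} of repeat elements with a \code{repClass}
#'   metadata column (\code{LINE}, \code{SINE}, \code{LTR}, \code{other}).
#' @slot enhancers \code{GRanges} of enhancer elements.
#' @slot promoters derived \code{GRanges}, one per TSS (TSS +/- flank),
#'   with \code{gene_id}.
#' @slot promoterFlank flank (bp) applied on each side of the TSS.
#' @exportClass AnnotationBundle
setClass("AnnotationBundle",
         representation(genes = "GRanges", cgis = "GRanges",
                        repeats = "GRanges", enhancers = "GRanges",
                        promoters = "GRanges", promoterFlank = "numeric"))

setValidity("AnnotationBundle", function(object) {
  msg <- character()
  if (!"gene_id" %in% names(mcols(object@genes)))
    msg <- c(msg, "genes must carry a gene_id column")
  if (length(object@repeats) &&
      !"repClass" %in% names(mcols(object@repeats)))
    msg <- c(msg, "repeats must carry a repClass column")
  if (object@promoterFlank <= 0)
    msg <- c(msg, "promoterFlank must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct an AnnotationBundle
#'
#' @param genes stranded \code{GRanges} of gene/transcript bodies with a
#'   \code{gene_id} column; the TSS is the 5' end.
#' @param cgis \code{GRanges} of CpG islands.
#' @param repeats \code{GRanges} with a \code{repClass} column; may be empty.
#' @param enhancers \code{GRanges}; may be empty.
#' @param promoterFlank promoter half-width around each TSS in bp
#'   (default 1000, i.e. TSS +/- 1 kb).
#' @return An \linkS4class{AnnotationBundle} with derived promoters.
#' @export
AnnotationBundle <- function(genes, cgis = GRanges(), repeats = GRanges(),
                             enhancers = GRanges(), promoterFlank = 1000) {
  if (length(repeats) && is.null(repeats$repClass))
    repeats$repClass <- "other"
  new("AnnotationBundle", genes = genes, cgis = cgis, repeats = repeats,
      enhancers = enhancers,
      promoters = buildPromoters(genes, flank = promoterFlank),
      promoterFlank = promoterFlank)
}

setMethod("show", "AnnotationBundle", function(object) {
  cat("AnnotationBundle:", length(object@genes), "gene model(s),",
      length(object@promoters), "promoter(s) (TSS +/-",
      object@promoterFlank, "bp),", length(object@cgis), "CGI(s),",
      length(object@repeats), "repeat(s),", length(object@enhancers),
      "enhancer(s)\n")
})
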