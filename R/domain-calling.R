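# Bivalent-domain calling and cross-line consensus.
#
# Per line, a bivalent domain is a maximal piece where an H3K4me3 peak and an
# H3K27me3 peak overlap by at least minOverlap bases; the domain coordinates
# are the overlap itself, so both marks cover every reported base. Per-line
# domains are union-merged across lines into consensus regions that record
# which lines contributed; regions supported by all lines are the
# high-confidence (HC) list. Single-mark (K4only / K27only) lists are the
# per-base cross-line intersection of that mark's peaks, width-filtered, with
# any region touching a bivalent domain of any line discarded entirely.

#' Call bivalent domains for one cell line
#'
#' Intersects the H3K4me3 and H3K27me3 peak sets of one cell line and keeps
#' overlap pieces of at least \code{minOverlap} bases (default 1 kb; a piece
#' of exactly 1000 bp is kept).
#'
#' @param k4,k27 \linkS4class{PeakSet}s for H3K4me3 and H3K27me3 from the same
#'   cell line (plain \code{GRanges} also accepted, in which case the
#'   cell-line check is skipped).
#' @param minOverlap minimum overlap width in bp.
#' @return A \code{GRanges} of bivalent domains with a \code{cellLine}
#'   metadata column (when known).
#' @export
callBivalentDomains <- function(k4, k27, minOverlap = 1000) {
  line <- NA_character_
  if (is(k4, "PeakSet") && is(k27, "PeakSet")) {
    if (cellLine(k4) != cellLine(k27))
      stop("peak sets come from different cell lines: ",
           cellLine(k4), " vs ", cellLine(k27))
    line <- cellLine(k4)
  }
  g4 <- if (is(k4, "PeakSet")) peaks(k4) else k4
  g27 <- if (is(k27, "PeakSet")) peaks(k27) else k27
  dom <- intersectIntervals(g4, g27, minWidth = minOverlap)
  dom$cellLine <- rep(line, length(dom))
  dom
}

#' Union-merge per-line bivalent domains into consensus regions
#'
#' Merges the domains of all lines into maximal connected regions; each merged
#' region records every line that contributes at least one overlapping base.
#'
#' @param domains named list of per-line domain \code{GRanges} (names are the
#'   cell-line identifiers).
#' @return A \code{GRanges} with metadata columns \code{n_lines} (support
#'   count) and \code{lines} (comma-separated supporting lines).
#' @export
mergeAcrossLines <- function(domains) {
  stopifnot(is.list(domains))
  if (!length(domains)) {
    out <- GRanges()
    out$n_lines <- integer()
    out$lines <- character()
    return(out)
  }
  if (is.null(names(domains)) || any(!nzchar(names(domains))))
    stop("'domains' must be a named list (cell-line identifiers)")
  merged <- normalizeIntervals(do.call(c, unname(lapply(domains, granges))))
  support <- matrix(FALSE, nrow = length(merged), ncol = length(domains),
                    dimnames = list(NULL, names(domains)))
  for (ln in names(domains))
    support[, ln] <- countOverlaps(merged, domains[[ln]],
                                   ignore.strand = TRUE) > 0L
  merged$n_lines <- as.integer(rowSums(support))
  merged$lines <- if (length(merged))
    apply(support, 1L, function(z) paste(colnames(support)[z], collapse = ","))
  else character()
  merged
}

#' Keep consensus regions supported by enough cell lines
#'
#' @param regions \code{GRanges} with an \code{n_lines} column (from
#'   \code{\link{mergeAcrossLines}}).
#' @param nRequired minimum number of supporting lines.
#' @return The subset with \code{n_lines >= nRequired}.
#' @export
selectHighConfidence <- function(regions, nRequired) {
  stopifnot(!is.null(regions$n_lines), nRequired >= 1)
  regions[regions$n_lines >= nRequired]
}

#' Call single-mark (K4only / K27only) consensus regions
#'
#' Per-base intersection of one mark's peaks over all cell lines, keeping
#' pieces of at least \code{minWidth} bases, then discarding any region that
#' overlaps (by even one base) a bivalent domain of any line.
#'
#' @param markPeaks named list of per-line \linkS4class{PeakSet}s (or
#'   \code{GRanges}) for one mark.
#' @param bivalentDomains \code{GRanges} (or list of \code{GRanges}) pooling
#'   the bivalent domains of every line.
#' @param minWidth minimum region width (bp).
#' @return A \code{GRanges}; every returned region is common to all lines and
#'   bivalent-free.
#' @export
callExclusiveRegions <- function(markPeaks, bivalentDomains,
                                 minWidth = 1000) {
  stopifnot(is.list(markPeaks), length(markPeaks) >= 1L)
  mk <- vapply(markPeaks, function(p)
    if (is(p, "PeakSet")) mark(p) else NA_character_, character(1L))
  if (length(unique(mk[!is.na(mk)])) > 1L)
    stop("all peak sets must share the same mark")
  grl <- lapply(markPeaks, function(p)
    if (is(p, "PeakSet")) peaks(p) else p)
  common <- Reduce(function(a, b)
    GenomicRanges::intersect(normalizeIntervals(a), normalizeIntervals(b),
                             ignore.strand = TRUE), grl)
  common <- common[width(common) >= minWidth]
  if (is.list(bivalentDomains))
    bivalentDomains <- do.call(c, unname(lapply(bivalentDomains, granges)))
  if (length(bivalentDomains))
    common <- common[!overlapsWithin(common, bivalentDomains)]
  common
}

#' Drop regions on excluded chromosomes
#'
#' The cell lines derive from both female and male embryos, so the sex
#' chromosomes are excluded from all consensus lists by default.
#'
#' @param regions a \code{GRanges}.
#' @param exclude chromosome names to drop (default \code{chrX}, \code{chrY}).
#' @return The filtered \code{GRanges} (excluded seqlevels removed).
#' @export
excludeChromosomes <- function(regions, exclude = c("chrX", "chrY")) {
  keep <- !(as.character(seqnames(regions)) %in% exclude)
  out <- regions[keep]
  seqlevels(out) <- setdiff(seqlevels(out), exclude)
  out
}

#' Call the three high-confidence chromatin-state lists
#'
#' Full consensus pipeline: per-line bivalent domains, cross-line union-merge
#' with support counting, restriction to regions supported by all (or
#' \code{nRequired}) lines, single-mark K4only / K27only consensus with
#' bivalent exclusion, and sex-chromosome removal. The three lists are
#' pairwise disjoint by construction.
#'
#' @param k4,k27 named lists of per-line \linkS4class{PeakSet}s (one entry per
#'   cell line, same names in both lists).
#' @param minOverlap minimum K4/K27 overlap for a bivalent domain (bp).
#' @param minWidth minimum width of single-mark regions (bp).
#' @param nRequired lines required for high confidence (default: all).
#' @param excludeChroms chromosomes removed from every list.
#' @return A \linkS4class{ChromatinStates} object.
#' @examples
#' k4 <- list(A = PeakSet("A", "H3K4me3", bedRanges("chr1", 0, 5000)))
#' k27 <- list(A = PeakSet("A", "H3K27me3", bedRanges("chr1", 3000, 9000)))
#' callChromatinStates(k4, k27)
#' @export
callChromatinStates <- function(k4, k27, minOverlap = 1000, minWidth = 1000,
                                nRequired = NULL,
                                excludeChroms = c("chrX", "chrY")) {
  stopifnot(is.list(k4), is.list(k27))
  lines <- names(k4)
  if (is.null(lines) || !setequal(lines, names(k27)))
    stop("k4 and k27 must be named lists over the same cell lines")
  if (is.null(nRequired)) nRequired <- length(lines)
  if (nRequired > length(lines))
    stop("nRequired exceeds the number of cell lines")

  perLine <- lapply(setNames(lines, lines), function(ln)
    callBivalentDomains(k4[[ln]], k27[[ln]], minOverlap = minOverlap))
  merged <- excludeChromosomes(mergeAcrossLines(perLine), excludeChroms)
  hcBiv <- selectHighConfidence(merged, nRequired)

  allDomains <- do.call(c, unname(lapply(perLine, granges)))
  k4only <- excludeChromosomes(
    callExclusiveRegions(k4, allDomains, minWidth = minWidth), excludeChroms)
  k27only <- excludeChromosomes(
    callExclusiveRegions(k27, allDomains, minWidth = minWidth), excludeChroms)

  mk <- function(gr, category, prefix, nLines, linesTxt) {
    if (!length(gr)) {
      gr <- GRanges()
      gr$region_id <- character()
      gr$category <- factor(character(),
                            levels = c("bivalent", "K4only", "K27only"))
      gr$n_lines <- integer()
      gr$lines <- character()
      return(gr)
    }
    out <- granges(gr)
    out$region_id <- sprintf("%s_%05d", prefix, seq_along(out))
    out$category <- factor(rep(category, length(out)),
                           levels = c("bivalent", "K4only", "K27only"))
    out$n_lines <- nLines
    out$lines <- linesTxt
    out
  }
  allLines <- paste(lines, collapse = ",")
  hc <- c(mk(hcBiv, "bivalent", "BIV", hcBiv$n_lines, hcBiv$lines),
          mk(k4only, "K4only", "K4", rep(length(lines), length(k4only)),
             rep(allLines, length(k4only))),
          mk(k27only, "K27only", "K27", rep(length(lines), length(k27only)),
             rep(allLines, length(k27only))))
  hc <- hc[order(as.character(seqnames(hc)), start(hc))]

  new("ChromatinStates", regions = hc, mergedBivalent = merged,
      cellLines = lines,
      params = list(minOverlap = minOverlap, minWidth = minWidth,
                    nRequired = nRequired, excludeChroms = excludeChroms))
}
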