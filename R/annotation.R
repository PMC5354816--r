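# Region annotation: CGI / promoter / gene-body / intergenic classification,
# per-gene promoter chromatin signatures and retroelement frequency profiles
# around the TSS.

#' Promoter intervals around every TSS
#'
#' One promoter per transcript: TSS +/- \code{flank} (default 1 kb), clipped
#' at the chromosome start. The TSS is the 5' end of the stranded gene model.
#'
#' @param genes stranded \code{GRanges} with a \code{gene_id} column.
#' @param flank half-width in bp.
#' @return A \code{GRanges} of promoters with \code{gene_id} and \code{tss}
#'   (0-based TSS position) columns.
#' @export
buildPromoters <- function(genes, flank = 1000) {
  stopifnot(flank >= 1)
  if (!length(genes)) {
    out <- GRanges()
    out$gene_id <- character()
    out$tss <- integer()
    return(out)
  }
  if (is.null(genes$gene_id)) stop("genes must carry a gene_id column")
  minus <- as.logical(strand(genes) == "-")
  # 0-based TSS: BED start for + transcripts, BED end - 1 for - transcripts
  tss0 <- ifelse(minus, end(genes) - 1L, start(genes) - 1L)
  out <- bedRanges(as.character(seqnames(genes)),
                   pmax(0, tss0 - flank), tss0 + flank,
                   strand = as.character(strand(genes)))
  out$gene_id <- genes$gene_id
  out$tss <- as.integer(tss0)
  out
}

#' Annotate consensus regions with genomic features
#'
#' Every flag is any-overlap (>= 1 bp, or \code{minBp}). The mutually
#' exclusive \code{feature_class} follows the precedence
#' CGI/promoter > promoter > gene body > intergenic, where "CGI/promoter"
#' means the region overlaps both a CGI and a promoter. Enhancer overlap is
#' recorded independently (it is read on the non-promoter subset downstream).
#'
#' @param regionsGr \code{GRanges} of regions (e.g. \code{regions(states)}).
#' @param bundle an \linkS4class{AnnotationBundle}.
#' @param minBp minimum shared bases for an overlap flag.
#' @return The input \code{GRanges} with added columns \code{is_cgi},
#'   \code{is_promoter}, \code{is_cgi_promoter}, \code{feature_class},
#'   \code{enhancer_overlap} and \code{gene_ids} (comma-separated genes whose
#'   promoter the region touches).
#' @export
annotateRegions <- function(regionsGr, bundle, minBp = 1L) {
  stopifnot(is(bundle, "AnnotationBundle"))
  n <- length(regionsGr)
  isCgi <- if (length(bundle@cgis))
    overlapsWithin(regionsGr, bundle@cgis, minBp) else rep(FALSE, n)
  isProm <- if (length(bundle@promoters))
    overlapsWithin(regionsGr, bundle@promoters, minBp) else rep(FALSE, n)
  inBody <- if (length(bundle@genes))
    overlapsWithin(regionsGr, bundle@genes, minBp) else rep(FALSE, n)
  enh <- if (length(bundle@enhancers))
    overlapsWithin(regionsGr, bundle@enhancers, minBp) else rep(FALSE, n)

  cls <- rep("intergenic", n)
  cls[inBody] <- "gene body"
  cls[isProm] <- "promoter"
  cls[isCgi & isProm] <- "CGI/promoter"

  geneIds <- rep("", n)
  if (length(bundle@promoters) && n) {
    hits <- findOverlaps(regionsGr, bundle@promoters, ignore.strand = TRUE,
                         minoverlap = as.integer(minBp))
    if (length(hits)) {
      agg <- tapply(bundle@promoters$gene_id[subjectHits(hits)],
                    queryHits(hits),
                    function(g) paste(sort(unique(g)), collapse = ","))
      geneIds[as.integer(names(agg))] <- as.character(agg)
    }
  }

  out <- regionsGr
  out$is_cgi <- isCgi
  out$is_promoter <- isProm
  out$is_cgi_promoter <- isCgi & isProm
  out$feature_class <- factor(cls, levels = c("CGI/promoter", "promoter",
                                              "gene body", "intergenic"))
  out$enhancer_overlap <- enh
  out$gene_ids <- geneIds
  out
}

#' Per-gene promoter chromatin signature
#'
#' A gene's promoters are "marked" when they overlap a categorized region.
#' The gene's signature is the common category when all marked promoters
#' agree, \code{none} when no promoter is marked, and \code{mixed} otherwise;
#' mixed genes are excluded from the expression and ontology gene lists.
#'
#' @param regionsGr categorized region \code{GRanges} (must carry
#'   \code{category}).
#' @param bundle an \linkS4class{AnnotationBundle}.
#' @param minBp minimum shared bases for a promoter to count as marked.
#' @return A \code{data.frame} with columns \code{gene_id} and \code{class}
#'   (factor: \code{K4only}, \code{bivalent}, \code{K27only}, \code{none},
#'   \code{mixed}).
#' @export
promoterSignatures <- function(regionsGr, bundle, minBp = 1L) {
  stopifnot(!is.null(regionsGr$category))
  prom <- bundle@promoters
  geneIds <- sort(unique(prom$gene_id))
  cls <- setNames(rep("none", length(geneIds)), geneIds)
  if (length(prom) && length(regionsGr)) {
    hits <- findOverlaps(prom, regionsGr, ignore.strand = TRUE,
                         minoverlap = as.integer(minBp))
    if (length(hits)) {
      cat4 <- as.character(regionsGr$category)[subjectHits(hits)]
      per <- tapply(cat4, prom$gene_id[queryHits(hits)],
                    function(z) {
                      u <- unique(z)
                      if (length(u) == 1L) u else "mixed"
                    })
      cls[names(per)] <- as.character(per)
    }
  }
  data.frame(gene_id = geneIds,
             class = factor(unname(cls),
                            levels = c("K4only", "bivalent", "K27only",
                                       "none", "mixed")),
             stringsAsFactors = FALSE)
}

#' Retroelement frequency profile around TSS
#'
#' For each repeat class and each bin of offsets relative to the TSS
#' (strand-oriented: negative offsets are upstream), the fraction of TSS
#' whose bin interval overlaps a repeat of that class.
#'
#' @param tss stranded width-1 \code{GRanges} of TSS positions (e.g. derived
#'   from promoters), or any stranded \code{GRanges} whose 5' end is used.
#' @param repeats \code{GRanges} with a \code{repClass} column.
#' @param window half-window in bp (default 4000, i.e. TSS +/- 4 kb).
#' @param bin bin width in bp; must divide \code{window}.
#' @param classes repeat classes to profile.
#' @return A \code{data.frame} with columns \code{class}, \code{offset}
#'   (bin start relative to the TSS) and \code{frequency}.
#' @export
retroelementProfile <- function(tss, repeats, window = 4000, bin = 100,
                                classes = c("LINE", "SINE", "LTR")) {
  stopifnot(window %% bin == 0)
  minus <- as.logical(strand(tss) == "-")
  tss0 <- ifelse(minus, end(tss) - 1L, start(tss) - 1L)
  chrom <- as.character(seqnames(tss))
  offsets <- seq(-window, window - bin, by = bin)
  out <- vector("list", length(classes))
  names(out) <- classes
  for (cl in classes) {
    rep_cl <- repeats[!is.na(repeats$repClass) & repeats$repClass == cl]
    freq <- vapply(offsets, function(off) {
      # genomic interval of this strand-oriented bin for every TSS; minus-strand
      # bins are the point reflection around the TSS, so flipping every strand
      # reverses the profile exactly
      lo <- ifelse(minus, tss0 - off - bin, tss0 + off)
      hi <- lo + bin
      lo <- pmax(lo, 0)
      valid <- hi > lo
      if (!length(rep_cl) || !any(valid)) return(0)
      binGr <- bedRanges(chrom[valid], lo[valid], hi[valid])
      sum(countOverlaps(binGr, rep_cl, ignore.strand = TRUE) > 0L) /
        length(tss0)
    }, numeric(1L))
    out[[cl]] <- data.frame(class = cl, offset = offsets, frequency = freq,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
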