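# Expression integration: per-class summaries, normalization to the per-tissue
# median of H3K4me3-only genes, per-cluster medians and per-gene IQR across
# tissues. All summaries are computed on log2(RPKM + pseudocount); genes with
# a mixed promoter signature are excluded throughout.

.exprCheck <- function(expr) {
  stopifnot(is.matrix(expr), is.numeric(expr),
            !is.null(rownames(expr)), !is.null(colnames(expr)))
  if (any(expr < 0, na.rm = TRUE)) stop("RPKM values must be non-negative")
}

.classedGenes <- function(expr, signatures, class) {
  g <- signatures$gene_id[signatures$class == class]
  intersect(rownames(expr), g)
}

#' Per-class, per-tissue expression summaries
#'
#' Median and quartiles of \code{log2(RPKM + pseudocount)} for genes of each
#' promoter chromatin class in each tissue. Classes with no gene are reported
#' as absent (\code{NA} with \code{n = 0}), not as zero.
#'
#' @param expr genes x tissues RPKM matrix with dimnames.
#' @param signatures \code{data.frame} from \code{\link{promoterSignatures}};
#'   mixed-class genes are dropped.
#' @param pseudocount added to RPKM before log2 (default 0.1).
#' @param classes classes to summarize.
#' @return A \code{data.frame} with columns \code{class}, \code{tissue},
#'   \code{n}, \code{q1}, \code{median}, \code{q3}.
#' @export
classExpressionSummary <- function(expr, signatures, pseudocount = 0.1,
                                   classes = c("K4only", "bivalent",
                                               "K27only")) {
  .exprCheck(expr)
  lg <- log2(expr + pseudocount)
  res <- list()
  for (cl in classes) {
    gs <- .classedGenes(expr, signatures, cl)
    for (ts in colnames(expr)) {
      if (length(gs)) {
        q <- stats::quantile(lg[gs, ts], c(0.25, 0.5, 0.75), names = FALSE, type = 7)
      } else q <- rep(NA_real_, 3L)
      res[[length(res) + 1L]] <- data.frame(
        class = cl, tissue = ts, n = length(gs),
        q1 = q[1L], median = q[2L], q3 = q[3L], stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Normalize expression to the per-tissue K4only median
#'
#' Each value becomes \code{log2(RPKM + pseudocount)} minus the same-tissue
#' median of the H3K4me3-only-class genes, whose expression is globally
#' stable across tissues; by construction the per-tissue K4only median of the
#' result is exactly 0.
#'
#' @inheritParams classExpressionSummary
#' @return Numeric matrix, same dimensions as \code{expr}, on the normalized
#'   log2 scale.
#' @export
normalizeToK4 <- function(expr, signatures, pseudocount = 0.1) {
  .exprCheck(expr)
  k4 <- .classedGenes(expr, signatures, "K4only")
  if (!length(k4)) stop("no K4only-class gene present in the matrix")
  lg <- log2(expr + pseudocount)
  ref <- apply(lg[k4, , drop = FALSE], 2L, stats::median, na.rm = TRUE)
  if (any(is.na(ref))) stop("a tissue has no usable K4only gene")
  sweep(lg, 2L, ref, "-")
}

#' Per-tissue medians for all bivalent genes and each cluster
#'
#' @param normalized matrix from \code{\link{normalizeToK4}}.
#' @param signatures promoter-signature \code{data.frame}.
#' @param clusterMap \code{data.frame} with \code{gene_id} and \code{cluster}
#'   (the bivalent cluster of the gene's promoter region).
#' @return A \code{data.frame}: one row per tissue with columns
#'   \code{all_bivalent}, \code{cluster1}, \code{cluster2}, \code{cluster3}
#'   (\code{NA} when a cluster has no gene).
#' @export
clusterExpressionMedians <- function(normalized, signatures, clusterMap) {
  biv <- .classedGenes(normalized, signatures, "bivalent")
  med <- function(gs, ts) if (length(gs)) stats::median(normalized[gs, ts]) else
    NA_real_
  out <- data.frame(tissue = colnames(normalized), stringsAsFactors = FALSE)
  out$all_bivalent <- vapply(out$tissue, function(ts) med(biv, ts),
                             numeric(1L))
  for (k in 1:3) {
    gs <- intersect(biv, clusterMap$gene_id[clusterMap$cluster == k])
    out[[paste0("cluster", k)]] <- vapply(out$tissue, function(ts)
      med(gs, ts), numeric(1L))
  }
  rownames(out) <- NULL
  out
}

#' Per-gene interquartile range across tissues
#'
#' IQR (type-7 quantiles, linear interpolation) of each gene's normalized
#' expression across tissues; a tissue-specific gene has a large IQR, a
#' uniformly expressed or uniformly silent gene a small one.
#'
#' @param normalized matrix from \code{\link{normalizeToK4}}.
#' @param signatures optional promoter-signature \code{data.frame}; when
#'   given, only genes of \code{classes} are reported.
#' @param classes classes kept when \code{signatures} is supplied.
#' @return Named numeric vector of IQRs.
#' @export
iqrByGene <- function(normalized, signatures = NULL,
                      classes = c("K4only", "bivalent", "K27only")) {
  stopifnot(ncol(normalized) >= 4)
  gs <- rownames(normalized)
  if (!is.null(signatures))
    gs <- intersect(gs, signatures$gene_id[signatures$class %in% classes])
  vapply(setNames(gs, gs), function(g) {
    q <- stats::quantile(normalized[g, ], c(0.25, 0.75), names = FALSE, type = 7)
    q[2L] - q[1L]
  }, numeric(1L))
}
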