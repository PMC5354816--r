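# Methylation-array integration: probe -> chromatin-category mapping, beta
# bands, empirical-Bayes moderated two-group differential methylation with BH
# correction and |delta beta| filtering, CIMP stratification, category
# distributions and pan-cancer recurrence.
#
# The moderated t follows the standard hierarchical model: per-probe residual
# variances s^2 with d degrees of freedom are shrunk toward a prior (d0, s0^2)
# estimated by method of moments on log variances; the moderated statistic is
# referenced to a t distribution on d0 + d degrees of freedom.

#' Map array probes to chromatin-state regions
#'
#' Each probe is assigned the category of the (single, regions being
#' disjoint) region containing its position; probes in no region are
#' \code{none}. Coordinates are half-open: a probe sitting exactly at a
#' region's exclusive end is outside it.
#'
#' @param manifest \code{data.frame} with columns \code{probe_id},
#'   \code{chrom} and \code{pos} (0-based position), e.g. from
#'   \code{\link{readManifest}}.
#' @param states a \linkS4class{ChromatinStates} object or categorized region
#'   \code{GRanges}.
#' @param clusters optional \code{data.frame} (\code{region_id},
#'   \code{cluster}) from \code{\link{clusterBivalentRegions}}.
#' @return A \code{data.frame}: \code{probe_id}, \code{category} (factor
#'   \code{none}/\code{bivalent}/\code{K4only}/\code{K27only}),
#'   \code{region_id} (\code{NA} outside regions) and \code{cluster}
#'   (\code{NA} unless a clustered bivalent region).
#' @export
mapProbes <- function(manifest, states, clusters = NULL) {
  stopifnot(all(c("probe_id", "chrom", "pos") %in% names(manifest)))
  regionsGr <- if (is(states, "ChromatinStates")) regions(states) else states
  stopifnot(!is.null(regionsGr$category), !is.null(regionsGr$region_id))
  probeGr <- bedRanges(manifest$chrom, manifest$pos, manifest$pos + 1)
  hits <- findOverlaps(probeGr, regionsGr, ignore.strand = TRUE)
  category <- rep("none", nrow(manifest))
  regionId <- rep(NA_character_, nrow(manifest))
  category[queryHits(hits)] <-
    as.character(regionsGr$category)[subjectHits(hits)]
  regionId[queryHits(hits)] <- regionsGr$region_id[subjectHits(hits)]
  out <- data.frame(probe_id = manifest$probe_id,
                    category = factor(category,
                                      levels = c("none", "bivalent",
                                                 "K4only", "K27only")),
                    region_id = regionId, stringsAsFactors = FALSE)
  out$cluster <- if (!is.null(clusters))
    clusters$cluster[match(out$region_id, clusters$region_id)]
  else rep(NA_integer_, nrow(out))
  out$cluster[out$category != "bivalent"] <- NA_integer_
  out
}

#' Beta-value bands and their distribution over chromatin categories
#'
#' Bands partition the non-missing probes: \code{<0.1} (strictly
#' unmethylated), \code{[0.1,0.3)}, \code{[0.3,0.7]} (intermediate; a beta of
#' exactly 0.3 or 0.7 is intermediate) and \code{>0.7} (methylated).
#'
#' @param beta numeric vector of beta values in [0, 1] (NA allowed).
#' @param categories optional factor/character of per-probe chromatin
#'   categories; when given, a band x category count table is attached.
#' @param thresholds named vector \code{c(low, unmeth, meth)}.
#' @return A factor of bands along \code{beta}; when \code{categories} is
#'   supplied, attribute \code{table} holds the band x category counts.
#' @export
betaCategories <- function(beta, categories = NULL,
                           thresholds = c(low = 0.1, unmeth = 0.3,
                                          meth = 0.7)) {
  ok <- !is.na(beta)
  if (any(beta[ok] < 0 | beta[ok] > 1))
    stop("beta values must lie in [0, 1]")
  lv <- c("<0.1", "[0.1,0.3)", "[0.3,0.7]", ">0.7")
  band <- rep(NA_character_, length(beta))
  band[ok & beta < thresholds["low"]] <- lv[1L]
  band[ok & beta >= thresholds["low"] & beta < thresholds["unmeth"]] <- lv[2L]
  band[ok & beta >= thresholds["unmeth"] & beta <= thresholds["meth"]] <- lv[3L]
  band[ok & beta > thresholds["meth"]] <- lv[4L]
  band <- factor(band, levels = lv)
  if (!is.null(categories))
    attr(band, "table") <- table(band = band, category = categories)
  band
}

# Invert the trigamma function by Newton iteration (for the method-of-moments
# prior df estimate). Monotone decreasing on (0, Inf).
.trigammaInverse <- function(x, tol = 1e-8, maxIter = 100L) {
  vapply(x, function(z) {
    if (!is.finite(z) || z <= 0) return(Inf)
    if (z > 1e7) return(1 / sqrt(z))
    y <- 0.5 + 1 / z
    for (i in seq_len(maxIter)) {
      tri <- trigamma(y)
      dif <- tri * (1 - tri / z) / psigamma(y, 2L)
      y <- y + dif
      if (-dif / y < tol) break
    }
    y
  }, numeric(1L))
}

# Method-of-moments estimate of the variance prior (d0, s0^2) from per-probe
# sample variances s2 on d df, via the distribution of log variances.
# Two degenerate branches: exactly identical sample variances are a true
# fixed point (d0 = Inf, s0^2 = the common variance, so the moderated t
# collapses to the ordinary t); a merely non-positive excess spread keeps
# d0 = Inf but uses the bias-corrected location estimate, which stays
# calibrated under a global null.
.estimateVarPrior <- function(s2, d) {
  s2 <- s2[is.finite(s2) & s2 > 0]
  if (length(s2) < 2L) return(list(d0 = Inf, s02 = mean(s2)))
  z <- log(s2)
  if (stats::var(z) < 1e-15)
    return(list(d0 = Inf, s02 = exp(mean(z))))
  e <- z - digamma(d / 2) + log(d / 2)
  emean <- mean(e)
  evar <- stats::var(z) - trigamma(d / 2)
  if (!is.finite(evar) || evar <= 0)
    return(list(d0 = Inf, s02 = exp(emean)))
  d0 <- 2 * .trigammaInverse(evar)
  s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s02 = s02)
}

#' Moderated two-group t-test per probe
#'
#' Unpaired two-group comparison of beta values with empirical-Bayes variance
#' shrinkage: \code{s2_mod = (d0 * s02 + d * s2) / (d0 + d)},
#' \code{t = delta / sqrt(s2_mod * (1/n1 + 1/n2))}, two-sided p from a t
#' distribution on \code{d0 + d} df. Probes with fewer than 2 non-missing
#' values in either group are returned with \code{NA} statistics.
#'
#' @param beta probes x samples numeric matrix (rownames = probe ids).
#' @param status factor/character along columns with levels \code{tumor} and
#'   \code{normal} (delta = mean tumor - mean normal).
#' @param d0 prior degrees of freedom; \code{NULL} (default) estimates it by
#'   method of moments; \code{0} gives the ordinary t exactly; \code{Inf}
#'   fully pools the variances.
#' @return A \code{data.frame}: \code{probe_id}, \code{delta_beta},
#'   \code{t_mod}, \code{df}, \code{p}, \code{s2}, \code{n_tumor},
#'   \code{n_normal}, plus attributes \code{d0} and \code{s02}.
#' @export
moderatedTTest <- function(beta, status, d0 = NULL) {
  stopifnot(is.matrix(beta), ncol(beta) == length(status))
  status <- as.character(status)
  bad <- setdiff(unique(status), c("tumor", "normal"))
  if (length(bad)) stop("unknown status label(s): ", paste(bad, collapse = ", "))
  tum <- beta[, status == "tumor", drop = FALSE]
  nor <- beta[, status == "normal", drop = FALSE]
  n1 <- rowSums(!is.na(tum))
  n2 <- rowSums(!is.na(nor))
  if (!any(n1 >= 2L & n2 >= 2L))
    stop("need at least 2 non-missing samples per group for some probe")
  m1 <- rowMeans(tum, na.rm = TRUE)
  m2 <- rowMeans(nor, na.rm = TRUE)
  ss1 <- rowSums((tum - m1)^2, na.rm = TRUE)
  ss2 <- rowSums((nor - m2)^2, na.rm = TRUE)
  usable <- n1 >= 2L & n2 >= 2L
  d <- n1 + n2 - 2L
  s2 <- ifelse(usable, (ss1 + ss2) / pmax(d, 1L), NA_real_)

  dCommon <- unique(d[usable])
  if (is.null(d0)) {
    if (length(dCommon) == 1L) {
      pri <- .estimateVarPrior(s2[usable], dCommon)
    } else {
      # mixed residual df (missing values): estimate on the modal df stratum
      dm <- as.integer(names(which.max(table(d[usable]))))
      pri <- .estimateVarPrior(s2[usable & d == dm], dm)
    }
    if (!is.finite(pri$s02) || pri$s02 <= 0) {
      warning("variance-prior estimation failed; falling back to ordinary t")
      pri <- list(d0 = 0, s02 = 0)
    }
  } else {
    stopifnot(d0 >= 0)
    s2u <- s2[usable]
    pri <- list(d0 = d0,
                s02 = if (d0 > 0) exp(mean(log(s2u[s2u > 0]))) else 0)
  }
  s2mod <- if (is.infinite(pri$d0)) rep(pri$s02, length(s2))
  else (pri$d0 * pri$s02 + d * s2) / (pri$d0 + d)
  se <- sqrt(s2mod * (1 / n1 + 1 / n2))
  delta <- m1 - m2
  tmod <- delta / se
  dfTot <- pri$d0 + d
  p <- 2 * pt(-abs(tmod), df = dfTot)
  out <- data.frame(
    probe_id = if (!is.null(rownames(beta))) rownames(beta)
               else as.character(seq_len(nrow(beta))),
    delta_beta = delta, t_mod = tmod, df = dfTot, p = p, s2 = s2,
    n_tumor = n1, n_normal = n2, stringsAsFactors = FALSE)
  out[!usable, c("delta_beta", "t_mod", "df", "p", "s2")] <- NA_real_
  rownames(out) <- NULL
  attr(out, "d0") <- pri$d0
  attr(out, "s02") <- pri$s02
  out
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment (\code{stats::p.adjust} with \code{method = "BH"});
#' NA p-values yield NA q-values.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return Numeric vector of q-values.
#' @export
bhFdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Call differentially methylated probes
#'
#' \code{hyper} when \code{delta_beta > deltaMin} and \code{q < fdrMax};
#' \code{hypo} when \code{delta_beta < -deltaMin} and \code{q < fdrMax};
#' \code{none} otherwise (including untested probes).
#'
#' @param results \code{data.frame} from \code{\link{moderatedTTest}}.
#' @param deltaMin minimum absolute beta difference (default 0.25).
#' @param fdrMax FDR threshold (default 0.05).
#' @return The input with added \code{q} and \code{call} columns.
#' @export
callDmps <- function(results, deltaMin = 0.25, fdrMax = 0.05) {
  stopifnot(all(c("delta_beta", "p") %in% names(results)),
            deltaMin > 0, deltaMin < 1, fdrMax > 0, fdrMax < 1)
  results$q <- bhFdr(results$p)
  call <- rep("none", nrow(results))
  ok <- !is.na(results$q) & !is.na(results$delta_beta)
  call[ok & results$delta_beta > deltaMin & results$q < fdrMax] <- "hyper"
  call[ok & results$delta_beta < -deltaMin & results$q < fdrMax] <- "hypo"
  results$call <- factor(call, levels = c("hyper", "hypo", "none"))
  results
}

#' Differential methylation for one tumor type (optionally one CIMP arm)
#'
#' Selects the tumor samples of \code{tumorType} (restricted to a CIMP arm
#' when \code{cimp} is given; samples with missing CIMP status are excluded
#' from arms) and their matched normals (via \code{pair_id}), then runs the
#' moderated t-test and DMP calling.
#'
#' @param beta probes x samples matrix (colnames = sample ids).
#' @param samples sample sheet \code{data.frame} with columns
#'   \code{sample_id}, \code{type}, \code{status} (\code{tumor} /
#'   \code{normal}), \code{pair_id} and \code{cimp} (\code{positive} /
#'   \code{negative} / NA).
#' @param tumorType tumor type to analyze.
#' @param cimp \code{NULL} (all tumors), \code{"positive"} or
#'   \code{"negative"}.
#' @param deltaMin,fdrMax passed to \code{\link{callDmps}}.
#' @param d0 passed to \code{\link{moderatedTTest}}.
#' @return A called result \code{data.frame} (see \code{\link{callDmps}}),
#'   or \code{NULL} when the arm has no tumor sample.
#' @export
diffMethylation <- function(beta, samples, tumorType, cimp = NULL,
                            deltaMin = 0.25, fdrMax = 0.05, d0 = NULL) {
  need <- c("sample_id", "type", "status", "pair_id")
  stopifnot(all(need %in% names(samples)))
  sel <- samples[samples$type == tumorType, , drop = FALSE]
  tumors <- sel[sel$status == "tumor", , drop = FALSE]
  if (!is.null(cimp)) {
    cimp <- match.arg(cimp, c("positive", "negative"))
    tumors <- tumors[!is.na(tumors$cimp) & tumors$cimp == cimp, , drop = FALSE]
  }
  if (!nrow(tumors)) return(NULL)
  normals <- sel[sel$status == "normal" &
                   sel$pair_id %in% tumors$pair_id, , drop = FALSE]
  ids <- c(tumors$sample_id, normals$sample_id)
  stopifnot(all(ids %in% colnames(beta)))
  sub <- beta[, ids, drop = FALSE]
  status <- c(rep("tumor", nrow(tumors)), rep("normal", nrow(normals)))
  callDmps(moderatedTTest(sub, status, d0 = d0),
           deltaMin = deltaMin, fdrMax = fdrMax)
}

#' CIMP-stratified differential methylation
#'
#' Runs \code{\link{diffMethylation}} independently on the CIMP-positive and
#' CIMP-negative tumors of one type, each against its own matched normals.
#' Arms without tumors are absent from the result.
#'
#' @inheritParams diffMethylation
#' @return Named list with elements \code{positive} and/or \code{negative}.
#' @export
stratifyCimp <- function(beta, samples, tumorType, deltaMin = 0.25,
                         fdrMax = 0.05, d0 = NULL) {
  stopifnot("cimp" %in% names(samples))
  out <- list()
  for (arm in c("positive", "negative")) {
    res <- diffMethylation(beta, samples, tumorType, cimp = arm,
                           deltaMin = deltaMin, fdrMax = fdrMax, d0 = d0)
    if (!is.null(res)) out[[arm]] <- res
  }
  out
}

#' Distribution of DMPs over chromatin categories and bivalent clusters
#'
#' For each call arm (hyper, hypo): the fraction of called probes per
#' chromatin category (summing to 1), the cluster 1/2/3 split within the
#' bivalent hyper probes, the genomic-feature split (when the manifest
#' carries a \code{feature} column) and, as a reference, the category
#' distribution of the whole probe universe. Arms without any call are
#' reported as \code{NULL}, not as zeros.
#'
#' @param calls called \code{data.frame} from \code{\link{callDmps}} (needs
#'   \code{probe_id} and \code{call}).
#' @param probeMap \code{data.frame} from \code{\link{mapProbes}}.
#' @param manifest optional manifest with a \code{feature} column for the
#'   feature split.
#' @return A list: \code{hyper}, \code{hypo} (named fraction vectors or
#'   NULL), \code{hyper_clusters}, \code{hyper_features}, \code{reference}.
#' @export
categoryDistribution <- function(calls, probeMap, manifest = NULL) {
  stopifnot(all(c("probe_id", "call") %in% names(calls)))
  cat4 <- probeMap$category[match(calls$probe_id, probeMap$probe_id)]
  lv <- c("none", "bivalent", "K4only", "K27only")
  frac <- function(idx) {
    if (!any(idx)) return(NULL)
    tb <- table(factor(as.character(cat4[idx]), levels = lv))
    setNames(as.numeric(tb) / sum(tb), lv)
  }
  hyperIdx <- calls$call == "hyper"
  hypoIdx <- calls$call == "hypo"
  clustersOfHyper <- NULL
  if (any(hyperIdx)) {
    cl <- probeMap$cluster[match(calls$probe_id[hyperIdx],
                                 probeMap$probe_id)]
    cl <- cl[!is.na(cl)]
    if (length(cl)) {
      tb <- table(factor(cl, levels = 1:3))
      clustersOfHyper <- setNames(as.numeric(tb) / sum(tb),
                                  paste0("cluster", 1:3))
    }
  }
  features <- NULL
  if (!is.null(manifest) && "feature" %in% names(manifest) && any(hyperIdx)) {
    fe <- manifest$feature[match(calls$probe_id[hyperIdx],
                                 manifest$probe_id)]
    tb <- table(fe)
    if (sum(tb)) features <- setNames(as.numeric(tb) / sum(tb), names(tb))
  }
  refTb <- table(factor(as.character(probeMap$category), levels = lv))
  list(hyper = frac(hyperIdx), hypo = frac(hypoIdx),
       hyper_clusters = clustersOfHyper, hyper_features = features,
       reference = setNames(as.numeric(refTb) / sum(refTb), lv))
}

#' Pan-cancer recurrence of hypermethylated probes
#'
#' Probes called hyper in at least \code{minTypes} of the supplied per-type
#' analyses; run separately per CIMP arm by the caller.
#'
#' @param hyperSets named list (one entry per tumor type) of character
#'   vectors of hyper probe ids.
#' @param minTypes minimum number of types (default 5).
#' @param probeMap optional \code{\link{mapProbes}} result: when given, the
#'   promoter regions hit by recurrent probes are reported too.
#' @return A list: \code{probes} (recurrent probe ids), \code{counts}
#'   (per-probe type counts, all probes seen hyper at least once),
#'   \code{n_types} (number of analyses) and \code{regions} (region ids,
#'   when \code{probeMap} given).
#' @export
recurrence <- function(hyperSets, minTypes = 5, probeMap = NULL) {
  stopifnot(is.list(hyperSets), length(hyperSets) >= minTypes)
  all <- unlist(lapply(hyperSets, unique), use.names = FALSE)
  counts <- table(all)
  probes <- names(counts)[counts >= minTypes]
  regions <- NULL
  if (!is.null(probeMap)) {
    rid <- probeMap$region_id[match(probes, probeMap$probe_id)]
    regions <- sort(unique(rid[!is.na(rid)]))
  }
  list(probes = sort(probes),
       counts = setNames(as.integer(counts), names(counts)),
       n_types = length(hyperSets), regions = regions)
}
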