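# Seeded synthetic-data generator with planted truth. The generator emulates
# the statistical structure the analysis assumes: five peak-set replicates
# with boundary jitter and dropout, CGI/promoter-concentrated bivalency,
# retroelement depletion around bivalent TSS, a three-cluster factor-signal
# structure over bivalent regions, beta matrices with hypermethylation planted
# preferentially at cluster-2 bivalent CGI probes, and tissue-specific
# expression of bivalent genes. Everything is deterministic under the spec
# seed; sub-generators draw from seeds derived by fixed offsets.

.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Synthetic genome and study specification
#'
#' Defaults describe the study conditions the pipeline is validated under:
#' five 10-Mb autosomes plus a 5-Mb chrX, ~600 planted chromatin-state
#' regions over ~800 genes, bivalent cluster proportions 17/22/61, five
#' cell lines, eight tumor types with 20 tumor/normal pairs each, and a
#' ~20,000-probe array.
#'
#' @param seed master seed; all sub-generators derive their streams from it.
#' @param chromLengths named vector of chromosome lengths (bp).
#' @param nBivalent,nK4only,nK27only planted region counts per category.
#' @param nGenes total gene models (marked regions are promoter-anchored;
#'   the remainder are unmarked "none" genes).
#' @param clusterProportions proportions of bivalent regions in clusters
#'   1/2/3 (defaults mirror the 17\%/22\%/~60\% split of the reference
#'   analysis).
#' @param cgiPromoterFraction per-category probability that a planted
#'   region's promoter carries a CGI.
#' @param repeatDensity expected repeats per bp (uniform placement).
#' @param repeatDepletion keep-probability for repeats within +/- 1 kb of a
#'   bivalent TSS.
#' @return A classed list (\code{genomeSpec}).
#' @export
genomeSpec <- function(seed = 1L,
                       chromLengths = c(chr1 = 1e7, chr2 = 1e7, chr3 = 1e7,
                                        chr4 = 1e7, chr5 = 1e7, chrX = 5e6),
                       nBivalent = 200L, nK4only = 220L, nK27only = 180L,
                       nGenes = 800L,
                       clusterProportions = c(0.17, 0.22, 0.61),
                       cgiPromoterFraction = c(bivalent = 0.90,
                                               K4only = 0.80,
                                               K27only = 0.05,
                                               none = 0.30),
                       repeatDensity = 1 / 4000,
                       repeatDepletion = 0.3) {
  stopifnot(all(chromLengths > 0),
            abs(sum(clusterProportions) - 1) < 1e-8,
            all(cgiPromoterFraction >= 0 & cgiPromoterFraction <= 1),
            nGenes >= nBivalent + nK4only + nK27only)
  structure(list(seed = as.integer(seed), chromLengths = chromLengths,
                 nBivalent = nBivalent, nK4only = nK4only,
                 nK27only = nK27only, nGenes = nGenes,
                 clusterProportions = clusterProportions,
                 cgiPromoterFraction = cgiPromoterFraction,
                 repeatDensity = repeatDensity,
                 repeatDepletion = repeatDepletion),
            class = "genomeSpec")
}

#' Simulate genome annotations and the planted-truth skeleton
#'
#' Lays out genes on a non-overlapping grid, assigns each planted region
#' category (and bivalent cluster) to a gene promoter, builds CGIs at the
#' configured fraction of promoters plus methylated gene-body CGIs at
#' unmarked genes, places repeats uniformly with depletion around bivalent
#' TSS, and puts enhancers in promoter-free space.
#'
#' @param spec a \code{\link{genomeSpec}}.
#' @return A list: \code{bundle} (an \linkS4class{AnnotationBundle}) and
#'   \code{truth} (list with the planted region table and per-gene classes).
#' @export
simulateAnnotations <- function(spec) {
  stopifnot(inherits(spec, "genomeSpec"))
  .withSeed(spec$seed + 101L, {
    chroms <- names(spec$chromLengths)
    spacing <- 50000L
    slots <- do.call(rbind, lapply(chroms, function(ch) {
      ns <- floor(spec$chromLengths[[ch]] / spacing) - 1L
      data.frame(chrom = ch, slot = seq_len(ns), stringsAsFactors = FALSE)
    }))
    stopifnot(nrow(slots) >= spec$nGenes)
    pick <- slots[sort(sample.int(nrow(slots), spec$nGenes)), ]
    tss <- pick$slot * spacing + sample(-5000:5000, spec$nGenes,
                                        replace = TRUE)
    strand <- sample(c("+", "-"), spec$nGenes, replace = TRUE)
    geneId <- sprintf("GENE%04d", seq_len(spec$nGenes))
    bodyLen <- sample(4000:12000, spec$nGenes, replace = TRUE)
    bStart <- ifelse(strand == "+", tss, tss - bodyLen + 1L)
    genes <- bedRanges(pick$chrom, bStart, bStart + bodyLen, strand = strand)
    genes$gene_id <- geneId

    nMarked <- spec$nBivalent + spec$nK4only + spec$nK27only
    markedIdx <- sample.int(spec$nGenes, nMarked)
    category <- rep("none", spec$nGenes)
    category[markedIdx] <- sample(rep(c("bivalent", "K4only", "K27only"),
                                      c(spec$nBivalent, spec$nK4only,
                                        spec$nK27only)))
    widths <- ifelse(category == "bivalent", 2000L,
                     ifelse(category == "K4only", 2400L,
                            ifelse(category == "K27only", 3000L, NA)))
    cluster <- rep(NA_integer_, spec$nGenes)
    bivIdx <- which(category == "bivalent")
    nClus <- round(spec$clusterProportions * length(bivIdx))
    nClus[3L] <- length(bivIdx) - sum(nClus[1:2])
    cluster[bivIdx] <- sample(rep(1:3, nClus))

    isMarked <- category != "none"
    rStart <- ifelse(isMarked, tss - widths %/% 2L, NA)
    regionTable <- data.frame(
      truth_id = sprintf("TRUE%04d", seq_len(spec$nGenes))[isMarked],
      chrom = pick$chrom[isMarked],
      start = rStart[isMarked],
      end = (rStart + widths)[isMarked],
      category = category[isMarked],
      cluster = cluster[isMarked],
      gene_id = geneId[isMarked],
      tss = tss[isMarked],
      stringsAsFactors = FALSE)

    # promoter CGIs at the configured per-category fraction
    cgiProb <- spec$cgiPromoterFraction[category]
    cgiProb[is.na(cgiProb)] <- 0
    hasCgi <- runif(spec$nGenes) < cgiProb
    cgis <- bedRanges(pick$chrom[hasCgi], tss[hasCgi] - 400L,
                      tss[hasCgi] + 400L)
    regionTable$cgi <- hasCgi[isMarked]
    # methylated gene-body CGIs at a third of the unmarked genes
    bodyCgiIdx <- which(category == "none" & runif(spec$nGenes) < 1 / 3)
    bodyCgis <- bedRanges(pick$chrom[bodyCgiIdx], tss[bodyCgiIdx] + 3500L,
                          tss[bodyCgiIdx] + 4300L)
    geneTable <- data.frame(gene_id = geneId, chrom = pick$chrom, tss = tss,
                            strand = strand, class = category,
                            cluster = cluster, promoter_cgi = hasCgi,
                            body_cgi = seq_len(spec$nGenes) %in% bodyCgiIdx,
                            stringsAsFactors = FALSE)

    # repeats: uniform, then thinned around bivalent TSS
    reps <- do.call(rbind, lapply(chroms, function(ch) {
      len <- spec$chromLengths[[ch]]
      n <- rpois(1L, len * spec$repeatDensity)
      if (!n) return(NULL)
      st <- sort(sample.int(len - 400L, n))
      data.frame(chrom = ch, start = st, end = st + 300L,
                 stringsAsFactors = FALSE)
    }))
    repGr <- bedRanges(reps$chrom, reps$start, reps$end)
    repGr$repClass <- sample(c("LINE", "SINE", "LTR", "other"),
                             length(repGr), replace = TRUE,
                             prob = c(0.3, 0.35, 0.2, 0.15))
    bivTss <- bedRanges(pick$chrom[bivIdx], pmax(tss[bivIdx] - 1000L, 0),
                        tss[bivIdx] + 1000L)
    mid <- bedRanges(as.character(seqnames(repGr)),
                     (start(repGr) - 1L + end(repGr)) %/% 2L,
                     (start(repGr) - 1L + end(repGr)) %/% 2L + 1L)
    nearBiv <- overlapsWithin(mid, bivTss)
    keep <- !nearBiv | runif(length(repGr)) < spec$repeatDepletion
    repGr <- repGr[keep]

    # enhancers in promoter-free space
    nEnh <- 300L
    enhCh <- sample(chroms, nEnh, replace = TRUE,
                    prob = spec$chromLengths / sum(spec$chromLengths))
    enhSt <- vapply(enhCh, function(ch)
      sample.int(spec$chromLengths[[ch]] - 1000L, 1L), numeric(1L))
    enh <- bedRanges(enhCh, enhSt, enhSt + 1000L)
    promAll <- bedRanges(pick$chrom, pmax(tss - 2000L, 0), tss + 2000L)
    enh <- enh[!overlapsWithin(enh, promAll)]

    bundle <- AnnotationBundle(genes = genes, cgis = normalizeIntervals(
      c(cgis, bodyCgis)), repeats = repGr, enhancers = enh,
      promoterFlank = 1000)
    list(bundle = bundle,
         truth = list(regions = regionTable, genes = geneTable,
                      seed = spec$seed, chromLengths = spec$chromLengths))
  })
}

#' Expected high-confidence region lists from the planted truth
#'
#' The pipeline excludes sex chromosomes, so the expected lists are the
#' autosomal planted regions.
#'
#' @param truth truth list from \code{\link{simulateAnnotations}}.
#' @param excludeChroms chromosomes the pipeline drops.
#' @return The planted region \code{data.frame} restricted to kept
#'   chromosomes.
#' @export
truthRegions <- function(truth, excludeChroms = c("chrX", "chrY")) {
  truth$regions[!truth$regions$chrom %in% excludeChroms, , drop = FALSE]
}

#' Simulate per-line H3K4me3 / H3K27me3 peak sets
#'
#' Each planted bivalent region emits, per line, an H3K4me3 peak extending
#' 800 bp beyond the region start side and an H3K27me3 peak extending 800 bp
#' beyond the end side, so their overlap is exactly the planted region at
#' zero jitter. Single-mark regions emit one peak equal to the region in
#' every line. Boundary jitter is Gaussian; dropout removes a bivalent
#' region's peak pair from a line, creating line-specific regions.
#'
#' @param truth truth list from \code{\link{simulateAnnotations}}.
#' @param nLines number of cell lines.
#' @param jitterSd boundary jitter SD (bp).
#' @param dropout per-line, per-region drop probability for bivalent peak
#'   pairs.
#' @param seed RNG seed (defaults to the truth seed).
#' @return A list with named lists \code{k4} and \code{k27} of
#'   \linkS4class{PeakSet}s, one per line.
#' @export
simulatePeaksets <- function(truth, nLines = 5L, jitterSd = 50,
                             dropout = 0.05, seed = NULL) {
  stopifnot(jitterSd >= 0, dropout >= 0, dropout < 1)
  if (is.null(seed)) seed <- truth$seed
  .withSeed(seed + 202L, {
    tr <- truth$regions
    lines <- paste0("LINE", seq_len(nLines))
    jit <- function(n) if (jitterSd > 0)
      as.integer(round(rnorm(n, 0, jitterSd))) else integer(n)
    k4 <- list(); k27 <- list()
    for (ln in lines) {
      biv <- tr[tr$category == "bivalent", , drop = FALSE]
      keepBiv <- runif(nrow(biv)) >= dropout
      biv <- biv[keepBiv, , drop = FALSE]
      n <- nrow(biv)
      k4b <- data.frame(chrom = biv$chrom,
                        start = biv$start - 800L + jit(n),
                        end = biv$end + jit(n))
      k27b <- data.frame(chrom = biv$chrom,
                         start = biv$start + jit(n),
                         end = biv$end + 800L + jit(n))
      k4o <- tr[tr$category == "K4only", , drop = FALSE]
      k4s <- data.frame(chrom = k4o$chrom,
                        start = k4o$start + jit(nrow(k4o)),
                        end = k4o$end + jit(nrow(k4o)))
      k27o <- tr[tr$category == "K27only", , drop = FALSE]
      k27s <- data.frame(chrom = k27o$chrom,
                         start = k27o$start + jit(nrow(k27o)),
                         end = k27o$end + jit(nrow(k27o)))
      mkGr <- function(df) {
        df$start <- pmax(df$start, 0L)
        df <- df[df$end > df$start, , drop = FALSE]
        normalizeIntervals(bedRanges(df$chrom, df$start, df$end))
      }
      k4[[ln]] <- PeakSet(ln, "H3K4me3", mkGr(rbind(k4b, k4s)))
      k27[[ln]] <- PeakSet(ln, "H3K27me3", mkGr(rbind(k27b, k27s)))
    }
    list(k4 = k4, k27 = k27, lines = lines)
  })
}

#' Simulate four-factor signal tracks over the planted regions
#'
#' Per factor, a Gaussian bump at every planted bivalent region with a
#' cluster-dependent amplitude (cluster 1: PolII/TAF1-high; cluster 2:
#' EZH2-high with moderate TCF12; cluster 3: intermediate for all four) times
#' per-region lognormal variation, plus Poisson background, binned at
#' \code{binSize}.
#'
#' @param truth truth list from \code{\link{simulateAnnotations}}.
#' @param binSize bin width (bp).
#' @param separation multiplier on the between-cluster amplitude contrasts;
#'   0 erases the cluster structure entirely.
#' @param ampNoiseSd SD of the per-region lognormal amplitude factor.
#' @param background Poisson mean per bin.
#' @param seed RNG seed (defaults to the truth seed).
#' @return Named list of \linkS4class{SignalTrack}s (\code{EZH2},
#'   \code{PolII}, \code{TAF1}, \code{TCF12}).
#' @export
simulateTracks <- function(truth, binSize = 100L, separation = 1,
                           ampNoiseSd = 0.25, background = 0.1,
                           seed = NULL) {
  if (is.null(seed)) seed <- truth$seed
  .withSeed(seed + 303L, {
    factors <- c("EZH2", "PolII", "TAF1", "TCF12")
    # rows: clusters 1..3; cols: factors. Amplitudes in per-base signal units.
    base <- rbind(c(1, 10, 10, 1),
                  c(10, 0.5, 0.5, 5),
                  c(3, 3, 3, 2))
    colnames(base) <- factors
    mid <- colMeans(base)
    amp <- sweep(sweep(base, 2L, mid, "-") * separation, 2L, mid, "+")
    amp[amp < 0.05] <- 0.05
    biv <- truth$regions[truth$regions$category == "bivalent", , drop = FALSE]
    chroms <- names(truth$chromLengths)
    nbin <- setNames(as.integer(ceiling(truth$chromLengths / binSize)),
                     chroms)
    tracks <- list()
    for (f in factors) {
      vals <- lapply(chroms, function(ch) rpois(nbin[[ch]], background) * 1.0)
      names(vals) <- chroms
      if (nrow(biv)) {
        regAmp <- amp[biv$cluster, f] * exp(rnorm(nrow(biv), 0, ampNoiseSd))
        for (i in seq_len(nrow(biv))) {
          ch <- biv$chrom[i]
          center <- (biv$start[i] + biv$end[i]) / 2
          lo <- max(1L, floor((center - 2500) / binSize) + 1L)
          hi <- min(nbin[[ch]], ceiling((center + 2500) / binSize))
          bmid <- (seq(lo, hi) - 0.5) * binSize
          bump <- regAmp[i] * exp(-((bmid - center)^2) / (2 * 500^2))
          vals[[ch]][lo:hi] <- vals[[ch]][lo:hi] + bump
        }
      }
      cov <- RleList(lapply(chroms, function(ch) {
        len <- as.integer(truth$chromLengths[[ch]])
        r <- Rle(vals[[ch]], rep(binSize, nbin[[ch]]))
        r[seq_len(len)]
      }), compress = FALSE)
      names(cov) <- chroms
      tracks[[f]] <- SignalTrack(cov, rpm = FALSE)
    }
    tracks
  })
}

#' Simulate an array manifest, beta matrices and sample sheet
#'
#' Probes are placed inside the planted regions (denser in CGI-rich bivalent
#' and K4only regions), in unmarked promoter and gene-body CGIs, and as
#' genome background. Normal-tissue betas follow the planted methylome
#' (CGI/promoters unmethylated, gene-body CGIs and background methylated).
#' Hypermethylation is planted preferentially at cluster-2 bivalent CGI
#' probes: a per-type shared set gains \code{effect} in every tumor of the
#' type, arm-specific extras only in the CIMP-positive (large) or
#' CIMP-negative (small) tumors; a pan-cancer subset recurs across
#' \code{panTypes} types. A small hypomethylated set is planted in
#' methylated none-region probes.
#'
#' @param truth truth list from \code{\link{simulateAnnotations}}.
#' @param nProbes total probe count.
#' @param nPairs tumor/normal pairs per tumor type.
#' @param nTypes number of tumor types.
#' @param effect planted beta shift.
#' @param noiseSd truncated-normal beta noise SD.
#' @param nSharedHyper per-type hyper probes planted in every tumor.
#' @param nPosExtra,nNegExtra arm-specific extra hyper probes.
#' @param nHypo per-type hypomethylated probes.
#' @param nPanCancer size of the designed recurrent pan-cancer core.
#' @param panTypes number of types the pan-cancer core recurs in.
#' @param hyperWeights draw weights over the candidate pools
#'   (cluster-2 bivalent, cluster-3 bivalent, cluster-1 bivalent, none);
#'   cluster-2 probes are by far the most heavily hit relative to their pool
#'   size. Draws exceeding a pool spill into the remaining pools.
#' @param seed RNG seed (defaults to the truth seed).
#' @return A list: \code{manifest}, \code{beta} (probes x samples),
#'   \code{samples} (sample sheet) and \code{truth} (planted per-type /
#'   per-arm hyper and hypo probe sets, the designed pan-cancer core and the
#'   realized per-arm recurrent sets).
#' @export
simulateMethylomes <- function(truth, nProbes = 20000L, nPairs = 20L,
                               nTypes = 8L, effect = 0.4, noiseSd = 0.05,
                               nSharedHyper = 200L, nPosExtra = 150L,
                               nNegExtra = 40L, nHypo = 60L,
                               nPanCancer = 120L, panTypes = 6L,
                               hyperWeights = c(c2 = 0.30, c3 = 0.25,
                                                c1 = 0.05, none = 0.40),
                               seed = NULL) {
  stopifnot(effect > 0, effect < 1, noiseSd > 0, panTypes <= nTypes)
  if (is.null(seed)) seed <- truth$seed
  .withSeed(seed + 404L, {
    tr <- truth$regions
    gn <- truth$genes
    probes <- list()
    addProbes <- function(chrom, pos, relation, feature, gene, class,
                          cluster, baseMean) {
      probes[[length(probes) + 1L]] <<- data.frame(
        chrom = chrom, pos = as.integer(pos), cgi_relation = relation,
        feature = feature, gene_ids = gene, class = class,
        cluster = cluster, base_mean = baseMean, stringsAsFactors = FALSE)
    }
    perRegion <- c(bivalent = 8L, K4only = 8L, K27only = 3L)
    for (i in seq_len(nrow(tr))) {
      np <- perRegion[[tr$category[i]]]
      pos <- sort(sample(seq(tr$start[i], tr$end[i] - 1L), np))
      baseMean <- switch(tr$category[i], bivalent = 0.05, K4only = 0.05,
                         K27only = 0.80)
      addProbes(tr$chrom[i], pos,
                ifelse(tr$cgi[i], "core", "open sea"), "promoter",
                tr$gene_id[i], tr$category[i], tr$cluster[i], baseMean)
    }
    noneProm <- gn[gn$class == "none" & gn$promoter_cgi, , drop = FALSE]
    for (i in seq_len(nrow(noneProm))) {
      pos <- sort(sample(seq(noneProm$tss[i] - 400L, noneProm$tss[i] + 399L),
                         6L))
      addProbes(noneProm$chrom[i], pos, "core", "promoter",
                noneProm$gene_id[i], "none", NA_integer_, 0.08)
    }
    bodyCgi <- gn[gn$body_cgi, , drop = FALSE]
    for (i in seq_len(nrow(bodyCgi))) {
      pos <- sort(sample(seq(bodyCgi$tss[i] + 3500L, bodyCgi$tss[i] + 4299L),
                         5L))
      addProbes(bodyCgi$chrom[i], pos, "core", "gene body",
                bodyCgi$gene_id[i], "none", NA_integer_, 0.85)
    }
    man <- do.call(rbind, probes)
    nBg <- nProbes - nrow(man)
    if (nBg > 0) {
      chroms <- names(truth$chromLengths)
      bgCh <- sample(chroms, nBg, replace = TRUE,
                     prob = truth$chromLengths / sum(truth$chromLengths))
      bgPos <- vapply(bgCh, function(ch)
        sample.int(truth$chromLengths[[ch]] - 1L, 1L), numeric(1L))
      bg <- data.frame(chrom = bgCh, pos = as.integer(bgPos),
                       cgi_relation = "open sea", feature = "intergenic",
                       gene_ids = "", class = "none", cluster = NA_integer_,
                       base_mean = ifelse(runif(nBg) < 0.7, 0.85, 0.10),
                       stringsAsFactors = FALSE)
      # background probes must not fall inside planted regions
      inReg <- overlapsWithin(bedRanges(bg$chrom, bg$pos, bg$pos + 1L),
                              bedRanges(tr$chrom, tr$start, tr$end))
      man <- rbind(man, bg[!inReg, , drop = FALSE])
    }
    man$probe_id <- sprintf("cg%07d", seq_len(nrow(man)))
    man <- man[, c("probe_id", "chrom", "pos", "cgi_relation", "feature",
                   "gene_ids", "class", "cluster", "base_mean")]
    rownames(man) <- NULL

    # candidate pools for hyper planting, cluster-2 bivalent CGI first
    unmeth <- man$base_mean < 0.3   # planted shift must keep beta in [0,1]
    pool <- function(cls, clus = NULL) {
      idx <- which(man$class == cls & unmeth &
                     (if (is.null(clus)) TRUE else
                        !is.na(man$cluster) & man$cluster == clus))
      man$probe_id[idx]
    }
    weights <- hyperWeights / sum(hyperWeights)
    pools <- list(c2 = pool("bivalent", 2L), c3 = pool("bivalent", 3L),
                  c1 = pool("bivalent", 1L), none = pool("none"))
    drawComposed <- function(n, exclude = character()) {
      avail <- lapply(pools, setdiff, exclude)
      want <- round(weights * n)
      picked <- character()
      for (k in names(pools)) {
        take <- min(want[[k]], length(avail[[k]]))
        picked <- c(picked, sample(avail[[k]], take))
      }
      short <- n - length(picked)
      if (short > 0) {  # spill into whatever remains
        rest <- setdiff(unlist(avail, use.names = FALSE), picked)
        picked <- c(picked, sample(rest, min(short, length(rest))))
      }
      picked[seq_len(min(n, length(picked)))]
    }
    types <- sprintf("T%02d", seq_len(nTypes))
    panCancer <- drawComposed(nPanCancer)
    panTypesPick <- sort(sample(types, panTypes))
    hyperShared <- list(); hyperPos <- list(); hyperNeg <- list()
    hypoSets <- list()
    methylated <- man$probe_id[man$class == "none" & man$base_mean > 0.7]
    for (ty in types) {
      shared <- if (ty %in% panTypesPick)
        c(panCancer, drawComposed(max(nSharedHyper - nPanCancer, 0L),
                                  exclude = panCancer))
      else drawComposed(nSharedHyper, exclude = panCancer)
      hyperShared[[ty]] <- shared
      hyperPos[[ty]] <- c(shared, drawComposed(nPosExtra, exclude = shared))
      hyperNeg[[ty]] <- c(shared, drawComposed(nNegExtra,
                                               exclude = hyperPos[[ty]]))
      hypoSets[[ty]] <- sample(methylated, nHypo)
    }
    # realized recurrent sets per arm (the pan-cancer core is a subset by
    # construction; pool re-use across types can add further recurrences)
    recur <- function(sets, minTypes = 5L) {
      cnt <- table(unlist(lapply(sets, unique), use.names = FALSE))
      sort(names(cnt)[cnt >= minTypes])
    }

    samples <- do.call(rbind, lapply(types, function(ty) {
      pid <- sprintf("%s_P%02d", ty, seq_len(nPairs))
      rbind(data.frame(sample_id = paste0(pid, "_T"), type = ty,
                       status = "tumor", pair_id = pid,
                       cimp = rep(c("positive", "negative"),
                                  length.out = nPairs),
                       stringsAsFactors = FALSE),
            data.frame(sample_id = paste0(pid, "_N"), type = ty,
                       status = "normal", pair_id = pid, cimp = NA_character_,
                       stringsAsFactors = FALSE))
    }))
    rownames(samples) <- NULL

    clamp <- function(x) pmin(pmax(x, 0), 1)
    beta <- matrix(NA_real_, nrow = nrow(man), ncol = nrow(samples),
                   dimnames = list(man$probe_id, samples$sample_id))
    for (j in seq_len(nrow(samples))) {
      mu <- man$base_mean
      if (samples$status[j] == "tumor") {
        ty <- samples$type[j]
        arm <- samples$cimp[j]
        hy <- if (arm == "positive") hyperPos[[ty]] else hyperNeg[[ty]]
        mu <- mu + effect * (man$probe_id %in% hy)
        mu <- mu - effect * (man$probe_id %in% hypoSets[[ty]])
      }
      beta[, j] <- clamp(mu + rnorm(nrow(man), 0, noiseSd))
    }

    list(manifest = man, beta = beta, samples = samples,
         truth = list(hyper_shared = hyperShared, hyper_pos = hyperPos,
                      hyper_neg = hyperNeg, hypo = hypoSets,
                      pan_cancer = panCancer, pan_types = panTypesPick,
                      recurrent_pos = recur(hyperPos),
                      recurrent_neg = recur(hyperNeg),
                      effect = effect))
  })
}

#' Simulate a tissue expression matrix
#'
#' Log-normal RPKM per gene and tissue: K4only genes strongly expressed
#' everywhere, K27only genes silent everywhere, unmarked genes intermediate,
#' bivalent genes switching between an active and a silent level with a
#' cluster-dependent activity probability (cluster 1 most often active,
#' cluster 2 mostly silent).
#'
#' @param truth truth list from \code{\link{simulateAnnotations}}.
#' @param nTissues number of tissues.
#' @param seed RNG seed (defaults to the truth seed).
#' @return RPKM matrix, genes x tissues.
#' @export
simulateExpression <- function(truth, nTissues = 34L, seed = NULL) {
  if (is.null(seed)) seed <- truth$seed
  .withSeed(seed + 505L, {
    gn <- truth$genes
    tissues <- sprintf("tissue_%02d", seq_len(nTissues))
    lg <- matrix(NA_real_, nrow = nrow(gn), ncol = nTissues,
                 dimnames = list(gn$gene_id, tissues))
    pAct <- c(0.8, 0.15, 0.5)
    for (i in seq_len(nrow(gn))) {
      lg[i, ] <- switch(gn$class[i],
        K4only = rnorm(nTissues, 6, 0.7),
        K27only = rnorm(nTissues, -4, 0.7),
        none = rnorm(nTissues, 2, 1),
        bivalent = {
          on <- runif(nTissues) < pAct[gn$cluster[i]]
          ifelse(on, rnorm(nTissues, 5, 0.7), rnorm(nTissues, -3, 0.7))
        })
    }
    2^lg
  })
}

#' Generate a full synthetic study
#'
#' Runs every generator off one \code{\link{genomeSpec}} and returns all
#' inputs plus the planted truth.
#'
#' @param spec a \code{\link{genomeSpec}}.
#' @param nLines,jitterSd,dropout passed to \code{\link{simulatePeaksets}}.
#' @param tracks whether to simulate the factor tracks.
#' @param methylomes whether to simulate the methylation study.
#' @param expression whether to simulate the expression matrix.
#' @param ... passed to \code{\link{simulateMethylomes}}.
#' @return A list: \code{spec}, \code{bundle}, \code{truth}, \code{peaks}
#'   (with \code{k4} and \code{k27}), and optionally \code{tracks},
#'   \code{methylomes}, \code{expression}.
#' @export
simulateStudy <- function(spec = genomeSpec(), nLines = 5L, jitterSd = 50,
                          dropout = 0.05, tracks = TRUE, methylomes = TRUE,
                          expression = TRUE, ...) {
  ann <- simulateAnnotations(spec)
  out <- list(spec = spec, bundle = ann$bundle, truth = ann$truth)
  out$peaks <- simulatePeaksets(ann$truth, nLines = nLines,
                                jitterSd = jitterSd, dropout = dropout)
  if (tracks) out$tracks <- simulateTracks(ann$truth)
  if (methylomes) out$methylomes <- simulateMethylomes(ann$truth, ...)
  if (expression) out$expression <- simulateExpression(ann$truth)
  out
}
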