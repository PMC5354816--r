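# File interfaces: BED-family peak readers, bedGraph tracks, manifest /
# beta-matrix / sample-sheet TSVs, export products (region table, browser
# track, array-annotation file) and the pipeline configuration + runner.
# Every writer round-trips through its reader, and all outputs are
# byte-reproducible under a fixed config and seed.

.NARROW_COLS <- c(signalValue = "numeric", pValue = "numeric",
                  qValue = "numeric", peak = "integer")
.BROAD_COLS <- c(signalValue = "numeric", pValue = "numeric",
                 qValue = "numeric")

#' Read a peak file (BED3+, narrowPeak or broadPeak)
#'
#' narrowPeak/broadPeak q-values (column 9, -log10) are converted to an
#' \code{fdr} metadata column (\code{fdr = 10^-qValue}); a missing q-value
#' (encoded -1) gives \code{NA}.
#'
#' @param path file path.
#' @param cellLine,mark identifiers stored on the returned
#'   \linkS4class{PeakSet}.
#' @param dialect \code{"auto"} (by extension), \code{"bed"},
#'   \code{"narrowPeak"} or \code{"broadPeak"}.
#' @return A \linkS4class{PeakSet}.
#' @export
readPeaks <- function(path, cellLine = "NA", mark = "NA",
                      dialect = c("auto", "bed", "narrowPeak", "broadPeak")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.narrowPeak$", path)) "narrowPeak"
    else if (grepl("\\.broadPeak$", path)) "broadPeak"
    else "bed"
  }
  gr <- switch(dialect,
    bed = rtracklayer::import(path, format = "BED"),
    narrowPeak = rtracklayer::import(path, format = "BED",
                                     extraCols = .NARROW_COLS),
    broadPeak = rtracklayer::import(path, format = "BED",
                                    extraCols = .BROAD_COLS))
  if (!is.null(gr$qValue)) {
    q <- gr$qValue
    gr$fdr <- ifelse(q < 0, NA_real_, 10^(-q))
  }
  PeakSet(cellLine, mark, gr)
}

#' Write a PeakSet as narrowPeak (or BED3)
#'
#' @param x a \linkS4class{PeakSet} or \code{GRanges}.
#' @param path output path; a \code{.narrowPeak} extension writes the
#'   10-column dialect (q-value from the \code{fdr} column when present),
#'   anything else plain BED3.
#' @return \code{path}, invisibly.
#' @export
writePeaks <- function(x, path) {
  gr <- if (is(x, "PeakSet")) peaks(x) else x
  bed <- asBed(granges(gr))
  if (grepl("\\.narrowPeak$", path)) {
    fdr <- if (!is.null(gr$fdr)) gr$fdr else rep(NA_real_, length(gr))
    q <- ifelse(is.na(fdr), -1, -log10(fdr))
    sig <- if (!is.null(gr$score)) gr$score else rep(0, length(gr))
    out <- data.frame(bed$chrom, bed$start, bed$end,
                      name = sprintf("peak_%d", seq_len(nrow(bed))),
                      score = 0L, strand = ".", signalValue = sig,
                      pValue = -1, qValue = q, peak = -1L)
  } else {
    out <- bed[, c("chrom", "start", "end")]
  }
  write.table(format(out, scientific = FALSE, trim = TRUE), path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph signal track
#'
#' @param path bedGraph path (4 columns, 0-based half-open).
#' @param totalReads read count for RPM scaling; default: total signal area.
#' @return A \linkS4class{SignalTrack}.
#' @export
readBedGraph <- function(path, totalReads = NULL) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  SignalTrack(gr, totalReads = totalReads)
}

#' Write a SignalTrack as bedGraph
#' @param x a \linkS4class{SignalTrack}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeBedGraph <- function(x, path) {
  stopifnot(is(x, "SignalTrack"))
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in names(x@cov)) {
    r <- x@cov[[ch]]
    ends <- cumsum(runLength(r))
    starts <- c(0, utils::head(ends, -1L))
    v <- runValue(r)
    keep <- v != 0
    if (any(keep))
      writeLines(sprintf("%s\t%d\t%d\t%g", ch, starts[keep], ends[keep],
                         v[keep]), con)
  }
  invisible(path)
}

#' Write the annotated region table (TSV)
#'
#' One row per high-confidence region with coordinates (BED convention),
#' category, per-line support, annotation flags and cluster — the
#' machine-readable master list of the analysis.
#'
#' @param regionsGr annotated region \code{GRanges} (from
#'   \code{\link{annotateRegions}}, optionally with a \code{cluster} column).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeRegionTable <- function(regionsGr, path) {
  df <- asBed(regionsGr)
  df$width <- df$end - df$start
  front <- c("region_id", "chrom", "start", "end", "width", "category")
  df <- df[, c(front, setdiff(names(df), front))]
  df <- df[order(df$chrom, df$start), ]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a region table written by \code{\link{writeRegionTable}}
#' @param path TSV path.
#' @return A \code{GRanges} with all table columns as metadata.
#' @export
readRegionTable <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  gr <- bedRanges(df$chrom, df$start, df$end)
  for (col in setdiff(names(df), c("chrom", "start", "end", "width")))
    mcols(gr)[[col]] <- df[[col]]
  gr$category <- factor(gr$category,
                        levels = c("bivalent", "K4only", "K27only"))
  gr
}

.CATEGORY_RGB <- c(bivalent = "0,0,0", K4only = "0,0,255",
                   K27only = "128,0,128")

#' Write a genome-browser track (BED9)
#'
#' Fixed palette: bivalent black (0,0,0), K4only blue (0,0,255), K27only
#' purple (128,0,128); rows ordered by chromosome and start; itemRgb on.
#'
#' @param regionsGr region \code{GRanges} with \code{region_id} and
#'   \code{category}.
#' @param path output path.
#' @param name track name in the header line.
#' @return \code{path}, invisibly.
#' @export
writeBrowserTrack <- function(regionsGr, path,
                              name = "hESC_chromatin_states") {
  df <- asBed(regionsGr)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf('track name="%s" itemRgb="On"', name), con)
  if (nrow(df)) {
    df <- df[order(df$chrom, df$start), ]
    writeLines(sprintf("%s\t%d\t%d\t%s\t0\t.\t%d\t%d\t%s",
                       df$chrom, df$start, df$end, df$region_id,
                       df$start, df$end,
                       .CATEGORY_RGB[as.character(df$category)]), con)
  }
  invisible(path)
}

#' Write the array-annotation file
#'
#' Tab-delimited, one row per manifest probe, ready for joining chromatin
#' categories onto any methylation dataset: columns \code{TargetID},
#' \code{ChromatinState} (\code{None}, \code{Bivalent}, \code{H3K4me3only},
#' \code{H3K27me3only}), \code{BivalentCluster} (1/2/3 or NA) and
#' \code{RegionID}.
#'
#' @param probeMap \code{data.frame} from \code{\link{mapProbes}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeArrayAnnotation <- function(probeMap, path) {
  stateName <- c(none = "None", bivalent = "Bivalent",
                 K4only = "H3K4me3only", K27only = "H3K27me3only")
  out <- data.frame(TargetID = probeMap$probe_id,
                    ChromatinState = stateName[as.character(probeMap$category)],
                    BivalentCluster = probeMap$cluster,
                    RegionID = probeMap$region_id,
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Read an Illumina-style probe manifest
#'
#' Expects the columns \code{TargetID}, \code{CHR}, \code{MAPINFO} (1-based;
#' converted to 0-based), and optionally \code{UCSC_REFGENE_GROUP} and
#' \code{RELATION_TO_UCSC_CPG_ISLAND}. Chromosome names are normalized to
#' the \code{chr} form.
#'
#' @param path TSV path.
#' @return A \code{data.frame} with \code{probe_id}, \code{chrom},
#'   \code{pos} (0-based), \code{feature}, \code{cgi_relation}.
#' @export
readManifest <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("TargetID", "CHR", "MAPINFO")
  if (!all(need %in% names(df)))
    stop("manifest must contain columns: ", paste(need, collapse = ", "))
  chrom <- as.character(df$CHR)
  chrom <- ifelse(grepl("^chr", chrom), chrom, paste0("chr", chrom))
  out <- data.frame(probe_id = df$TargetID, chrom = chrom,
                    pos = as.integer(df$MAPINFO) - 1L,
                    stringsAsFactors = FALSE)
  out$feature <- if ("UCSC_REFGENE_GROUP" %in% names(df))
    df$UCSC_REFGENE_GROUP else NA_character_
  out$cgi_relation <- if ("RELATION_TO_UCSC_CPG_ISLAND" %in% names(df))
    df$RELATION_TO_UCSC_CPG_ISLAND else NA_character_
  out
}

#' Write a manifest in the Illumina-style column layout
#' @param manifest \code{data.frame} with \code{probe_id}, \code{chrom},
#'   \code{pos} (0-based) and optional \code{feature} / \code{cgi_relation}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeManifest <- function(manifest, path) {
  out <- data.frame(TargetID = manifest$probe_id,
                    CHR = sub("^chr", "", manifest$chrom),
                    MAPINFO = manifest$pos + 1L,
                    UCSC_REFGENE_GROUP =
                      if (!is.null(manifest$feature)) manifest$feature
                      else NA_character_,
                    RELATION_TO_UCSC_CPG_ISLAND =
                      if (!is.null(manifest$cgi_relation))
                        manifest$cgi_relation else NA_character_,
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a beta matrix (probes x samples TSV)
#' @param path TSV with probe ids in the first column, sample ids as header.
#' @return Numeric matrix with dimnames.
#' @export
readBetaMatrix <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "double"
  if (any(m < 0 | m > 1, na.rm = TRUE))
    stop("beta values outside [0, 1] in ", path)
  m
}

#' Write a beta matrix
#' @param beta numeric matrix with dimnames.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeBetaMatrix <- function(beta, path) {
  df <- data.frame(probe_id = rownames(beta), beta, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write the sample sheet
#'
#' Columns: \code{Sample_ID}, \code{Type}, \code{Status}, \code{Pair_ID},
#' \code{CIMP}.
#'
#' @param path TSV path.
#' @return \code{data.frame} with lower-case internal column names.
#' @export
readSampleSheet <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("Sample_ID", "Type", "Status", "Pair_ID", "CIMP")
  if (!all(need %in% names(df)))
    stop("sample sheet must contain columns: ", paste(need, collapse = ", "))
  data.frame(sample_id = df$Sample_ID, type = df$Type,
             status = tolower(df$Status), pair_id = df$Pair_ID,
             cimp = ifelse(df$CIMP %in% c("positive", "negative"),
                           df$CIMP, NA_character_),
             stringsAsFactors = FALSE)
}

#' @rdname readSampleSheet
#' @param samples internal sample sheet \code{data.frame}.
#' @export
writeSampleSheet <- function(samples, path) {
  out <- data.frame(Sample_ID = samples$sample_id, Type = samples$type,
                    Status = samples$status, Pair_ID = samples$pair_id,
                    CIMP = ifelse(is.na(samples$cimp), "NA", samples$cimp),
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Thresholds and options of the full analysis, with the reference defaults:
#' 1 kb bivalent overlap and single-mark width, TSS +/- 1 kb promoters,
#' |delta beta| > 0.25 at FDR < 0.05, beta bands 0.1/0.3/0.7, sex
#' chromosomes excluded, recurrence in >= 5 of 8 types.
#'
#' @param seed master seed used by the synthetic study and K-means.
#' @param minOverlap,minWidth,promoterFlank,deltaMin,fdrMax,betaBands,excludeChroms,minRecurrentTypes
#'   thresholds (see the linked functions).
#' @param kmeansStarts,kmeansSeed K-means settings.
#' @param ... further entries stored verbatim (e.g. input paths).
#' @return A classed list (\code{pipelineConfig}).
#' @export
pipelineConfig <- function(seed = 1L, minOverlap = 1000, minWidth = 1000,
                           promoterFlank = 1000, deltaMin = 0.25,
                           fdrMax = 0.05,
                           betaBands = c(low = 0.1, unmeth = 0.3, meth = 0.7),
                           excludeChroms = c("chrX", "chrY"),
                           minRecurrentTypes = 5L, kmeansStarts = 50L,
                           kmeansSeed = 1729L, ...) {
  stopifnot(minOverlap > 0, minWidth > 0, promoterFlank > 0,
            deltaMin > 0, deltaMin < 1, fdrMax > 0, fdrMax < 1)
  structure(c(list(seed = as.integer(seed), minOverlap = minOverlap,
                   minWidth = minWidth, promoterFlank = promoterFlank,
                   deltaMin = deltaMin, fdrMax = fdrMax,
                   betaBands = betaBands, excludeChroms = excludeChroms,
                   minRecurrentTypes = minRecurrentTypes,
                   kmeansStarts = kmeansStarts, kmeansSeed = kmeansSeed),
              list(...)),
            class = "pipelineConfig")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file; entries override the \code{\link{pipelineConfig}}
#'   defaults.
#' @return A \code{pipelineConfig}.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipelineConfig, y)
}

#' Run the full pipeline on a synthetic study
#'
#' Generates the study from the config seed, calls the chromatin-state
#' lists, annotates them, clusters the bivalent regions, maps the array
#' probes, runs CIMP-stratified differential methylation for every tumor
#' type, computes the pan-cancer recurrence and the expression summaries,
#' and writes the full output tree (region table, browser track, array
#' annotation, per-type DMP tables, recurrence lists, run log). Outputs are
#' byte-identical across runs with the same config.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @param outDir output directory (created).
#' @return Invisibly, a list with all in-memory results.
#' @export
runPipeline <- function(config = pipelineConfig(), outDir) {
  stopifnot(inherits(config, "pipelineConfig"))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  study <- simulateStudy(genomeSpec(seed = config$seed))
  states <- callChromatinStates(study$peaks$k4, study$peaks$k27,
                                minOverlap = config$minOverlap,
                                minWidth = config$minWidth,
                                excludeChroms = config$excludeChroms)
  ann <- annotateRegions(regions(states), study$bundle)
  biv <- ann[ann$category == "bivalent"]
  clusters <- clusterBivalentRegions(biv, study$tracks,
                                     seed = config$kmeansSeed,
                                     nStarts = config$kmeansStarts)
  ann$cluster <- clusters$cluster[match(ann$region_id, clusters$region_id)]
  writeRegionTable(ann, file.path(outDir, "regions.tsv"))
  writeBrowserTrack(ann, file.path(outDir, "regions_browser.bed"))

  probeMap <- mapProbes(study$methylomes$manifest, states, clusters)
  writeArrayAnnotation(probeMap, file.path(outDir, "array_annotation.tsv"))

  types <- unique(study$methylomes$samples$type)
  dmp <- list()
  hyperSets <- list(positive = list(), negative = list())
  for (ty in types) {
    arms <- stratifyCimp(study$methylomes$beta, study$methylomes$samples,
                         ty, deltaMin = config$deltaMin,
                         fdrMax = config$fdrMax)
    dmp[[ty]] <- arms
    for (arm in names(arms)) {
      res <- arms[[arm]]
      hyperSets[[arm]][[ty]] <- res$probe_id[res$call == "hyper"]
      keep <- res$call != "none"
      write.table(res[keep, c("probe_id", "delta_beta", "t_mod", "p", "q",
                              "call")],
                  file.path(outDir, sprintf("dmps_%s_%s.tsv", ty, arm)),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  rec <- lapply(hyperSets, recurrence, minTypes = config$minRecurrentTypes,
                probeMap = probeMap)
  for (arm in names(rec))
    writeLines(rec[[arm]]$probes,
               file.path(outDir, sprintf("recurrent_probes_%s.txt", arm)))

  signatures <- promoterSignatures(ann, study$bundle)
  norm <- normalizeToK4(study$expression, signatures)
  bivAnn <- ann[ann$category == "bivalent" & !is.na(ann$cluster) &
                  nzchar(ann$gene_ids)]
  gl <- strsplit(bivAnn$gene_ids, ",", fixed = TRUE)
  geneCluster <- unique(data.frame(
    gene_id = unlist(gl),
    cluster = rep(bivAnn$cluster, lengths(gl)), stringsAsFactors = FALSE))
  exprMed <- clusterExpressionMedians(norm, signatures, geneCluster)
  write.table(exprMed, file.path(outDir, "expression_cluster_medians.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  # planted truth alongside the outputs, so downstream checks never have to
  # re-derive it from generator internals
  write.table(study$truth$regions, file.path(outDir, "truth_regions.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(study$truth$genes, file.path(outDir, "truth_genes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  log <- c(sprintf("package=bivalency %s", packageVersion("bivalency")),
           sprintf("seed=%d", config$seed),
           sprintf("minOverlap=%g", config$minOverlap),
           sprintf("minWidth=%g", config$minWidth),
           sprintf("deltaMin=%g", config$deltaMin),
           sprintf("fdrMax=%g", config$fdrMax),
           sprintf("n_hc_regions=%d", length(states)),
           sprintf("n_probes=%d", nrow(probeMap)))
  writeLines(log, file.path(outDir, "run_log.txt"))

  invisible(list(study = study, states = states, annotated = ann,
                 clusters = clusters, probeMap = probeMap, dmp = dmp,
                 recurrence = rec, signatures = signatures,
                 expressionMedians = exprMed))
}
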