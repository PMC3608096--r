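#' @include cnv.R snvfilter.R synthdata.R
NULL

#' Parameters for the multiphasic pipeline
#'
#' Collects every stage's tunables with the study defaults: autosomal
#' dominant full-penetrance model (disease allele frequency 1e-5, theta
#' 0), QC at depth >= 10 / GQ >= 30, LOD threshold 1.5 with 10 Mb hot-spot
#' gap and >= 2 markers per hot spot, per-exon CNV alpha 0.05, and
#' known-variant handling in annotate-only mode.
#'
#' @param penetrance,diseaseFreq,theta disease model (see
#'   [diseaseModel()]).
#' @param minDepth,minGq,strict genotype QC (see [qcFilter()]).
#' @param lodThreshold,maxGap,minMarkers hot-spot detection (see
#'   [detectHotspots()]).
#' @param minBaselineDepth,cnvAlpha,nBins,scanAlpha CNV stage (see
#'   [normalizeCoverage()], [callExonCnv()], [cnvCosegScan()]).
#' @param knownMode,maxFreq known-variant handling (see [knownFilter()]).
#' @param intersectHotspots restrict candidates to hot spots (see
#'   [hotspotIntersect()]).
#' @return a named list of parameters.
#' @export
pipelineParams <- function(penetrance = c(0, 1, 1), diseaseFreq = 1e-5,
                           theta = 0, minDepth = 10, minGq = 30,
                           strict = FALSE, lodThreshold = 1.5,
                           maxGap = 1e7, minMarkers = 2L,
                           minBaselineDepth = 10, cnvAlpha = 0.05,
                           nBins = 20, scanAlpha = 0.05,
                           knownMode = "annotate_only", maxFreq = 0.01,
                           intersectHotspots = TRUE) {
  list(penetrance = penetrance, diseaseFreq = diseaseFreq, theta = theta,
       minDepth = minDepth, minGq = minGq, strict = strict,
       lodThreshold = lodThreshold, maxGap = maxGap,
       minMarkers = as.integer(minMarkers),
       minBaselineDepth = minBaselineDepth, cnvAlpha = cnvAlpha,
       nBins = nBins, scanAlpha = scanAlpha, knownMode = knownMode,
       maxFreq = maxFreq, intersectHotspots = intersectHotspots)
}

#' Run the multiphasic family-exome analysis
#'
#' Executes the three evidence streams in order -- exon CNV calling with
#' the co-segregation exact test, single-point linkage with hot-spot
#' detection, and the variant filter funnel intersected with the hot
#' spots -- and returns a run report. Deterministic given its inputs. The
#' CNV stage is skipped when \code{coverage} is NULL; an optional second
#' genotype panel is scanned under the same model and compared to the WES
#' track.
#'
#' @param ped a \linkS4class{FamPedigree}.
#' @param variants annotated WES \linkS4class{GenotypePanel}.
#' @param coverage optional \linkS4class{ExonCoverage}.
#' @param validationPanel optional second \linkS4class{GenotypePanel}
#'   (e.g. array platform).
#' @param params a [pipelineParams()] list.
#' @return a \code{famphaseReport}: list with per-stage results
#'   (\code{cnv}, \code{linkage}, \code{snv}, \code{validation}),
#'   candidate table and funnel counts.
#' @export
runPipeline <- function(ped, variants, coverage = NULL,
                        validationPanel = NULL,
                        params = pipelineParams()) {
  model <- diseaseModel(params$penetrance, params$diseaseFreq,
                        params$theta)
  report <- list(params = params, pedigree = ped)

  if (!is.null(coverage)) {
    ratios <- normalizeCoverage(coverage, params$minBaselineDepth)
    calls <- callExonCnv(ratios, alpha = params$cnvAlpha,
                         nBins = params$nBins)
    scan <- cnvCosegScan(calls, ped, alpha = params$scanAlpha)
    report$cnv <- list(
      calls = calls, scan = scan,
      nExons = nrow(calls), nMasked = sum(rowData(calls)$masked),
      significant = metadata(scan)$significant,
      minP = if (length(scan)) min(scan$p) else NA_real_)
  }

  track <- lodScan(ped, variants, model, minDepth = params$minDepth,
                   minGq = params$minGq, strict = params$strict)
  hotspots <- detectHotspots(track, lodThreshold = params$lodThreshold,
                             maxGap = params$maxGap,
                             minMarkers = params$minMarkers)
  report$linkage <- list(track = track, hotspots = hotspots,
                         nMarkers = length(track),
                         maxLod = if (length(track)) max(track$lod)
                                  else NA_real_)

  funnel <- snvFunnel(variants, ped, hotspots,
                      minDepth = params$minDepth, minGq = params$minGq,
                      strict = params$strict,
                      knownMode = params$knownMode,
                      maxFreq = params$maxFreq,
                      intersect = params$intersectHotspots)
  report$snv <- funnel
  report$candidates <- funnel$candidates
  report$counts <- funnel$counts

  if (!is.null(validationPanel)) {
    vtrack <- lodScan(ped, validationPanel, model)
    report$validation <- list(
      track = vtrack,
      concordance = compareTracks(track, vtrack,
                                  lodThreshold = params$lodThreshold,
                                  maxGap = params$maxGap,
                                  minMarkers = params$minMarkers))
  }
  structure(report, class = "famphaseReport")
}

#' Cross-platform concordance of two LOD tracks
#'
#' For each hot spot detected in track A, reports the maximum LOD among
#' track-B markers inside the hot-spot interval and whether it reaches
#' the threshold; the recovered fraction summarises how well an
#' independent marker panel confirms the candidate loci.
#'
#' @param trackA,trackB LOD tracks from [lodScan()] computed under the
#'   same disease model.
#' @param lodThreshold,maxGap,minMarkers hot-spot parameters applied to
#'   track A.
#' @return list with \code{hotspots} (data.frame: chrom, start, end,
#'   maxLodA, maxLodB, recovered) and \code{recovery} (fraction of A hot
#'   spots recovered in B).
#' @export
compareTracks <- function(trackA, trackB, lodThreshold = 1.5,
                          maxGap = 1e7, minMarkers = 2L) {
  hs <- detectHotspots(trackA, lodThreshold, maxGap, minMarkers)
  if (!length(hs))
    return(list(hotspots = data.frame(), recovery = NA_real_))
  if (!length(trackB)) {
    .warnf("validation track is empty; recovery 0")
    df <- data.frame(chrom = as.character(seqnames(hs)),
                     start = start(hs), end = end(hs),
                     maxLodA = hs$maxLod, maxLodB = NA_real_,
                     recovered = FALSE)
    return(list(hotspots = df, recovery = 0))
  }
  ov <- suppressWarnings(findOverlaps(trackB, hs))
  maxB <- rep(NA_real_, length(hs))
  if (length(ov)) {
    agg <- tapply(trackB$lod[S4Vectors::queryHits(ov)],
                  S4Vectors::subjectHits(ov), max)
    maxB[as.integer(names(agg))] <- as.numeric(agg)
  }
  recovered <- !is.na(maxB) & maxB >= lodThreshold
  df <- data.frame(chrom = as.character(seqnames(hs)), start = start(hs),
                   end = end(hs), maxLodA = hs$maxLod, maxLodB = maxB,
                   recovered = recovered)
  list(hotspots = df, recovery = mean(recovered))
}

#' @export
print.famphaseReport <- function(x, ...) {
  cat("Multiphasic family-exome analysis report\n")
  cat("----------------------------------------\n")
  if (!is.null(x$cnv))
    cat(sprintf("CNV stage: %d exons (%d masked); co-segregation scan min p = %s; %d exon(s) below alpha\n",
                x$cnv$nExons, x$cnv$nMasked,
                format(x$cnv$minP, digits = 4),
                length(x$cnv$significant)))
  cat(sprintf("Linkage: %d markers scanned; max LOD = %s; %d hot spot(s)\n",
              x$linkage$nMarkers, format(x$linkage$maxLod, digits = 5),
              length(x$linkage$hotspots)))
  cat("Variant funnel: ",
      paste(sprintf("%s=%d", names(x$counts), x$counts),
            collapse = " -> "), "\n", sep = "")
  cat(sprintf("Candidates: %d\n", nrow(x$candidates)))
  if (!is.null(x$validation))
    cat(sprintf("Validation panel: hot-spot recovery %.2f\n",
                x$validation$concordance$recovery))
  invisible(x)
}

#' Write all pipeline outputs as text artifacts
#'
#' Emits the LOD track, hot spots (BED-like), CNV calls and scan, the
#' candidate table (both TSV and the six-column report layout) and a
#' plain-text funnel/report summary. Output is deterministic: rerunning
#' the pipeline on identical inputs reproduces every file byte for byte.
#'
#' @param report a \code{famphaseReport} from [runPipeline()].
#' @param dir output directory (created if needed).
#' @return invisible character vector of written paths.
#' @export
writeReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  wr <- function(df, name, col.names = TRUE) {
    p <- file.path(dir, name)
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = col.names)
    paths <<- c(paths, p)
  }
  tr <- report$linkage$track
  wr(data.frame(marker_id = tr$markerId,
                chrom = as.character(seqnames(tr)), pos = start(tr),
                lod = tr$lod), "lod_track.tsv")
  hs <- report$linkage$hotspots
  wr(data.frame(chrom = as.character(seqnames(hs)), start = start(hs),
                end = end(hs), n_markers = hs$nMarkers,
                max_lod = hs$maxLod), "hotspots.tsv")
  if (!is.null(report$cnv)) {
    calls <- report$cnv$calls
    st <- assay(calls, "state")
    lr <- assay(calls, "log2Ratio")
    pv <- assay(calls, "pValue")
    idx <- which(!is.na(st) & st != "normal", arr.ind = TRUE)
    wr(data.frame(exon = rownames(calls)[idx[, 1]],
                  sample = colnames(calls)[idx[, 2]],
                  log2_ratio = round(lr[idx], 4), p = signif(pv[idx], 4),
                  state = st[idx]), "cnv_calls.tsv")
    sc <- report$cnv$scan
    wr(data.frame(exon = sc$exon, chrom = as.character(seqnames(sc)),
                  p = signif(sc$p, 6),
                  minus_log10_p = round(sc$minusLog10P, 4)),
       "cnv_scan.tsv")
  }
  wr(report$candidates, "candidates.tsv")
  p <- file.path(dir, "candidate_table.txt")
  writeLines(renderCandidateTable(report$candidates), p)
  paths <- c(paths, p)
  p <- file.path(dir, "report.txt")
  con <- file(p, "w")
  sink(con); print(report); sink()
  close(con)
  paths <- c(paths, p)
  invisible(paths)
}

#' Run the pipeline from a YAML run configuration
#'
#' Reads a YAML file with input paths (\code{ped}, \code{vcf},
#' \code{annotation}, \code{bed}, \code{depth}, optional \code{array})
#' and optional \code{params} overrides for [pipelineParams()], runs
#' [runPipeline()] and writes all artifacts to \code{outdir}.
#'
#' @param config path to a YAML file, or an equivalent named list.
#' @return the \code{famphaseReport}, invisibly.
#' @export
runAll <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  for (f in c("ped", "vcf", "annotation", "depth")) {
    if (is.null(config[[f]])) .stopf("run config lacks '%s'", f)
    if (!file.exists(config[[f]]))
      .stopf("input file not found: %s", config[[f]])
  }
  params <- do.call(pipelineParams, as.list(config$params))
  ped <- readPed(config$ped)
  variants <- readVariantVcf(config$vcf, annotation = config$annotation)
  coverage <- readDepthTsv(config$depth)
  validation <- if (!is.null(config$array))
    readGenotypeTsv(config$array) else NULL
  report <- runPipeline(ped, variants, coverage, validation, params)
  if (!is.null(config$outdir)) writeReport(report, config$outdir)
  invisible(report)
}
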