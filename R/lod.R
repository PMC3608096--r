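#' @include likelihood.R panels.R
NULL

#' Single-point LOD scan over a genotype panel
#'
#' Computes one LOD score per QC-passing marker. For WES-derived panels,
#' markers are excluded when any genotyped subject falls below the depth or
#' genotype-quality thresholds (default: keep iff depth >= \code{minDepth}
#' and GQ >= \code{minGq}; \code{strict = TRUE} requires strictly greater,
#' matching tools that phrase the filter as "greater than"); array panels
#' carry no per-genotype QC and skip these filters. Sex-chromosome markers
#' are excluded by default (no X-linked model is implemented), as are
#' non-SNV records and markers with no observed genotype. Markers whose
#' genotypes are impossible under both hypotheses are dropped with a
#' message; LOD values of \code{-Inf} (impossible only at the test theta)
#' are floored at \code{lodFloor} so the track stays finite.
#'
#' @param ped a \linkS4class{FamPedigree}.
#' @param panel a \linkS4class{GenotypePanel}.
#' @param model a \linkS4class{DiseaseModel}.
#' @param minDepth,minGq per-genotype QC thresholds (WES panels only).
#' @param strict if \code{TRUE}, QC keeps only depth > minDepth and
#'   GQ > minGq.
#' @param autosomesOnly drop sex-chromosome markers (default TRUE).
#' @param snvOnly drop indel records (default TRUE).
#' @param altFreq marker allele frequencies: \code{NULL} (default) to
#'   estimate from genotyped founders via [estimateAlleleFreqs()],
#'   \code{"stored"} to use \code{rowData()$altFreq}, or a numeric vector.
#' @param lodFloor finite floor substituted for \code{-Inf} LODs.
#' @return A \code{GRanges} LOD track, sorted by position, with
#'   \code{mcols} \code{markerId} and \code{lod}. Empty (with a warning)
#'   if no marker survives QC.
#' @export
lodScan <- function(ped, panel, model = diseaseModel(), minDepth = 10,
                    minGq = 30, strict = FALSE, autosomesOnly = TRUE,
                    snvOnly = TRUE, altFreq = NULL, lodFloor = -99) {
  gr <- rowRanges(panel)
  rd <- rowData(panel)
  keep <- rep(TRUE, nrow(panel))
  if (autosomesOnly) keep <- keep & .isAutosome(as.character(seqnames(gr)))
  if (snvOnly && "type" %in% names(rd)) keep <- keep & rd$type == "snv"
  dos <- assay(panel, "dosage")
  subj <- intersect(colnames(panel), pedigreeIds(ped))
  if (!length(subj)) .stopf("no panel subjects found in the pedigree")
  dos <- dos[, subj, drop = FALSE]
  if (panel@platform == "wes") {
    if (all(c("depth", "gq") %in% names(assays(panel)))) {
      dp <- assay(panel, "depth")[, subj, drop = FALSE]
      gq <- assay(panel, "gq")[, subj, drop = FALSE]
      genoed <- !is.na(dos)
      fail <- if (strict) (dp <= minDepth | gq <= minGq)
              else (dp < minDepth | gq < minGq)
      fail[is.na(fail)] <- TRUE
      keep <- keep & rowSums(genoed & fail) == 0
    } else {
      .warnf("WES panel lacks depth/gq assays; QC filters skipped")
    }
  }
  keep <- keep & rowSums(!is.na(dos)) > 0
  if (!any(keep)) {
    .warnf("no markers survive QC; returning empty LOD track")
    empty <- GRanges()
    mcols(empty) <- DataFrame(markerId = character(0), lod = numeric(0))
    return(empty)
  }
  sub <- panel[keep, ]
  dsub <- t(dos[keep, , drop = FALSE])  # ids x markers for the likelihood
  af <- if (is.null(altFreq)) {
    estimateAlleleFreqs(sub, ped)
  } else if (identical(altFreq, "stored")) {
    rowData(sub)$altFreq
  } else {
    rep_len(as.numeric(altFreq), nrow(sub))
  }
  lod <- lodSinglePoint(ped, dsub, af, model)
  bad <- is.nan(lod)
  if (any(bad)) {
    message(sprintf("lodScan: dropping %d marker(s) impossible under both hypotheses",
                    sum(bad)))
    sub <- sub[!bad, ]; lod <- lod[!bad]
  }
  lod[lod == -Inf] <- lodFloor
  out <- rowRanges(sub)
  mcols(out) <- DataFrame(markerId = rowData(sub)$markerId, lod = lod)
  names(out) <- NULL
  out
}

#' Cluster high-LOD markers into candidate hot spots
#'
#' Greedily merges markers with LOD >= \code{lodThreshold} on the same
#' chromosome whenever consecutive high-LOD markers are separated by at
#' most \code{maxGap} bases, and reports clusters with at least
#' \code{minMarkers} members. Isolated high-LOD markers below
#' \code{minMarkers} are dropped with a message: a locus supported by a
#' single marker is indistinguishable from a chance perfect co-segregation
#' in a small family, whereas the study's candidate loci were clusters of
#' closely spaced peaks.
#'
#' @param track a LOD track from [lodScan()].
#' @param lodThreshold minimum member LOD (the study's candidate threshold
#'   is 1.5).
#' @param maxGap maximum distance between consecutive member markers (bp).
#' @param minMarkers minimum markers per hot spot.
#' @return \code{GRanges} of hot spots (start/end = positions of the first
#'   and last member marker) with \code{mcols} \code{nMarkers},
#'   \code{maxLod} and \code{markerIds} (comma-separated).
#' @export
detectHotspots <- function(track, lodThreshold = 1.5, maxGap = 1e7,
                           minMarkers = 2L) {
  hi <- track[!is.na(track$lod) & track$lod >= lodThreshold]
  empty <- GRanges()
  mcols(empty) <- DataFrame(nMarkers = integer(0), maxLod = numeric(0),
                            markerIds = character(0))
  if (!length(hi)) return(empty)
  hi <- hi[.genomeOrder(as.character(seqnames(hi)), start(hi))]
  chrom <- as.character(seqnames(hi))
  pos <- start(hi)
  newClust <- c(TRUE, chrom[-1] != chrom[-length(chrom)] |
                  diff(pos) > maxGap)
  cl <- cumsum(newClust)
  groups <- split(seq_along(cl), cl)
  sizes <- lengths(groups)
  dropped <- sum(sizes < minMarkers)
  if (dropped)
    message(sprintf("detectHotspots: %d cluster(s) below minMarkers = %d dropped",
                    dropped, minMarkers))
  groups <- groups[sizes >= minMarkers]
  if (!length(groups)) return(empty)
  first <- vapply(groups, function(i) i[1], integer(1))
  last <- vapply(groups, function(i) i[length(i)], integer(1))
  out <- GRanges(chrom[first], IRanges(pos[first], pos[last]))
  mcols(out) <- DataFrame(
    nMarkers = unname(lengths(groups)),
    maxLod = unname(vapply(groups, function(i) max(hi$lod[i]),
                           numeric(1))),
    markerIds = unname(vapply(groups, function(i)
      paste(hi$markerId[i], collapse = ","), character(1))))
  names(out) <- NULL
  out[.genomeOrder(as.character(seqnames(out)), start(out))]
}
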