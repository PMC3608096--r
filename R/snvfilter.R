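#' @include panels.R lod.R
NULL

# Effect classes treated as amino-acid-changing and therefore candidate-
# eligible; synonymous and unclassified records are dropped.
.CODING_EFFECTS <- c("nonsynonymous", "stopgain", "stoploss", "frameshift",
                     "nonframeshift", "splicing")

#' @noRd
.sequencedIn <- function(panel, ped) {
  subj <- intersect(colnames(panel), pedigreeIds(ped))
  if (!length(subj)) .stopf("no panel subjects found in the pedigree")
  subj
}

#' Per-genotype QC filter for variants
#'
#' Keeps variants for which every sequenced member's genotype meets the
#' depth and genotype-quality thresholds (default: depth >=
#' \code{minDepth} and GQ >= \code{minGq}; \code{strict = TRUE} requires
#' strictly greater). A missing genotype, depth or GQ in any sequenced
#' member fails the variant. Sex-chromosome variants are dropped when
#' \code{autosomesOnly} is set.
#'
#' @param panel a WES \linkS4class{GenotypePanel} with depth/gq assays.
#' @param ped the \linkS4class{FamPedigree}; sequenced members are the
#'   panel subjects present in the pedigree.
#' @param minDepth,minGq thresholds (reads; phred).
#' @param autosomesOnly drop chrX/chrY variants.
#' @param strict strict inequality mode.
#' @return the filtered \linkS4class{GenotypePanel}.
#' @export
qcFilter <- function(panel, ped, minDepth = 10, minGq = 30,
                     autosomesOnly = FALSE, strict = FALSE) {
  subj <- .sequencedIn(panel, ped)
  if (!all(c("depth", "gq") %in% names(assays(panel))))
    .stopf("qcFilter requires depth and gq assays")
  dp <- assay(panel, "depth")[, subj, drop = FALSE]
  gq <- assay(panel, "gq")[, subj, drop = FALSE]
  dos <- assay(panel, "dosage")[, subj, drop = FALSE]
  ok <- if (strict) (dp > minDepth & gq > minGq) else
    (dp >= minDepth & gq >= minGq)
  ok[is.na(ok)] <- FALSE
  ok[is.na(dos)] <- FALSE
  keep <- rowSums(ok) == length(subj)
  if (autosomesOnly)
    keep <- keep & .isAutosome(as.character(seqnames(rowRanges(panel))))
  panel[keep, ]
}

#' Filter or annotate known variants
#'
#' In \code{drop_known} mode, removes variants carrying a known-variant id
#' (dbSNP-style) or a population frequency above \code{maxFreq}. The
#' default \code{annotate_only} passes everything through: in a family
#' study the decisive filter is co-segregation, and known common variants
#' can still co-segregate and appear in the candidate table (as several of
#' the study's final candidates did, with population frequencies up to
#' 0.50), so novelty is best used as an annotation rather than a hard
#' filter.
#'
#' @param panel an annotated \linkS4class{GenotypePanel}.
#' @param mode \code{"annotate_only"} (default) or \code{"drop_known"}.
#' @param maxFreq population-frequency ceiling in \code{drop_known} mode.
#' @return the (possibly) filtered panel.
#' @export
knownFilter <- function(panel, mode = c("annotate_only", "drop_known"),
                        maxFreq = 0.01) {
  mode <- match.arg(mode)
  if (mode == "annotate_only") return(panel)
  rd <- rowData(panel)
  known <- !is.na(rd$knownId) |
    (!is.na(rd$popFreq) & rd$popFreq > maxFreq)
  panel[!known, ]
}

#' Keep amino-acid-changing variants
#'
#' Retains variants annotated as nonsynonymous, stopgain, stoploss,
#' frameshift, nonframeshift or splicing; synonymous and other classes are
#' dropped, and variants with no effect annotation are dropped with a
#' warning.
#'
#' @param panel an annotated \linkS4class{GenotypePanel}.
#' @return the filtered panel.
#' @export
effectFilter <- function(panel) {
  eff <- rowData(panel)$effect
  if (is.null(eff)) .stopf("panel carries no effect annotation")
  if (anyNA(eff))
    .warnf("dropping %d variant(s) with missing effect annotation",
           sum(is.na(eff)))
  panel[!is.na(eff) & eff %in% .CODING_EFFECTS, ]
}

#' Keep variants co-segregating under a dominant model
#'
#' Retains variants carried (dosage >= 1, heterozygous or homozygous) by
#' every sequenced affected member and absent (dosage 0) from every
#' sequenced unaffected member. Sequenced members with unknown affection
#' are not constrained. A missing dosage in any constrained member drops
#' the variant (conservative: a lost genotype can be recovered by relaxing
#' QC, a false candidate cannot).
#'
#' @param panel a \linkS4class{GenotypePanel}.
#' @param ped the \linkS4class{FamPedigree}; affection must be known for
#'   the members used.
#' @return the filtered panel.
#' @export
segregationFilter <- function(panel, ped) {
  subj <- .sequencedIn(panel, ped)
  aff <- affectionOf(ped)[subj]
  dos <- assay(panel, "dosage")[, subj, drop = FALSE]
  affCols <- subj[aff == "affected"]
  unaCols <- subj[aff == "unaffected"]
  okAff <- dos[, affCols, drop = FALSE] >= 1
  okUna <- dos[, unaCols, drop = FALSE] == 0
  okAff[is.na(okAff)] <- FALSE
  okUna[is.na(okUna)] <- FALSE
  keep <- rowSums(okAff) == length(affCols) &
    rowSums(okUna) == length(unaCols)
  panel[keep, ]
}

#' Intersect surviving variants with linkage hot spots
#'
#' Keeps variants falling inside any hot-spot interval (inclusive 1-based
#' endpoints) and annotates each with the containing hot spot's maximum
#' LOD. With \code{intersect = FALSE} the unintersected set is returned
#' (maxLod \code{NA}), so the segregation-only candidate list remains
#' reportable alongside the linkage-restricted one.
#'
#' @param panel a \linkS4class{GenotypePanel} of segregation survivors.
#' @param hotspots \code{GRanges} from [detectHotspots()].
#' @param intersect apply the hot-spot restriction (default TRUE).
#' @return a candidate table: data.frame with columns \code{gene},
#'   \code{chrom}, \code{pos}, \code{ref}, \code{alt}, \code{type},
#'   \code{hgvsC}, \code{hgvsP}, \code{popFreq}, \code{knownId},
#'   \code{maxLod}, sorted by (chrom, pos).
#' @export
hotspotIntersect <- function(panel, hotspots, intersect = TRUE) {
  gr <- rowRanges(panel)
  maxLod <- rep(NA_real_, length(gr))
  if (intersect) {
    if (is.null(hotspots) || length(hotspots) == 0) {
      .warnf("empty hot-spot set: no variants survive intersection")
      keep <- logical(length(gr))
    } else {
      # seqlevel sets may legitimately differ (hot spots cover few
      # chromosomes); overlap on shared ones without the Seqinfo warning
      ov <- suppressWarnings(findOverlaps(gr, hotspots))
      keep <- logical(length(gr))
      keep[S4Vectors::queryHits(ov)] <- TRUE
      lodHit <- tapply(hotspots$maxLod[S4Vectors::subjectHits(ov)],
                       S4Vectors::queryHits(ov), max)
      maxLod[as.integer(names(lodHit))] <- as.numeric(lodHit)
    }
  } else {
    keep <- rep(TRUE, length(gr))
  }
  sub <- panel[keep, ]
  rd <- rowData(sub)
  grs <- rowRanges(sub)
  getcol <- function(col, default) {
    if (col %in% names(rd)) rd[[col]] else rep(default, nrow(sub))
  }
  out <- data.frame(
    gene = getcol("gene", NA_character_),
    chrom = as.character(seqnames(grs)),
    pos = start(grs),
    ref = rd$ref, alt = rd$alt,
    type = getcol("type", NA_character_),
    hgvsC = getcol("hgvsC", NA_character_),
    hgvsP = getcol("hgvsP", NA_character_),
    popFreq = getcol("popFreq", NA_real_),
    knownId = getcol("knownId", NA_character_),
    maxLod = maxLod[keep],
    stringsAsFactors = FALSE)
  out <- out[.genomeOrder(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Render a candidate table in the six-column report layout
#'
#' One row per candidate: gene, chromosome, nucleotide change, amino-acid
#' change, population frequency, known-variant id; missing frequency/id
#' rendered as \code{"-"}.
#'
#' @param candidates data.frame from [hotspotIntersect()].
#' @return character vector of tab-separated lines (header first).
#' @export
renderCandidateTable <- function(candidates) {
  hdr <- paste("Gene", "Chr", "Nucleotide variation", "Amino acid variation",
               "Frequency in 1,000 genome", "dbSNP", sep = "\t")
  if (!nrow(candidates)) return(hdr)
  dash <- function(x) ifelse(is.na(x), "-", as.character(x))
  rows <- paste(dash(candidates$gene), dash(candidates$chrom),
                dash(candidates$hgvsC), dash(candidates$hgvsP),
                dash(candidates$popFreq), dash(candidates$knownId),
                sep = "\t")
  c(hdr, rows)
}

#' Run the full variant filter funnel
#'
#' QC -> known-variant handling -> effect class -> dominant co-segregation
#' -> hot-spot intersection, recording the surviving count at each stage.
#' The funnel is the scientific narrative of the analysis (tens of
#' thousands of variants in, a handful of candidates out), so the counts
#' are returned for audit.
#'
#' @param panel annotated WES \linkS4class{GenotypePanel}.
#' @param ped \linkS4class{FamPedigree}.
#' @param hotspots \code{GRanges} from [detectHotspots()] (or NULL with
#'   \code{intersect = FALSE}).
#' @param minDepth,minGq,autosomesOnly,strict passed to [qcFilter()].
#' @param knownMode,maxFreq passed to [knownFilter()].
#' @param intersect passed to [hotspotIntersect()].
#' @return list with \code{candidates} (data.frame) and \code{counts}
#'   (named integer vector of survivors per stage).
#' @export
snvFunnel <- function(panel, ped, hotspots = NULL, minDepth = 10,
                      minGq = 30, autosomesOnly = FALSE, strict = FALSE,
                      knownMode = "annotate_only", maxFreq = 0.01,
                      intersect = TRUE) {
  counts <- c(input = nrow(panel))
  p <- qcFilter(panel, ped, minDepth, minGq, autosomesOnly, strict)
  counts["qc"] <- nrow(p)
  p <- knownFilter(p, knownMode, maxFreq)
  counts["known"] <- nrow(p)
  p <- effectFilter(p)
  counts["effect"] <- nrow(p)
  p <- segregationFilter(p, ped)
  counts["segregation"] <- nrow(p)
  candidates <- hotspotIntersect(p, hotspots, intersect = intersect)
  counts["hotspot"] <- nrow(candidates)
  stopifnot(all(diff(counts) <= 0))  # funnel monotonicity
  list(candidates = candidates, counts = counts)
}
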