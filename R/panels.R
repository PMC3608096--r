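#' @include AllClasses.R
NULL

#' Construct a genotype panel
#'
#' @param dosage integer matrix of alt-allele dosages (markers x subjects;
#'   values 0/1/2 or \code{NA}); column names are subject ids.
#' @param chrom,pos marker coordinates (1-based).
#' @param ref,alt reference / alternate alleles.
#' @param markerId marker names; defaults to \code{chrom:pos_ref/alt}.
#' @param platform \code{"wes"} or \code{"array"}.
#' @param altFreq optional population/founder alt-allele frequencies.
#' @param depth,gq optional per-genotype read depth and phred-scaled
#'   genotype quality matrices (same shape as \code{dosage}); required by
#'   the WES QC filters.
#' @param rowData optional extra per-marker annotation (a
#'   \code{\link[S4Vectors]{DataFrame}} or data.frame), e.g. \code{gene},
#'   \code{effect}, \code{hgvsC}, \code{hgvsP}, \code{knownId},
#'   \code{popFreq}, \code{type}.
#' @return A \linkS4class{GenotypePanel}, rows sorted by (chrom, pos).
#' @export
GenotypePanel <- function(dosage, chrom, pos, ref, alt, markerId = NULL,
                          platform = c("wes", "array"), altFreq = NA_real_,
                          depth = NULL, gq = NULL, rowData = NULL) {
  platform <- match.arg(platform)
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  n <- nrow(dosage)
  if (is.null(markerId))
    markerId <- sprintf("%s:%d_%s/%s", chrom, as.integer(pos), ref, alt)
  rd <- DataFrame(markerId = as.character(markerId),
                  ref = as.character(ref), alt = as.character(alt),
                  altFreq = rep_len(as.numeric(altFreq), n))
  if (!is.null(rowData)) {
    extra <- as(rowData, "DataFrame")
    for (col in setdiff(names(extra), names(rd))) rd[[col]] <- extra[[col]]
  }
  if (!"type" %in% names(rd))
    rd$type <- ifelse(nchar(rd$ref) == 1 & nchar(rd$alt) == 1, "snv", "indel")
  gr <- GRanges(as.character(chrom),
                IRanges(as.integer(pos), width = 1L))
  names(gr) <- rd$markerId
  assays <- list(dosage = dosage)
  if (!is.null(depth)) {
    depth <- as.matrix(depth); storage.mode(depth) <- "numeric"
    assays$depth <- depth
  }
  if (!is.null(gq)) {
    gq <- as.matrix(gq); storage.mode(gq) <- "numeric"
    assays$gq <- gq
  }
  mcols(gr) <- rd
  se <- SummarizedExperiment(assays = assays, rowRanges = gr)
  colnames(se) <- colnames(dosage)
  ord <- .genomeOrder(as.character(seqnames(gr)), start(gr))
  new("GenotypePanel", se[ord, ], platform = platform)
}

#' Genotype panel accessors
#'
#' @param panel a \linkS4class{GenotypePanel}.
#' @return \code{dosages}: the integer dosage matrix; \code{platform}: the
#'   platform string; \code{markerInfo}: per-marker annotation
#'   (\code{rowData} plus \code{chrom}/\code{pos}); \code{subjects}: subject
#'   ids.
#' @export
dosages <- function(panel) assay(panel, "dosage")

#' @rdname dosages
#' @export
platform <- function(panel) panel@platform

#' @rdname dosages
#' @export
subjects <- function(panel) colnames(panel)

#' @rdname dosages
#' @export
markerInfo <- function(panel) {
  rd <- rowData(panel)
  gr <- rowRanges(panel)
  cbind(DataFrame(chrom = as.character(seqnames(gr)), pos = start(gr)), rd)
}

setMethod("show", "GenotypePanel", function(object) {
  cat(sprintf("GenotypePanel (%s): %d markers x %d subjects\n",
              object@platform, nrow(object), ncol(object)))
  d <- assay(object, "dosage")
  cat(sprintf("  missing dosages: %.2f%%  assays: %s\n",
              100 * mean(is.na(d)), paste(names(assays(object)),
                                          collapse = ", ")))
  callNextMethod()
})

#' Estimate marker allele frequencies from genotyped founders
#'
#' Frequencies enter the pedigree likelihood only through founder
#' Hardy-Weinberg priors; when all founders are genotyped those priors
#' cancel from the LOD ratio, so the estimate mainly matters for markers
#' with ungenotyped founders. Markers with fewer than \code{minFounders}
#' genotyped founders fall back to \code{default}. Estimates are clamped
#' away from 0 and 1 so likelihoods stay defined.
#'
#' @param panel a \linkS4class{GenotypePanel}.
#' @param ped the \linkS4class{FamPedigree} identifying founders.
#' @param minFounders minimum genotyped founders for estimation.
#' @param default frequency used when too few founders are genotyped.
#' @param clamp bounds applied to the estimate.
#' @return numeric vector of alt-allele frequencies, one per marker.
#' @export
estimateAlleleFreqs <- function(panel, ped, minFounders = 2,
                                default = 0.5, clamp = c(1e-3, 1 - 1e-3)) {
  fo <- intersect(founders(ped), colnames(panel))
  dos <- assay(panel, "dosage")
  if (length(fo)) {
    fd <- dos[, fo, drop = FALSE]
    ngeno <- rowSums(!is.na(fd))
    f <- rowSums(fd, na.rm = TRUE) / (2 * pmax(ngeno, 1L))
    f[ngeno < minFounders] <- default
  } else {
    f <- rep(default, nrow(dos))
  }
  pmin(pmax(f, clamp[1]), clamp[2])
}

#' Match two genotype panels on common subjects and markers
#'
#' Restricts both panels to the intersection of subject ids and of
#' (chrom, pos, ref, alt) marker keys, identically ordered, so that e.g. an
#' exome-derived panel and a SNP-array panel can be analysed over the same
#' support. Markers whose ref/alt are swapped between the panels are
#' reconciled by recoding the second panel's dosages as \eqn{2 - d} (and its
#' alt frequency as \eqn{1 - f}) before matching; recoded markers are
#' flagged in \code{rowData()$alleleFlipped} and reported via
#' \code{message()}, since an undetected strand flip would silently corrupt
#' dosages.
#'
#' @param a,b \linkS4class{GenotypePanel} objects.
#' @return a list with elements \code{a} and \code{b}: the matched panels.
#' @export
harmonizePanels <- function(a, b) {
  key <- function(p) {
    gr <- rowRanges(p); rd <- rowData(p)
    paste(as.character(seqnames(gr)), start(gr), rd$ref, rd$alt, sep = "|")
  }
  swapKey <- function(p) {
    gr <- rowRanges(p); rd <- rowData(p)
    paste(as.character(seqnames(gr)), start(gr), rd$alt, rd$ref, sep = "|")
  }
  ka <- key(a); kb <- key(b)
  flip <- !(kb %in% ka) & (swapKey(b) %in% ka)
  if (any(flip)) {
    message(sprintf("harmonizePanels: recoding %d allele-swapped marker(s) in second panel",
                    sum(flip)))
    d <- assay(b, "dosage")
    d[flip, ] <- 2L - d[flip, ]
    assay(b, "dosage") <- d
    rd <- rowData(b)
    tmp <- rd$ref[flip]; rd$ref[flip] <- rd$alt[flip]; rd$alt[flip] <- tmp
    rd$altFreq[flip] <- 1 - rd$altFreq[flip]
    rowData(b) <- rd
    kb <- key(b)
  }
  common <- intersect(ka, kb)
  subj <- intersect(colnames(a), colnames(b))
  if (!length(common) || !length(subj))
    .stopf("harmonizePanels: empty overlap (%d common markers, %d common subjects)",
           length(common), length(subj))
  ia <- match(common, ka); ib <- match(common, kb)
  ord <- .genomeOrder(as.character(seqnames(rowRanges(a)))[ia],
                      start(rowRanges(a))[ia])
  outA <- a[ia[ord], subj]
  outB <- b[ib[ord], subj]
  rowData(outA)$alleleFlipped <- FALSE
  rowData(outB)$alleleFlipped <- flip[ib[ord]]
  list(a = outA, b = outB)
}

#' Read / write an array-style genotype matrix TSV
#'
#' Tab-separated with columns \code{marker_id}, \code{chrom}, \code{pos},
#' optionally \code{ref} and \code{alt}, then one dosage column per subject
#' (0/1/2, \code{NA} = missing).
#'
#' @param file path.
#' @param platform platform tag for the resulting panel.
#' @return \code{readGenotypeTsv}: a \linkS4class{GenotypePanel}.
#' @export
readGenotypeTsv <- function(file, platform = "array") {
  df <- read.delim(file, stringsAsFactors = FALSE, check.names = FALSE)
  fixed <- intersect(c("marker_id", "chrom", "pos", "ref", "alt"), names(df))
  subj <- setdiff(names(df), fixed)
  if (!all(c("marker_id", "chrom", "pos") %in% fixed))
    .stopf("'%s' lacks marker_id/chrom/pos columns", file)
  if (!length(subj)) .stopf("'%s' has no subject dosage columns", file)
  dos <- as.matrix(df[, subj, drop = FALSE])
  ref <- if ("ref" %in% fixed) df$ref else "A"
  alt <- if ("alt" %in% fixed) df$alt else "B"
  GenotypePanel(dos, chrom = df$chrom, pos = df$pos, ref = ref, alt = alt,
                markerId = df$marker_id, platform = platform)
}

#' @rdname readGenotypeTsv
#' @param panel a \linkS4class{GenotypePanel} to serialise.
#' @return \code{writeGenotypeTsv}: the file path, invisibly.
#' @export
writeGenotypeTsv <- function(panel, file) {
  gr <- rowRanges(panel); rd <- rowData(panel)
  out <- data.frame(marker_id = rd$markerId,
                    chrom = as.character(seqnames(gr)), pos = start(gr),
                    ref = rd$ref, alt = rd$alt,
                    check.names = FALSE, stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(assay(panel, "dosage")))
  write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read a multi-sample VCF into a genotype panel
#'
#' Parses a VCF v4.x with per-sample GT (and optionally DP/GQ) via
#' \pkg{VariantAnnotation} and returns a WES \linkS4class{GenotypePanel} of
#' biallelic records; multi-allelic records are dropped with a warning.
#' Genotypes are stored as alt-allele dosage (\code{"./."} maps to
#' \code{NA}). An annotation sidecar keyed by (chrom, pos, ref, alt) can be
#' merged into \code{rowData} at read time.
#'
#' @param file path to a VCF (plain text or bgzipped).
#' @param annotation optional path to an annotation TSV
#'   (see [readAnnotationTsv()]) or a data.frame of the same layout.
#' @return A \linkS4class{GenotypePanel} with \code{platform = "wes"}.
#' @export
readVariantVcf <- function(file, annotation = NULL) {
  vcf <- VariantAnnotation::readVcf(file)
  alts <- VariantAnnotation::alt(vcf)
  nalt <- lengths(alts)
  if (any(nalt != 1)) {
    .warnf("dropping %d multi-allelic record(s)", sum(nalt != 1))
    vcf <- vcf[nalt == 1]
    alts <- VariantAnnotation::alt(vcf)
  }
  gr <- SummarizedExperiment::rowRanges(vcf)
  gt <- VariantAnnotation::geno(vcf)$GT
  dos <- matrix(NA_integer_, nrow(gt), ncol(gt),
                dimnames = dimnames(gt))
  code <- gsub("\\|", "/", gt)
  dos[code %in% c("0/0")] <- 0L
  dos[code %in% c("0/1", "1/0")] <- 1L
  dos[code %in% c("1/1")] <- 2L
  g <- VariantAnnotation::geno(vcf)
  depth <- if ("DP" %in% names(g)) g$DP else NULL
  gq <- if ("GQ" %in% names(g)) g$GQ else NULL
  ref <- as.character(VariantAnnotation::ref(vcf))
  alt <- as.character(unlist(alts))
  panel <- GenotypePanel(dos, chrom = as.character(seqnames(gr)),
                         pos = start(gr), ref = ref, alt = alt,
                         platform = "wes", depth = depth, gq = gq)
  if (!is.null(annotation)) panel <- annotatePanel(panel, annotation)
  panel
}

#' Read a variant annotation sidecar
#'
#' Tab-separated with columns \code{chrom}, \code{pos}, \code{ref},
#' \code{alt}, \code{gene}, \code{effect}, \code{hgvs_c}, \code{hgvs_p},
#' \code{known_id}, \code{pop_freq}. \code{"-"} or empty entries become
#' \code{NA}. Annotation (the output of tools such as gene-model
#' annotators) is consumed, never computed, by this package.
#'
#' @param file path (or a data.frame already in this layout).
#' @return data.frame.
#' @export
readAnnotationTsv <- function(file) {
  df <- if (is.data.frame(file)) file
        else read.delim(file, stringsAsFactors = FALSE, na.strings = c("NA", "-", ""))
  need <- c("chrom", "pos", "ref", "alt", "gene", "effect")
  miss <- setdiff(need, names(df))
  if (length(miss))
    .stopf("annotation lacks column(s): %s", paste(miss, collapse = ", "))
  for (col in c("hgvs_c", "hgvs_p", "known_id"))
    if (is.null(df[[col]])) df[[col]] <- NA_character_
  if (is.null(df$pop_freq)) df$pop_freq <- NA_real_
  df
}

#' @rdname readAnnotationTsv
#' @param panel a \linkS4class{GenotypePanel} to annotate.
#' @param annotation annotation TSV path or data.frame.
#' @return \code{annotatePanel}: the panel with \code{gene}, \code{effect},
#'   \code{hgvsC}, \code{hgvsP}, \code{knownId}, \code{popFreq} merged into
#'   \code{rowData} by (chrom, pos, ref, alt).
#' @export
annotatePanel <- function(panel, annotation) {
  ann <- readAnnotationTsv(annotation)
  gr <- rowRanges(panel); rd <- rowData(panel)
  keyP <- paste(as.character(seqnames(gr)), start(gr), rd$ref, rd$alt,
                sep = "|")
  keyA <- paste(ann$chrom, ann$pos, ann$ref, ann$alt, sep = "|")
  i <- match(keyP, keyA)
  rd$gene <- ann$gene[i]
  rd$effect <- ann$effect[i]
  rd$hgvsC <- ann$hgvs_c[i]
  rd$hgvsP <- ann$hgvs_p[i]
  rd$knownId <- ann$known_id[i]
  rd$popFreq <- ann$pop_freq[i]
  rowData(panel) <- rd
  panel
}
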