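#' @include AllClasses.R
NULL

#' Construct a per-exon coverage matrix
#'
#' @param depth numeric matrix (exons x samples) of mean read depth;
#'   column names are sample ids.
#' @param chrom,start,end exon intervals, 1-based inclusive (as held in
#'   \code{GRanges}); use [readExonBed()]/[readDepthTsv()] for file input,
#'   which convert from BED's 0-based half-open convention.
#' @param name unique exon names.
#' @return An \linkS4class{ExonCoverage}, rows sorted by position.
#' @export
ExonCoverage <- function(depth, chrom, start, end, name = NULL) {
  depth <- as.matrix(depth)
  storage.mode(depth) <- "numeric"
  chrom <- rep_len(as.character(chrom), nrow(depth))
  if (is.null(name)) name <- sprintf("%s:%d-%d", chrom, start, end)
  gr <- GRanges(chrom, IRanges(as.integer(start), as.integer(end)))
  names(gr) <- as.character(name)
  se <- SummarizedExperiment(assays = list(depth = depth), rowRanges = gr)
  colnames(se) <- colnames(depth)
  rownames(se) <- name
  ord <- .genomeOrder(as.character(chrom), as.integer(start))
  new("ExonCoverage", se[ord, ])
}

#' Read exon definitions and depth matrices
#'
#' \code{readExonBed} imports a BED3+name exon file (0-based half-open)
#' via \pkg{rtracklayer}, returning 1-based \code{GRanges}.
#' \code{readDepthTsv} reads the per-exon depth matrix TSV written by
#' [emitFixture()] or produced by external coverage tools: columns
#' \code{exon}, \code{chrom}, \code{start}, \code{end} (0-based half-open,
#' matching the BED) and one depth column per sample.
#'
#' @param file path.
#' @return \code{readExonBed}: a named \code{GRanges};
#'   \code{readDepthTsv}: an \linkS4class{ExonCoverage}.
#' @export
readExonBed <- function(file) {
  gr <- rtracklayer::import(file, format = "BED")
  if (!is.null(gr$name)) names(gr) <- gr$name
  gr
}

#' @rdname readExonBed
#' @export
readDepthTsv <- function(file) {
  df <- read.delim(file, stringsAsFactors = FALSE, check.names = FALSE)
  fixed <- c("exon", "chrom", "start", "end")
  if (!all(fixed %in% names(df)))
    .stopf("'%s' lacks exon/chrom/start/end columns", file)
  samples <- setdiff(names(df), fixed)
  depth <- as.matrix(df[, samples, drop = FALSE])
  ExonCoverage(depth, chrom = df$chrom, start = df$start + 1L,
               end = df$end, name = df$exon)
}

#' @rdname readExonBed
#' @param cov an \linkS4class{ExonCoverage} to serialise.
#' @export
writeDepthTsv <- function(cov, file) {
  gr <- rowRanges(cov)
  out <- data.frame(exon = rownames(cov),
                    chrom = as.character(seqnames(gr)),
                    start = start(gr) - 1L, end = end(gr),
                    check.names = FALSE, stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(assay(cov, "depth")))
  write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
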