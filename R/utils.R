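# Internal helpers shared across stages.

#' @noRd
.chromRank <- function(chrom) {
  x <- sub("^chr", "", as.character(chrom), ignore.case = TRUE)
  r <- suppressWarnings(as.integer(x))
  r[toupper(x) == "X"] <- 23L
  r[toupper(x) == "Y"] <- 24L
  r[toupper(x) %in% c("M", "MT")] <- 25L
  r[is.na(r)] <- 26L
  r
}

#' @noRd
.isAutosome <- function(chrom) .chromRank(chrom) <= 22L

#' Order by genomic position (chromosome rank, then base position)
#' @noRd
.genomeOrder <- function(chrom, pos) order(.chromRank(chrom), pos)

#' Run an expression under a local RNG seed, restoring the caller's RNG state.
#' @noRd
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# hg19 autosome lengths, used only to lay out synthetic marker/exon positions.
.AUTOSOME_LENGTHS <- c(
  chr1 = 249250621, chr2 = 243199373, chr3 = 198022430, chr4 = 191154276,
  chr5 = 180915260, chr6 = 171115067, chr7 = 159138663, chr8 = 146364022,
  chr9 = 141213431, chr10 = 135534747, chr11 = 135006516, chr12 = 133851895,
  chr13 = 115169878, chr14 = 107349540, chr15 = 102531392, chr16 = 90354753,
  chr17 = 81195210, chr18 = 78077248, chr19 = 59128983, chr20 = 63025520,
  chr21 = 48129895, chr22 = 51304566)

#' @noRd
.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @noRd
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
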