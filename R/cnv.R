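#' @include coverage.R pedigree.R
NULL

#' Normalise per-exon coverage to log2 ratios
#'
#' Corrects library size (per-sample factor = total exon depth scaled to
#' the across-sample mean), forms a family-internal baseline per exon, and
#' returns \eqn{\log_2(\mathrm{depth}/\mathrm{baseline})}. The ratio for
#' each sample is taken against the \emph{leave-one-out} median of the
#' other samples' size-normalised depths: a sample never sits in its own
#' control baseline, so a copy-number event shared by up to half the
#' family (exactly the situation a co-segregating event creates) keeps
#' its full signal instead of dragging the baseline toward itself. The
#' all-sample median is reported as \code{rowData()$baseline} and used
#' for masking and depth binning. Exons whose baseline is below
#' \code{minBaselineDepth} (including zero) are masked rather than
#' producing unstable or infinite ratios; a zero depth at an unmasked
#' exon is floored at half a read before the log.
#'
#' @param cov an \linkS4class{ExonCoverage} with >= 2 samples.
#' @param minBaselineDepth minimum baseline depth (reads) for an exon to be
#'   callable.
#' @return A \code{RangedSummarizedExperiment} with assay \code{log2Ratio}
#'   (NA where masked) and \code{rowData} columns \code{baseline} and
#'   \code{masked}, suitable for [callExonCnv()].
#' @export
normalizeCoverage <- function(cov, minBaselineDepth = 10) {
  d <- assay(cov, "depth")
  if (ncol(d) < 2) .stopf("normalization requires >= 2 samples")
  tot <- colSums(d)
  if (any(tot == 0)) .stopf("sample(s) with zero total depth")
  sizeFactor <- tot / mean(tot)
  norm <- sweep(d, 2, sizeFactor, "/")
  # row-sorted depths give both the all-sample median and each sample's
  # leave-one-out median as order statistics
  srt <- t(apply(norm, 1, sort))
  ns <- ncol(norm)
  baseline <- if (ns %% 2 == 0) (srt[, ns / 2] + srt[, ns / 2 + 1]) / 2
              else srt[, (ns + 1) / 2]
  masked <- baseline < minBaselineDepth
  if (ns %% 2 == 0) {
    k <- ns / 2
    loo <- ifelse(norm <= srt[, k], srt[, k + 1], srt[, k])
  } else {
    m <- (ns - 1) / 2
    loo <- ifelse(norm <= srt[, m], (srt[, m + 1] + srt[, m + 2]) / 2,
                  ifelse(norm >= srt[, m + 2],
                         (srt[, m] + srt[, m + 1]) / 2,
                         (srt[, m] + srt[, m + 2]) / 2))
  }
  dimnames(loo) <- dimnames(norm)
  num <- pmax(norm, 0.5)  # floor zero depths at half a read
  den <- pmax(loo, 0.5)
  lr <- log2(num / den)
  lr[masked, ] <- NA_real_
  se <- SummarizedExperiment(
    assays = list(log2Ratio = lr, depth = d),
    rowRanges = rowRanges(cov))
  colnames(se) <- colnames(cov)
  rownames(se) <- rownames(cov)
  rowData(se)$baseline <- baseline
  rowData(se)$masked <- masked
  se
}

#' Call per-exon copy-number states from log2 ratios
#'
#' Exons are grouped into \code{nBins} equal-occupancy bins of baseline
#' depth (depth determines the sampling noise of a ratio, so the null
#' spread must be estimated per depth stratum; bins holding fewer than 10
#' exons are merged with a neighbour). Within each bin the null centre and
#' spread are estimated robustly (median; MAD x 1.4826), each ratio is
#' converted to a z score and a two-sided normal p-value, and states are
#' assigned: gain iff \eqn{p < \alpha} and ratio > 0, loss iff
#' \eqn{p < \alpha} and ratio < 0, otherwise normal (strict inequality:
#' a ratio exactly at the \eqn{\alpha} boundary stays normal).
#'
#' @param ratios output of [normalizeCoverage()].
#' @param alpha per-exon significance level for state calls.
#' @param nBins number of equal-occupancy baseline-depth bins.
#' @return A \linkS4class{CnvCalls}.
#' @export
callExonCnv <- function(ratios, alpha = 0.05, nBins = 20) {
  lr <- assay(ratios, "log2Ratio")
  masked <- rowData(ratios)$masked
  baseline <- rowData(ratios)$baseline
  n <- nrow(lr)
  pv <- matrix(NA_real_, n, ncol(lr), dimnames = dimnames(lr))
  state <- matrix(NA_character_, n, ncol(lr), dimnames = dimnames(lr))
  idx <- which(!masked)
  if (length(idx)) {
    ord <- idx[order(baseline[idx])]
    nb <- max(1L, min(as.integer(nBins), length(ord)))
    bin <- rep(seq_len(nb), each = ceiling(length(ord) / nb),
               length.out = length(ord))
    # merge undersized bins with their neighbour
    repeat {
      tab <- table(bin)
      small <- names(tab)[tab < 10]
      if (!length(small) || length(tab) == 1) break
      b <- as.integer(small[1])
      levs <- sort(unique(bin))
      nb2 <- if (b == max(levs)) levs[which(levs == b) - 1] else
        levs[which(levs == b) + 1]
      bin[bin == b] <- nb2
    }
    for (b in unique(bin)) {
      rows <- ord[bin == b]
      vals <- lr[rows, , drop = FALSE]
      med <- median(vals, na.rm = TRUE)
      scale <- max(mad(vals, center = med, na.rm = TRUE), 1e-8)
      z <- (vals - med) / scale
      p <- 2 * pnorm(-abs(z))
      st <- matrix("normal", nrow(vals), ncol(vals))
      st[p < alpha & vals > 0] <- "gain"
      st[p < alpha & vals < 0] <- "loss"
      pv[rows, ] <- p
      state[rows, ] <- st
    }
  }
  se <- SummarizedExperiment(
    assays = list(log2Ratio = lr, pValue = pv, state = state),
    rowRanges = rowRanges(ratios))
  colnames(se) <- colnames(ratios)
  rownames(se) <- rownames(ratios)
  rowData(se)$baseline <- baseline
  rowData(se)$masked <- masked
  new("CnvCalls", se, alpha = alpha)
}

#' Tabulate CNV states against affection for one exon
#'
#' Builds the 3x2 contingency table (rows gain/normal/loss, columns
#' affection groups) of per-sample CNV states at one exon. Groups default
#' to affected/unaffected from the pedigree; an arbitrary two-group
#' partition of the samples can be supplied instead (the study used
#' alternative partitions, defined by the segregation of known
#' copy-variable genes, to validate the method). Samples with unknown
#' affection, or with a masked/missing call, are excluded with a warning.
#'
#' @param calls a \linkS4class{CnvCalls}.
#' @param exon exon name or row index.
#' @param ped a \linkS4class{FamPedigree} (used when \code{groups} is NULL).
#' @param groups optional named character vector mapping sample id to group
#'   label (exactly 2 distinct labels).
#' @return 3x2 integer matrix with row names gain/normal/loss.
#' @export
cosegContingency <- function(calls, exon, ped = NULL, groups = NULL) {
  if (is.null(groups)) {
    if (is.null(ped)) .stopf("either ped or groups must be supplied")
    aff <- affectionOf(ped)
    samp <- intersect(colnames(calls), names(aff))
    unk <- samp[aff[samp] == "unknown"]
    if (length(unk))
      .warnf("excluding sample(s) with unknown affection: %s",
             paste(unk, collapse = ", "))
    samp <- setdiff(samp, unk)
    groups <- setNames(aff[samp], samp)
    glev <- c("affected", "unaffected")
  } else {
    glev <- unique(groups)
    if (length(glev) != 2) .stopf("groups must define exactly 2 labels")
    samp <- names(groups)
  }
  st <- assay(calls, "state")[exon, samp]
  if (anyNA(st)) {
    .warnf("excluding sample(s) with masked/missing call: %s",
           paste(samp[is.na(st)], collapse = ", "))
    samp <- samp[!is.na(st)]
    st <- st[samp]
  }
  tab <- table(factor(st, levels = c("gain", "normal", "loss")),
               factor(groups[samp], levels = glev))
  m <- matrix(as.integer(tab), 3, 2,
              dimnames = list(c("gain", "normal", "loss"), glev))
  m
}

#' Exact conditional test for a 3x2 contingency table
#'
#' Fisher's exact test with both margins fixed, computed by full
#' enumeration of the table space (tiny at family sample sizes): the
#' p-value is the total conditional hypergeometric probability of all 3x2
#' tables with the observed margins whose probability does not exceed the
#' observed table's (probability ordering; ties included up to a relative
#' tolerance of 1e-12). An empty table yields p = 1 by convention.
#'
#' @param tab non-negative integer matrix with 3 rows and 2 columns
#'   (rows: CNV states; columns: affection groups).
#' @return the exact p-value.
#' @examples
#' # gains in all 4 affected, normal in all 4 unaffected
#' tab <- rbind(gain = c(4, 0), normal = c(0, 4), loss = c(0, 0))
#' fisherExact3x2(tab)   # 2/70
#' @export
fisherExact3x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(3, 2)) || any(tab < 0) ||
      any(tab != round(tab)) || anyNA(tab))
    .stopf("tab must be a non-negative integer 3x2 matrix")
  N <- sum(tab)
  if (N == 0) return(1)
  r <- rowSums(tab); c1 <- sum(tab[, 1])
  grid <- expand.grid(a1 = 0:min(r[1], c1), a2 = 0:min(r[2], c1))
  grid$a3 <- c1 - grid$a1 - grid$a2
  grid <- grid[grid$a3 >= 0 & grid$a3 <= r[3], ]
  logp <- lchoose(r[1], grid$a1) + lchoose(r[2], grid$a2) +
    lchoose(r[3], grid$a3) - lchoose(N, c1)
  obs <- lchoose(r[1], tab[1, 1]) + lchoose(r[2], tab[2, 1]) +
    lchoose(r[3], tab[3, 1]) - lchoose(N, c1)
  min(1, sum(exp(logp[logp <= obs + log1p(1e-12)])))
}

#' Scan all exons for CNV co-segregation with affection
#'
#' Applies [cosegContingency()] and [fisherExact3x2()] to every unmasked
#' exon and returns the per-exon p-value track (identical tables are
#' computed once). This is the family-level test of whether abnormal copy
#' number states are distributed unevenly between affected and unaffected
#' members; a fully co-segregating event in a 4-vs-4 family attains the
#' design minimum p = 2/70.
#'
#' @param calls a \linkS4class{CnvCalls}.
#' @param ped a \linkS4class{FamPedigree}.
#' @param alpha significance level defining the reported significant set.
#' @param groups optional two-group sample partition overriding affection
#'   (see [cosegContingency()]).
#' @return \code{GRanges} over unmasked exons, sorted by position, with
#'   \code{mcols} \code{exon}, \code{p} and \code{minusLog10P};
#'   \code{metadata()$significant} holds the exon names with
#'   \eqn{p < \alpha}.
#' @export
cnvCosegScan <- function(calls, ped, alpha = 0.05, groups = NULL) {
  if (is.null(groups)) {
    aff <- affectionOf(ped)
    samp <- intersect(colnames(calls), names(aff))
    samp <- samp[aff[samp] != "unknown"]
    groups <- setNames(aff[samp], samp)
  }
  glev <- unique(groups)
  samp <- names(groups)
  st <- assay(calls, "state")[, samp, drop = FALSE]
  unmasked <- which(!rowData(calls)$masked)
  st <- st[unmasked, , drop = FALSE]
  counts <- sapply(glev, function(g) {
    cols <- samp[groups == g]
    sub <- st[, cols, drop = FALSE]
    cbind(gain = rowSums(sub == "gain", na.rm = TRUE),
          normal = rowSums(sub == "normal", na.rm = TRUE),
          loss = rowSums(sub == "loss", na.rm = TRUE))
  }, simplify = FALSE)
  key <- paste(counts[[1]][, 1], counts[[1]][, 2], counts[[1]][, 3],
               counts[[2]][, 1], counts[[2]][, 2], counts[[2]][, 3])
  uk <- unique(key)
  pOf <- vapply(uk, function(k) {
    v <- as.integer(strsplit(k, " ")[[1]])
    fisherExact3x2(cbind(v[1:3], v[4:6]))
  }, numeric(1))
  p <- unname(pOf[match(key, uk)])
  out <- rowRanges(calls)[unmasked]
  mcols(out) <- DataFrame(exon = rownames(calls)[unmasked], p = p,
                          minusLog10P = -log10(p))
  names(out) <- NULL
  ord <- .genomeOrder(as.character(seqnames(out)), start(out))
  out <- out[ord]
  metadata(out)$significant <- out$exon[out$p < alpha]
  metadata(out)$alpha <- alpha
  out
}
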