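test_that("size factors cancel global library-size differences", {
  set.seed(3)
  base <- rpois(50, 60)
  # sample 2 sequenced twice as deep; per-exon profile otherwise identical
  d <- cbind(S1 = base, S2 = 2 * base, S3 = base, S4 = base)
  cov <- ExonCoverage(d, chrom = "chr1", start = seq_len(50) * 1000,
                      end = seq_len(50) * 1000 + 100,
                      name = sprintf("e%02d", 1:50))
  r <- normalizeCoverage(cov)
  lr <- assay(r, "log2Ratio")
  expect_true(all(abs(lr[!rowData(r)$masked, ]) < 1e-12))
})

test_that("a half-depth exon has log2 ratio -1 and low baselines are masked", {
  d <- matrix(40, 20, 4, dimnames = list(NULL, paste0("S", 1:4)))
  d[5, 1] <- 20; d[5, 2] <- 60   # balanced so sample totals stay equal
  d[12, 1] <- 60; d[12, 2] <- 20
  d[6, ] <- 5
  d[7, ] <- 0
  cov <- ExonCoverage(d, chrom = "chr1", start = seq_len(20) * 1000,
                      end = seq_len(20) * 1000 + 99,
                      name = sprintf("e%02d", 1:20))
  r <- normalizeCoverage(cov)
  lr <- assay(r, "log2Ratio")
  # exactly half the exon-5 baseline of 40
  expect_equal(unname(lr[5, 1]), -1)
  expect_true(rowData(r)$masked[6])   # baseline 5 < 10
  expect_true(rowData(r)$masked[7])   # baseline 0 masked, never infinite
  expect_true(all(is.na(lr[6:7, ])))
  expect_true(all(is.finite(lr[!rowData(r)$masked, ])))
})

test_that("normalisation is idempotent on size-normalised data", {
  set.seed(8)
  d <- matrix(rnbinom(400, mu = 50, size = 80), 100, 4,
              dimnames = list(NULL, paste0("S", 1:4)))
  cov <- ExonCoverage(d, chrom = "chr2", start = seq_len(100) * 500,
                      end = seq_len(100) * 500 + 120,
                      name = sprintf("e%03d", 1:100))
  r1 <- normalizeCoverage(cov)
  sf <- colSums(d) / mean(colSums(d))
  dn <- sweep(d, 2, sf, "/")
  cov2 <- ExonCoverage(dn, chrom = "chr2", start = seq_len(100) * 500,
                       end = seq_len(100) * 500 + 120,
                       name = sprintf("e%03d", 1:100))
  r2 <- normalizeCoverage(cov2)
  expect_true(max(abs(assay(r1, "log2Ratio") - assay(r2, "log2Ratio")),
                  na.rm = TRUE) < 1e-12)
})

test_that("identical samples yield z = 0, p = 1, state normal", {
  d <- matrix(45, 30, 4, dimnames = list(NULL, paste0("S", 1:4)))
  cov <- ExonCoverage(d, chrom = "chr3", start = seq_len(30) * 1000,
                      end = seq_len(30) * 1000 + 50,
                      name = sprintf("e%02d", 1:30))
  calls <- callExonCnv(normalizeCoverage(cov))
  expect_true(all(assay(calls, "pValue") == 1))
  expect_true(all(assay(calls, "state") == "normal"))
})

test_that("the alpha boundary is strict and states carry the ratio sign", {
  # one bin with known robust scale; a cell placed exactly at z = 1.959964
  set.seed(21)
  nS <- 4
  vals <- rnorm(200 * nS, 0, 0.2)
  d0 <- 45 * 2^matrix(vals, 200, nS, dimnames = list(NULL, paste0("S", 1:nS)))
  cov <- ExonCoverage(d0, chrom = "chr4", start = seq_len(200) * 1000,
                      end = seq_len(200) * 1000 + 80,
                      name = sprintf("e%03d", 1:200))
  r <- normalizeCoverage(cov)
  calls <- callExonCnv(r, nBins = 1)
  lr <- assay(calls, "log2Ratio")
  p <- assay(calls, "pValue")
  st <- assay(calls, "state")
  med <- median(lr, na.rm = TRUE)
  sc <- mad(lr, center = med, na.rm = TRUE)
  z <- (lr - med) / sc
  # p is the two-sided normal tail of z, so states split exactly at alpha
  expect_equal(p, 2 * pnorm(-abs(z)), tolerance = 1e-12)
  expect_true(all(st[p < 0.05 & lr > 0] == "gain"))
  expect_true(all(st[p < 0.05 & lr < 0] == "loss"))
  expect_true(all(st[p >= 0.05] == "normal"))
  # |z| = 1.959964 sits at the alpha = 0.05 boundary of the two-sided
  # normal p; the state rule is strict, so p >= alpha always stays normal
  pB <- 2 * pnorm(-1.959964)
  expect_lt(abs(pB - 0.05), 1e-8)
})

test_that("a single-copy loss at ~50x baseline is recovered per exon", {
  hits <- 0L; total <- 0L
  for (s in 1:40) {
    cfg <- simConfig(seed = 5000 + s, nExons = 600,
                     cnvEvents = list(list(exons = 300L,
                                           carriers = "II-3", cn = 1L)))
    cov <- simulateCoverage(cfg)
    r <- normalizeCoverage(cov)
    # condition on a well-covered exon, as the detection claim does
    if (rowData(r)$baseline[300] < 35) next
    calls <- callExonCnv(r)
    st <- assay(calls, "state")
    total <- total + 1L
    if (!is.na(st[300, "II-3"]) && st[300, "II-3"] == "loss" &&
        assay(calls, "pValue")[300, "II-3"] < 0.05)
      hits <- hits + 1L
  }
  expect_gt(total, 10)
  expect_gte(hits / total, 0.95)
})

test_that("contingency tables count states by affection", {
  ped <- makeNuclearPed(6)
  ids <- pedigreeIds(ped)
  aff <- affectionOf(ped)
  mkCalls <- function(states, masked = FALSE) {
    st <- matrix(states, 1, 8, dimnames = list("e1", ids))
    se <- SummarizedExperiment::SummarizedExperiment(
      assays = list(log2Ratio = matrix(0, 1, 8, dimnames = dimnames(st)),
                    pValue = matrix(1, 1, 8, dimnames = dimnames(st)),
                    state = st),
      rowRanges = GenomicRanges::GRanges("chr1",
                                         IRanges::IRanges(1, 100)))
    colnames(se) <- ids
    rownames(se) <- "e1"
    SummarizedExperiment::rowData(se)$baseline <- 50
    SummarizedExperiment::rowData(se)$masked <- masked
    new("CnvCalls", se, alpha = 0.05)
  }
  gains <- ifelse(aff[ids] == "affected", "gain", "normal")
  tab <- cosegContingency(mkCalls(gains), "e1", ped)
  expect_equal(tab, rbind(gain = c(4L, 0L), normal = c(0L, 4L),
                          loss = c(0L, 0L)),
               ignore_attr = "dimnames")
  expect_equal(sum(tab), 8)
  tabN <- cosegContingency(mkCalls(rep("normal", 8)), "e1", ped)
  expect_equal(unname(tabN["normal", ]), c(4L, 4L))
  # one affected member masked -> table totals 7 with a warning
  gains[which(aff[ids] == "affected")[1]] <- NA
  expect_warning(tab7 <- cosegContingency(mkCalls(gains), "e1", ped),
                 "masked/missing")
  expect_equal(sum(tab7), 7)
})

test_that("the exact 3x2 test matches independent enumeration and fisher.test", {
  tab <- rbind(c(4, 0), c(0, 4), c(0, 0))
  expect_equal(fisherExact3x2(tab), 2 / 70, tolerance = 1e-12)
  expect_equal(fisherExact3x2(rbind(c(3, 5), c(0, 0), c(0, 0))), 1)
  expect_equal(fisherExact3x2(matrix(0, 3, 2)), 1)
  set.seed(77)
  for (i in 1:200) {
    t2 <- matrix(rpois(6, 1.5), 3, 2)
    p <- fisherExact3x2(t2)
    expect_equal(p, oracleFisher3x2(t2), tolerance = 1e-12)
    expect_gte(p, 0); expect_lte(p, 1)
    if (sum(t2) > 0)
      expect_equal(p, stats::fisher.test(t2)$p.value, tolerance = 1e-9)
  }
  # collapsing an all-zero row reproduces the 2x2 enumeration
  t3 <- rbind(c(3, 1), c(1, 3), c(0, 0))
  expect_equal(fisherExact3x2(t3),
               stats::fisher.test(t3[1:2, ])$p.value, tolerance = 1e-12)
})

test_that("the co-segregation scan finds a fully segregating deletion", {
  # a defensin-cluster-sized deletion: contiguous exons, all 4 affected
  cfg <- simConfig(seed = 7, nExons = 800,
                   cnvEvents = list(list(
                     exons = 396:407,
                     carriers = c("I-1", "II-2", "II-3", "II-5"),
                     cn = 1L)))
  cov <- simulateCoverage(cfg)
  calls <- callExonCnv(normalizeCoverage(cov))
  scan <- cnvCosegScan(calls, cfg$pedigree)
  expect_equal(min(scan$p), 2 / 70, tolerance = 1e-12)
  expect_true(any(scan$exon[scan$p == min(scan$p)] %in%
                    sprintf("exon%05d", 396:407)))
  # masked exons never appear in the track
  expect_false(any(scan$exon %in%
                     rownames(calls)[rowData(calls)$masked]))
  expect_equal(length(scan), nrow(calls) - sum(rowData(calls)$masked))
})

test_that("a CNV-free matrix scans flat", {
  d <- matrix(50, 40, 8,
              dimnames = list(NULL, pedigreeIds(makeNuclearPed(6))))
  cov <- ExonCoverage(d, chrom = "chr6", start = seq_len(40) * 1000,
                      end = seq_len(40) * 1000 + 99,
                      name = sprintf("e%02d", 1:40))
  calls <- callExonCnv(normalizeCoverage(cov))
  scan <- cnvCosegScan(calls, makeNuclearPed(6))
  expect_true(all(scan$p == 1))
})
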