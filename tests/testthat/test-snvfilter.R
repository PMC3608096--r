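# A small 4-member family and hand-built panels exercise each filter rule.

snvPed <- makeNuclearPed(2)          # F affected, M unaffected, C1 aff, C2 unaff
snvIds <- pedigreeIds(snvPed)
segDos <- function(affCarry = 1L, unaffCarry = 0L) {
  matrix(c(affCarry, unaffCarry, affCarry, unaffCarry), 1, 4,
         dimnames = list(NULL, snvIds))
}

test_that("QC keeps a variant only when every sequenced member passes", {
  dos <- segDos()
  mk <- function(depth, gq) {
    p <- makeVariantPanel(snvPed, dos, "chr1", 100)
    SummarizedExperiment::assay(p, "depth")[1, 2] <- depth
    SummarizedExperiment::assay(p, "gq")[1, 2] <- gq
    p
  }
  expect_equal(nrow(qcFilter(mk(50, 99), snvPed)), 1)
  expect_equal(nrow(qcFilter(mk(9, 99), snvPed)), 0)
  expect_equal(nrow(qcFilter(mk(10, 99), snvPed)), 1)   # boundary kept
  expect_equal(nrow(qcFilter(mk(10, 99), snvPed, strict = TRUE)), 0)
  expect_equal(nrow(qcFilter(mk(50, 29), snvPed)), 0)
  # missing genotype fails QC
  p <- mk(50, 99)
  SummarizedExperiment::assay(p, "dosage")[1, 3] <- NA
  expect_equal(nrow(qcFilter(p, snvPed)), 0)
  # chrX dropped only with autosomesOnly
  px <- makeVariantPanel(snvPed, dos, "chrX", 100)
  expect_equal(nrow(qcFilter(px, snvPed)), 1)
  expect_equal(nrow(qcFilter(px, snvPed, autosomesOnly = TRUE)), 0)
  # monotonicity: raising thresholds never grows the surviving set
  set.seed(31)
  big <- makeVariantPanel(
    snvPed, matrix(1L, 50, 4, dimnames = list(NULL, snvIds)),
    chrom = "chr2", pos = seq_len(50) * 100,
    depth = sample(5:60, 200, replace = TRUE),
    gq = sample(10:99, 200, replace = TRUE))
  k10 <- rowData(qcFilter(big, snvPed, minDepth = 10))$markerId
  k20 <- rowData(qcFilter(big, snvPed, minDepth = 20))$markerId
  g50 <- rowData(qcFilter(big, snvPed, minGq = 50))$markerId
  expect_true(all(k20 %in% k10))
  expect_true(all(g50 %in% k10))
})

test_that("known-variant handling annotates by default and drops on demand", {
  mk <- function(knownId, popFreq)
    makeVariantPanel(snvPed, segDos(), "chr3", 500, knownId = knownId,
                     popFreq = popFreq)
  novel <- mk(NA, NA)
  common <- mk("rs3732765", 0.23)
  idOnly <- mk("rs123", NA)
  expect_equal(nrow(knownFilter(novel)), 1)
  expect_equal(nrow(knownFilter(novel, "drop_known")), 1)
  expect_equal(nrow(knownFilter(common)), 1)
  expect_equal(nrow(knownFilter(common, "drop_known", maxFreq = 0.01)), 0)
  expect_equal(nrow(knownFilter(idOnly, "drop_known")), 0)  # id suffices
})

test_that("only amino-acid-changing effects survive the effect filter", {
  for (eff in c("nonsynonymous", "stopgain", "frameshift", "splicing"))
    expect_equal(nrow(effectFilter(
      makeVariantPanel(snvPed, segDos(), "chr1", 9, effect = eff))), 1,
      label = eff)
  for (eff in c("synonymous", "other"))
    expect_equal(nrow(effectFilter(
      makeVariantPanel(snvPed, segDos(), "chr1", 9, effect = eff))), 0,
      label = eff)
  expect_warning(
    n <- nrow(effectFilter(makeVariantPanel(snvPed, segDos(), "chr1", 9,
                                            effect = NA_character_))),
    "missing effect")
  expect_equal(n, 0)
})

test_that("segregation requires carriers in all affected and none unaffected", {
  mk <- function(d) makeVariantPanel(
    snvPed, matrix(d, 1, 4, dimnames = list(NULL, snvIds)), "chr2", 50)
  expect_equal(nrow(segregationFilter(mk(c(1, 0, 1, 0)), snvPed)), 1)
  expect_equal(nrow(segregationFilter(mk(c(2, 0, 1, 0)), snvPed)), 1)  # hom ok
  expect_equal(nrow(segregationFilter(mk(c(1, 1, 1, 0)), snvPed)), 0)  # unaff carrier
  expect_equal(nrow(segregationFilter(mk(c(1, 0, 0, 0)), snvPed)), 0)  # aff non-carrier
  expect_equal(nrow(segregationFilter(mk(c(NA, 0, 1, 0)), snvPed)), 0) # missing drops
})

test_that("the three content filters commute", {
  set.seed(13)
  n <- 120
  dos <- matrix(sample(0:2, n * 4, replace = TRUE), n,
                dimnames = list(NULL, snvIds))
  panel <- makeVariantPanel(
    snvPed, dos, chrom = "chr7", pos = seq_len(n) * 50,
    depth = sample(c(5, 50), n * 4, replace = TRUE, prob = c(0.1, 0.9)),
    gq = sample(c(20, 99), n * 4, replace = TRUE, prob = c(0.1, 0.9)),
    effect = sample(c("nonsynonymous", "synonymous"), n, replace = TRUE))
  runs <- list(
    function(p) segregationFilter(effectFilter(qcFilter(p, snvPed)),
                                  snvPed),
    function(p) qcFilter(effectFilter(segregationFilter(p, snvPed)),
                         snvPed),
    function(p) effectFilter(segregationFilter(qcFilter(p, snvPed),
                                               snvPed)))
  ids <- lapply(runs, function(f) sort(rowData(f(panel))$markerId))
  expect_equal(ids[[1]], ids[[2]])
  expect_equal(ids[[1]], ids[[3]])
})

test_that("hot-spot intersection uses inclusive 1-based boundaries", {
  hs <- GenomicRanges::GRanges("chr5", IRanges::IRanges(1000, 2000))
  S4Vectors::mcols(hs) <- S4Vectors::DataFrame(nMarkers = 2L, maxLod = 1.8,
                                               markerIds = "a,b")
  mk <- function(pos) makeVariantPanel(snvPed, segDos(), "chr5", pos,
                                       gene = "GENE5", hgvsC = "c.1A>G",
                                       hgvsP = "p.K1R")
  inside <- hotspotIntersect(mk(2000), hs)
  expect_equal(nrow(inside), 1)
  expect_equal(inside$maxLod, 1.8)
  expect_equal(nrow(hotspotIntersect(mk(2001), hs)), 0)  # 1 bp past the end
  expect_equal(nrow(hotspotIntersect(mk(999), hs)), 0)
  # intersection off keeps the variant with no LOD annotation
  off <- hotspotIntersect(mk(5), hs, intersect = FALSE)
  expect_equal(nrow(off), 1)
  expect_true(is.na(off$maxLod))
  expect_warning(none <- hotspotIntersect(mk(1500), GenomicRanges::GRanges()),
                 "empty hot-spot")
  expect_equal(nrow(none), 0)
})

test_that("candidate rows render in the six-column layout", {
  p <- makeVariantPanel(snvPed, segDos(), "chr17", 79478000,
                        gene = "ACTG1", hgvsC = "c.T914C",
                        hgvsP = "p.M305T")
  ct <- hotspotIntersect(p, NULL, intersect = FALSE)
  lines <- renderCandidateTable(ct)
  expect_length(lines, 2)
  expect_equal(lines[2], "ACTG1\tchr17\tc.T914C\tp.M305T\t-\t-")
  p2 <- makeVariantPanel(snvPed, segDos(), "chr11", 1000, gene = "OR8G5",
                         hgvsC = "c.G716A", hgvsP = "p.G239E",
                         knownId = "rs2512167", popFreq = 0.5)
  lines2 <- renderCandidateTable(hotspotIntersect(p2, NULL,
                                                  intersect = FALSE))
  expect_match(lines2[2], "0.5\trs2512167$")
  # empty table renders the header only
  expect_length(renderCandidateTable(ct[0, ]), 1)
})
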