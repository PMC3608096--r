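test_that("config validation enforces a dominant-consistent pedigree", {
  # an affected child of two unaffected parents is impossible under full
  # penetrance
  bad <- FamPedigree(id = c("F", "M", "C"), father = c(NA, NA, "F"),
                     mother = c(NA, NA, "M"),
                     sex = c("male", "female", "male"),
                     affection = c("unaffected", "unaffected", "affected"),
                     sequenced = TRUE)
  expect_error(simConfig(pedigree = bad), "affected founder")
  expect_error(simConfig(causalChrom = "chrX"), "autosomal")
  expect_error(simConfig(cnvEvents = list(list(exons = 1, carriers = "nope",
                                               cn = 1L))), "carriers")
  expect_error(simConfig(cnvEvents = list(list(exons = 1,
                                               carriers = "I-1", cn = 2L))),
               "copy number")
})

test_that("an error-free gene drop is Mendelian-clean with carriers = affected", {
  cfg <- simConfig(seed = 11, nMarkers = 400, nIndels = 10, nExons = 50,
                   cnvEvents = list())
  drop <- geneDrop(cfg)
  expect_equal(nrow(mendelianCheck(cfg$pedigree, drop$panel)), 0)
  aff <- affectionOf(cfg$pedigree)
  expect_setequal(drop$truth$carriers, names(aff)[aff == "affected"])
  # causal dosages equal carrier status in the full matrix
  causal <- drop$truth$dosageAll[match(drop$truth$causalId,
                                       drop$truth$markers$markerId), ]
  expect_true(all(causal[drop$truth$carriers] >= 1))
  expect_true(all(causal[setdiff(names(causal),
                                 drop$truth$carriers)] == 0))
  # exactly one causal variant in the truth sidecar
  expect_equal(sum(drop$truth$markers$causal), 1)
})

test_that("founder genotypes follow the configured allele frequency", {
  cfg <- simConfig(seed = 19, nMarkers = 10000, nIndels = 0,
                   freqRange = c(0.3, 0.3), cnvEvents = list())
  drop <- geneDrop(cfg)
  tm <- drop$truth$markers
  plain <- !tm$cluster
  # I-2 is a non-carrier founder: 2 x 10k binomial draws at p = 0.3
  f <- mean(drop$truth$dosageAll[plain, "I-2"]) / 2
  expect_lt(abs(f - 0.3), 0.01)
})

test_that("coverage scales linearly with copy number", {
  loss <- 101:300; gain <- 1001:1200
  cfg <- simConfig(seed = 23, nExons = 2000,
                   cnvEvents = list(
                     list(exons = loss, carriers = "II-2", cn = 1L),
                     list(exons = gain, carriers = "II-2", cn = 3L)))
  cov <- simulateCoverage(cfg)
  d <- assay(cov, "depth")
  others <- setdiff(colnames(d), "II-2")
  norm <- setdiff(seq_len(2000), c(loss, gain))
  # double ratio cancels both exon and sample factors
  rel <- function(ev) (mean(d[ev, "II-2"]) / mean(d[norm, "II-2"])) /
    (mean(d[ev, others]) / mean(d[norm, others]))
  expect_lt(abs(rel(loss) - 0.5), 0.05)
  expect_lt(abs(rel(gain) - 1.5), 0.10)
  # only implanted exons depart from two copies in the truth matrix
  cn <- metadata(cov)$trueCopyNumber
  expect_setequal(rownames(cn)[rowSums(cn != 2) > 0],
                  sprintf("exon%05d", c(loss, gain)))
})

test_that("the same seed reproduces the drop and the coverage exactly", {
  cfg <- simConfig(seed = 31, nMarkers = 300, nIndels = 5, nExons = 80,
                   cnvEvents = list())
  d1 <- geneDrop(cfg); d2 <- geneDrop(cfg)
  expect_identical(dosages(d1$panel), dosages(d2$panel))
  expect_identical(assay(d1$panel, "depth"), assay(d2$panel, "depth"))
  expect_identical(d1$truth$markers, d2$truth$markers)
  c1 <- simulateCoverage(cfg); c2 <- simulateCoverage(cfg)
  expect_identical(assay(c1, "depth"), assay(c2, "depth"))
})

test_that("genotype errors degrade GQ so QC can catch them", {
  cfg <- simConfig(seed = 37, nMarkers = 3000, nIndels = 0,
                   errorRate = 0.01, cnvEvents = list())
  drop <- geneDrop(cfg)
  errs <- drop$truth$errors
  expect_gt(nrow(errs), 0)
  gq <- assay(drop$panel, "gq")
  i <- match(errs$markerId, rowData(drop$panel)$markerId)
  j <- match(errs$sample, colnames(drop$panel))
  expect_true(all(gq[cbind(i, j)] < 41))
  expect_true(all(gq[cbind(i, j)] >= 5))
})

test_that("emitted fixtures re-parse to the in-memory objects", {
  dir <- withr::local_tempdir()
  cfg <- simConfig(seed = 41, nMarkers = 250, nIndels = 8, nExons = 60,
                   cnvEvents = list(list(exons = 10:12,
                                         carriers = c("II-3", "II-7"),
                                         cn = 1L)))
  fx <- emitFixture(cfg, dir)
  # pedigree
  ped <- readPed(fx$ped)
  expect_equal(pedigreeMembers(ped)[, 1:5],
               pedigreeMembers(cfg$pedigree)[, 1:5])
  # VCF with annotation sidecar
  panel <- readVariantVcf(fx$vcf, annotation = fx$annotation)
  expect_equal(dim(panel), dim(fx$drop$panel))
  expect_identical(dosages(panel), dosages(fx$drop$panel))
  expect_true(all(assay(panel, "depth") == assay(fx$drop$panel, "depth")))
  expect_true(all(assay(panel, "gq") == assay(fx$drop$panel, "gq")))
  expect_equal(rowData(panel)$markerId, rowData(fx$drop$panel)$markerId)
  expect_equal(rowData(panel)$effect, rowData(fx$drop$panel)$effect)
  expect_equal(rowData(panel)$popFreq, rowData(fx$drop$panel)$popFreq,
               tolerance = 1e-9)
  # depth matrix and exon BED
  cov <- readDepthTsv(fx$depth)
  expect_identical(assay(cov, "depth"), assay(fx$coverage, "depth"))
  bed <- readExonBed(fx$bed)
  expect_equal(names(bed), rownames(fx$coverage))
  expect_equal(GenomicRanges::start(bed),
               GenomicRanges::start(rowRanges(fx$coverage)))
  # array panel
  arr <- readGenotypeTsv(fx$array)
  expect_identical(dosages(arr), dosages(fx$arrayPanel))
  # truth sidecar lists exactly one causal variant
  tv <- read.delim(fx$truthVariants)
  expect_equal(sum(tv$causal), 1)
})
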