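test_that("PED parsing handles trios, missing codes and extra columns", {
  tmp <- withr::local_tempfile(lines = c(
    "# comment",
    "FAM1 F 0 0 1 2 extra column",
    "FAM1 M 0 0 2 1",
    "FAM1 C F M 2 2"))
  ped <- readPed(tmp)
  expect_s4_class(ped, "FamPedigree")
  expect_length(ped, 3)
  expect_equal(sort(founders(ped)), c("F", "M"))
  expect_equal(unname(affectionOf(ped)[c("F", "M", "C")]),
               c("affected", "unaffected", "affected"))
  expect_equal(pedigreeName(ped), "FAM1")
})

test_that("pedigree serialisation round-trips", {
  ped <- defaultFamilyPedigree()
  tmp <- withr::local_tempfile()
  writePed(ped, tmp)
  back <- readPed(tmp, sequenced = sequencedIds(ped))
  expect_equal(pedigreeMembers(back), pedigreeMembers(ped))
  expect_equal(pedigreeName(back), pedigreeName(ped))
})

test_that("the packaged 13-member family matches the study design", {
  ped <- readPed(system.file("extdata", "family13.ped",
                             package = "famphase"),
                 sequenced = c("I-1", "I-2", "II-1", "II-2", "II-3",
                               "II-5", "II-7", "II-9"))
  expect_length(ped, 13)
  aff <- affectionOf(ped)
  sq <- sequencedIds(ped)
  expect_length(sq, 8)
  expect_equal(sum(aff[sq] == "affected"), 4)
  expect_equal(sum(aff[sq] == "unaffected"), 4)
  # the transmitting founder is among the sequenced affected
  expect_true(any(aff[intersect(founders(ped), sq)] == "affected"))
  # one equivocal member maps to unknown affection
  expect_equal(sum(aff == "unknown"), 1)
  expect_equal(pedigreeMembers(ped), pedigreeMembers(defaultFamilyPedigree()))
})

test_that("structural errors are rejected", {
  tmp <- withr::local_tempfile(lines = c(
    "F1 A 0 0 1 1", "F1 C X9 A 1 2"))
  expect_error(readPed(tmp), "X9")
  expect_error(FamPedigree(id = c("A", "A")), "duplicate")
  expect_error(FamPedigree(id = c("A", "B"), father = c("B", "A"),
                           mother = c("B", "A")), "cyclic|parent")
  expect_error(FamPedigree(id = c("A", "B"), father = c(NA, "A"),
                           mother = c(NA, NA)), "single parent")
})

test_that("mendelianCheck flags impossible transmissions and skips missing", {
  ped <- makeNuclearPed(2)
  mk <- function(d) makeVariantPanel(
    ped, matrix(d, 1, 4, dimnames = list(NULL, c("F", "M", "C1", "C2"))),
    chrom = "chr1", pos = 100)
  # parents 0/0, child 1 -> one violation
  v <- mendelianCheck(ped, mk(c(0, 0, 1, 0)))
  expect_equal(nrow(v), 1)
  expect_equal(v$childId, "C1")
  # parents 1/1: any child dosage possible
  for (d in 0:2)
    expect_equal(nrow(mendelianCheck(ped, mk(c(1, 1, d, 1)))), 0)
  # missing child is skipped
  expect_equal(nrow(mendelianCheck(ped, mk(c(0, 0, NA, 0)))), 0)
  # parent 0 x 2 forces child 1
  expect_equal(nrow(mendelianCheck(ped, mk(c(0, 2, 1, 1)))), 0)
  expect_equal(nrow(mendelianCheck(ped, mk(c(0, 2, 2, 1)))), 1)
})

test_that("harmonizePanels intersects subjects and markers", {
  ped <- makeNuclearPed(6)
  ids <- pedigreeIds(ped)
  mkPanel <- function(subj, chrom, pos, ref, alt) {
    d <- matrix(sample(0:2, length(pos) * length(subj), replace = TRUE),
                length(pos), dimnames = list(NULL, subj))
    GenotypePanel(d, chrom, pos, ref, alt, platform = "array")
  }
  set.seed(1)
  a <- mkPanel(ids, "chr1", c(100, 200, 300), c("A", "C", "G"),
               c("T", "T", "A"))
  b <- mkPanel(ids[1:7], "chr1", c(100, 200, 999), c("A", "C", "T"),
               c("T", "T", "C"))
  h <- harmonizePanels(a, b)
  expect_equal(dim(h$a), c(2L, 7L))
  expect_equal(dim(h$b), c(2L, 7L))
  expect_equal(rowData(h$a)$markerId, rowData(h$b)$markerId)
  expect_equal(colnames(h$a), colnames(h$b))
  # identity on identical panels
  hi <- harmonizePanels(a, a)
  expect_equal(dosages(hi$a), dosages(a))
  expect_equal(dosages(hi$b), dosages(a))
  # idempotence
  h2 <- harmonizePanels(h$a, h$b)
  expect_equal(dosages(h2$a), dosages(h$a))
  # no overlap -> explicit error
  c2 <- mkPanel(ids, "chr9", c(1, 2, 3), c("A", "A", "A"), c("G", "G", "G"))
  expect_error(harmonizePanels(a, c2), "empty overlap")
})

test_that("allele-swapped markers are recoded so frequencies agree", {
  ped <- makeNuclearPed(6)
  ids <- pedigreeIds(ped)
  set.seed(2)
  d <- matrix(sample(0:2, 3 * 8, replace = TRUE), 3,
              dimnames = list(NULL, ids))
  a <- GenotypePanel(d, "chr2", c(10, 20, 30), c("A", "C", "G"),
                     c("T", "G", "A"), platform = "array")
  dSwap <- d
  dSwap[2, ] <- 2L - d[2, ]
  b <- GenotypePanel(dSwap, "chr2", c(10, 20, 30),
                     c("A", "G", "G"), c("T", "C", "A"),
                     platform = "array")
  expect_message(h <- harmonizePanels(a, b), "allele-swapped")
  # dosages agree after recoding (the flipped marker keeps its own id)
  expect_equal(unname(dosages(h$a)), unname(dosages(h$b)))
  expect_true(any(rowData(h$b)$alleleFlipped))
  # alt-allele frequencies computed from dosages now agree marker-wise
  fa <- unname(rowSums(dosages(h$a))) / (2 * ncol(h$a))
  fb <- unname(rowSums(dosages(h$b))) / (2 * ncol(h$b))
  expect_equal(fa, fb)
})
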