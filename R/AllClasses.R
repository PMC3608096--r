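#' @include utils.R
NULL

#' Family pedigree with affection status
#'
#' An ordered collection of individuals with parent links, sex, affection
#' status and a flag marking the exome-sequenced subset. Founders have both
#' parent ids missing (\code{NA}); non-founders have both parents present in
#' the pedigree. The parental graph must be acyclic and parental sexes
#' consistent (father not female, mother not male) where known.
#'
#' @slot members data.frame with columns \code{id}, \code{father},
#'   \code{mother}, \code{sex} (\code{male}/\code{female}/\code{unknown}),
#'   \code{affection} (\code{affected}/\code{unaffected}/\code{unknown}) and
#'   \code{sequenced} (logical).
#' @slot name single family identifier.
#' @aliases FamPedigree-class
#' @seealso [FamPedigree()], [readPed()], [mendelianCheck()]
#' @exportClass FamPedigree
setClass("FamPedigree",
         representation(members = "data.frame", name = "character"))

setValidity("FamPedigree", function(object) {
  df <- object@members
  need <- c("id", "father", "mother", "sex", "affection", "sequenced")
  if (!all(need %in% names(df)))
    return(paste("members must have columns:", paste(need, collapse = ", ")))
  msgs <- character()
  if (anyDuplicated(df$id))
    msgs <- c(msgs, sprintf("duplicate individual id(s): %s",
                            paste(unique(df$id[duplicated(df$id)]),
                                  collapse = ", ")))
  if (any(is.na(df$id) | df$id == ""))
    msgs <- c(msgs, "empty individual id")
  one_parent <- xor(is.na(df$father), is.na(df$mother))
  if (any(one_parent))
    msgs <- c(msgs, sprintf("individual(s) with a single parent: %s",
                            paste(df$id[one_parent], collapse = ", ")))
  dangling <- setdiff(c(df$father, df$mother), c(df$id, NA))
  if (length(dangling))
    msgs <- c(msgs, sprintf("parent id(s) not in pedigree: %s",
                            paste(dangling, collapse = ", ")))
  if (!all(df$sex %in% c("male", "female", "unknown")))
    msgs <- c(msgs, "sex must be male/female/unknown")
  if (!all(df$affection %in% c("affected", "unaffected", "unknown")))
    msgs <- c(msgs, "affection must be affected/unaffected/unknown")
  fa_sex <- df$sex[match(df$father, df$id)]
  mo_sex <- df$sex[match(df$mother, df$id)]
  if (any(fa_sex == "female", na.rm = TRUE))
    msgs <- c(msgs, "a father is recorded as female")
  if (any(mo_sex == "male", na.rm = TRUE))
    msgs <- c(msgs, "a mother is recorded as male")
  if (!length(msgs) && nrow(df)) {
    # cycle check: repeatedly strip individuals none of whose parents remain
    remaining <- df$id
    repeat {
      fa <- df$father[match(remaining, df$id)]
      mo <- df$mother[match(remaining, df$id)]
      strip <- !(fa %in% remaining) & !(mo %in% remaining)
      if (!any(strip)) break
      remaining <- remaining[!strip]
      if (!length(remaining)) break
    }
    if (length(remaining))
      msgs <- c(msgs, sprintf("cyclic ancestry involving: %s",
                              paste(remaining, collapse = ", ")))
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Autosomal disease model for parametric linkage
#'
#' Penetrance vector \eqn{(f_0, f_1, f_2)} = probability of being affected
#' given 0/1/2 copies of the disease allele, population disease allele
#' frequency \eqn{q}, and recombination fraction \eqn{\theta} between the
#' disease locus and the test marker. The defaults -- full-penetrance
#' dominant \eqn{(0, 1, 1)}, \eqn{q = 10^{-5}}, \eqn{\theta = 0} -- describe
#' a rare, fully penetrant dominant trait tested for complete linkage;
#' \eqn{\theta = 0.5} is the no-linkage null.
#'
#' @slot penetrance numeric(3) in [0, 1].
#' @slot diseaseFreq disease allele frequency in (0, 1).
#' @slot theta recombination fraction in [0, 0.5].
#' @aliases DiseaseModel-class
#' @seealso [diseaseModel()], [lodSinglePoint()]
#' @exportClass DiseaseModel
setClass("DiseaseModel",
         representation(penetrance = "numeric", diseaseFreq = "numeric",
                        theta = "numeric"))

setValidity("DiseaseModel", function(object) {
  msgs <- character()
  if (length(object@penetrance) != 3 ||
      any(object@penetrance < 0 | object@penetrance > 1))
    msgs <- c(msgs, "penetrance must be 3 values in [0, 1]")
  if (length(object@diseaseFreq) != 1 || object@diseaseFreq <= 0 ||
      object@diseaseFreq >= 1)
    msgs <- c(msgs, "diseaseFreq must be a single value in (0, 1)")
  if (length(object@theta) != 1 || object@theta < 0 || object@theta > 0.5)
    msgs <- c(msgs, "theta must be a single value in [0, 0.5]")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Biallelic genotype panel over family members
#'
#' A \linkS4class{RangedSummarizedExperiment} holding alt-allele dosages
#' (\code{0/1/2}, \code{NA} = missing) for a set of biallelic markers
#' (rows, sorted by genomic position) over a set of subjects (columns).
#' WES-derived panels additionally carry per-genotype \code{depth} and
#' \code{gq} assays used by the QC filters, and may carry functional
#' annotation columns (\code{gene}, \code{effect}, \code{hgvsC},
#' \code{hgvsP}, \code{knownId}, \code{popFreq}) in \code{rowData}.
#'
#' @slot platform \code{"wes"} or \code{"array"}.
#' @aliases GenotypePanel-class
#' @seealso [GenotypePanel()], [readVariantVcf()], [readGenotypeTsv()],
#'   [harmonizePanels()]
#' @exportClass GenotypePanel
setClass("GenotypePanel",
         contains = "RangedSummarizedExperiment",
         representation(platform = "character"))

setValidity("GenotypePanel", function(object) {
  msgs <- character()
  if (length(object@platform) != 1 ||
      !object@platform %in% c("wes", "array"))
    msgs <- c(msgs, "platform must be 'wes' or 'array'")
  if (!"dosage" %in% names(assays(object)))
    msgs <- c(msgs, "a 'dosage' assay is required")
  else {
    d <- assay(object, "dosage")
    if (!all(d %in% c(0L, 1L, 2L, NA)))
      msgs <- c(msgs, "dosages must be 0, 1, 2 or NA")
  }
  rd <- rowData(object)
  for (col in c("markerId", "ref", "alt"))
    if (!col %in% names(rd)) msgs <- c(msgs, sprintf("rowData$%s missing", col))
  if (is.null(colnames(object)))
    msgs <- c(msgs, "subject ids (colnames) are required")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Per-exon read-depth matrix
#'
#' A \linkS4class{RangedSummarizedExperiment} whose rows are exon intervals
#' (unique, position-sorted; imported from BED as 0-based half-open and held
#' as 1-based \linkS4class{GRanges}) and whose single \code{depth} assay is
#' the mean read depth of each exon in each sample (finite, non-negative).
#'
#' @aliases ExonCoverage-class
#' @seealso [ExonCoverage()], [readDepthTsv()], [normalizeCoverage()]
#' @exportClass ExonCoverage
setClass("ExonCoverage", contains = "RangedSummarizedExperiment")

setValidity("ExonCoverage", function(object) {
  msgs <- character()
  if (!"depth" %in% names(assays(object)))
    msgs <- c(msgs, "a 'depth' assay is required")
  else {
    d <- assay(object, "depth")
    if (any(!is.finite(d)) || any(d < 0))
      msgs <- c(msgs, "depths must be finite and >= 0")
  }
  if (is.null(rownames(object)))
    msgs <- c(msgs, "exon names (rownames) are required")
  else if (anyDuplicated(rownames(object)))
    msgs <- c(msgs, "exon names must be unique")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Per-exon, per-sample copy-number calls
#'
#' Result of [callExonCnv()]: assays \code{log2Ratio}, \code{pValue} and
#' \code{state} (\code{"gain"}/\code{"normal"}/\code{"loss"}; \code{NA} for
#' masked exons), with the per-exon \code{baseline} depth and \code{masked}
#' flag in \code{rowData}. States obey: gain iff \eqn{p < \alpha} and
#' log2 ratio > 0; loss iff \eqn{p < \alpha} and log2 ratio < 0; otherwise
#' normal.
#'
#' @slot alpha significance level used for state assignment.
#' @aliases CnvCalls-class
#' @seealso [callExonCnv()], [cnvCosegScan()]
#' @exportClass CnvCalls
setClass("CnvCalls",
         contains = "RangedSummarizedExperiment",
         representation(alpha = "numeric"))

setValidity("CnvCalls", function(object) {
  msgs <- character()
  need <- c("log2Ratio", "pValue", "state")
  miss <- setdiff(need, names(assays(object)))
  if (length(miss))
    msgs <- c(msgs, paste("missing assay(s):", paste(miss, collapse = ", ")))
  if (length(object@alpha) != 1 || object@alpha <= 0 || object@alpha >= 1)
    msgs <- c(msgs, "alpha must be in (0, 1)")
  if (!length(msgs)) {
    st <- assay(object, "state")
    if (!all(st %in% c("gain", "normal", "loss", NA)))
      msgs <- c(msgs, "states must be gain/normal/loss/NA")
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})
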