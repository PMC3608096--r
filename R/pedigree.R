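#' @include AllClasses.R
NULL

#' Construct a family pedigree
#'
#' @param id character vector of unique individual ids.
#' @param father,mother parent ids; \code{NA} for founders (both must be
#'   \code{NA} together).
#' @param sex \code{"male"}, \code{"female"} or \code{"unknown"}.
#' @param affection \code{"affected"}, \code{"unaffected"} or
#'   \code{"unknown"} (equivocal phenotype).
#' @param sequenced logical; whether the individual was exome-sequenced.
#' @param name family name.
#' @return A \linkS4class{FamPedigree}.
#' @examples
#' trio <- FamPedigree(id = c("F", "M", "C"),
#'                     father = c(NA, NA, "F"), mother = c(NA, NA, "M"),
#'                     sex = c("male", "female", "female"),
#'                     affection = c("affected", "unaffected", "affected"))
#' founders(trio)
#' @export
FamPedigree <- function(id, father = NA, mother = NA, sex = "unknown",
                        affection = "unknown", sequenced = FALSE,
                        name = "FAM1") {
  n <- length(id)
  df <- data.frame(
    id = as.character(id),
    father = as.character(rep_len(father, n)),
    mother = as.character(rep_len(mother, n)),
    sex = as.character(rep_len(sex, n)),
    affection = as.character(rep_len(affection, n)),
    sequenced = as.logical(rep_len(sequenced, n)),
    stringsAsFactors = FALSE)
  new("FamPedigree", members = df, name = as.character(name)[1])
}

#' @describeIn FamPedigree number of individuals.
#' @param x a \code{FamPedigree}.
#' @export
setMethod("length", "FamPedigree", function(x) nrow(x@members))

setMethod("show", "FamPedigree", function(object) {
  df <- object@members
  cat(sprintf("FamPedigree '%s': %d individuals (%d founders)\n",
              object@name, nrow(df), sum(is.na(df$father))))
  cat(sprintf("  affected: %d  unaffected: %d  unknown: %d  sequenced: %d\n",
              sum(df$affection == "affected"),
              sum(df$affection == "unaffected"),
              sum(df$affection == "unknown"),
              sum(df$sequenced)))
})

#' Pedigree accessors
#'
#' @param ped a \linkS4class{FamPedigree}.
#' @return \code{pedigreeMembers}: the members data.frame;
#'   \code{pedigreeIds}: individual ids; \code{founders}: ids of individuals
#'   with no parents; \code{affectionOf}: named affection vector;
#'   \code{sequencedIds}: ids flagged as sequenced;
#'   \code{pedigreeName}: the family name.
#' @export
pedigreeMembers <- function(ped) ped@members

#' @rdname pedigreeMembers
#' @export
pedigreeIds <- function(ped) ped@members$id

#' @rdname pedigreeMembers
#' @export
pedigreeName <- function(ped) ped@name

#' @rdname pedigreeMembers
#' @export
founders <- function(ped) ped@members$id[is.na(ped@members$father)]

#' @rdname pedigreeMembers
#' @export
affectionOf <- function(ped) {
  setNames(ped@members$affection, ped@members$id)
}

#' @rdname pedigreeMembers
#' @export
sequencedIds <- function(ped) ped@members$id[ped@members$sequenced]

#' Read / write 6-column PED pedigree files
#'
#' The common whitespace-delimited PED dialect: columns family id,
#' individual id, father, mother, sex, phenotype, with \code{0} meaning
#' missing parent/sex/phenotype, sex \code{1} = male / \code{2} = female,
#' and phenotype \code{1} = unaffected / \code{2} = affected. Extra columns
#' are ignored. All rows must belong to one family.
#'
#' @param file path to a PED file.
#' @param sequenced optional character vector of individual ids to flag as
#'   sequenced (PED itself does not carry this; it is normally inferred from
#'   the VCF sample columns).
#' @return \code{readPed}: a \linkS4class{FamPedigree}.
#' @export
readPed <- function(file, sequenced = character()) {
  lines <- readLines(file)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (!length(lines)) .stopf("no pedigree records in '%s'", file)
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 6))
    .stopf("PED line(s) with fewer than 6 columns: %s",
           paste(which(nf < 6), collapse = ", "))
  m <- t(vapply(fields, function(f) f[1:6], character(6)))
  fam <- unique(m[, 1])
  if (length(fam) > 1)
    .stopf("PED file contains multiple families: %s",
           paste(fam, collapse = ", "))
  sex <- c("0" = "unknown", "1" = "male", "2" = "female")[m[, 5]]
  sex[is.na(sex)] <- "unknown"
  aff <- c("0" = "unknown", "1" = "unaffected", "2" = "affected")[m[, 6]]
  aff[is.na(aff)] <- "unknown"
  FamPedigree(id = m[, 2],
              father = ifelse(m[, 3] == "0", NA, m[, 3]),
              mother = ifelse(m[, 4] == "0", NA, m[, 4]),
              sex = unname(sex), affection = unname(aff),
              sequenced = m[, 2] %in% sequenced, name = fam)
}

#' @rdname readPed
#' @param ped a \linkS4class{FamPedigree} to serialise.
#' @return \code{writePed}: the file path, invisibly.
#' @export
writePed <- function(ped, file) {
  df <- ped@members
  out <- data.frame(
    fam = ped@name, id = df$id,
    father = ifelse(is.na(df$father), "0", df$father),
    mother = ifelse(is.na(df$mother), "0", df$mother),
    sex = c(male = "1", female = "2", unknown = "0")[df$sex],
    phen = c(affected = "2", unaffected = "1", unknown = "0")[df$affection])
  write.table(out, file, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' Screen a genotype panel for Mendelian-inconsistent transmissions
#'
#' Flags every non-founder whose alt-allele dosage is impossible given the
#' dosages of its parents (e.g. parents 0/0 with a dosage-1 child). Missing
#' dosages are skipped, never flagged: a missing child is not checked, and a
#' missing or ungenotyped parent is treated as able to transmit either
#' allele. Mendelian errors in marker data reduce the power of linkage
#' analysis and can create spurious peaks, so this screen is worth running
#' before [lodScan()].
#'
#' @param ped a \linkS4class{FamPedigree}.
#' @param panel a \linkS4class{GenotypePanel}; its subjects must be a subset
#'   of the pedigree ids.
#' @return data.frame with columns \code{markerId} and \code{childId}, one
#'   row per violation (zero rows if the panel is Mendelian-clean).
#' @export
mendelianCheck <- function(ped, panel) {
  df <- ped@members
  subj <- colnames(panel)
  extra <- setdiff(subj, df$id)
  if (length(extra))
    .stopf("panel subjects not in pedigree: %s", paste(extra, collapse = ", "))
  dos <- assay(panel, "dosage")
  ids <- rowData(panel)$markerId
  # transmissible allele counts form an interval per parent:
  #   dosage 0 -> {0}, 1 -> {0,1}, 2 -> {1}, missing/absent -> {0,1}
  bound <- function(parent, lower) {
    out <- matrix(if (lower) 0 else 1, nrow(dos), length(subj))
    ok <- !is.na(parent) & parent %in% subj
    if (any(ok)) {
      pd <- dos[, match(parent[ok], subj), drop = FALSE]
      v <- if (lower) (pd == 2) else (pd >= 1)
      v[is.na(v)] <- if (lower) FALSE else TRUE
      out[, ok] <- v + 0
    }
    out
  }
  children <- df[match(subj, df$id), ]
  lo <- bound(children$father, TRUE) + bound(children$mother, TRUE)
  hi <- bound(children$father, FALSE) + bound(children$mother, FALSE)
  viol <- !is.na(dos) & (dos < lo | dos > hi)
  idx <- which(viol, arr.ind = TRUE)
  data.frame(markerId = ids[idx[, 1]], childId = subj[idx[, 2]],
             stringsAsFactors = FALSE)
}
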