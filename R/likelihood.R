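#' @include AllClasses.R pedigree.R
NULL

#' @rdname DiseaseModel-class
#' @param penetrance numeric(3): P(affected | 0, 1, 2 disease alleles).
#' @param diseaseFreq disease allele frequency in (0, 1).
#' @param theta recombination fraction in [0, 0.5] used for the test
#'   hypothesis; the null is always theta = 0.5.
#' @export
diseaseModel <- function(penetrance = c(0, 1, 1), diseaseFreq = 1e-5,
                         theta = 0) {
  new("DiseaseModel", penetrance = as.numeric(penetrance),
      diseaseFreq = as.numeric(diseaseFreq), theta = as.numeric(theta))
}

setMethod("show", "DiseaseModel", function(object) {
  cat(sprintf(
    "DiseaseModel: penetrance (%g, %g, %g), disease allele freq %g, theta %g\n",
    object@penetrance[1], object@penetrance[2], object@penetrance[3],
    object@diseaseFreq, object@theta))
})

#' Nuclear-family peeling schedule for a zero-loop pedigree
#'
#' Decomposes the pedigree into nuclear families and orders them so that
#' each family, when processed, shares at most one member (the pivot) with
#' the still-unprocessed part of the pedigree. This is the classic
#' Elston-Stewart traversal; it exists whenever the pedigree has no loops
#' (no consanguineous matings), which the constructor of the synthetic
#' study family guarantees and which real PED input is checked for here.
#'
#' @param ped a \linkS4class{FamPedigree}.
#' @return list with \code{steps} (list of \code{f}, \code{m},
#'   \code{children}, \code{pivot}; 0-based indices into the member table;
#'   pivot -1 means the family closes a connected component) and
#'   \code{roots} (0-based indices of individuals in no nuclear family).
#' @keywords internal
peelingSchedule <- function(ped) {
  df <- ped@members
  n <- nrow(df)
  fa <- match(df$father, df$id)
  mo <- match(df$mother, df$id)
  kids <- which(!is.na(fa))
  couple <- paste(fa[kids], mo[kids])
  fams <- lapply(split(kids, couple), function(ch) {
    list(f = fa[ch[1]], m = mo[ch[1]], children = ch)
  })
  nf <- length(fams)
  membership <- vector("list", n)
  for (j in seq_len(nf)) {
    for (i in c(fams[[j]]$f, fams[[j]]$m, fams[[j]]$children))
      membership[[i]] <- c(membership[[i]], j)
  }
  active <- rep(TRUE, nf)
  steps <- list()
  while (any(active)) {
    placed <- FALSE
    for (j in which(active)) {
      mem <- c(fams[[j]]$f, fams[[j]]$m, fams[[j]]$children)
      conn <- mem[vapply(mem, function(i)
        sum(active[membership[[i]]]) > 1, logical(1))]
      if (length(conn) <= 1) {
        pivot <- if (length(conn)) conn[1] else -1L
        steps[[length(steps) + 1L]] <- list(
          f = fams[[j]]$f - 1L, m = fams[[j]]$m - 1L,
          children = as.integer(fams[[j]]$children - 1L),
          pivot = as.integer(if (pivot > 0) pivot - 1L else -1L))
        active[j] <- FALSE
        placed <- TRUE
        break
      }
    }
    if (!placed)
      .stopf("pedigree contains loops; peeling schedule not available")
  }
  roots <- which(lengths(membership) == 0)
  list(steps = steps, roots = as.integer(roots - 1L))
}

#' Two-locus pedigree log-likelihood
#'
#' Exact log-likelihood (natural log) of observed marker dosages and
#' affection statuses under a two-locus disease-marker model: founders
#' carry Hardy-Weinberg / linkage-equilibrium haplotype priors (disease
#' allele frequency from \code{model}, marker allele frequency
#' \code{altFreq}), non-founders receive one haplotype per parent with
#' recombination fraction \code{theta} between loci, and every phenotyped
#' member contributes a penetrance factor. Members without a dosage (or
#' absent from \code{dosage}) contribute phenotype information only;
#' members with \code{affection == "unknown"} contribute no penetrance
#' factor. Computed by Elston-Stewart peeling over the 16-state ordered
#' two-locus genotype space (compiled; log-rescaled per nuclear family).
#'
#' @param ped a \linkS4class{FamPedigree} (zero-loop).
#' @param dosage named vector of alt-allele dosages (names = individual
#'   ids, values 0/1/2/NA), or a matrix with one column per marker
#'   (rownames = ids).
#' @param altFreq marker alt-allele frequency in (0, 1); recycled across
#'   markers.
#' @param model a \linkS4class{DiseaseModel}.
#' @param theta recombination fraction; defaults to \code{model@theta}.
#' @return numeric log-likelihood, one value per marker.
#' @examples
#' ped <- FamPedigree("A")   # single unphenotyped founder
#' pedigreeLogLik(ped, c(A = 1), altFreq = 0.5,
#'                model = diseaseModel())   # log(2 * 0.5 * 0.5)
#' @export
pedigreeLogLik <- function(ped, dosage, altFreq, model = diseaseModel(),
                           theta = NULL) {
  if (is.null(theta)) theta <- model@theta
  if (!is.numeric(theta) || length(theta) != 1 || is.na(theta) ||
      theta < 0 || theta > 0.5)
    .stopf("theta must be a single value in [0, 0.5]")
  validObject(model)
  df <- ped@members
  if (is.null(dim(dosage)))
    dosage <- matrix(dosage, ncol = 1, dimnames = list(names(dosage), NULL))
  if (is.null(rownames(dosage)))
    .stopf("dosage must carry individual ids as names/rownames")
  unknown <- setdiff(rownames(dosage), df$id)
  if (length(unknown))
    .stopf("dosage for individual(s) not in pedigree: %s",
           paste(unknown, collapse = ", "))
  dm <- matrix(NA_integer_, nrow(df), ncol(dosage))
  dm[match(rownames(dosage), df$id), ] <- as.integer(round(dosage))
  if (any(colSums(!is.na(dm)) == 0))
    .stopf("likelihood undefined: a marker has no observed dosages")
  if (any(dm < 0 | dm > 2, na.rm = TRUE))
    .stopf("dosages must be 0, 1 or 2 (or NA)")
  altFreq <- rep_len(as.numeric(altFreq), ncol(dm))
  if (any(!is.finite(altFreq) | altFreq <= 0 | altFreq >= 1))
    .stopf("altFreq must lie strictly between 0 and 1")
  sched <- peelingSchedule(ped)
  affCode <- c(unknown = 0L, unaffected = 1L, affected = 2L)[df$affection]
  .twoLocusLogLik(dm, altFreq, sched$steps, sched$roots,
                  as.integer(is.na(df$father)), unname(affCode),
                  model@penetrance, model@diseaseFreq, theta)
}

#' Single-point LOD score
#'
#' \eqn{LOD = \log_{10} L(\theta) - \log_{10} L(0.5)} for one biallelic
#' marker, with \eqn{\theta} taken from the disease model (the study
#' convention: \eqn{\theta} is fixed, typically at 0, not maximised over).
#' A marker whose genotypes are impossible at \eqn{\theta} but not under
#' the no-linkage null yields \code{-Inf}.
#'
#' @inheritParams pedigreeLogLik
#' @return numeric LOD (dimensionless, log10 scale), one per marker.
#' @seealso [lodScan()] for whole-panel scans with QC.
#' @export
lodSinglePoint <- function(ped, dosage, altFreq, model = diseaseModel()) {
  l1 <- pedigreeLogLik(ped, dosage, altFreq, model, theta = model@theta)
  l0 <- pedigreeLogLik(ped, dosage, altFreq, model, theta = 0.5)
  (l1 - l0) / log(10)
}
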