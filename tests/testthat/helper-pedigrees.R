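# Pedigree builders shared across tests.

# Nuclear family: affected father, unaffected mother, children alternating
# affected/unaffected (affected children listed first when pattern given).
makeNuclearPed <- function(nChildren, childAffection = NULL) {
  if (is.null(childAffection))
    childAffection <- rep(c("affected", "unaffected"),
                          length.out = nChildren)
  FamPedigree(
    id = c("F", "M", paste0("C", seq_len(nChildren))),
    father = c(NA, NA, rep("F", nChildren)),
    mother = c(NA, NA, rep("M", nChildren)),
    sex = c("male", "female",
            rep(c("male", "female"), length.out = nChildren)),
    affection = c("affected", "unaffected", childAffection),
    sequenced = TRUE)
}

# Random zero-loop pedigree of n members (3 <= n <= 8): grows by adding
# children of existing couples or married-in founders.
randomPedigree <- function(n) {
  id <- c("P1", "P2")
  father <- c(NA, NA)
  mother <- c(NA, NA)
  sex <- c("male", "female")
  couples <- list(c("P1", "P2"))
  i <- 2L
  while (i < n) {
    i <- i + 1L
    nid <- paste0("P", i)
    # prefer children; sometimes marry a new founder to an existing child
    kids <- setdiff(id, unlist(couples))
    if (length(kids) && runif(1) < 0.25 && i < n) {
      mate <- sample(kids, 1)
      mateSex <- sex[match(mate, id)]
      id <- c(id, nid); father <- c(father, NA); mother <- c(mother, NA)
      sex <- c(sex, if (mateSex == "male") "female" else "male")
      couples <- c(couples, list(if (mateSex == "male") c(mate, nid)
                                 else c(nid, mate)))
    } else {
      cp <- couples[[sample.int(length(couples), 1)]]
      id <- c(id, nid)
      father <- c(father, cp[1]); mother <- c(mother, cp[2])
      sex <- c(sex, sample(c("male", "female"), 1))
    }
  }
  FamPedigree(id = id, father = father, mother = mother, sex = sex,
              affection = sample(c("affected", "unaffected", "unknown"),
                                 length(id), replace = TRUE,
                                 prob = c(0.4, 0.4, 0.2)),
              sequenced = TRUE)
}

# Drop a single biallelic marker through a pedigree (plain Mendelian
# sampling, ignoring phenotype) and return dosages with optional missing.
dropMarker <- function(ped, freq, missingProb = 0) {
  df <- pedigreeMembers(ped)
  hap <- matrix(NA_integer_, nrow(df), 2, dimnames = list(df$id, NULL))
  done <- setNames(is.na(df$father), df$id)
  for (id in df$id[done]) hap[id, ] <- rbinom(2, 1, freq)
  while (any(!done)) {
    for (id in df$id[!done]) {
      f <- df$father[match(id, df$id)]; m <- df$mother[match(id, df$id)]
      if (!done[f] || !done[m]) next
      hap[id, 1] <- hap[f, sample(1:2, 1)]
      hap[id, 2] <- hap[m, sample(1:2, 1)]
      done[id] <- TRUE
    }
  }
  dos <- rowSums(hap)
  if (missingProb > 0)
    dos[runif(length(dos)) < missingProb] <- NA
  dos
}

# A small annotated WES panel built directly (for filter tests).
makeVariantPanel <- function(ped, dosage, chrom, pos, ref = "A", alt = "G",
                             depth = 50, gq = 99, gene = "GENEX",
                             effect = "nonsynonymous",
                             knownId = NA_character_, popFreq = NA_real_,
                             hgvsC = NA_character_, hgvsP = NA_character_) {
  dosage <- as.matrix(dosage)
  n <- nrow(dosage)
  GenotypePanel(
    dosage, chrom = chrom, pos = pos,
    ref = rep_len(ref, n), alt = rep_len(alt, n), platform = "wes",
    depth = matrix(rep_len(depth, n * ncol(dosage)), n),
    gq = matrix(rep_len(gq, n * ncol(dosage)), n),
    rowData = S4Vectors::DataFrame(
      gene = rep_len(gene, n), effect = rep_len(effect, n),
      hgvsC = rep_len(hgvsC, n), hgvsP = rep_len(hgvsP, n),
      knownId = rep_len(knownId, n), popFreq = rep_len(popFreq, n)))
}
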