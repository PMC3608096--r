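#' @include pedigree.R panels.R coverage.R
NULL

#' The default 13-member, three-generation study-design pedigree
#'
#' Two founders, six siblings, one married-in spouse with equivocal
#' affection, and four grandchildren; six members affected in a dominant
#' pattern. Eight members are flagged sequenced (the two founders and the
#' six siblings): four affected (including the transmitting founder) and
#' four unaffected, which is the regime where a fully informative,
#' perfectly co-segregating marker attains LOD
#' \eqn{(6-1)\log_{10}2 \approx 1.505} from six phase-unknown meioses.
#'
#' @return A \linkS4class{FamPedigree}.
#' @export
defaultFamilyPedigree <- function() {
  FamPedigree(
    id        = c("I-1", "I-2", "II-1", "II-2", "II-3", "II-5", "II-6",
                  "II-7", "II-9", "III-1", "III-2", "III-3", "III-4"),
    father    = c(NA, NA, "I-1", "I-1", "I-1", "I-1", NA, "I-1", "I-1",
                  "II-5", "II-5", "II-5", "II-5"),
    mother    = c(NA, NA, "I-2", "I-2", "I-2", "I-2", NA, "I-2", "I-2",
                  "II-6", "II-6", "II-6", "II-6"),
    sex       = c("male", "female", "female", "male", "female", "male",
                  "female", "male", "female", "male", "female", "male",
                  "female"),
    affection = c("affected", "unaffected", "unaffected", "affected",
                  "affected", "affected", "unknown", "unaffected",
                  "unaffected", "affected", "unaffected", "affected",
                  "unaffected"),
    sequenced = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE,
                  FALSE, FALSE, FALSE, FALSE),
    name = "SYNFAM1")
}

#' Simulation configuration for a synthetic family exome
#'
#' The defaults describe the emulated study conditions: the 13-member
#' pedigree with 8 sequenced members, 18,000 autosomal coding SNVs (plus
#' 430 indels) with allele frequencies uniform on (0.05, 0.95), mean
#' per-genotype depth 45x (the study's samples averaged 40-51x) with mild
#' negative-binomial overdispersion, 5,000 exons, and an implanted fully
#' penetrant dominant causal variant on chr17 accompanied by a small fully
#' linked cluster of family-private variants (candidate loci in real data
#' are LD blocks of co-segregating exonic variants, so the hot-spot stage
#' requires more than an isolated marker at the causal locus).
#'
#' @param pedigree a \linkS4class{FamPedigree}; affection must follow a
#'   dominant pattern (every affected non-founder has an affected parent,
#'   and exactly one founder is affected).
#' @param nMarkers autosomal SNV marker count (includes the causal
#'   cluster).
#' @param nIndels additional indel records (annotated, excluded from
#'   linkage scans).
#' @param causalChrom,causalPos causal locus (autosomal).
#' @param linkedCluster number of extra family-private variants fully
#'   linked (theta = 0) to the causal variant.
#' @param clusterSpacing spacing (bp) between linked-cluster variants.
#' @param freqRange uniform range for marker alt-allele frequencies.
#' @param meanDepth mean per-genotype read depth (x coverage).
#' @param depthSize negative-binomial size (dispersion) for depths; 200
#'   gives a log2-ratio spread of ~0.24 at 45x, typical of within-family
#'   exome depth after normalisation.
#' @param errorRate per-genotype error probability in sequenced members.
#' @param knownFrac fraction of decoy variants given a known id and
#'   population frequency.
#' @param nExons number of simulated exons.
#' @param cnvEvents list of implanted events, each
#'   \code{list(exons = <row indices>, carriers = <ids>, cn = 0/1/3/4)};
#'   the defaults implant a 3-exon single-copy loss in II-3/II-7 and a
#'   3-exon single-copy gain in I-2/II-9 (non-co-segregating, like the
#'   copy-variable loci the study observed).
#' @param seed integer; fully determines the output.
#' @return a validated \code{SimConfig} list.
#' @export
simConfig <- function(pedigree = defaultFamilyPedigree(),
                      nMarkers = 18000L, nIndels = 430L,
                      causalChrom = "chr17", causalPos = 79478000L,
                      linkedCluster = 2L, clusterSpacing = 250000L,
                      freqRange = c(0.05, 0.95), meanDepth = 45,
                      depthSize = 200, errorRate = 0, knownFrac = 0.95,
                      nExons = 5000L,
                      cnvEvents = list(
                        list(exons = 1001:1003,
                             carriers = c("II-3", "II-7"), cn = 1L),
                        list(exons = 3001:3003,
                             carriers = c("I-2", "II-9"), cn = 3L)),
                      seed = 1L) {
  validObject(pedigree)
  if (!.isAutosome(causalChrom))
    .stopf("causal locus must be autosomal")
  df <- pedigree@members
  affected <- df$id[df$affection == "affected"]
  affFounders <- intersect(affected, founders(pedigree))
  if (length(affFounders) != 1)
    .stopf("config requires exactly one affected founder (the transmitting carrier); found %d",
           length(affFounders))
  nonF <- df[!is.na(df$father), ]
  for (i in seq_len(nrow(nonF))) {
    if (nonF$affection[i] == "affected") {
      pa <- df$affection[match(c(nonF$father[i], nonF$mother[i]), df$id)]
      if (!any(pa == "affected"))
        .stopf("affected member '%s' has no affected parent: impossible under full-penetrance dominant inheritance",
               nonF$id[i])
    }
  }
  for (ev in cnvEvents) {
    if (!all(ev$carriers %in% df$id))
      .stopf("cnv event carriers not in pedigree")
    if (!ev$cn %in% c(0L, 1L, 3L, 4L))
      .stopf("cnv event copy number must be 0, 1, 3 or 4")
    if (any(ev$exons < 1 | ev$exons > nExons))
      .stopf("cnv event exon indices out of range")
  }
  stopifnot(nMarkers > linkedCluster + 1, errorRate >= 0, errorRate < 1,
            meanDepth > 0, depthSize > 0,
            freqRange[1] > 0, freqRange[2] < 1,
            freqRange[1] <= freqRange[2])
  structure(list(
    pedigree = pedigree, nMarkers = as.integer(nMarkers),
    nIndels = as.integer(nIndels), causalChrom = causalChrom,
    causalPos = as.integer(causalPos),
    linkedCluster = as.integer(linkedCluster),
    clusterSpacing = as.integer(clusterSpacing),
    freqRange = freqRange, meanDepth = meanDepth, depthSize = depthSize,
    errorRate = errorRate, knownFrac = knownFrac,
    nExons = as.integer(nExons), cnvEvents = cnvEvents,
    seed = as.integer(seed)), class = "SimConfig")
}

#' @noRd
.randomAlleles <- function(n) {
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  shift <- sample(1:3, n, replace = TRUE)
  alt <- bases[(match(ref, bases) - 1 + shift) %% 4 + 1]
  cbind(ref, alt)
}

#' Drop genotypes through the pedigree
#'
#' Gene-dropping simulation: founder haplotypes are drawn per marker from
#' the configured allele frequencies under Hardy-Weinberg and linkage
#' equilibrium; each non-founder receives one haplotype per parent with
#' free recombination between markers (single-point analysis never uses
#' inter-marker linkage). The causal variant and its linked cluster ride
#' on one haplotype of the affected founder and are transmitted with
#' theta = 0, conditioned so that carrier status equals affection status
#' exactly (full-penetrance dominant model). Genotype errors are then
#' injected in sequenced members at the configured rate, with degraded GQ
#' so that QC filters are exercised.
#'
#' @param config a [simConfig()].
#' @return list with \code{panel} (annotated WES
#'   \linkS4class{GenotypePanel} over the sequenced members) and
#'   \code{truth} (marker table with simulated frequencies and causal /
#'   cluster flags, full 13-member dosage matrix, carrier set, injected
#'   error positions).
#' @export
geneDrop <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  .withSeed(config$seed, {
    ped <- config$pedigree
    df <- ped@members
    nAll <- config$nMarkers + config$nIndels
    nClust <- config$linkedCluster + 1L
    nRand <- nAll - nClust

    chromP <- .AUTOSOME_LENGTHS / sum(.AUTOSOME_LENGTHS)
    chrom <- sample(names(.AUTOSOME_LENGTHS), nRand, replace = TRUE,
                    prob = chromP)
    pos <- 1L + as.integer(floor(runif(nRand) * .AUTOSOME_LENGTHS[chrom]))
    freq <- runif(nRand, config$freqRange[1], config$freqRange[2])
    isIndel <- c(rep(FALSE, config$nMarkers - nClust),
                 rep(TRUE, config$nIndels))

    # causal variant plus fully linked family-private cluster
    off <- c(0L, (seq_len(config$linkedCluster) -
                    (config$linkedCluster %/% 2 + 1L)) *
               config$clusterSpacing)
    off <- off[seq_len(nClust)]
    off[-1][off[-1] >= 0] <- off[-1][off[-1] >= 0] + config$clusterSpacing
    clChrom <- rep(config$causalChrom, nClust)
    clPos <- config$causalPos + sort(off)
    causalRow <- which(sort(off) == 0L)

    chrom <- c(chrom, clChrom)
    pos <- c(pos, as.integer(clPos))
    freq <- c(freq, rep(0.005, nClust))
    isIndel <- c(isIndel, rep(FALSE, nClust))
    clusterFlag <- c(rep(FALSE, nRand), rep(TRUE, nClust))
    causalFlag <- c(rep(FALSE, nRand),
                    seq_len(nClust) == causalRow)

    ord <- .genomeOrder(chrom, pos)
    chrom <- chrom[ord]; pos <- pos[ord]; freq <- freq[ord]
    isIndel <- isIndel[ord]; clusterFlag <- clusterFlag[ord]
    causalFlag <- causalFlag[ord]
    n <- nAll
    al <- .randomAlleles(n)
    ref <- al[, "ref"]; alt <- al[, "alt"]
    ref[isIndel] <- paste0(ref[isIndel],
                           vapply(which(isIndel), function(i)
                             paste(sample(c("A", "C", "G", "T"),
                                          sample(1:3, 1), replace = TRUE),
                                   collapse = ""), character(1)))
    markerId <- sprintf("%s:%d_%s/%s", chrom, pos, ref, alt)
    clIdx <- which(clusterFlag)

    # founder haplotypes under HWE; cluster variants private to the
    # affected founder's first haplotype
    affFounder <- intersect(df$id[df$affection == "affected"],
                            founders(ped))
    carriers <- df$id[df$affection == "affected"]
    hap1 <- hap2 <- matrix(0L, n, nrow(df),
                           dimnames = list(NULL, df$id))
    carrierHap <- setNames(integer(nrow(df)), df$id)  # 0 none, 1, 2
    for (id in founders(ped)) {
      hap1[, id] <- rbinom(n, 1L, freq)
      hap2[, id] <- rbinom(n, 1L, freq)
      hap1[clIdx, id] <- 0L
      hap2[clIdx, id] <- 0L
    }
    hap1[clIdx, affFounder] <- 1L
    carrierHap[affFounder] <- 1L

    # transmit in pedigree order (parents precede children by
    # construction of the member table; enforce topologically)
    done <- setNames(is.na(df$father), df$id)
    pending <- df$id[!done]
    while (length(pending)) {
      for (id in pending) {
        f <- df$father[match(id, df$id)]
        m <- df$mother[match(id, df$id)]
        if (!done[f] || !done[m]) next
        isCarrier <- id %in% carriers
        pick <- function(parent) {
          bits <- rbinom(n, 1L, 0.5)  # 0 -> hap1, 1 -> hap2
          if (carrierHap[parent] > 0) {
            want <- if (isCarrier && parent == .carrierParent(df, id,
                                                             carriers))
              carrierHap[parent] - 1L else
                2L - carrierHap[parent]
            bits[clIdx] <- want
          }
          ifelse(bits == 0L, hap1[, parent], hap2[, parent])
        }
        hap1[, id] <- pick(f)
        hap2[, id] <- pick(m)
        if (isCarrier) {
          cp <- .carrierParent(df, id, carriers)
          carrierHap[id] <- if (cp == f) 1L else 2L
        }
        done[id] <- TRUE
      }
      left <- df$id[!done]
      if (identical(left, pending))
        .stopf("unresolvable pedigree order")
      pending <- left
    }

    dosAll <- hap1 + hap2
    seqIds <- sequencedIds(ped)
    dos <- dosAll[, seqIds, drop = FALSE]

    # genotype errors + QC metadata
    gq <- matrix(99, n, length(seqIds), dimnames = list(NULL, seqIds))
    errs <- matrix(FALSE, n, length(seqIds))
    if (config$errorRate > 0) {
      errs <- matrix(rbinom(n * length(seqIds), 1L,
                            config$errorRate) == 1L, n, length(seqIds))
      if (any(errs)) {
        shift <- sample(1:2, sum(errs), replace = TRUE)
        dos[errs] <- (dos[errs] + shift) %% 3L
        gq[errs] <- round(runif(sum(errs), 5, 40))
      }
    }
    depth <- matrix(pmax(1, rnbinom(n * length(seqIds),
                                    mu = config$meanDepth,
                                    size = config$depthSize)),
                    n, length(seqIds), dimnames = list(NULL, seqIds))

    ann <- .simAnnotation(n, chrom, pos, ref, alt, isIndel, clusterFlag,
                          causalFlag, config$knownFrac)
    panel <- GenotypePanel(dos, chrom = chrom, pos = pos, ref = ref,
                           alt = alt, markerId = markerId,
                           platform = "wes", altFreq = NA_real_,
                           depth = depth, gq = gq,
                           rowData = DataFrame(
                             gene = ann$gene, effect = ann$effect,
                             hgvsC = ann$hgvs_c, hgvsP = ann$hgvs_p,
                             knownId = ann$known_id,
                             popFreq = ann$pop_freq,
                             type = ifelse(isIndel, "indel", "snv")))
    errIdx <- which(errs, arr.ind = TRUE)
    truth <- list(
      markers = data.frame(
        markerId = markerId, chrom = chrom, pos = pos, ref = ref,
        alt = alt, freq = freq, type = ifelse(isIndel, "indel", "snv"),
        causal = causalFlag, cluster = clusterFlag,
        stringsAsFactors = FALSE),
      dosageAll = dosAll,
      carriers = carriers,
      causalId = markerId[causalFlag],
      clusterIds = markerId[clusterFlag],
      errors = data.frame(markerId = markerId[errIdx[, 1]],
                          sample = seqIds[errIdx[, 2]],
                          stringsAsFactors = FALSE),
      annotation = ann)
    list(panel = panel, truth = truth)
  })
}

#' @noRd
.carrierParent <- function(df, id, carriers) {
  f <- df$father[match(id, df$id)]
  m <- df$mother[match(id, df$id)]
  if (f %in% carriers) f else m
}

#' @noRd
.simAnnotation <- function(n, chrom, pos, ref, alt, isIndel, clusterFlag,
                           causalFlag, knownFrac) {
  gene <- sprintf("%sg%d", sub("^chr", "G", chrom), pos %/% 200000L)
  effect <- character(n)
  effect[!isIndel] <- sample(
    c("nonsynonymous", "synonymous", "stopgain", "splicing", "other"),
    sum(!isIndel), replace = TRUE, prob = c(0.46, 0.44, 0.02, 0.03, 0.05))
  effect[isIndel] <- sample(c("frameshift", "nonframeshift"),
                            sum(isIndel), replace = TRUE)
  aa <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  cpos <- sample.int(3000L, n, replace = TRUE)
  hgvs_c <- ifelse(isIndel,
                   sprintf("c.%ddel%s", cpos, substr(ref, 2, nchar(ref))),
                   sprintf("c.%d%s>%s", cpos, ref, alt))
  hgvs_p <- rep(NA_character_, n)
  aaChanging <- effect %in% .CODING_EFFECTS
  hgvs_p[aaChanging] <- sprintf(
    "p.%s%d%s", sample(aa, sum(aaChanging), replace = TRUE),
    (cpos[aaChanging] - 1L) %/% 3L + 1L,
    ifelse(effect[aaChanging] == "frameshift", "fs",
           sample(aa, sum(aaChanging), replace = TRUE)))
  known <- runif(n) < knownFrac
  known_id <- ifelse(known, sprintf("rs%d", sample.int(99999999L, n)),
                     NA_character_)
  pop_freq <- ifelse(known, signif(runif(n, 0.001, 0.5), 2), NA_real_)
  # the implanted cluster is family-private and novel; the causal variant
  # is nonsynonymous, its companions alternate synonymous/nonsynonymous
  cl <- which(clusterFlag)
  known_id[cl] <- NA_character_
  pop_freq[cl] <- NA_real_
  companions <- setdiff(cl, which(causalFlag))
  effect[companions] <- rep(c("synonymous", "nonsynonymous"),
                            length.out = length(companions))
  effect[causalFlag] <- "nonsynonymous"
  gene[causalFlag] <- "DISG1"
  hgvs_p[cl] <- ifelse(effect[cl] %in% .CODING_EFFECTS,
                       sprintf("p.%s%d%s",
                               sample(aa, length(cl), replace = TRUE),
                               (cpos[cl] - 1L) %/% 3L + 1L,
                               sample(aa, length(cl), replace = TRUE)),
                       NA_character_)
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt, gene = gene,
             effect = effect, hgvs_c = hgvs_c, hgvs_p = hgvs_p,
             known_id = known_id, pop_freq = pop_freq,
             stringsAsFactors = FALSE)
}

#' Simulate the per-exon depth matrix
#'
#' Lays out \code{nExons} exon intervals over the autosomes (log-normal
#' lengths around ~180 bp) and draws each exon x sample depth from a
#' negative binomial with mean
#' \eqn{\mathrm{meanDepth} \times s_j \times e_i \times c_{ij}/2}
#' (sample factor \eqn{s_j}, exon capture factor \eqn{e_i}, true copy
#' number \eqn{c_{ij}}): depth scales linearly with copy number, which is
#' what makes exome read depth usable for CNV inference. Copy numbers are
#' 2 except at the configured implanted events.
#'
#' @param config a [simConfig()].
#' @return An \linkS4class{ExonCoverage} over the sequenced samples;
#'   \code{metadata()} carries \code{trueCopyNumber} (exon x sample
#'   matrix) and \code{events}.
#' @export
simulateCoverage <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  .withSeed(config$seed + 7919L, {
    ped <- config$pedigree
    seqIds <- sequencedIds(ped)
    nE <- config$nExons
    chrom <- sample(names(.AUTOSOME_LENGTHS), nE, replace = TRUE,
                    prob = .AUTOSOME_LENGTHS / sum(.AUTOSOME_LENGTHS))
    len <- pmin(pmax(round(rlnorm(nE, log(180), 0.35)), 80L), 2000L)
    start <- 1L + as.integer(floor(runif(nE) *
                                     (.AUTOSOME_LENGTHS[chrom] - len)))
    ord <- .genomeOrder(chrom, start)
    chrom <- chrom[ord]; start <- start[ord]; len <- len[ord]
    name <- sprintf("exon%05d", seq_len(nE))

    cn <- matrix(2L, nE, length(seqIds), dimnames = list(name, seqIds))
    for (ev in config$cnvEvents) {
      carr <- intersect(ev$carriers, seqIds)
      cn[ev$exons, carr] <- as.integer(ev$cn)
    }
    exonFac <- rlnorm(nE, -0.08, 0.4)
    sampFac <- rlnorm(length(seqIds), -0.00125, 0.05)
    mu <- config$meanDepth * outer(exonFac, sampFac) * cn / 2
    depth <- matrix(rnbinom(length(mu), mu = pmax(mu, 1e-9),
                            size = config$depthSize),
                    nE, length(seqIds), dimnames = list(name, seqIds))
    cov <- ExonCoverage(depth, chrom = chrom, start = start,
                        end = start + len - 1L, name = name)
    metadata(cov)$trueCopyNumber <- cn[rownames(cov), , drop = FALSE]
    metadata(cov)$events <- config$cnvEvents
    cov
  })
}

#' Subsample an array-style validation panel from a gene drop
#'
#' Emulates the second genotyping platform of the study design: a subset
#' of the markers, genotyped without sequencing QC metadata, on the
#' sequenced members plus additional family members. The causal cluster
#' is retained by default (the validation platform covered the candidate
#' loci).
#'
#' @param drop output of [geneDrop()].
#' @param config the [simConfig()] used for the drop.
#' @param extraSubjects additional pedigree members genotyped on the
#'   array.
#' @param fraction fraction of SNV markers retained.
#' @param keepCluster always retain the causal cluster markers.
#' @return A \linkS4class{GenotypePanel} with \code{platform = "array"}.
#' @export
arrayPanel <- function(drop, config,
                       extraSubjects = c("III-1", "III-2", "III-4"),
                       fraction = 0.3, keepCluster = TRUE) {
  .withSeed(config$seed + 104729L, {
    tm <- drop$truth$markers
    ped <- config$pedigree
    subj <- intersect(c(sequencedIds(ped), extraSubjects),
                      pedigreeIds(ped))
    snv <- which(tm$type == "snv")
    keep <- snv[runif(length(snv)) < fraction]
    if (keepCluster) keep <- sort(union(keep, which(tm$cluster)))
    dos <- drop$truth$dosageAll[keep, subj, drop = FALSE]
    GenotypePanel(dos, chrom = tm$chrom[keep], pos = tm$pos[keep],
                  ref = tm$ref[keep], alt = tm$alt[keep],
                  markerId = tm$markerId[keep], platform = "array")
  })
}

#' Write a complete synthetic fixture to disk
#'
#' Runs [geneDrop()] and [simulateCoverage()] and writes the full input
#' file set consumed by the pipeline readers -- PED pedigree, multi-sample
#' VCF (GT:DP:GQ), annotation sidecar TSV, exon BED, per-exon depth TSV,
#' array genotype TSV -- plus ground-truth sidecars
#' (\code{truth_variants.tsv}, \code{truth_exons.tsv}) for recovery
#' checks. All files are plain text.
#'
#' @param config a [simConfig()].
#' @param dir output directory (created if needed).
#' @return invisible list of file paths plus the in-memory \code{drop},
#'   \code{coverage} and \code{arrayPanel} objects.
#' @export
emitFixture <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  drop <- geneDrop(config)
  cov <- simulateCoverage(config)
  arr <- arrayPanel(drop, config)
  ped <- config$pedigree
  paths <- list(
    ped = file.path(dir, "family.ped"),
    vcf = file.path(dir, "variants.vcf"),
    annotation = file.path(dir, "annotation.tsv"),
    bed = file.path(dir, "exons.bed"),
    depth = file.path(dir, "depth.tsv"),
    array = file.path(dir, "array_panel.tsv"),
    truthVariants = file.path(dir, "truth_variants.tsv"),
    truthExons = file.path(dir, "truth_exons.tsv"))
  writePed(ped, paths$ped)
  .writeVcf(drop$panel, paths$vcf)
  ann <- drop$truth$annotation
  ann$pop_freq <- ifelse(is.na(ann$pop_freq), "-",
                         format(ann$pop_freq, trim = TRUE))
  ann$known_id[is.na(ann$known_id)] <- "-"
  ann$hgvs_p[is.na(ann$hgvs_p)] <- "-"
  write.table(ann, paths$annotation, sep = "\t", quote = FALSE,
              row.names = FALSE)
  gr <- rowRanges(cov)
  bed <- data.frame(chrom = as.character(seqnames(gr)),
                    start = start(gr) - 1L, end = end(gr),
                    name = rownames(cov))
  write.table(bed, paths$bed, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  writeDepthTsv(cov, paths$depth)
  writeGenotypeTsv(arr, paths$array)
  write.table(drop$truth$markers[drop$truth$markers$cluster, ],
              paths$truthVariants, sep = "\t", quote = FALSE,
              row.names = FALSE)
  cnTruth <- metadata(cov)$trueCopyNumber
  aberr <- which(cnTruth != 2L, arr.ind = TRUE)
  write.table(data.frame(exon = rownames(cnTruth)[aberr[, 1]],
                         sample = colnames(cnTruth)[aberr[, 2]],
                         cn = cnTruth[aberr]),
              paths$truthExons, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(paths, list(drop = drop, coverage = cov,
              arrayPanel = arr)))
}

#' @noRd
.writeVcf <- function(panel, file) {
  gr <- rowRanges(panel)
  rd <- rowData(panel)
  dos <- assay(panel, "dosage")
  dp <- assay(panel, "depth")
  gq <- assay(panel, "gq")
  gt <- matrix("./.", nrow(dos), ncol(dos))
  gt[!is.na(dos) & dos == 0L] <- "0/0"
  gt[!is.na(dos) & dos == 1L] <- "0/1"
  gt[!is.na(dos) & dos == 2L] <- "1/1"
  cells <- matrix(paste0(gt, ":", as.integer(dp), ":", as.integer(gq)),
                  nrow(dos), ncol(dos))
  body <- cbind(as.character(seqnames(gr)), start(gr), rd$markerId,
                rd$ref, rd$alt, ".", "PASS", ".", "GT:DP:GQ", cells)
  hdr <- c("##fileformat=VCFv4.2",
           "##source=famphase synthetic family exome",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
           '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", colnames(dos)), collapse = "\t"))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(file)
}
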