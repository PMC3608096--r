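---
title: "Multiphasic family whole-exome analysis: models, parameters and design"
author: "famphase maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiphasic family whole-exome analysis: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famphase)
```

# The problem

A single family segregates a rare, fully penetrant autosomal dominant
phenotype (the motivating case is nonsyndromic hearing loss). Whole-exome
sequencing of a handful of members is the only data source, and the
question is which of the ~20,000 called variants is causal. One line of
evidence is rarely decisive at this sample size, so the package computes
three quasi-independent ones from the same exome run and intersects them:

1. **Exon copy number.** Read depth varies linearly with copy number, so
   per-exon depth ratios give gain/normal/loss calls, and an exact test
   asks whether abnormal states co-segregate with affection.
2. **Single-point parametric linkage.** Every exome SNV is a biallelic
   marker; the pedigree likelihood under a dominant disease model yields a
   LOD score per marker, and clusters of high-LOD markers ("hot spots")
   are candidate loci.
3. **Variant co-segregation.** Variants are pushed through a
   QC/effect/segregation funnel; survivors inside hot spots form the
   candidate table.

# The linkage model

For a marker with alleles (ref, alt) and a biallelic disease locus, each
haplotype is a pair (disease allele, marker allele); an individual's
two-locus genotype is an ordered haplotype pair (16 states). The
likelihood of observed marker dosages and affection statuses is

* founders: Hardy–Weinberg and linkage-equilibrium haplotype priors with
  disease allele frequency $q$ and marker allele frequency $p$;
* non-founders: one haplotype per parent, transmitted intact with
  probability $(1-\theta)/2$ each or recombined with probability
  $\theta/2$ each;
* phenotyped members: penetrance factors $f_i = P(\text{affected} \mid i$
  disease alleles$)$; members with equivocal ("unknown") affection
  contribute no penetrance factor.

$LOD = \log_{10} L(\theta) - \log_{10} L(0.5)$. Following the study
convention, $\theta$ is fixed (default 0), never maximised over. The
default model is $(f_0,f_1,f_2) = (0,1,1)$, $q = 10^{-5}$.

The likelihood is evaluated exactly by Elston–Stewart peeling over
nuclear families (compiled code, log-rescaled per family so 13-member
pedigrees with $q = 10^{-5}$ cannot underflow). The peeling schedule
exists for any loop-free pedigree; loops are rejected with an error. The
test suite checks the engine against an independent brute-force
enumeration over founder genotypes and transmission indicators, and
against the textbook closed form for a phase-unknown fully informative
marker: $n$ perfectly co-segregating meioses give
$(n-1)\log_{10} 2$ — 1.50515 for the study design's six informative
meioses, which is why the hot-spot threshold of 1.5 sits just below the
attainable maximum.

**Marker allele frequencies.** The source data do not state per-marker
frequencies. Frequencies only enter through founder priors, which cancel
from the LOD whenever the founders are genotyped; the default therefore
estimates them from genotyped founders (fallback 0.5 when fewer than two
founders are genotyped), clamped away from 0 and 1.

**QC boundary.** Genotypes are dropped when depth or GQ fall below the
thresholds; the default keeps depth $\ge 10$ and GQ $\ge 30$, which
reconciles "below 10× is excluded" with "greater than 10 is kept" in the
usual tool descriptions. `strict = TRUE` switches to the strict reading
(`> 10`, `> 30`). Sex chromosomes are excluded from linkage entirely (no
X-linked model).

**Hot spots.** Markers with LOD ≥ 1.5 on one chromosome are merged when
consecutive high markers are ≤ 10 Mb apart; clusters need ≥ 2 markers.
The 10 Mb gap and 2-marker minimum are this package's defaults (the
smallest reported candidate locus in the motivating study contained two
exons); isolated single-marker peaks are indistinguishable from chance
perfect co-segregation, which in an eight-member family occurs at a rate
of roughly 0.6–0.9% per marker.

# The CNV model

Per-exon mean depths are library-size corrected (per-sample totals scaled
to their mean), and each sample's ratio is taken against the
*leave-one-out* median of the other samples at that exon. A sample never
sits in its own control baseline — the convention of external-baseline
exome CNV callers — because with a shared all-sample median an event
carried by half the family drags the baseline toward itself, halving the
log2 signal for carriers and pushing non-carriers ~+0.4: exactly the
co-segregating events the scan exists to find would be the ones it
attenuates. The all-sample median is still computed and reported per exon;
it drives masking (baseline < 10 reads is uncallable) and depth binning.

Ratios are tested per depth bin (20 equal-occupancy baseline bins, bins
under 10 exons merged) with a robust z score (bin median, MAD × 1.4826)
and a two-sided normal p-value. States follow the sign rule: gain iff
$p < \alpha$ and ratio > 0, loss iff $p < \alpha$ and ratio < 0, with
$\alpha = 0.05$.

Per exon, the 3×2 table of states × affection is tested with Fisher's
exact test, computed by full enumeration of tables with the observed
margins under probability ordering (ties included at relative tolerance
1e-12). For four affected and four unaffected members the most extreme
attainable p-value is $2/70 \approx 0.0286$; the test is conservative,
so phenotype-permuted null data show a rejection rate well below
$\alpha$ (the calibration tests assert the one-sided bound
$\le \alpha + 3\,SE$, which is the property exactness guarantees —
discrete tables cannot achieve the nominal rate from below and above).
Group labels are configurable so the scan can be validated on arbitrary
two-group partitions of the samples, not only affection.

# The variant funnel

`qcFilter` (every sequenced member ≥ 10×, GQ ≥ 30), `knownFilter`,
`effectFilter` (amino-acid-changing classes), `segregationFilter`
(dosage ≥ 1 in all sequenced affected, 0 in all sequenced unaffected;
unknown-affection members unconstrained; any missing genotype among
constrained members drops the variant — a lost true positive can be
recovered by relaxing QC, a false positive cannot), then intersection
with hot-spot intervals.

`knownFilter` defaults to `annotate_only`: in a family design the
decisive filter is co-segregation, and genuinely causal variants can be
absent from databases while several co-segregating candidates are common
polymorphisms — a hard novelty filter is therefore kept optional
(`drop_known`) rather than default.

# The synthetic family generator

No patient data are deposited for this design, so the generator produces
complete inputs with the statistical structure the analysis assumes. The
defaults are the emulated study conditions and are not tuned per run:

* 13-member, 3-generation pedigree; 8 sequenced (both founders + six
  siblings; 4 affected including the transmitting founder, 4 unaffected);
  one married-in spouse with equivocal phenotype; 4 grandchildren.
* 18,000 autosomal coding SNVs plus 430 indels; allele frequencies
  uniform on (0.05, 0.95); linkage equilibrium between markers (free
  recombination), since single-point analysis never uses inter-marker
  linkage.
* A causal nonsynonymous variant at chr17:79,478,000 carried het by every
  affected member (full penetrance conditions carrier status on the
  prespecified affection pattern; a configuration demanding affected
  non-carriers is rejected). Two additional family-private variants
  250 kb away ride the same founder haplotype at $\theta = 0$. Real
  candidate loci are LD blocks of co-segregating exonic variants (the
  motivating study's chr17 hot spot contained 13 exons); with fully
  unlinked markers the causal locus would form a ≥ 2-marker hot spot only
  by chance (~50% of runs), so a minimal linked cluster is part of the
  emulated conditions rather than a free parameter.
* Depth: negative binomial with mean 45× (the study's samples averaged
  40–51×), size 200, log-normal exon capture factors (sdlog 0.4) and
  per-sample factors (sdlog 0.05); per-exon depth scales linearly with
  copy number. The implied null log2-ratio spread is ≈ 0.24 at 45×,
  typical of within-family exome data after normalisation.
* Default CNV events: a 3-exon single-copy loss in II-3/II-7 and a 3-exon
  single-copy gain in I-2/II-9 — non-co-segregating, like the
  copy-variable loci (defensin cluster, GSTM1-type deletions) such
  families actually show.
* Genotype errors (default rate 0) replace the true dosage with a random
  other value and degrade GQ to uniform(5, 40), so the QC filters are
  exercised; correct genotypes carry GQ 99.

What the generator does **not** emulate: LD structure beyond the causal
cluster, GC-dependent coverage bias, base-level breakpoints inside exons,
population stratification, and calling artefacts correlated across
samples. Passing tests therefore demonstrate correctness of the
statistical machinery under the stated model, not robustness to every
artefact of real exome data.

# Numerical choices and degenerate inputs

* Likelihoods are carried in log space with per-family rescaling;
  a marker impossible under both hypotheses is dropped from scans with a
  message, and one impossible only at the test $\theta$ (LOD $-\infty$)
  is floored at −99 so tracks stay finite.
* Bin MAD of exactly 0 (constant ratios) is floored at 1e-8, so identical
  samples give z = 0 and p = 1 rather than 0/0.
* A zero depth at a callable exon is floored at half a read before the
  log; a zero or sub-threshold baseline masks the exon entirely.
* The state rule is strict at the $\alpha$ boundary: $p \ge \alpha$ is
  always "normal".
* Allele-swapped markers between two platforms are recoded ($d \to 2-d$)
  and flagged; the harmonisation is deliberately loud (message + rowData
  flag) because a silent strand flip corrupts dosages undetectably.
* Ties at the track maximum are expected: 1.50515 is the attainable
  ceiling for this design, reached by the causal cluster and occasionally
  by chance co-segregators.

# Problem sizes used by the validation suite

The acceptance tests run the full default generator (18,000 markers,
5,000 exons) for the 100-run end-to-end recovery checks and 200-replicate
CNV recovery checks; oracle-equivalence uses 200 random pedigrees of 3–8
members (the largest paired with $\theta = 0$, where the enumeration
oracle's state space stays tractable); null calibration uses 1,000
phenotype permutations over a 2,000-exon event-free matrix and the
~18,000 unlinked markers of one default drop as independent null
replicates of the per-marker LOD exceedance rate. These sizes were chosen
so each property is measured with standard errors well below the margins
being asserted.

# Known limitations

* Single-copy **gains** are intrinsically harder than losses for a
  depth-ratio test: the expected signal is $\log_2 1.5 \approx 0.585$
  against $-1$ for a loss, so at 45× with realistic exon-to-exon capture
  variability the per-carrier sensitivity of a 3-exon gain is ≈ 85%
  (losses: ~100%, measured over 200 seeded replicates). Reliable gain
  detection needs deeper coverage or longer events; the package reports
  this honestly rather than inflating power by narrowing the null spread.
* Single-point linkage only; no multipoint, no haplotype reconstruction,
  no X-linked or imprinting models.
* The CNV caller is a per-exon depth-ratio test: it makes no attempt at
  base-level breakpoints, GC correction, or integer copy-number
  genotyping of highly duplicated loci — the pluggable `CnvCalls`
  container accepts calls from any external per-exon caller.
* The co-segregation scan treats family members as independent samples in
  the contingency table (the study's own stated simplification); p-values
  are exact for the table but not corrected for relatedness.
* `segregationFilter` implements strict full-penetrance dominance;
  phenocopies or reduced penetrance require relaxing it by lowering QC or
  using the unintersected candidate list.
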