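Package: famphase
Title: Multiphasic Family Whole-Exome Analysis: CNV Co-Segregation,
    Single-Point Parametric Linkage, and Variant Segregation Filtering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for gene discovery in single families with a dominant
    Mendelian phenotype from whole-exome sequencing alone. Implements
    per-exon read-depth copy-number calling with an exact 3x2 Fisher
    co-segregation scan, exact single-point parametric linkage analysis
    (two-locus Elston-Stewart pedigree likelihood over exome SNV markers,
    LOD scores, hot-spot clustering), a Mendelian co-segregation variant
    filter funnel intersected with linkage hot spots, and a gene-dropping
    simulator that generates complete synthetic family-exome data sets
    (pedigree, multi-sample VCF, annotation sidecar, exon intervals and
    depth matrices) for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
biocViews: Genetics, CopyNumberVariation, VariantAnnotation, Sequencing,
    LinkageDisequilibrium
RoxygenNote: 7.3.3
Collate: 
    'utils.R'
    'AllClasses.R'
    'RcppExports.R'
    'pedigree.R'
    'coverage.R'
    'cnv.R'
    'famphase-package.R'
    'likelihood.R'
    'panels.R'
    'lod.R'
    'synthdata.R'
    'snvfilter.R'
    'pipeline.R'
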