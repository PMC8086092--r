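Package: emscan
Title: Candidate Dwarfing-Gene Discovery from EMS Mutant RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for mapping candidate causal genes in an EMS-mutagenized
    plant line from RNA-seq of mutant and wild-type replicates. Implements
    the three-step homozygous-SNP filter (depth, replicate support,
    heterozygosity, group difference), transition/transversion substitution
    spectrum statistics, codon-aware synonymous/nonsynonymous effect
    annotation against gene models, an exact conditional binomial
    differential-expression contrast with Benjamini-Hochberg FDR,
    hypergeometric pathway enrichment with Bonferroni correction,
    2^-ddCt relative quantification, lodging-index phenotype arithmetic,
    and the SNP-by-DEG candidate intersection. A seeded synthetic-study
    generator (genome, gene models, variant calls, counts, Ct values)
    with planted truth makes the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
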