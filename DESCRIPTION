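Package: panelGWAS
Title: Mixed-Model Association Mapping and Population-Genetic Summaries
    for Structured Inbred Diversity Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for genome-wide association analysis in structured,
    near-homozygous diversity panels such as rice landrace collections.
    Provides a SummarizedExperiment-based genotype container with
    marker/line filters, an EMMAX-style kinship linear mixed model with
    variance decomposition of marker, covariate and polygenic terms,
    SNP-covariate conditioning and epistatic interaction scans, formulaic
    QTL peak calling, principal components, linkage-disequilibrium decay,
    site-frequency spectra, private/shared SNP accounting, extended
    haplotype grouping, GFF3-based SNP functional annotation, broad-sense
    heritability from replicated multi-environment trials, and a
    Balding-Nichols panel simulator with planted trait architectures for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer,
    Biostrings,
    data.table,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
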