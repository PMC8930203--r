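Package: sexkaryo
Title: Genetic Sex and Sex-Chromosome Karyotype Inference from Sequencing Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Infers genetic sex from targeted-panel, exome, or genome
    sequencing data and screens cohorts for sex-chromosome aneuploidies.
    Five sex-associated features (X-chromosome heterozygosity, the fractions
    of high-quality reads mapping to X and Y, their ratio, and mean read
    depth over the SRY gene) are extracted from BAM and VCF files, scaled,
    and clustered with a two-component Gaussian mixture model fitted by
    expectation-maximization. Each sample is then classified into one of six
    sex-chromosome karyotypes (XX, XY, XYY, XXY, XXX, X) through explicit
    statistical gates on the X/Y read-mapping fractions. Includes a
    synthetic-cohort simulator and miniature BAM/VCF fixture writers for
    fully self-contained validation, plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation,
    methods,
    parallel,
    stats,
    tools,
    utils
Suggests:
    ggplot2,
    jsonlite,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
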