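Package: crosspaint
Title: Parental Genome Contribution and Graphical Genotypes for Biparental Crosses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies each parent's genomic contribution to the progeny of a
    biparental diploid cross from a multi-sample VCF. Identifies informative
    SNPs (sites where the two parents are homozygous for different alleles),
    classifies every progeny genotype at those sites as homozygous parent A,
    homozygous parent B, or heterozygous, optionally corrects sporadic
    genotyping errors with an iterative sliding-window majority filter, and
    tallies allele counts into per-chromosome and genome-wide contribution
    percentages. Renders scale-true chromosome ideograms as stacked-proportion
    bins colored by parental origin, with optional gene or marker annotation
    overlays, exported as deterministic SVG or rasterized PNG/JPEG. Ships a
    seeded biparental-cross simulator (F1, F2, backcross, recombinant inbred
    lines) that emits standard VCF plus a ground-truth ancestry table, so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    grid,
    jsonlite,
    parallel,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
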