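Package: markercmp
Title: Comparing Microsatellite and SNP Panels for Population Genetic Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis tools for comparing the performance of
    multiallelic microsatellite panels against large biallelic SNP panels in
    small, structured populations. Provides a Balding-Nichols/pedigree genotype
    simulator with known family structure, Genepop and VCF input/output, a
    reproducible marker and individual quality-filter chain, population
    diversity summaries (allele counts, rarefied allelic richness, expected
    heterozygosity, Hardy-Weinberg tests), Nei F_ST with permutation tests,
    linkage-disequilibrium effective population size with jackknife confidence
    intervals and a chromosome-number bias correction, allele-sharing
    relatedness (Bxy) with locus-subset precision curves, pairwise sibship
    classification from IBD-coefficient mixture likelihoods with marker-specific
    genotyping error, and standardized multilocus heterozygosity with
    heterozygosity-heterozygosity correlations.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    igraph,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
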