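Package: baleenpop
Title: Population-Genomic Diagnostics from Small Numbers of Whole Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Whole-genome population diagnostics for studies with very few
    sequenced individuals, as is common for endangered marine mammals. Provides
    genotype-table ingestion from VCF with depth and scaffold filters,
    per-individual heterozygosity and its conversion to equilibrium effective
    population size (theta = 4 Ne mu), detection of runs of homozygosity with
    window-based scanning and F_ROH inbreeding summaries, pairwise
    identity-by-state relatedness with the pairwise population concordance
    binomial test, the four-taxon ABBA-BABA D-statistic with weighted
    block-jackknife standard errors and topology rotation tests, preparation and
    bootstrap resampling of multihetsep input for sequentially-Markovian
    coalescent inference together with rescaling of its output to calendar years
    and diploid effective sizes, trapezoidal environmental-envelope habitat
    scoring on gridded layers, and seeded synthetic-data generators that emulate
    the statistical structure each analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    IRanges,
    stats,
    utils,
    vcfR
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
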