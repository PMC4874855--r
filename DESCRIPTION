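Package: ampliMHC
Title: Amplicon-Based MHC Genotyping and Diversity Analysis
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Genotypes multilocus MHC class IIB exon 2 alleles from MID-tagged
    amplicon deep-sequencing reads using frequency-based artifact filtering
    (maximum per-amplicon frequency and within-amplicon thresholds), flags
    pseudogene-like alleles, and computes downstream molecular-evolution and
    population-genetic summaries: partitioned dN/dS by the modified
    Nei-Gojobori method with Jukes-Cantor correction, Tamura-Nei and amino-acid
    p-distances, nucleotide diversity, Tajima's D, rarefied allelic richness,
    heterozygosities, randomization tests, and individual-level heterozygosity
    correlations. Includes a synthetic amplicon-read and genotype simulator
    with known truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    ape,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
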