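Package: pawprint
Title: Microsatellite and mtDNA D-Loop Diversity, Forensic Identification,
    and Marker-Panel Selection for Domestic Cat Breeds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Population-genetic analysis of diploid microsatellite genotypes
    and mitochondrial D-loop haplotypes, built around the marker panels used
    to survey domestic cat breeds. Computes per-locus diversity
    statistics (allele counts, rarefied allelic richness, heterozygosities,
    polymorphic information content, Hardy-Weinberg exact tests, null-allele
    and M-ratio diagnostics), population structure (Weir-Cockerham
    F-statistics, R_ST, Nei distance, AMOVA, relatedness, linkage
    disequilibrium), the forensic identification statistics used for
    individual and parentage testing (matching probability, probability of
    identity and its sibling and small-sample variants, probability of
    exclusion, genotype accumulation curves), ant-colony-optimized selection
    of minimal marker panels, and mtDNA D-loop diversity, differentiation,
    neutrality and mismatch-distribution statistics. A synthetic-data module
    generates genotype tables, pedigrees and haplotype alignments with known
    truth so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
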