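Package: mnpkit
Title: Multiple Nucleotide Polymorphism Markers for Fungal Strain Identification
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Discovers multiple nucleotide polymorphism (MNP) markers from
    multi-sample SNP callsets of cultivated fungi, genotypes strains at those
    markers from haplotype read counts, and quantifies pairwise genetic
    similarity for variety identification. Implements GATK-style hard-filter
    and allele-frequency quality control for VCF callsets, 100-bp sliding
    window marker discovery scored by polymorphism information content (PIC),
    haplotype genotyping with an allele-fraction heterozygote threshold, a
    portable genotype database with incremental strain addition, genetic
    similarity fingerprinting (GS = n/N x 100) with hierarchical clustering,
    a sequencing-depth titration study by binomial read thinning, an ISSR
    band-matrix comparator (Jaccard distance and linkage clustering), and a
    population simulator with known truth (subpopulations, F1 hybrid trios,
    clones, engineered marker sharing) so every stage is testable without
    external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
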