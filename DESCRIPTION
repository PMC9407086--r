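Package: ylineage
Title: Paternal Lineage Analysis from Y-STR Haplotypes and Y-SNP Haplogroups
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for forensic and population-genetic analysis of the male-specific
    Y chromosome. Computes per-locus gene diversity and the standard forensic summary
    parameters (haplotype diversity, match probability, discrimination capacity,
    fraction of unique haplotypes) of Y-STR haplotypes under the four common
    commercial typing panels; screens genotype tables for microvariant alleles,
    copy-number duplications and null calls; estimates pairwise Rst between
    populations by analysis of molecular variance on repeat scores, with
    multidimensional scaling and neighbor-joining tree construction; calls
    hierarchical Y-SNP haplogroups from a 24-marker panel with clade-level frequency
    aggregation and principal component analysis; and builds weighted median-joining
    haplotype networks with ancestral-haplotype inference. Includes a forward-time
    Wright-Fisher simulator of male lineages under the stepwise mutation model for
    validation and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    MASS,
    igraph,
    jsonlite,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
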