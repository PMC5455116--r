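Package: domesticscan
Title: Domestication Scans from Multi-Accession Variant Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for scanning crop genomes for the footprint of
    domestication using per-accession variant calls. Reads per-accession
    VCF files against a shared reference, applies a stringent
    depth/quality/homozygosity filter to wild accessions, and performs
    cohort set algebra: variants common to all accessions of a wild
    species, species-specific variants, positions variant in every wild
    accession (partitioned into shared-allele and discordant-allele
    positions), and common wild alleles absent from every cultivated
    accession. Variants are placed against gene models (genic, 2-kb
    flank, intergenic), coding effects are predicted by strand-aware
    codon translation (stop gain/loss, start loss, splice site,
    frameshift), and sliding-window selection statistics (nucleotide
    diversity, Watterson's theta, Tajima's D, Hudson's Fst) are computed
    in SNP-index windows, with threshold-passing windows merged into
    candidate selection regions and their resident genes reported. A
    synthetic-cohort simulator generates reference, annotation and VCF
    inputs with planted ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    vcfR,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
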