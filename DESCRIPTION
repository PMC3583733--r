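Package: ylineage
Title: Y-Chromosome Haplogroup Assignment from Whole-Genome SNP Calls
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Determines the Y-chromosome (sub-)haplogroup of a sample from a
    whole-genome SNP calling profile, a haplogroup tree and a marker
    conversion table, resolving each known marker to its ancestral, derived
    or other allelic state against the reference sequence, gating the search
    on a call-quality test that exploits the composite nature of the
    reference Y chromosome, and combining vertical, horizontal, combinatorial
    and most-specific tree searches into a final assignment in both the
    alphanumeric and mutation-based nomenclatures. Also converts VCF and
    Complete Genomics variant files into the profile format, reports markers
    in derived state that are absent from the tree in use, lists called SNPs
    with yet-unknown phylogenetic position, and ships a seeded synthetic
    fixture generator with a brute-force assignment oracle for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    utils,
    stats,
    Biostrings,
    IRanges,
    vcfR,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
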