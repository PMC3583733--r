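# Packaged fictive example: a small tree with haplogroups X, Y and Z and a
# sample belonging to sub-haplogroup Z2b3a, used throughout the
# documentation and tests to walk through every stage of the search.

#' Load the packaged fictive example
#'
#' A hand-built, deliberately small input bundle: a ten-node tree with main
#' haplogroups `X`, `Y` and `Z` (leaves `X1a`, `Y`, `Z1`, the paragroup
#' `Z2b*` and `Z2b3a`), a conversion table of thirteen markers (including
#' an indel, the default exclusions `V218`/`MEH2`, a tree-absent marker
#' `L999` and a marker without an hg19 position), a 1300 bp synthetic
#' reference and the call profile of a fictive individual belonging to
#' `Z2b3a` — with one false positive call on `X1a`, one derived `L999` call
#' and one novel SNP at position 1201. Running [assignHaplogroup()] on it
#' exercises every stage: vertical `{X1a, Z2b*, Z2b3a}`, horizontal
#' `{Z2b}`, combinatorial `{Z2b*, Z2b3a}`, final `{Z2b3a}`.
#'
#' @return named list with elements `tree`, `markers`, `reference`,
#'   `profile` and `dir` (the extdata directory the files were read from).
#' @export
fictiveFixture <- function() {
  dir <- system.file("extdata", "fictive", package = "ylineage",
                     mustWork = TRUE)
  list(tree = readTreeFile(file.path(dir, "tree.tsv")),
       markers = readConversionFile(file.path(dir, "conversion.tsv")),
       reference = readReferenceY(file.path(dir, "reference.fa"), "hg19"),
       profile = readProfile(file.path(dir, "profile.tsv"), "hg19",
                             sampleId = "fictive_Z2b3a"),
       dir = dir)
}
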