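# Reference Y-chromosome sequence: FASTA loading and 1-based base lookup.

#' Wrap a DNA sequence as a build-labelled reference
#'
#' @param sequence a [Biostrings::DNAString], or a character string coerced
#'   to one.
#' @param build `"hg18"` or `"hg19"`.
#' @return a [ReferenceSequence-class].
#' @export
ReferenceSequence <- function(sequence, build) {
  build <- match.arg(build, c("hg18", "hg19"))
  if (is.character(sequence)) sequence <- Biostrings::DNAString(sequence)
  new("ReferenceSequence", build = build, sequence = sequence)
}

#' Read the Y-chromosome record of a reference FASTA
#'
#' Picks the record whose ID (first whitespace token of the header) is the Y
#' chromosome: `Y`, `chrY` or `24`, case-insensitively; if none matches
#' exactly, the first ID containing a `Y`/`y` is used. Errors when no
#' candidate exists.
#'
#' @param path FASTA file path.
#' @param build `"hg18"` or `"hg19"` — the build of the reference.
#' @return a [ReferenceSequence-class].
#' @importFrom Biostrings readDNAStringSet DNAString
#' @export
readReferenceY <- function(path, build) {
  build <- match.arg(build, c("hg18", "hg19"))
  seqs <- Biostrings::readDNAStringSet(path)
  ids <- vapply(strsplit(names(seqs), "\\s+"), `[`, "", 1L)
  hit <- which(tolower(ids) %in% c("y", "chry", "24"))
  if (length(hit) == 0L) hit <- grep("y", ids, ignore.case = TRUE)
  if (length(hit) == 0L)
    stop("no Y-chromosome record found in ", path,
         " (IDs: ", paste(head(ids, 5L), collapse = ", "), ")")
  ReferenceSequence(seqs[[hit[1L]]], build)
}

#' Reference base(s) at 1-based position(s)
#'
#' @param reference a [ReferenceSequence-class].
#' @param positions integer vector of 1-based positions.
#' @return uppercase character vector, one base per position; `NA` for
#'   positions outside the sequence.
#' @importFrom IRanges IRanges
#' @export
baseAt <- function(reference, positions) {
  n <- length(reference@sequence)
  out <- rep(NA_character_, length(positions))
  ok <- !is.na(positions) & positions >= 1L & positions <= n
  if (any(ok)) {
    hits <- Biostrings::extractAt(
      reference@sequence, IRanges::IRanges(start = positions[ok], width = 1L))
    out[ok] <- toupper(as.character(hits))
  }
  out
}

#' Build label of a reference
#' @param reference a [ReferenceSequence-class].
#' @export
referenceBuild <- function(reference) reference@build

setMethod("length", "ReferenceSequence", function(x) length(x@sequence))

setMethod("show", "ReferenceSequence", function(object) {
  cat("ReferenceSequence (", object@build, "): ",
      length(object@sequence), " bp\n", sep = "")
})
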