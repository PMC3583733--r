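# SNP calling profile: construction, TSV round trip, lookups.

#' Build a SnpProfile from a call table
#'
#' Rows whose alleles are not single `A/C/G/T` bases are dropped (counted in
#' `nSkipped`); duplicate positions keep the first occurrence with a warning,
#' so merged call sets behave deterministically whatever the input order.
#'
#' @param calls data.frame with columns `position`, `ref_allele`,
#'   `obs_allele`.
#' @param build `"hg18"` or `"hg19"`.
#' @param sampleId sample label.
#' @param nSkipped rows already discarded upstream (added to the count).
#' @return a [SnpProfile-class].
#' @export
SnpProfile <- function(calls, build, sampleId = "sample", nSkipped = 0L) {
  build <- match.arg(build, c("hg18", "hg19"))
  df <- as.data.frame(calls, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) {
    df <- data.frame(position = integer(0), ref_allele = character(0),
                     obs_allele = character(0), stringsAsFactors = FALSE)
    return(new("SnpProfile", build = build, calls = df, sampleId = sampleId,
               nSkipped = as.integer(nSkipped)))
  }
  df$position <- suppressWarnings(as.integer(df$position))
  df$ref_allele <- toupper(as.character(df$ref_allele))
  df$obs_allele <- toupper(as.character(df$obs_allele))
  ok <- !is.na(df$position) & df$position >= 1L &
    .isSnpAllele(df$ref_allele) & .isSnpAllele(df$obs_allele)
  skipped <- sum(!ok) + as.integer(nSkipped)
  df <- df[ok, , drop = FALSE]
  dup <- duplicated(df$position)
  if (any(dup)) {
    warning(sum(dup), " duplicate position(s) in profile; keeping the first",
            " occurrence of each")
    df <- df[!dup, , drop = FALSE]
  }
  df <- df[order(df$position), , drop = FALSE]
  rownames(df) <- NULL
  new("SnpProfile", build = build, calls = df, sampleId = sampleId,
      nSkipped = skipped)
}

#' Read a SNP calling profile from TSV
#'
#' Headerless three-column layout: `position` (1-based), `ref_allele`,
#' `obs_allele` — the common denominator of SNP caller outputs. Rows with
#' multi-base alleles (indels) or an unparseable position are skipped and
#' counted in `nSkipped(profile)`; duplicate positions keep the first
#' occurrence with a warning.
#'
#' @param path TSV file path.
#' @param build `"hg18"` or `"hg19"` — the build the calls refer to.
#' @param sampleId sample label (defaults to the file name).
#' @return a [SnpProfile-class].
#' @export
readProfile <- function(path, build, sampleId = NULL) {
  if (is.null(sampleId))
    sampleId <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    return(SnpProfile(data.frame(), build, sampleId))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  getf <- function(i) vapply(parts, function(x)
    if (length(x) >= i) x[[i]] else NA_character_, "")
  SnpProfile(data.frame(position = getf(1L), ref_allele = getf(2L),
                        obs_allele = getf(3L), stringsAsFactors = FALSE),
             build, sampleId)
}

#' Write a SnpProfile to the headerless profile TSV
#' @param profile a [SnpProfile-class].
#' @param path output file path.
#' @export
writeProfile <- function(profile, path) {
  write.table(profile@calls, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Calls of a profile
#' @param profile a [SnpProfile-class].
#' @return data.frame `position`, `ref_allele`, `obs_allele`, sorted by
#'   position.
#' @export
profileCalls <- function(profile) profile@calls

#' Build label of a profile
#' @param profile a [SnpProfile-class].
#' @export
profileBuild <- function(profile) profile@build

#' Number of input rows skipped as non-SNP when the profile was read
#' @param profile a [SnpProfile-class].
#' @export
nSkipped <- function(profile) profile@nSkipped

#' The call at a position, if any
#' @param profile a [SnpProfile-class].
#' @param position 1-based position.
#' @return one-row data.frame, or a zero-row data.frame when not called.
#' @export
callAt <- function(profile, position) {
  profile@calls[profile@calls$position == position, , drop = FALSE]
}

setMethod("length", "SnpProfile", function(x) nrow(x@calls))

setMethod("show", "SnpProfile", function(object) {
  cat("SnpProfile '", object@sampleId, "' (", object@build, "): ",
      nrow(object@calls), " calls", sep = "")
  if (object@nSkipped) cat(",", object@nSkipped, "non-SNP rows skipped")
  cat("\n")
})
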