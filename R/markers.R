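# Marker conversion table: construction, TSV round trip, lookup indices.

#' Build a MarkerTable from a marker data.frame
#'
#' Normalises the columns, derives the `is_indel` flag from the conversion
#' alleles when absent, and builds the synonym index. A synonym colliding
#' with another marker's canonical name, or claimed by two markers, is
#' dropped from the index with a warning (first mapping wins).
#'
#' @param markers data.frame with columns `name`, `synonyms` (list column or
#'   comma-separated character), `rs_id`, `pos_hg18`, `pos_hg19`,
#'   `ancestral`, `mutant` and optionally `is_indel`.
#' @return a [MarkerTable-class].
#' @export
MarkerTable <- function(markers) {
  df <- as.data.frame(markers, stringsAsFactors = FALSE)
  if (is.null(df$synonyms)) df$synonyms <- replicate(nrow(df), character(0), FALSE)
  if (is.character(df$synonyms)) {
    df$synonyms <- lapply(df$synonyms, function(s) {
      s <- trimws(strsplit(ifelse(is.na(s), "", s), ",", fixed = TRUE)[[1]])
      s[nzchar(s)]
    })
  }
  df$synonyms <- I(df$synonyms)
  if (is.null(df$rs_id)) df$rs_id <- NA_character_
  df$rs_id[!is.na(df$rs_id) & !nzchar(df$rs_id)] <- NA_character_
  for (p in c("pos_hg18", "pos_hg19")) {
    if (is.null(df[[p]])) df[[p]] <- NA_integer_
    df[[p]] <- suppressWarnings(as.integer(df[[p]]))
  }
  df$ancestral <- toupper(as.character(df$ancestral))
  df$mutant <- toupper(as.character(df$mutant))
  if (is.null(df$is_indel))
    df$is_indel <- !(.isSnpAllele(df$ancestral) & .isSnpAllele(df$mutant))
  rownames(df) <- NULL

  idx <- character(0)
  for (i in seq_len(nrow(df))) {
    for (s in df$synonyms[[i]]) {
      if (s %in% df$name) {
        if (!identical(s, df$name[i]))
          warning("synonym '", s, "' of ", df$name[i],
                  " collides with a canonical marker name; ignored")
        next
      }
      if (s %in% names(idx)) {
        if (idx[[s]] != df$name[i])
          warning("synonym '", s, "' claimed by both ", idx[[s]], " and ",
                  df$name[i], "; keeping the first")
        next
      }
      idx[[s]] <- df$name[i]
    }
  }
  new("MarkerTable", markers = df, synonymIndex = idx)
}

#' Read a marker conversion table from TSV
#'
#' Expected layout (header required, extra trailing columns tolerated):
#' `name`, `synonyms` (comma-separated, may be empty), `rs_id` (may be
#' empty), `pos_hg18`, `pos_hg19` (may be empty), `conversion` in the exact
#' form `<ancestral>-><mutant>`, e.g. `A->C`. Conversions that are not a
#' single-base substitution (e.g. `4G->3G`) mark the marker as an indel;
#' malformed conversion strings reject the row with a warning; a duplicate
#' canonical name is an error.
#'
#' @param path TSV file path.
#' @return a [MarkerTable-class].
#' @export
readConversionFile <- function(path) {
  df <- read.delim(path, header = TRUE, colClasses = "character",
                   na.strings = NULL, check.names = FALSE,
                   blank.lines.skip = TRUE)
  need <- c("name", "synonyms", "rs_id", "pos_hg18", "pos_hg19", "conversion")
  if (nrow(df) == 0L || ncol(df) == 0L) {
    empty <- data.frame(name = character(0), synonyms = I(list()),
                        rs_id = character(0),
                        pos_hg18 = integer(0), pos_hg19 = integer(0),
                        ancestral = character(0), mutant = character(0),
                        is_indel = logical(0))
    return(MarkerTable(empty))
  }
  if (!all(need %in% names(df)))
    stop("conversion table is missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  conv <- strsplit(df$conversion, "->", fixed = TRUE)
  ok <- lengths(conv) == 2L &
    vapply(conv, function(x) all(nzchar(trimws(x))), logical(1))
  if (any(!ok)) {
    warning(sum(!ok), " row(s) with malformed conversion string rejected: ",
            paste(head(df$name[!ok], 5L), collapse = ", "))
    df <- df[ok, , drop = FALSE]
    conv <- conv[ok]
  }
  if (anyDuplicated(df$name))
    stop("duplicate canonical marker name: ",
         df$name[duplicated(df$name)][1L])
  anc <- toupper(trimws(vapply(conv, `[`, "", 1L)))
  mut <- toupper(trimws(vapply(conv, `[`, "", 2L)))
  MarkerTable(data.frame(
    name = df$name, synonyms = df$synonyms,
    rs_id = df$rs_id, pos_hg18 = df$pos_hg18, pos_hg19 = df$pos_hg19,
    ancestral = anc, mutant = mut,
    is_indel = !(.isSnpAllele(anc) & .isSnpAllele(mut)),
    stringsAsFactors = FALSE))
}

#' Write a MarkerTable to the conversion TSV layout
#'
#' Inverse of [readConversionFile()]: `writeConversionFile()` then
#' `readConversionFile()` reproduces an equal table.
#'
#' @param markers a [MarkerTable-class].
#' @param path output file path.
#' @export
writeConversionFile <- function(markers, path) {
  df <- markers@markers
  out <- data.frame(
    name = df$name,
    synonyms = vapply(df$synonyms, paste, "", collapse = ","),
    rs_id = ifelse(is.na(df$rs_id), "", df$rs_id),
    pos_hg18 = ifelse(is.na(df$pos_hg18), "", as.character(df$pos_hg18)),
    pos_hg19 = ifelse(is.na(df$pos_hg19), "", as.character(df$pos_hg19)),
    conversion = paste0(df$ancestral, "->", df$mutant),
    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Resolve marker names (canonical or synonym) to canonical names
#'
#' @param markers a [MarkerTable-class].
#' @param names character vector of marker names or synonyms.
#' @return character vector of canonical names; `NA` where unknown.
#' @export
resolveMarker <- function(markers, names) {
  out <- ifelse(names %in% markers@markers$name, names,
                unname(markers@synonymIndex[names]))
  as.character(out)
}

#' Fetch one marker definition row by name or synonym
#'
#' @inheritParams resolveMarker
#' @param name a single marker name or synonym.
#' @return one-row data.frame (the marker definition).
#' @export
getMarker <- function(markers, name) {
  canon <- resolveMarker(markers, name)
  if (is.na(canon)) stop("unknown marker: ", name)
  markers@markers[markers@markers$name == canon, , drop = FALSE]
}

#' Marker positions on one build
#'
#' @inheritParams resolveMarker
#' @param build `"hg18"` or `"hg19"`.
#' @return named integer vector, canonical name -> position (`NA` when the
#'   marker has no position on that build).
#' @export
markerPositions <- function(markers, build) {
  build <- match.arg(build, c("hg18", "hg19"))
  df <- markers@markers
  setNames(df[[paste0("pos_", build)]], df$name)
}

#' Markers located at a position on one build
#'
#' Several markers may share a position (co-located definitions are legal
#' and reported, not fatal).
#'
#' @inheritParams markerPositions
#' @param position 1-based position.
#' @return character vector of canonical names (possibly empty).
#' @export
markersAtPosition <- function(markers, build, position) {
  pos <- markerPositions(markers, build)
  names(pos)[!is.na(pos) & pos == position]
}

#' Canonical marker names
#' @inheritParams resolveMarker
#' @export
markerNames <- function(markers) markers@markers$name

setMethod("length", "MarkerTable", function(x) nrow(x@markers))

setMethod("show", "MarkerTable", function(object) {
  df <- object@markers
  cat("MarkerTable with", nrow(df), "markers (",
      sum(df$is_indel), "indels,", length(object@synonymIndex),
      "synonyms indexed )\n")
  if (nrow(df)) {
    cat("  e.g.", df$name[1L], paste0(df$ancestral[1L], "->", df$mutant[1L]),
        "\n")
  }
})
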