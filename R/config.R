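# Plain key=value configuration for the command-line entry points.

#' Read an analysis configuration file
#'
#' `key=value` lines; blank lines and `#` comments ignored. Recognised keys:
#' `sufficient_threshold`, `insufficient_threshold`, `quality_threshold`
#' (numbers), `exclusions` (comma-separated marker names), `strand_rescue`
#' (`true`/`false`), `build` (`hg18`/`hg19`), `quality_panel_file` (TSV of
#' marker names, one per line). Unknown keys raise an error so typos do not
#' silently fall back to defaults.
#'
#' @param path config file path.
#' @return list with `params` (an [AssignParams-class]), `build` (or `NA`)
#'   and `panel` (character vector of marker names, or `NULL`).
#' @export
readAssignConfig <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) < 2L
  if (any(bad)) stop("malformed config line: ", lines[bad][1L])
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- trimws(vapply(kv, function(x) paste(x[-1L], collapse = "="), ""))
  known <- c("sufficient_threshold", "insufficient_threshold",
             "quality_threshold", "exclusions", "strand_rescue", "build",
             "quality_panel_file")
  if (!all(keys %in% known))
    stop("unknown config key: ", setdiff(keys, known)[1L])
  get <- function(k, default) if (k %in% keys) vals[[match(k, keys)]] else default
  params <- AssignParams(
    sufficientThreshold = as.numeric(get("sufficient_threshold", 0.85)),
    insufficientThreshold = as.numeric(get("insufficient_threshold", 0.05)),
    exclusions = {
      e <- get("exclusions", NA)
      if (is.na(e)) c("V218", "MEH2")
      else trimws(strsplit(e, ",", fixed = TRUE)[[1]])
    },
    strandRescue = tolower(get("strand_rescue", "true")) %in%
      c("true", "yes", "1"),
    qualityThreshold = as.numeric(get("quality_threshold", 0.5)))
  panel <- NULL
  pf <- get("quality_panel_file", NA)
  if (!is.na(pf)) {
    panel <- trimws(readLines(pf))
    panel <- panel[nzchar(panel) & !startsWith(panel, "#")]
  }
  list(params = params, build = get("build", NA_character_), panel = panel)
}
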