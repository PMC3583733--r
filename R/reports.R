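# Output files: the analysis summary plus the three curation lists that let
# a user check, correct and extend the phylogenetic tree in use.

#' Markers in derived state that are absent from the tree in use
#'
#' Known markers (conversion table) with state 1 whose canonical name *and*
#' all synonyms fail to appear among any node's defining markers. These are
#' candidates for extending the tree: their conversion is known but their
#' phylogenetic position is not part of the loaded phylogeny. A marker
#' referenced by the tree under a synonym only is, correctly, not listed.
#'
#' @param states a [StatusTable-class].
#' @param markers a [MarkerTable-class].
#' @param tree a [PhyloTree-class].
#' @return data.frame `marker`, `synonyms` (comma-joined), sorted by marker.
#' @export
findConvNotTree <- function(states, markers, tree) {
  treeRaw <- unique(unlist(tree@markers, use.names = FALSE))
  treeCanon <- resolveMarker(markers, treeRaw)
  treeCanon <- unique(c(treeCanon[!is.na(treeCanon)],
                        treeRaw))  # unresolvable tree names kept verbatim
  st <- states@states
  mutant <- st$marker[st$state == 1L]
  out <- mutant[!(mutant %in% treeCanon)]
  out <- sort(out)
  df <- markers@markers
  syn <- vapply(out, function(m)
    paste(df$synonyms[[match(m, df$name)]], collapse = ","), "")
  data.frame(marker = out, synonyms = unname(syn), stringsAsFactors = FALSE)
}

#' Called SNPs with yet-unknown phylogenetic position
#'
#' Profile calls whose position matches no conversion-table marker on the
#' active build — novel Y-SNPs worth placing on the tree. Together with the
#' known-marker calls they partition the profile: every call position is
#' either at a known marker or reported here, never both.
#'
#' @param profile a [SnpProfile-class].
#' @param markers a [MarkerTable-class].
#' @return data.frame `position`, `ref_allele`, `obs_allele`, sorted by
#'   position.
#' @export
findYuppSnps <- function(profile, markers) {
  known <- markerPositions(markers, profile@build)
  known <- known[!is.na(known)]
  df <- profile@calls[!(profile@calls$position %in% known), , drop = FALSE]
  df <- df[order(df$position), , drop = FALSE]
  rownames(df) <- NULL
  df
}

.writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write the four output files of an analysis
#'
#' Emits, under `outDir`: `analysis.txt` (quality score and category, the
#' four sub-algorithm results, the final haplogroups in both nomenclatures
#' and all warnings), `snp_status.tsv` (per-marker state with provenance,
#' plus the excluded markers with reasons), `conv_not_tree.tsv` and
#' `new_snps.tsv`. Output is sorted and timestamp-free, hence byte-stable
#' across re-runs on identical inputs.
#'
#' @param result an [AssignmentResult-class].
#' @param states a [StatusTable-class].
#' @param convNotTree data.frame from [findConvNotTree()].
#' @param yupp data.frame from [findYuppSnps()].
#' @param outDir output directory (created if missing).
#' @return invisibly, the four file paths.
#' @export
writeReports <- function(result, states, convNotTree, yupp, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(outDir, c("analysis.txt", "snp_status.tsv",
                               "conv_not_tree.tsv", "new_snps.tsv"))

  q <- result@quality
  lines <- c(
    paste0("quality_score\t", sprintf("%.6f", q@score)),
    paste0("quality_category\t", q@category),
    paste0("quality_panel_size\t", q@panelSize),
    paste0("vertical\t", paste(result@vertical, collapse = ",")),
    paste0("horizontal\t", paste(result@horizontal, collapse = ",")),
    paste0("combinatorial\t", paste(result@combinatorial, collapse = ",")),
    paste0("specific\t", paste(result@specific, collapse = ",")),
    paste0("final_alphanumeric\t",
           paste(result@finalAlphanumeric, collapse = ",")),
    paste0("final_mutation_based\t",
           paste(result@finalMutationBased, collapse = ",")),
    paste0("warning\t", result@warnings))
  writeLines(lines, paths[[1L]])

  st <- states@states
  ex <- states@excluded
  status <- rbind(
    data.frame(marker = st$marker, state = as.character(st$state),
               provenance = st$provenance, note = st$note,
               stringsAsFactors = FALSE),
    if (nrow(ex)) data.frame(marker = ex$marker, state = "excluded",
                             provenance = "", note = ex$reason,
                             stringsAsFactors = FALSE))
  status <- status[order(status$marker), , drop = FALSE]
  .writeTsv(status, paths[[2L]])
  .writeTsv(convNotTree, paths[[3L]])
  .writeTsv(yupp, paths[[4L]])
  invisible(paths)
}
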