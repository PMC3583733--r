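# Call-quality test. The reference Y chromosome is a composite of several
# sub-haplogroups while any sample belongs to exactly one, so explicit calls
# at backbone marker sites are always expected; the fraction of panel
# markers with a consistent explicit call estimates the calling quality.

#' Construct a quality panel
#'
#' @param panelMarkers canonical names of the panel markers.
#' @param expectedCallMarkers optional subset whose derived allele the
#'   reference carries (see [expectedCallMarkers()]).
#' @return a [QualityPanel-class].
#' @export
QualityPanel <- function(panelMarkers, expectedCallMarkers = character(0)) {
  new("QualityPanel", panelMarkers = unique(as.character(panelMarkers)),
      expectedCallMarkers = unique(as.character(expectedCallMarkers)))
}

#' Default quality panel: backbone markers of the shallow tree levels
#'
#' All (non-indel, position-bearing) markers defining nodes of depth at most
#' `maxDepth` in the loaded tree — the well-known backbone markers of the
#' major haplogroups.
#'
#' @param tree a [PhyloTree-class].
#' @param markers a [MarkerTable-class].
#' @param build active build (panel markers must have a position on it).
#' @param maxDepth maximum node depth included (default 2).
#' @param reference optional [ReferenceSequence-class]; when given, the
#'   panel's `expectedCallMarkers` are filled in.
#' @return a [QualityPanel-class].
#' @export
defaultQualityPanel <- function(tree, markers, build, maxDepth = 2L,
                                reference = NULL) {
  depths <- nodeDepths(tree)
  shallow <- names(depths)[depths >= 1L & depths <= maxDepth]
  raw <- unique(unlist(tree@markers[shallow], use.names = FALSE))
  canon <- resolveMarker(markers, raw)
  canon <- unique(canon[!is.na(canon)])
  df <- markers@markers
  keep <- df$name %in% canon & !df$is_indel & !is.na(df[[paste0("pos_", build)]])
  panel <- sort(df$name[keep])
  expected <- character(0)
  if (!is.null(reference))
    expected <- expectedCallMarkers(panel, markers, reference)
  QualityPanel(panel, expected)
}

#' Panel markers whose derived allele is carried by the reference
#'
#' At these sites a sample that does not belong to the corresponding
#' composite-reference lineage differs from the reference, so an explicit
#' (ancestral) call is expected there.
#'
#' @param panel character vector of canonical marker names.
#' @param markers a [MarkerTable-class].
#' @param reference a [ReferenceSequence-class].
#' @return subset of `panel`.
#' @export
expectedCallMarkers <- function(panel, markers, reference) {
  df <- markers@markers[markers@markers$name %in% panel, , drop = FALSE]
  pos <- df[[paste0("pos_", reference@build)]]
  ok <- !is.na(pos)
  hit <- rep(FALSE, nrow(df))
  hit[ok] <- baseAt(reference, pos[ok]) == df$mutant[ok]
  sort(df$name[hit %in% TRUE])
}

#' Run the call-quality test on a profile
#'
#' The score is the fraction of panel markers with an explicit call whose
#' observed allele equals the marker's ancestral or mutant allele (direct
#' comparison, no strand rescue — a consistent caller reports the listed
#' strand). Markers contribute to the numerator only when explicitly
#' called, so an empty or heavily truncated profile scores low however many
#' reference-derived states could be imputed, and a profile full of calls
#' matching neither allele scores low however many calls it has. The
#' category is `sufficient` iff `score >= threshold`.
#'
#' @param profile a [SnpProfile-class].
#' @param panel a [QualityPanel-class] or character vector of marker names.
#' @param markers a [MarkerTable-class].
#' @param reference optional [ReferenceSequence-class] (not used by the
#'   score itself; accepted so callers can pass the full input bundle).
#' @param threshold sufficiency threshold on the score (default 0.5).
#' @return a [QualityVerdict-class].
#' @export
evaluateQuality <- function(profile, panel, markers, reference = NULL,
                            threshold = 0.5) {
  if (is(panel, "QualityPanel")) panel <- panel@panelMarkers
  canon <- resolveMarker(markers, panel)
  canon <- unique(canon[!is.na(canon)])
  df <- markers@markers[markers@markers$name %in% canon, , drop = FALSE]
  pos <- df[[paste0("pos_", profile@build)]]
  df <- df[!df$is_indel & !is.na(pos), , drop = FALSE]
  if (nrow(df) == 0L)
    stop("effective quality panel is empty after intersecting with the ",
         "marker table")
  pos <- df[[paste0("pos_", profile@build)]]
  idx <- match(pos, profile@calls$position)
  called <- !is.na(idx)
  obs <- profile@calls$obs_allele[idx]
  consistent <- called & (obs == df$ancestral | obs == df$mutant)
  score <- sum(consistent, na.rm = TRUE) / nrow(df)
  new("QualityVerdict",
      score = score,
      category = if (score >= threshold) "sufficient" else "insufficient",
      nPanelCalled = sum(called),
      nConsistent = as.integer(sum(consistent, na.rm = TRUE)),
      panelSize = nrow(df),
      threshold = threshold)
}

#' Score of a quality verdict
#' @param verdict a [QualityVerdict-class].
#' @export
qualityScore <- function(verdict) verdict@score

#' Category of a quality verdict ("sufficient"/"insufficient")
#' @param verdict a [QualityVerdict-class].
#' @export
qualityCategory <- function(verdict) verdict@category

setMethod("show", "QualityVerdict", function(object) {
  cat("Call-quality: ", object@category, " (score ",
      sprintf("%.3f", object@score), " = ", object@nConsistent, "/",
      object@panelSize, " consistent panel calls; threshold ",
      object@threshold, ")\n", sep = "")
})

setMethod("show", "QualityPanel", function(object) {
  cat("QualityPanel:", length(object@panelMarkers), "markers,",
      length(object@expectedCallMarkers),
      "with reference-carried derived allele\n")
})
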