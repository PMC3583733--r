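# The tree search: per-node Boolean truth under quality-dependent
# thresholds, then four sub-algorithms — vertical (true leaves), horizontal
# (root-to-leaf descent over internal nodes), combinatorial (vertical leaves
# below a horizontal node) and most-specific.

#' Assignment parameters
#'
#' Both node-truth thresholds are strict ("more than"): a node sitting
#' exactly at the threshold is false. Under sufficient calling quality the
#' imputed reference states are trusted, so a node must be almost entirely
#' mutant (> 0.85). Under insufficient quality the reference-derived mutant
#' states are discarded and a single genuine mutant call among few usable
#' states suffices (> 0.05).
#'
#' @param sufficientThreshold,insufficientThreshold node-truth thresholds.
#' @param exclusions markers excluded from the whole analysis; `V218`
#'   (recurrent mutation within haplogroup I) and `MEH2` (ambiguous within
#'   haplogroup Q) by default.
#' @param strandRescue see [determineState()].
#' @param qualityThreshold see [evaluateQuality()].
#' @return an [AssignParams-class].
#' @export
AssignParams <- function(sufficientThreshold = 0.85,
                         insufficientThreshold = 0.05,
                         exclusions = c("V218", "MEH2"),
                         strandRescue = TRUE,
                         qualityThreshold = 0.5) {
  new("AssignParams", sufficientThreshold = sufficientThreshold,
      insufficientThreshold = insufficientThreshold,
      exclusions = exclusions, strandRescue = strandRescue,
      qualityThreshold = qualityThreshold)
}

#' Truth status of one tree node
#'
#' The node's defining markers (a paragroup uses its parent's) are resolved
#' to canonical names and intersected with the scored states. Under
#' sufficient quality, all states in \{0, 1\} enter the denominator and the
#' node is true iff the mutant fraction strictly exceeds
#' `sufficientThreshold`. Under insufficient quality, mutant states imputed
#' from the reference are removed from numerator *and* denominator before
#' the same computation against `insufficientThreshold`. "Other" (-1)
#' states never enter the denominator. No usable state at all makes the
#' node `indeterminate`.
#'
#' @param tree a [PhyloTree-class].
#' @param node node name.
#' @param states a [StatusTable-class].
#' @param markers a [MarkerTable-class] (synonym resolution).
#' @param quality a [QualityVerdict-class] (or the category string).
#' @param params an [AssignParams-class].
#' @return data.frame row: `node`, `truth`, `pct_mutant`, `n_used`.
#' @export
nodeTruth <- function(tree, node, states, markers, quality,
                      params = AssignParams()) {
  category <- if (is(quality, "QualityVerdict")) quality@category else quality
  mk <- nodeMarkers(tree, node)
  canon <- resolveMarker(markers, mk)
  canon <- unique(canon[!is.na(canon)])
  st <- states@states[states@states$marker %in% canon, , drop = FALSE]
  if (category == "insufficient")
    st <- st[!(st$state == 1L & st$provenance == "reference"), , drop = FALSE]
  used <- st[st$state %in% c(0L, 1L), , drop = FALSE]
  n <- nrow(used)
  if (n == 0L) {
    return(data.frame(node = node, truth = "indeterminate",
                      pct_mutant = NA_real_, n_used = 0L,
                      stringsAsFactors = FALSE))
  }
  pct <- mean(used$state == 1L)
  cut <- if (category == "sufficient") params@sufficientThreshold
         else params@insufficientThreshold
  data.frame(node = node, truth = if (pct > cut) "true" else "false",
             pct_mutant = pct, n_used = n, stringsAsFactors = FALSE)
}

#' Truth statuses for every node of the tree
#'
#' @inheritParams nodeTruth
#' @return data.frame with one row per node (tree file order): `node`,
#'   `truth`, `pct_mutant`, `n_used`.
#' @export
nodeTruthTable <- function(tree, states, markers, quality,
                           params = AssignParams()) {
  rows <- lapply(treeNodes(tree), nodeTruth, tree = tree, states = states,
                 markers = markers, quality = quality, params = params)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.truthOf <- function(statuses, node) {
  statuses$truth[match(node, statuses$node)]
}

#' Vertical sub-algorithm: the true leaves
#'
#' @param tree a [PhyloTree-class].
#' @param statuses node-status data.frame from [nodeTruthTable()].
#' @return sorted character vector of leaf names with truth `"true"`.
#'   Indeterminate leaves are excluded here and surfaced as warnings by
#'   [assignHaplogroup()].
#' @export
verticalScan <- function(tree, statuses) {
  leaves <- treeLeaves(tree)
  sort(leaves[.truthOf(statuses, leaves) == "true"])
}

#' Horizontal sub-algorithm: root-to-leaf descent over internal nodes
#'
#' Starting at the root, descends into every true internal child; a true
#' internal node none of whose internal children is true contributes
#' itself. Indeterminate internal nodes are passed through — the descent
#' continues below them — but are never returnable themselves. When no
#' internal child of the root is true the result is empty (the descent
#' "stopped at the root").
#'
#' @inheritParams verticalScan
#' @return sorted character vector of internal-node names.
#' @export
horizontalDescend <- function(tree, statuses) {
  internal <- function(n) !isLeaf(tree, n)
  descend <- function(node) {
    out <- character(0)
    for (child in childrenOf(tree, node)) {
      if (!internal(child)) next
      tr <- .truthOf(statuses, child)
      if (tr == "true") {
        below <- descend(child)
        out <- c(out, if (length(below)) below else child)
      } else if (tr == "indeterminate") {
        out <- c(out, descend(child))
      }
    }
    out
  }
  sort(unique(descend(rootName(tree))))
}

#' Combinatorial sub-algorithm
#'
#' Retains the vertical leaves that have at least one horizontal node among
#' their ancestors (or are one themselves), removing most vertical false
#' positives. An empty horizontal set yields an empty result; the fallback
#' is handled by [assignHaplogroup()].
#'
#' @param vertical,horizontal node-name sets from the two scans.
#' @param tree a [PhyloTree-class].
#' @return sorted character vector.
#' @export
combineVerticalHorizontal <- function(vertical, horizontal, tree) {
  if (length(horizontal) == 0L) return(character(0))
  keep <- vapply(vertical, function(v) {
    length(intersect(c(ancestors(tree, v), v), horizontal)) > 0L
  }, logical(1))
  sort(vertical[keep])
}

#' Most-specific sub-algorithm
#'
#' Drops every candidate that is an ancestor of another candidate. A
#' paragroup leaf additionally yields to any candidate inside its named
#' siblings' subtrees (its parent is a strict ancestor of that candidate):
#' `Z2b*` yields to `Z2b3a`. Incomparable candidates are all retained.
#'
#' @param candidates node-name set.
#' @param tree a [PhyloTree-class].
#' @return sorted character vector.
#' @export
mostSpecific <- function(candidates, tree) {
  if (length(candidates) <= 1L) return(sort(candidates))
  anc <- lapply(setNames(candidates, candidates),
                function(n) ancestors(tree, n))
  drop <- vapply(candidates, function(a) {
    any(vapply(candidates, function(b) {
      if (identical(a, b)) return(FALSE)
      if (a %in% anc[[b]]) return(TRUE)
      if (.isParagroupName(a)) {
        p <- parentOf(tree, a)
        if (!is.na(p) && p %in% anc[[b]]) return(TRUE)
      }
      FALSE
    }, logical(1)))
  }, logical(1))
  sort(candidates[!drop])
}

#' Name a node in the mutation-based nomenclature
#'
#' `"<main-haplogroup letter>-<first defining marker>"`, e.g. `R1b1b2a2*`
#' defined by `P312` becomes `R-P312*`; the trailing `*` of a paragroup is
#' preserved and a paragroup is named by its parent's markers. The root
#' keeps its own label. A node with no resolvable marker becomes
#' `"<letter>-?"` with a warning attribute.
#'
#' @param tree a [PhyloTree-class].
#' @param node node name.
#' @param markers a [MarkerTable-class].
#' @return the mutation-based name; attribute `"warning"` carries a message
#'   when no marker could be resolved.
#' @export
toMutationNomenclature <- function(tree, node, markers) {
  if (identical(node, rootName(tree))) return(node)
  star <- .isParagroupName(node)
  letter <- substr(node, 1L, 1L)
  mk <- nodeMarkers(tree, node)
  first <- if (length(mk)) {
    canon <- resolveMarker(markers, mk[1L])
    if (is.na(canon)) mk[1L] else canon
  } else NA_character_
  if (is.na(first)) {
    out <- paste0(letter, "-?", if (star) "*" else "")
    attr(out, "warning") <- paste0("no defining marker resolvable for ", node)
    return(out)
  }
  paste0(letter, "-", first, if (star) "*" else "")
}

#' Assign the haplogroup of a sample
#'
#' Full pipeline: call-quality test, per-marker states (calls first,
#' reference fallback), per-node truth under the quality-matched
#' thresholds, then the vertical, horizontal, combinatorial and
#' most-specific sub-algorithms. When the horizontal descent stops at the
#' root, the final result falls back to the most specific vertical leaves
#' and a warning records that only the vertical algorithm revealed results.
#' An insufficient quality verdict always appends a caution, since
#' non-called and false positive SNPs are then frequent.
#'
#' @param profile a [SnpProfile-class].
#' @param tree a [PhyloTree-class].
#' @param markers a [MarkerTable-class].
#' @param reference a [ReferenceSequence-class] on the profile's build.
#' @param panel quality panel ([QualityPanel-class] or marker names);
#'   default: [defaultQualityPanel()] of the loaded tree.
#' @param params an [AssignParams-class].
#' @return an [AssignmentResult-class].
#' @export
assignHaplogroup <- function(profile, tree, markers, reference,
                             panel = NULL, params = AssignParams()) {
  if (profile@build != reference@build)
    stop("profile is on ", profile@build, " but reference on ",
         reference@build)
  if (is.null(panel))
    panel <- defaultQualityPanel(tree, markers, profile@build,
                                 reference = reference)
  quality <- evaluateQuality(profile, panel, markers, reference,
                             threshold = params@qualityThreshold)
  states <- buildStatusTable(markers, profile, reference,
                             exclusions = params@exclusions,
                             strandRescue = params@strandRescue)
  statuses <- nodeTruthTable(tree, states, markers, quality, params)

  vertical <- verticalScan(tree, statuses)
  horizontal <- horizontalDescend(tree, statuses)
  combinatorial <- combineVerticalHorizontal(vertical, horizontal, tree)
  specific <- mostSpecific(combinatorial, tree)

  warnings <- character(0)
  if (quality@category == "insufficient")
    warnings <- c(warnings, paste0(
      "insufficient SNP calling quality (score ",
      sprintf("%.3f", quality@score), "): reference-derived mutant states ",
      "ignored; interpret the assignment with caution"))
  leaves <- treeLeaves(tree)
  indetLeaves <- leaves[.truthOf(statuses, leaves) == "indeterminate"]
  if (length(indetLeaves))
    warnings <- c(warnings, paste0(
      "leaves with indeterminate status (no usable marker state): ",
      paste(sort(indetLeaves), collapse = ", ")))
  noPos <- statusExcluded(states)
  noPos <- noPos$marker[startsWith(noPos$reason, "no position")]
  if (length(noPos))
    warnings <- c(warnings, paste0(
      "markers without a position on ", profile@build, " skipped: ",
      paste(sort(noPos), collapse = ", ")))

  if (length(horizontal) == 0L) {
    final <- mostSpecific(vertical, tree)
    warnings <- c(warnings, paste0(
      "horizontal descent stopped at the root; only the vertical ",
      "algorithm revealed results"))
  } else {
    final <- specific
  }
  mutNames <- vapply(final, function(n) {
    nm <- toMutationNomenclature(tree, n, markers)
    w <- attr(nm, "warning")
    if (!is.null(w)) warnings <<- c(warnings, w)
    as.character(nm)
  }, "")
  new("AssignmentResult", quality = quality, nodeStatuses = statuses,
      vertical = vertical, horizontal = horizontal,
      combinatorial = combinatorial, specific = specific,
      finalAlphanumeric = unname(final),
      finalMutationBased = unname(mutNames),
      warnings = warnings)
}

#' Final haplogroup names (alphanumeric nomenclature)
#' @param result an [AssignmentResult-class].
#' @export
finalHaplogroups <- function(result) result@finalAlphanumeric

#' Sub-algorithm result sets
#' @param result an [AssignmentResult-class].
#' @return named list with `vertical`, `horizontal`, `combinatorial`,
#'   `specific`.
#' @export
subAlgorithmResults <- function(result) {
  list(vertical = result@vertical, horizontal = result@horizontal,
       combinatorial = result@combinatorial, specific = result@specific)
}

#' Analysis warnings of an assignment
#' @param result an [AssignmentResult-class].
#' @export
assignmentWarnings <- function(result) result@warnings

#' Quality verdict of an assignment
#' @param result an [AssignmentResult-class].
#' @export
assignmentQuality <- function(result) result@quality

setMethod("show", "AssignmentResult", function(object) {
  cat("AssignmentResult\n")
  show(object@quality)
  cat("  vertical:      ", paste(object@vertical, collapse = ", "), "\n")
  cat("  horizontal:    ", paste(object@horizontal, collapse = ", "), "\n")
  cat("  combinatorial: ", paste(object@combinatorial, collapse = ", "), "\n")
  cat("  specific:      ", paste(object@specific, collapse = ", "), "\n")
  cat("  final:         ",
      paste(paste0(object@finalAlphanumeric, " (",
                   object@finalMutationBased, ")"), collapse = ", "), "\n")
  for (w in object@warnings) cat("  warning:", w, "\n")
})
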