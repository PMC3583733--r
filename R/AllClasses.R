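# S4 containers shared across the package. Tabular slots are plain
# data.frames (one row per marker / node / call); the haplogroup tree is a
# parent-pointer table plus a per-node marker list, which keeps the TSV round
# trip trivial and the traversals explicit.

#' @import methods
#' @importFrom utils read.delim write.table head
#' @importFrom stats setNames runif
#' @importClassesFrom Biostrings DNAString
NULL

.BASES <- c("A", "C", "G", "T")

.isSnpAllele <- function(x) {
  !is.na(x) & nchar(x) == 1L & x %in% .BASES
}

.complementBase <- function(x) chartr("ACGT", "TGCA", x)

.isParagroupName <- function(x) endsWith(x, "*")

#' Catalogue of Y-SNP marker definitions
#'
#' One row per marker: canonical name, synonyms, optional RefSNP id,
#' positions on the hg18 and hg19 builds, and the mutation conversion
#' (ancestral allele and derived = mutant allele). Markers whose conversion
#' is not a single-base substitution (e.g. `4G->3G`) carry `is_indel = TRUE`
#' and are excluded from state determination downstream.
#'
#' @slot markers data.frame with columns `name`, `synonyms` (list column of
#'   character vectors), `rs_id`, `pos_hg18`, `pos_hg19` (integer, `NA` when
#'   unknown), `ancestral`, `mutant`, `is_indel`.
#' @slot synonymIndex named character vector mapping each synonym to its
#'   canonical marker name.
#' @exportClass MarkerTable
setClass("MarkerTable",
  representation(markers = "data.frame", synonymIndex = "character"))

setValidity("MarkerTable", function(object) {
  df <- object@markers
  need <- c("name", "synonyms", "rs_id", "pos_hg18", "pos_hg19",
            "ancestral", "mutant", "is_indel")
  if (!all(need %in% names(df)))
    return(paste("missing columns:", paste(setdiff(need, names(df)), collapse = ", ")))
  if (nrow(df) == 0L) return(TRUE)
  if (anyDuplicated(df$name))
    return(paste("duplicate marker name:", df$name[duplicated(df$name)][1L]))
  snp <- !df$is_indel
  if (any(df$ancestral[snp] == df$mutant[snp]))
    return("ancestral and mutant allele identical for a non-indel marker")
  bad <- snp & !(.isSnpAllele(df$ancestral) & .isSnpAllele(df$mutant))
  if (any(bad))
    return(paste("non-indel marker with non-ACGT alleles:", df$name[bad][1L]))
  selfsyn <- mapply(function(n, s) n %in% s, df$name, df$synonyms)
  if (any(selfsyn))
    return(paste("marker listed among its own synonyms:", df$name[selfsyn][1L]))
  idx <- object@synonymIndex
  if (length(idx) && !all(idx %in% df$name))
    return("synonym index points at unknown canonical name")
  TRUE
})

#' Rooted haplogroup tree
#'
#' Parent-pointer representation of the haplogroup hierarchy: exactly one
#' node (the root) has no parent; every node lists its defining markers.
#' Paragroup leaves (names ending in `*`) have no children and, by
#' convention, no markers of their own — they are resolved against their
#' parent's defining markers.
#'
#' @slot nodes data.frame with columns `name` and `parent` (`NA` for the
#'   root), in file order.
#' @slot markers named list: node name -> character vector of defining
#'   marker names (possibly under synonyms).
#' @slot children named list: node name -> character vector of child names
#'   in file order.
#' @slot root name of the root node.
#' @slot depths named integer vector; `depths[root] == 0`.
#' @exportClass PhyloTree
setClass("PhyloTree",
  representation(nodes = "data.frame", markers = "list",
                 children = "list", root = "character",
                 depths = "integer"))

setValidity("PhyloTree", function(object) {
  df <- object@nodes
  if (!all(c("name", "parent") %in% names(df))) return("nodes needs name/parent")
  if (anyDuplicated(df$name))
    return(paste("duplicate haplogroup name:", df$name[duplicated(df$name)][1L]))
  rootRows <- which(is.na(df$parent))
  if (length(rootRows) != 1L) return("tree must have exactly one root")
  known <- df$parent[!is.na(df$parent)]
  if (!all(known %in% df$name))
    return(paste("unknown parent:", setdiff(known, df$name)[1L]))
  if (any(is.na(object@depths)))
    return("cycle detected: some nodes unreachable from the root")
  para <- .isParagroupName(df$name)
  hasKids <- lengths(object@children[df$name]) > 0L
  if (any(para & hasKids))
    return(paste("paragroup with children:", df$name[para & hasKids][1L]))
  TRUE
})

#' A sample's Y-chromosome SNP calling profile
#'
#' Calls are unique by position (duplicates are resolved keep-first at read
#' time) and restricted to single-base substitutions on one reference build.
#'
#' @slot build `"hg18"` or `"hg19"`.
#' @slot calls data.frame with columns `position` (1-based integer),
#'   `ref_allele`, `obs_allele` (single bases).
#' @slot sampleId sample label.
#' @slot nSkipped number of input rows discarded as non-SNP at read time.
#' @exportClass SnpProfile
setClass("SnpProfile",
  representation(build = "character", calls = "data.frame",
                 sampleId = "character", nSkipped = "integer"))

setValidity("SnpProfile", function(object) {
  if (!object@build %in% c("hg18", "hg19")) return("build must be hg18 or hg19")
  df <- object@calls
  if (!all(c("position", "ref_allele", "obs_allele") %in% names(df)))
    return("calls needs position/ref_allele/obs_allele")
  if (nrow(df) == 0L) return(TRUE)
  if (any(df$position < 1L)) return("positions are 1-based (>= 1)")
  if (anyDuplicated(df$position)) return("duplicate call positions")
  if (!all(.isSnpAllele(df$ref_allele)) || !all(.isSnpAllele(df$obs_allele)))
    return("alleles must be single bases in {A,C,G,T}")
  TRUE
})

#' Reference Y-chromosome sequence
#'
#' Thin wrapper around a [Biostrings::DNAString] tied to a build label;
#' 1-based base lookup via [baseAt()].
#'
#' @slot build `"hg18"` or `"hg19"`.
#' @slot sequence a `DNAString`.
#' @exportClass ReferenceSequence
setClass("ReferenceSequence",
  representation(build = "character", sequence = "DNAString"))

setValidity("ReferenceSequence", function(object) {
  if (!object@build %in% c("hg18", "hg19")) return("build must be hg18 or hg19")
  TRUE
})

#' Per-marker allelic states with provenance
#'
#' One row per eligible marker with its state (0 ancestral, 1 mutant/derived,
#' -1 other), whether the state came from an explicit call or from the
#' reference base, and an optional note (e.g. strand rescue). Markers that
#' cannot be scored (indels, exclusion list, no position on the active build)
#' are listed in `excluded` with a reason.
#'
#' @slot states data.frame: `marker`, `state` (integer), `provenance`
#'   (`"called"`/`"reference"`), `note`.
#' @slot excluded data.frame: `marker`, `reason`.
#' @slot build active build the table was computed on.
#' @exportClass StatusTable
setClass("StatusTable",
  representation(states = "data.frame", excluded = "data.frame",
                 build = "character"))

setValidity("StatusTable", function(object) {
  st <- object@states
  if (!all(c("marker", "state", "provenance", "note") %in% names(st)))
    return("states needs marker/state/provenance/note")
  if (nrow(st) && !all(st$state %in% c(-1L, 0L, 1L)))
    return("state must be in {-1, 0, 1}")
  if (nrow(st) && !all(st$provenance %in% c("called", "reference")))
    return("provenance must be called/reference")
  if (anyDuplicated(st$marker)) return("a marker appears twice in states")
  if (length(intersect(st$marker, object@excluded$marker)))
    return("a marker is both scored and excluded")
  TRUE
})

#' Panel of backbone markers for the call-quality test
#'
#' @slot panelMarkers canonical names of the panel markers (backbone markers
#'   of the major haplogroups).
#' @slot expectedCallMarkers subset whose derived allele is carried by the
#'   reference (composite-reference diagnostics): explicit calls at some of
#'   these sites are always expected, whatever the sample's lineage.
#' @exportClass QualityPanel
setClass("QualityPanel",
  representation(panelMarkers = "character", expectedCallMarkers = "character"))

setValidity("QualityPanel", function(object) {
  if (!all(object@expectedCallMarkers %in% object@panelMarkers))
    return("expectedCallMarkers must be a subset of panelMarkers")
  TRUE
})

#' Verdict of the call-quality test
#'
#' @slot score fraction in `[0, 1]` of panel markers with a consistent
#'   explicit call.
#' @slot category `"sufficient"` or `"insufficient"`.
#' @slot nPanelCalled panel markers with any explicit call.
#' @slot nConsistent panel markers whose called allele equals the marker's
#'   ancestral or mutant allele.
#' @slot panelSize effective panel size (denominator of the score).
#' @slot threshold threshold the category was decided against.
#' @exportClass QualityVerdict
setClass("QualityVerdict",
  representation(score = "numeric", category = "character",
                 nPanelCalled = "integer", nConsistent = "integer",
                 panelSize = "integer", threshold = "numeric"))

setValidity("QualityVerdict", function(object) {
  if (object@score < 0 || object@score > 1) return("score must be in [0,1]")
  if (!object@category %in% c("sufficient", "insufficient"))
    return("category must be sufficient/insufficient")
  TRUE
})

#' Parameters of the haplogroup assignment
#'
#' @slot sufficientThreshold node-truth threshold under sufficient calling
#'   quality (strict: a node is true iff its mutant fraction is *more than*
#'   this), default 0.85.
#' @slot insufficientThreshold node-truth threshold under insufficient
#'   quality (strict), default 0.05.
#' @slot exclusions marker names excluded from the analysis, default
#'   `c("V218", "MEH2")` (a known recurrent mutation and an ambiguous
#'   marker).
#' @slot strandRescue compare the complement of the observed allele when the
#'   direct comparison matches neither allele (published marker lists mix
#'   strands); default `TRUE`.
#' @slot qualityThreshold call-quality score needed for the sufficient
#'   category, default 0.5.
#' @exportClass AssignParams
setClass("AssignParams",
  representation(sufficientThreshold = "numeric",
                 insufficientThreshold = "numeric",
                 exclusions = "character",
                 strandRescue = "logical",
                 qualityThreshold = "numeric"))

setValidity("AssignParams", function(object) {
  th <- c(object@sufficientThreshold, object@insufficientThreshold,
          object@qualityThreshold)
  if (any(th < 0 | th > 1)) return("thresholds must be in [0,1]")
  TRUE
})

#' Result of a haplogroup assignment
#'
#' @slot quality the [QualityVerdict-class] of the run.
#' @slot nodeStatuses data.frame: `node`, `truth`
#'   (`"true"`/`"false"`/`"indeterminate"`), `pct_mutant`, `n_used`.
#' @slot vertical,horizontal,combinatorial,specific node-name sets from the
#'   four sub-algorithms (sorted).
#' @slot finalAlphanumeric,finalMutationBased final haplogroup names in the
#'   two nomenclatures, index-aligned.
#' @slot warnings character vector of analysis warnings.
#' @exportClass AssignmentResult
setClass("AssignmentResult",
  representation(quality = "QualityVerdict", nodeStatuses = "data.frame",
                 vertical = "character", horizontal = "character",
                 combinatorial = "character", specific = "character",
                 finalAlphanumeric = "character",
                 finalMutationBased = "character",
                 warnings = "character"))

setValidity("AssignmentResult", function(object) {
  if (!all(object@specific %in% object@combinatorial))
    return("specific must be a subset of combinatorial")
  if (!all(object@combinatorial %in% object@vertical))
    return("combinatorial must be a subset of vertical")
  if (length(object@finalAlphanumeric) != length(object@finalMutationBased))
    return("the two final nomenclature lists must be index-aligned")
  TRUE
})

#' Synthetic haplogroup fixture with known ground truth
#'
#' Bundle produced by [makeFixture()]: a tree, a marker table with one set of
#' markers per branch, a composite reference carrying the derived allele on
#' the branches ancestral to `referenceLineages`, and the ground-truth map of
#' derived markers per leaf.
#'
#' @slot tree a [PhyloTree-class].
#' @slot markers a [MarkerTable-class].
#' @slot reference a [ReferenceSequence-class].
#' @slot truth named list: leaf name -> canonical names of markers derived
#'   in that leaf (exactly its root-to-leaf path markers).
#' @slot markerNode named character: canonical marker name -> node whose
#'   branch carries it.
#' @slot params list of the generator settings (levels, branching, markers
#'   per branch, reference lineages, seed).
#' @exportClass HaplogroupFixture
setClass("HaplogroupFixture",
  representation(tree = "PhyloTree", markers = "MarkerTable",
                 reference = "ReferenceSequence", truth = "list",
                 markerNode = "character", params = "list"))
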