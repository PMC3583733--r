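# Seeded synthetic fixtures: a balanced haplogroup tree with markers on
# every branch, a composite reference carrying the derived allele along the
# paths of chosen "reference lineages", and error-injected call profiles
# with known ground truth. All randomness goes through one explicit
# Mersenne-Twister seed per call; nothing touches the global RNG state.

.childName <- function(parent, j, depth) {
  # alternate digits and lowercase letters below the top level, mimicking
  # the alphanumeric haplogroup nomenclature (A, A1, A1a, A1a1, ...)
  if (depth == 1L) return(LETTERS[[j]])
  if (depth %% 2L == 0L) paste0(parent, j) else paste0(parent, letters[[j]])
}

#' Generate a synthetic haplogroup fixture with known ground truth
#'
#' Builds a balanced rooted tree (`nLevels` levels below the root, each node
#' with `branching` children), puts `markersPerBranch` unique markers on
#' every branch at distinct positions (drawn without replacement from
#' `1..10 * nMarkers`, leaving room to plant novel SNPs), and constructs a
#' composite reference: the reference base equals the derived (mutant)
#' allele exactly on branches ancestral to (or on the path of) the
#' `referenceLineages` leaves, and the ancestral allele everywhere else —
#' emulating the real reference Y, a composite of several sub-haplogroups.
#' The ground truth records, per leaf, exactly the markers on its
#' root-to-leaf path.
#'
#' `referenceLineages = NULL` picks one leaf under each of the first three
#' depth-2 nodes (or all of them when fewer exist), which spreads the
#' composite ancestry widely enough that every leaf's zero-error profile
#' passes the default call-quality test.
#'
#' @param nLevels levels below the root (tree depth).
#' @param branching children per internal node.
#' @param markersPerBranch markers on each branch (>= 1).
#' @param referenceLineages leaf names whose paths the reference carries in
#'   derived state, or `NULL` for the default spread.
#' @param seed integer seed (Mersenne-Twister; local to this call).
#' @return a [HaplogroupFixture-class].
#' @importFrom withr with_seed
#' @export
makeFixture <- function(nLevels = 5L, branching = 2L, markersPerBranch = 2L,
                        referenceLineages = NULL, seed = 1L) {
  stopifnot(nLevels >= 1L, branching >= 1L, markersPerBranch >= 1L)
  name <- "Root"; parent <- NA_character_
  prev <- "Root"
  for (d in seq_len(nLevels)) {
    nxt <- character(0)
    for (p in prev) {
      kids <- vapply(seq_len(branching), function(j)
        .childName(p, j, d), "")
      name <- c(name, kids)
      parent <- c(parent, rep(p, branching))
      nxt <- c(nxt, kids)
    }
    prev <- nxt
  }
  nonRoot <- name[-1L]
  nMarkers <- length(nonRoot) * markersPerBranch
  markerName <- paste0("M", seq_len(nMarkers))
  markerNode <- setNames(rep(nonRoot, each = markersPerBranch), markerName)
  nodeMk <- split(markerName, factor(markerNode, levels = nonRoot))

  refLen <- 10L * nMarkers
  withr::with_seed(seed, {
    positions <- sample.int(refLen, nMarkers)
    ancestral <- sample(.BASES, nMarkers, replace = TRUE)
    mutant <- vapply(ancestral, function(a)
      sample(setdiff(.BASES, a), 1L), "")
    refBases <- sample(.BASES, refLen, replace = TRUE)
  })

  tree <- PhyloTree(data.frame(
    name = name, parent = parent,
    markers = I(c(list(character(0)), unname(nodeMk))),
    stringsAsFactors = FALSE))

  leaves <- treeLeaves(tree)
  if (is.null(referenceLineages)) {
    depths <- nodeDepths(tree)
    d2 <- names(depths)[depths == min(2L, nLevels)]
    d2 <- d2[seq_len(min(3L, length(d2)))]
    referenceLineages <- vapply(d2, function(n) {
      repeat {
        kids <- childrenOf(tree, n)
        if (length(kids) == 0L) return(n)
        n <- kids[[1L]]
      }
    }, "")
    referenceLineages <- unname(referenceLineages)
  }
  stopifnot(all(referenceLineages %in% leaves))

  markers <- MarkerTable(data.frame(
    name = markerName,
    synonyms = I(replicate(nMarkers, character(0), FALSE)),
    rs_id = NA_character_,
    pos_hg18 = positions, pos_hg19 = positions,
    ancestral = ancestral, mutant = mutant, is_indel = FALSE,
    stringsAsFactors = FALSE))

  # reference carries the derived allele exactly on the union of the
  # reference lineages' paths
  refNodes <- unique(unlist(lapply(referenceLineages, function(l)
    c(ancestors(tree, l), l))))
  refBases[positions] <- ancestral
  derivedIdx <- markerNode %in% refNodes
  refBases[positions[derivedIdx]] <- mutant[derivedIdx]
  reference <- ReferenceSequence(paste(refBases, collapse = ""), "hg19")

  truth <- lapply(setNames(leaves, leaves), function(l) {
    path <- c(setdiff(ancestors(tree, l), "Root"), l)
    unname(unlist(nodeMk[path], use.names = FALSE))
  })

  new("HaplogroupFixture", tree = tree, markers = markers,
      reference = reference, truth = truth, markerNode = markerNode,
      params = list(nLevels = nLevels, branching = branching,
                    markersPerBranch = markersPerBranch,
                    referenceLineages = referenceLineages, seed = seed))
}

#' Simulate an error-injected call profile for one leaf
#'
#' True calls are the positions where the leaf's allele differs from the
#' composite reference (derived on its path where the reference is
#' ancestral, ancestral where the reference is derived). Each true call is
#' dropped with probability `fnRate`; spurious calls are added with
#' probability `fpRate` at every non-differing site (marker positions where
#' leaf and reference agree, and all non-marker positions), observing a
#' random base different from the reference.
#'
#' @param fixture a [HaplogroupFixture-class].
#' @param leaf leaf name in the fixture's tree.
#' @param fpRate,fnRate error rates in `[0, 1]`.
#' @param seed integer seed (local to this call).
#' @return a [SnpProfile-class] on the fixture's build.
#' @export
simulateProfile <- function(fixture, leaf, fpRate = 0, fnRate = 0,
                            seed = 1L) {
  stopifnot(leaf %in% treeLeaves(fixture@tree),
            fpRate >= 0, fpRate <= 1, fnRate >= 0, fnRate <= 1)
  df <- fixture@markers@markers
  pos <- df$pos_hg19
  onPath <- df$name %in% fixture@truth[[leaf]]
  leafAllele <- ifelse(onPath, df$mutant, df$ancestral)
  refBase <- baseAt(fixture@reference, pos)
  differs <- leafAllele != refBase

  refLen <- length(fixture@reference)
  fpSites <- sort(c(pos[!differs], setdiff(seq_len(refLen), pos)))
  fpRef <- baseAt(fixture@reference, fpSites)

  withr::with_seed(seed, {
    keepTrue <- stats::runif(sum(differs)) >= fnRate
    addFp <- stats::runif(length(fpSites)) < fpRate
    fpObs <- vapply(fpRef[addFp], function(b)
      sample(setdiff(.BASES, b), 1L), "")
  })

  calls <- rbind(
    data.frame(position = pos[differs][keepTrue],
               ref_allele = refBase[differs][keepTrue],
               obs_allele = leafAllele[differs][keepTrue],
               stringsAsFactors = FALSE),
    data.frame(position = fpSites[addFp], ref_allele = fpRef[addFp],
               obs_allele = fpObs, stringsAsFactors = FALSE))
  SnpProfile(calls, "hg19", sampleId = paste0("sim_", leaf))
}

#' Brute-force assignment oracle
#'
#' Independent of the tree search: scores every leaf by the fraction of its
#' root-to-leaf path markers whose state (resolved with the same
#' calls-then-reference rules as [buildStatusTable()]) is derived, and
#' returns the arg-max set. Ties — e.g. two leaves with identical derived
#' marker sets by construction — are all returned.
#'
#' @param profile a [SnpProfile-class] over the fixture's coordinates.
#' @param fixture a [HaplogroupFixture-class].
#' @return sorted character vector of best-scoring leaf names (empty when no
#'   leaf has a usable state).
#' @export
oracleAssign <- function(profile, fixture) {
  states <- buildStatusTable(fixture@markers, profile, fixture@reference,
                             exclusions = character(0))
  st <- statusStates(states)
  score <- vapply(names(fixture@truth), function(leaf) {
    rows <- st[st$marker %in% fixture@truth[[leaf]] & st$state %in% c(0L, 1L),
               , drop = FALSE]
    if (nrow(rows) == 0L) return(NA_real_)
    mean(rows$state == 1L)
  }, numeric(1))
  if (all(is.na(score))) return(character(0))
  best <- max(score, na.rm = TRUE)
  sort(names(score)[!is.na(score) & score == best])
}

setMethod("show", "HaplogroupFixture", function(object) {
  p <- object@params
  cat("HaplogroupFixture: ", p$nLevels, " levels x branching ", p$branching,
      " (", length(treeLeaves(object@tree)), " leaves), ",
      length(object@markers), " markers, reference lineages: ",
      paste(p$referenceLineages, collapse = ", "),
      "; seed ", p$seed, "\n", sep = "")
})
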