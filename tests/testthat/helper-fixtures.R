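# In-code fixtures and independent brute-force oracles for the tree
# searches. The oracles deliberately recompute everything from parent
# pointers and exhaustive loops so they share no traversal code with the
# implementation.

# --- tiny builders ---------------------------------------------------------

mkMarkerTable <- function(...) {
  rows <- list(...)
  MarkerTable(data.frame(
    name = vapply(rows, `[[`, "", "name"),
    synonyms = I(lapply(rows, function(r) r$synonyms %||% character(0))),
    rs_id = vapply(rows, function(r) r$rs_id %||% NA_character_, ""),
    pos_hg18 = vapply(rows, function(r) r$pos_hg18 %||% NA_integer_, 1L),
    pos_hg19 = vapply(rows, function(r) r$pos_hg19 %||% NA_integer_, 1L),
    ancestral = vapply(rows, `[[`, "", "ancestral"),
    mutant = vapply(rows, `[[`, "", "mutant"),
    stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

mkRef <- function(bases, build = "hg19") {
  ReferenceSequence(paste(bases, collapse = ""), build)
}

mkProfile <- function(position, ref, obs, build = "hg19") {
  SnpProfile(data.frame(position = position, ref_allele = ref,
                        obs_allele = obs, stringsAsFactors = FALSE), build)
}

mkStatuses <- function(tree, true = character(0),
                       indeterminate = character(0)) {
  nodes <- treeNodes(tree)
  truth <- ifelse(nodes %in% true, "true",
                  ifelse(nodes %in% indeterminate, "indeterminate", "false"))
  data.frame(node = nodes, truth = truth, pct_mutant = NA_real_,
             n_used = 1L, stringsAsFactors = FALSE)
}

# single node carrying n markers with the given state/provenance mix; used
# to hand-check the node-truth arithmetic in both quality regimes
truthCase <- function(nMutantCalled, nMutantRef, nAncestral, quality,
                      params = AssignParams()) {
  n <- nMutantCalled + nMutantRef + nAncestral
  mt <- do.call(mkMarkerTable, lapply(seq_len(n), function(i)
    list(name = paste0("K", i), pos_hg19 = i, ancestral = "A", mutant = "C")))
  states <- new("StatusTable",
    states = data.frame(
      marker = paste0("K", seq_len(n)),
      state = rep(c(1L, 1L, 0L), c(nMutantCalled, nMutantRef, nAncestral)),
      provenance = rep(c("called", "reference", "called"),
                       c(nMutantCalled, nMutantRef, nAncestral)),
      note = "", stringsAsFactors = FALSE),
    excluded = data.frame(marker = character(0), reason = character(0)),
    build = "hg19")
  tree <- PhyloTree(data.frame(
    name = c("R", "H"), parent = c(NA, "R"),
    markers = I(list(character(0), paste0("K", seq_len(n))))))
  nodeTruth(tree, "H", states, mt, quality, params)
}

# --- random trees with random truth assignments ----------------------------

randomTree <- function(seed, maxDepth = NULL, paragroups = TRUE) {
  withr::with_seed(seed, {
    if (is.null(maxDepth)) maxDepth <- sample(2:6, 1L)
    name <- "Root"; parent <- NA_character_
    frontier <- "Root"; depth <- 0L; counter <- 0L
    while (depth < maxDepth && length(frontier) > 0L && length(name) < 100L) {
      nxt <- character(0)
      for (p in frontier) {
        k <- if (identical(p, "Root")) sample(1:3, 1L) else sample(0:3, 1L)
        if (k == 0L) next
        kids <- paste0("N", counter + seq_len(k)); counter <- counter + k
        name <- c(name, kids); parent <- c(parent, rep(p, k))
        nxt <- c(nxt, kids)
      }
      frontier <- nxt; depth <- depth + 1L
    }
    if (paragroups) {
      internal <- setdiff(unique(parent[!is.na(parent)]), NA)
      pick <- internal[stats::runif(length(internal)) < 0.3]
      if (length(pick)) {
        name <- c(name, paste0(pick, "*"))
        parent <- c(parent, pick)
      }
    }
    PhyloTree(data.frame(name = name, parent = parent,
                         stringsAsFactors = FALSE))
  })
}

randomStatuses <- function(tree, seed, pIndet = 0.1) {
  withr::with_seed(seed, {
    nodes <- treeNodes(tree)
    truth <- sample(c("true", "false", "indeterminate"), length(nodes),
                    replace = TRUE, prob = c(0.45, 0.45, pIndet))
    data.frame(node = nodes, truth = truth, pct_mutant = NA_real_,
               n_used = 1L, stringsAsFactors = FALSE)
  })
}

# --- brute-force counterparts ---------------------------------------------

truthLookup <- function(statuses) {
  stats::setNames(statuses$truth, statuses$node)
}

bfVertical <- function(tree, statuses) {
  tr <- truthLookup(statuses)
  out <- character(0)
  for (n in treeNodes(tree)) {
    if (length(childrenOf(tree, n)) == 0L && tr[[n]] == "true")
      out <- c(out, n)
  }
  sort(out)
}

# deepest internal non-root nodes that are true with every strict ancestor
# below the root true-or-indeterminate
bfHorizontal <- function(tree, statuses) {
  tr <- truthLookup(statuses)
  root <- rootName(tree)
  internal <- treeNodes(tree)[vapply(treeNodes(tree), function(n)
    length(childrenOf(tree, n)) > 0L, TRUE)]
  cand <- character(0)
  for (n in setdiff(internal, root)) {
    if (tr[[n]] != "true") next
    anc <- setdiff(ancestors(tree, n), root)
    if (all(tr[anc] %in% c("true", "indeterminate"))) cand <- c(cand, n)
  }
  keep <- vapply(cand, function(a)
    !any(vapply(cand, function(b) a %in% ancestors(tree, b), TRUE)), TRUE)
  sort(cand[keep])
}

bfCombine <- function(vertical, horizontal, tree) {
  out <- character(0)
  for (v in vertical) {
    for (h in horizontal) {
      if (h == v || h %in% ancestors(tree, v)) out <- c(out, v)
    }
  }
  sort(unique(out))
}

bfSpecific <- function(candidates, tree) {
  n <- length(candidates)
  if (n <= 1L) return(sort(candidates))
  isAnc <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    a <- candidates[[i]]; b <- candidates[[j]]
    if (a %in% ancestors(tree, b)) isAnc[i, j] <- TRUE
    if (endsWith(a, "*")) {
      p <- parentOf(tree, a)
      if (!is.na(p) && p %in% ancestors(tree, b)) isAnc[i, j] <- TRUE
    }
  }
  sort(candidates[!apply(isAnc, 1L, any)])
}

# --- toy converter inputs --------------------------------------------------

writeToyVcf <- function(path, records,
                        sampleCols = "S1",
                        haveGt = TRUE) {
  header <- c("##fileformat=VCFv4.1",
              "##contig=<ID=chrY>",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", if (haveGt) c("FORMAT", sampleCols)),
                    collapse = "\t"))
  writeLines(c(header, records), path)
  path
}

vcfRecord <- function(chrom, pos, ref, alt, gt = "1") {
  paste(chrom, pos, ".", ref, alt, "50", "PASS", ".", "GT", gt, sep = "\t")
}

writeToyCga <- function(path, rows) {
  header <- ">locus\tploidy\tchromosome\tbegin\tend\tvarType\treference\talleleSeq"
  writeLines(c("#ASSEMBLY_ID toy", header, rows), path)
  path
}

cgaRow <- function(chrom, begin, end, varType, ref, allele, locus = 1L) {
  paste(locus, 1L, chrom, begin, end, varType, ref, allele, sep = "\t")
}
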