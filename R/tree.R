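# Haplogroup tree: construction, TSV round trip, traversal queries.

.computeDepths <- function(name, parent) {
  depth <- setNames(rep(NA_integer_, length(name)), name)
  depth[is.na(parent)] <- 0L
  repeat {
    todo <- is.na(depth) & parent %in% names(depth)[!is.na(depth)]
    if (!any(todo)) break
    depth[name[todo]] <- depth[parent[todo]] + 1L
  }
  depth
}

#' Build a PhyloTree from a node table
#'
#' @param nodes data.frame with columns `name`, `parent` (`NA` or `""` for
#'   the root) and optionally `markers` (list column, or comma-separated
#'   character, of defining marker names). Children keep file order.
#' @return a [PhyloTree-class].
#' @export
PhyloTree <- function(nodes) {
  df <- as.data.frame(nodes, stringsAsFactors = FALSE)
  df$name <- as.character(df$name)
  df$parent <- as.character(df$parent)
  df$parent[!is.na(df$parent) & !nzchar(df$parent)] <- NA_character_
  if (anyDuplicated(df$name))
    stop("duplicate haplogroup name: ", df$name[duplicated(df$name)][1L])
  rootRows <- which(is.na(df$parent))
  if (length(rootRows) == 0L) stop("no root row (empty parent) found")
  if (length(rootRows) > 1L)
    stop("two roots: rows for ", paste(df$name[rootRows], collapse = ", "))
  orphan <- setdiff(df$parent[!is.na(df$parent)], df$name)
  if (length(orphan))
    stop("row references parent '", orphan[1L], "' absent from the file")

  mk <- df$markers
  if (is.null(mk)) mk <- replicate(nrow(df), character(0), FALSE)
  if (is.character(mk)) {
    mk <- lapply(mk, function(s) {
      s <- trimws(strsplit(ifelse(is.na(s), "", s), ",", fixed = TRUE)[[1]])
      s[nzchar(s)]
    })
  }
  markers <- setNames(unclass(mk), df$name)

  children <- lapply(setNames(df$name, df$name),
                     function(n) df$name[!is.na(df$parent) & df$parent == n])
  depths <- .computeDepths(df$name, df$parent)
  if (any(is.na(depths)))
    stop("cycle detected involving: ",
         paste(names(depths)[is.na(depths)], collapse = ", "))
  new("PhyloTree",
      nodes = data.frame(name = df$name, parent = df$parent,
                         stringsAsFactors = FALSE),
      markers = markers, children = children,
      root = df$name[rootRows], depths = depths)
}

#' Read a haplogroup tree from TSV
#'
#' Layout (header required, extra trailing columns tolerated): `haplogroup`,
#' `parent` (empty for the root), `defining_markers` (comma-separated marker
#' names, may be empty — paragroup rows usually are). Parent rows may appear
#' after child rows. Two roots, an orphan parent reference, a cycle or a
#' duplicate name raise an error naming the offending row.
#'
#' @param path TSV file path.
#' @return a [PhyloTree-class].
#' @export
readTreeFile <- function(path) {
  df <- read.delim(path, header = TRUE, colClasses = "character",
                   na.strings = NULL, check.names = FALSE,
                   blank.lines.skip = TRUE)
  need <- c("haplogroup", "parent", "defining_markers")
  if (!all(need %in% names(df)))
    stop("tree file is missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  PhyloTree(data.frame(name = df$haplogroup, parent = df$parent,
                       markers = df$defining_markers,
                       stringsAsFactors = FALSE))
}

#' Write a PhyloTree to the tree TSV layout
#'
#' @param tree a [PhyloTree-class].
#' @param path output file path.
#' @export
writeTreeFile <- function(tree, path) {
  df <- tree@nodes
  out <- data.frame(
    haplogroup = df$name,
    parent = ifelse(is.na(df$parent), "", df$parent),
    defining_markers = vapply(tree@markers[df$name], paste, "",
                              collapse = ","),
    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Ancestors of a node, root first
#'
#' The path from the root down to the node's parent; the node itself is
#' excluded, so `ancestors(tree, rootName(tree))` is empty.
#'
#' @param tree a [PhyloTree-class].
#' @param name a node name present in the tree.
#' @return character vector of node names, root first.
#' @export
ancestors <- function(tree, name) {
  if (!name %in% tree@nodes$name) stop("unknown node: ", name)
  parent <- setNames(tree@nodes$parent, tree@nodes$name)
  out <- character(0)
  p <- parent[[name]]
  while (!is.na(p)) {
    out <- c(p, out)
    p <- parent[[p]]
  }
  out
}

#' Node names of a tree
#' @param tree a [PhyloTree-class].
#' @export
treeNodes <- function(tree) tree@nodes$name

#' Leaf names of a tree (nodes without children)
#' @param tree a [PhyloTree-class].
#' @export
treeLeaves <- function(tree) {
  tree@nodes$name[lengths(tree@children[tree@nodes$name]) == 0L]
}

#' Children of a node, in file order
#' @inheritParams ancestors
#' @export
childrenOf <- function(tree, name) {
  if (!name %in% tree@nodes$name) stop("unknown node: ", name)
  tree@children[[name]]
}

#' Parent of a node (`NA` for the root)
#' @inheritParams ancestors
#' @export
parentOf <- function(tree, name) {
  if (!name %in% tree@nodes$name) stop("unknown node: ", name)
  tree@nodes$parent[tree@nodes$name == name]
}

#' Is a node a leaf?
#' @inheritParams ancestors
#' @export
isLeaf <- function(tree, name) length(childrenOf(tree, name)) == 0L

#' Root name of a tree
#' @param tree a [PhyloTree-class].
#' @export
rootName <- function(tree) tree@root

#' Node depths (root = 0)
#' @param tree a [PhyloTree-class].
#' @return named integer vector over all nodes.
#' @export
nodeDepths <- function(tree) tree@depths

#' Defining markers of a node
#'
#' Paragroup leaves (`"Z2b*"`) have no markers of their own and are resolved
#' against their parent's defining markers when `paragroupFromParent` is
#' `TRUE` (the default, matching how they are scored).
#'
#' @inheritParams ancestors
#' @param paragroupFromParent fall back to the parent's markers for
#'   marker-less paragroup nodes.
#' @export
nodeMarkers <- function(tree, name, paragroupFromParent = TRUE) {
  if (!name %in% tree@nodes$name) stop("unknown node: ", name)
  mk <- tree@markers[[name]]
  if (length(mk) == 0L && paragroupFromParent && .isParagroupName(name)) {
    p <- parentOf(tree, name)
    if (!is.na(p)) mk <- tree@markers[[p]]
  }
  mk
}

setMethod("show", "PhyloTree", function(object) {
  cat("PhyloTree: ", nrow(object@nodes), " nodes, ",
      length(treeLeaves(object)), " leaves, max depth ",
      max(object@depths), "; root '", object@root, "'\n", sep = "")
})
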