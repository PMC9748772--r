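#' Read a rooted newick tree
#'
#' Thin, validating wrapper around [ape::read.tree()]. The returned object is
#' a standard `phylo`; branch lengths are interpreted as millions of years
#' throughout the package.
#'
#' @param text a newick string, or `NULL` to read from `file`.
#' @param file path to a newick file.
#' @return a rooted `phylo` object.
#' @export
readNewick <- function(text = NULL, file = NULL) {
  if (is.null(text)) {
    if (is.null(file)) stopf("supply `text` or `file`")
    text <- paste(readLines(file, warn = FALSE), collapse = "")
  }
  no <- sum(strsplit(text, "")[[1]] == "(")
  nc <- sum(strsplit(text, "")[[1]] == ")")
  if (no != nc) {
    stopf("malformed newick: %d '(' but %d ')'", no, nc)
  }
  tree <- tryCatch(ape::read.tree(text = text), error = function(e) NULL)
  if (is.null(tree)) stopf("malformed newick string")
  checkPhylo(tree)
  tree
}

#' Write a tree as newick with 9 significant digits
#'
#' @param tree a `phylo` object.
#' @param file optional output path; if `NULL` the string is returned.
#' @return newick string (invisibly, if written to file).
#' @export
writeNewick <- function(tree, file = NULL) {
  checkPhylo(tree)
  txt <- ape::write.tree(tree, digits = 9)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

#' Validate the structural invariants of a phylogeny
#'
#' Checks for a single root, unique tip labels, and finite non-negative branch
#' lengths. Zero-length branches are allowed but trigger a warning.
#'
#' @param tree a `phylo` object.
#' @return the tree, invisibly.
#' @export
checkPhylo <- function(tree) {
  if (!inherits(tree, "phylo")) stopf("not a `phylo` object")
  if (anyDuplicated(tree$tip.label)) {
    dup <- tree$tip.label[duplicated(tree$tip.label)][1]
    stopf("duplicate tip label: '%s'", dup)
  }
  if (is.null(tree$edge.length)) stopf("tree has no branch lengths")
  if (length(tree$edge.length) != nrow(tree$edge) ||
      anyNA(tree$edge.length)) {
    stopf("missing branch length on %d edge(s)",
          sum(is.na(tree$edge.length)))
  }
  if (any(!is.finite(tree$edge.length)) || any(tree$edge.length < 0)) {
    stopf("branch lengths must be finite and >= 0")
  }
  if (any(tree$edge.length == 0)) {
    warnf("tree contains %d zero-length branch(es)",
          sum(tree$edge.length == 0))
  }
  # exactly one root: one node that never appears as a child
  kids <- tree$edge[, 2]
  parents <- unique(tree$edge[, 1])
  roots <- setdiff(parents, kids)
  if (length(roots) != 1) stopf("tree must have exactly one root")
  invisible(tree)
}

#' Node depths (time from root) for every node
#'
#' @param tree a `phylo` object.
#' @return numeric vector indexed by node id (tips `1..n` first).
#' @export
nodeDepths <- function(tree) {
  n <- ape::Ntip(tree)
  nn <- n + tree$Nnode
  depth <- numeric(nn)
  pre <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(pre$edge))) {
    depth[pre$edge[e, 2]] <- depth[pre$edge[e, 1]] + pre$edge.length[e]
  }
  depth
}

#' Is the tree ultrametric?
#'
#' @param tree a `phylo` object.
#' @param tol absolute tolerance on tip-depth spread.
#' @return logical.
#' @export
isUltrametric <- function(tree, tol = 1e-6) {
  d <- nodeDepths(tree)[seq_len(ape::Ntip(tree))]
  diff(range(d)) <= tol
}

#' Branch lengths along the path from a tip to the root
#'
#' Returns the ordered branch lengths `l_1, ..., l_N` with `l_1` the tip's own
#' branch and `l_N` a child-of-root branch, as used by the DR statistic.
#'
#' @param tree a `phylo` object.
#' @param tip a tip label.
#' @return numeric vector of branch lengths (tip first).
#' @export
tipToRootEdges <- function(tree, tip) {
  i <- match(tip, tree$tip.label)
  if (is.na(i)) stopf("unknown tip label: '%s'", tip)
  root <- ape::Ntip(tree) + 1
  parent <- integer(max(tree$edge))
  elen <- numeric(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  elen[tree$edge[, 2]] <- tree$edge.length
  out <- numeric(0)
  node <- i
  while (node != root) {
    out <- c(out, elen[node])
    node <- parent[node]
  }
  out
}

# postorder edge ordering + companion structures used by likelihood code
postorderEdges <- function(tree) {
  po <- ape::reorder.phylo(tree, "postorder")
  list(edge = po$edge, len = po$edge.length, ntip = ape::Ntip(tree))
}
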