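#' Construct a painted phylogeny from per-branch state segments
#'
#' A painted phylogeny is a `phylo` carrying, for every branch, an ordered
#' list of `(state, duration)` segments. Internally segments run rootward to
#' tipward; the mapped-newick dialect lists them tipward to rootward (the
#' phytools / SIMMAP convention `A:{tip_state,dur:...:root_state,dur}`).
#' The object is a phytools-compatible `simmap`.
#'
#' @param tree a `phylo` object.
#' @param maps a list (one element per edge, in `tree$edge` row order) of
#'   named numeric vectors: names are states, values are durations, ordered
#'   rootward to tipward.
#' @param states optional declared state set; defaults to states observed.
#' @return an object of class `c("simmap", "phylo")`.
#' @export
paintedPhylo <- function(tree, maps, states = NULL) {
  checkPhylo(tree)
  if (length(maps) != nrow(tree$edge)) {
    stopf("`maps` must have one element per edge (%d)", nrow(tree$edge))
  }
  obj <- tree
  obj$maps <- maps
  states <- states %||% sort(unique(unlist(lapply(maps, names))))
  obj$mapped.edge <- mappedEdgeMatrix(maps, states)
  class(obj) <- c("simmap", class(tree))
  checkPainting(obj, states = states)
  obj
}

mappedEdgeMatrix <- function(maps, states) {
  me <- matrix(0, length(maps), length(states),
               dimnames = list(NULL, states))
  for (e in seq_along(maps)) {
    for (s in names(maps[[e]])) me[e, s] <- me[e, s] + sum(maps[[e]][names(maps[[e]]) == s])
  }
  me
}

#' Validate a painting against its tree
#'
#' Segment durations on each branch must be positive (a single zero-duration
#' segment is permitted only on a zero-length branch), sum to the branch
#' length within `tol`, use states from the declared state set, and adjacent
#' segments must differ in state.
#'
#' @param ptree a painted phylogeny (`simmap`).
#' @param states optional declared state set.
#' @param tol duration-sum tolerance.
#' @return the painting, invisibly.
#' @export
checkPainting <- function(ptree, states = NULL, tol = 1e-9) {
  if (is.null(ptree$maps)) stopf("tree carries no painting")
  for (e in seq_along(ptree$maps)) {
    seg <- ptree$maps[[e]]
    len <- ptree$edge.length[e]
    if (length(seg) < 1) stopf("branch %d has no segments", e)
    if (len == 0) {
      if (!(length(seg) == 1 && seg[[1]] == 0)) {
        stopf("zero-length branch %d must carry one zero-duration segment", e)
      }
    } else if (any(seg <= 0)) {
      stopf("branch %d has a non-positive segment duration", e)
    }
    if (abs(sum(seg) - len) > tol) {
      stopf("branch %d: segment durations sum to %.9g but length is %.9g",
            e, sum(seg), len)
    }
    if (length(seg) > 1 && any(names(seg)[-1] == names(seg)[-length(seg)])) {
      stopf("branch %d has adjacent segments with equal state", e)
    }
    if (!is.null(states) && !all(names(seg) %in% states)) {
      stopf("branch %d uses state outside the declared set: %s", e,
            paste(setdiff(names(seg), states), collapse = ", "))
    }
  }
  invisible(ptree)
}

#' Read a painted (mapped-newick) tree
#'
#' Parses the `{state,duration:state,duration}` branch-annotation dialect
#' via [phytools::read.simmap()] and validates the painting.
#'
#' @param text mapped-newick string, or `NULL` to read from `file`.
#' @param file path to a mapped-newick file.
#' @param tol duration-sum tolerance for validation.
#' @return a painted phylogeny (`simmap`).
#' @export
readPaintedNewick <- function(text = NULL, file = NULL, tol = 1e-9) {
  if (is.null(text)) {
    if (is.null(file)) stopf("supply `text` or `file`")
    text <- paste(readLines(file, warn = FALSE), collapse = "\n")
  }
  ptree <- tryCatch(phytools::read.simmap(text = text, format = "phylip"),
                    error = function(e) stopf("malformed mapped-newick: %s",
                                              conditionMessage(e)))
  if (inherits(ptree, "multiSimmap") || inherits(ptree, "multiPhylo")) {
    for (t in ptree) checkPainting(t, tol = tol)
  } else {
    checkPainting(ptree, tol = tol)
  }
  ptree
}

#' Write a painted tree as mapped-newick
#'
#' @param ptree a painted phylogeny, or a list of them.
#' @param file optional output path.
#' @return mapped-newick string(s).
#' @export
writePaintedNewick <- function(ptree, file = NULL) {
  trees <- if (inherits(ptree, "simmap")) list(ptree) else ptree
  txt <- vapply(trees, function(t) {
    paste(utils::capture.output(
      phytools::write.simmap(t, file = "", map.order = "right-to-left")),
      collapse = "")
  }, character(1))
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  if (length(txt) == 1) txt[[1]] else txt
}

#' Strip a painting, returning the bare phylogeny
#'
#' @param ptree a painted phylogeny.
#' @return a `phylo` object.
#' @export
unpaint <- function(ptree) {
  tree <- ptree
  tree$maps <- NULL
  tree$mapped.edge <- NULL
  tree$node.states <- NULL
  tree$states <- NULL
  tree$Q <- NULL
  tree$logL <- NULL
  class(tree) <- "phylo"
  tree
}

#' States used by a painting
#'
#' @param ptree a painted phylogeny.
#' @return character vector of states.
#' @export
paintingStates <- function(ptree) {
  sort(unique(unlist(lapply(ptree$maps, names))))
}

#' Paint a tree uniformly from tip states (single state per branch lineage)
#'
#' Utility painting for regime-dependent continuous models when only tip
#' states are known: each branch gets its tipward clade's reconstructed state
#' via parsimony-free "descendant state" assignment is not attempted; instead
#' every branch is painted with the state of its child node if the child is a
#' tip, else with `default`. Prefer paintings sampled by [sampleHistories()].
#'
#' @param tree a `phylo` object.
#' @param tip_states named character vector (species to state).
#' @param default state for internal branches.
#' @return a painted phylogeny.
#' @export
paintFromTips <- function(tree, tip_states, default) {
  maps <- vector("list", nrow(tree$edge))
  ntip <- ape::Ntip(tree)
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2]
    st <- if (child <= ntip) unname(tip_states[tree$tip.label[child]]) else default
    maps[[e]] <- setNames(tree$edge.length[e], st)
  }
  paintedPhylo(tree, maps)
}
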