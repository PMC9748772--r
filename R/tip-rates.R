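#' Equal-splits measure and DR tip speciation rates
#'
#' For tip `i` with root-to-tip edges `l_1, ..., l_N` (edge 1 the tip's own
#' branch), the equal-splits measure is `ES_i = sum_j l_j (1/2)^(j-1)` (an
#' expected per-lineage waiting time, Myr) and the DR statistic is
#' `DR_i = 1 / ES_i` (speciation events per Myr). Computed for all tips in a
#' single preorder pass; identical to the per-tip path definition. A root
#' edge, if present, is ignored: paths end at the root node.
#'
#' @param tree a `phylo` object with branch lengths in Myr.
#' @return a data frame with `species`, `ES`, `DR`, `N_edges`.
#' @export
drStatistic <- function(tree) {
  checkPhylo(tree)
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  # es[v]: equal-splits contribution of the path root -> v, with the weight
  # of the edge *closest to v* equal to 1; going one edge tipward halves the
  # accumulated value and adds the new edge.
  es <- numeric(nn)
  nedges <- integer(nn)
  pre <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(pre$edge))) {
    p <- pre$edge[e, 1]
    v <- pre$edge[e, 2]
    es[v] <- es[p] / 2 + pre$edge.length[e]
    nedges[v] <- nedges[p] + 1L
  }
  ES <- es[seq_len(ntip)]
  if (any(ES <= 0)) {
    stopf("tip(s) with zero root-to-tip path length: %s",
          paste(tree$tip.label[ES <= 0], collapse = ", "))
  }
  data.frame(species = tree$tip.label, ES = ES, DR = 1 / ES,
             N_edges = nedges[seq_len(ntip)], stringsAsFactors = FALSE)
}
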