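#' Default raw foraging-niche to four-state map
#'
#' Maps raw foraging-niche labels to the four-state diving system
#' (`non-diving`, `plunge`, `foot`, `wing`). Splitting pursuit divers into
#' foot- versus wing-propelled cannot be recovered from the raw labels alone;
#' the default sends `"aquatic dive"` to `foot`, and the per-species override
#' table is the supported way to resolve pursuit mode and the handful of
#' surface/generalist taxa that also plunge dive. Exposed as data so projects
#' can supply their own mapping.
#'
#' @return named character vector (raw label to four-state label).
#' @export
defaultNicheMap <- function() {
  c("aquatic plunge"  = "plunge",
    "aquatic dive"    = "foot",
    "aquatic surface" = "non-diving",
    "aquatic aerial"  = "non-diving",
    "generalist"      = "non-diving",
    "terrestrial"     = "non-diving")
}

#' Four-state and two-state niche labels
#' @return character vector of state names.
#' @export
nicheStates4 <- function() c("non-diving", "plunge", "foot", "wing")

#' @rdname nicheStates4
#' @export
nicheStates2 <- function() c("non-diving", "diving")

#' Classify species into the two- and four-state diving systems
#'
#' Species with raw niche `"aquatic plunge"` or `"aquatic dive"` are diving;
#' everything else is non-diving unless overridden. The four-state label comes
#' from `niche_map` and is replaced by any per-species override, which always
#' wins (this is how manual reference-work recategorizations enter the
#' pipeline). `niche2` is then derived from `niche4` so the two systems stay
#' consistent.
#'
#' @param raw a data frame with columns `species` and `raw_niche` (other
#'   columns such as `diet`, `mass_log10`, `iucn`, `flightless` are carried
#'   through).
#' @param overrides named character vector: species to four-state label.
#' @param niche_map named character vector: raw label to four-state label.
#' @return the trait table with `niche2` and `niche4` columns; per-class
#'   counts in `attr(, "counts")`.
#' @export
classifyNiches <- function(raw, overrides = NULL,
                           niche_map = defaultNicheMap()) {
  if (!all(c("species", "raw_niche") %in% names(raw))) {
    stopf("`raw` needs columns `species` and `raw_niche`")
  }
  if (anyDuplicated(raw$species)) stopf("duplicate species in trait table")
  unmapped <- setdiff(unique(raw$raw_niche), names(niche_map))
  if (length(unmapped)) {
    stopf("unmapped raw niche label(s): %s", paste(unmapped, collapse = ", "))
  }
  tab <- raw
  tab$niche4 <- unname(niche_map[tab$raw_niche])
  if (!is.null(overrides) && length(overrides)) {
    unknown <- setdiff(names(overrides), tab$species)
    if (length(unknown)) {
      stopf("override names unknown species: %s",
            paste(unknown, collapse = ", "))
    }
    bad <- setdiff(unique(overrides), nicheStates4())
    if (length(bad)) stopf("invalid override state(s): %s",
                           paste(bad, collapse = ", "))
    idx <- match(names(overrides), tab$species)
    tab$niche4[idx] <- unname(overrides)
  }
  tab$niche2 <- ifelse(tab$niche4 == "non-diving", "non-diving", "diving")
  counts <- table(factor(tab$niche4, levels = nicheStates4()))
  attr(tab, "counts") <- counts
  tab
}

#' Reconcile a trait table with a tree's tip labels
#'
#' Reports species present in only one of the two; with `prune = TRUE`
#' returns the tree and table restricted to the intersection. The pipeline
#' refuses to run on any mismatch unless pruning is requested.
#'
#' @param table a trait table with a `species` column.
#' @param tree a `phylo` object.
#' @param prune restrict both to the common species?
#' @return a list with `missing_in_table`, `missing_in_tree`, `ok`, and (if
#'   `prune`) the pruned `tree` and `table`.
#' @export
validateAgainstTree <- function(table, tree, prune = FALSE) {
  in_tree <- tree$tip.label
  in_tab <- table$species
  rep <- list(missing_in_table = setdiff(in_tree, in_tab),
              missing_in_tree = setdiff(in_tab, in_tree))
  rep$ok <- length(rep$missing_in_table) == 0 &&
    length(rep$missing_in_tree) == 0
  if (prune) {
    common <- intersect(in_tree, in_tab)
    if (length(common) < 2) stopf("fewer than 2 species in common")
    drop <- setdiff(in_tree, common)
    rep$tree <- if (length(drop)) ape::drop.tip(tree, drop) else tree
    rep$table <- table[table$species %in% common, , drop = FALSE]
  }
  rep
}

#' Read / write the trait-table CSV schema
#'
#' Columns: `species, raw_niche, niche2, niche4, diet, mass_log10, iucn,
#' flightless` (UTF-8, "." decimal). Missing optional columns are tolerated
#' on read.
#'
#' @param file path to CSV.
#' @return data frame.
#' @export
readTraitTable <- function(file) {
  tab <- utils::read.csv(file, stringsAsFactors = FALSE,
                         comment.char = "#")
  if (!"species" %in% names(tab)) stopf("trait CSV lacks `species` column")
  tab
}

#' @rdname readTraitTable
#' @param table trait table to write.
#' @export
writeTraitTable <- function(table, file) {
  utils::write.csv(table, file, row.names = FALSE, quote = TRUE)
  invisible(file)
}
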