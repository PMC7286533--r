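#' Synthetic stand-in phylogenies
#'
#' Programmatically constructed trees shipped with the package for
#' simulation studies and tests: a 36-taxon mammal-like tree of total size
#' 6.18 expected neutral substitutions per site, containing a `human`/
#' `chimp` pair with realistically short terminal branches inside an
#' 18-taxon supraprimate-like clade (`human`, `chimp`, `sup03..sup18`;
#' the remaining taxa are `lau01..lau18`), and a 100-taxon vertebrate-like
#' tree of total size 18.5.  These are synthetic: topologies and branch
#' lengths are randomly generated and calibrated only in their totals and
#' the focal pair; they stand in for genome-browser neutral trees, which
#' are not redistributed here.
#'
#' @return A `phylo` object.
#' @export
synthetic_mammal_tree <- function() {
  parse_newick(system.file("extdata", "synthetic_mammal36.nwk",
                           package = "gerpmix", mustWork = TRUE))
}

#' @rdname synthetic_mammal_tree
#' @export
synthetic_vertebrate_tree <- function() {
  parse_newick(system.file("extdata", "synthetic_vertebrate100.nwk",
                           package = "gerpmix", mustWork = TRUE))
}

#' Supraprimate-like taxon set of the synthetic mammal tree
#'
#' The 18 tips forming the supraprimate-like clade of
#' [synthetic_mammal_tree()], used for phylogenetic-scope experiments.
#'
#' @return Character vector of 18 tip labels.
#' @export
synthetic_supraprimates <- function() {
  c("human", "chimp", paste0("sup", sprintf("%02d", 3:18)))
}
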