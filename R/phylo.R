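#' Parse a rooted newick tree with branch lengths
#'
#' Reads a newick string or file into an [ape::phylo] object and validates the
#' contract assumed throughout the package: the tree is rooted, every edge
#' carries a non-negative branch length (in expected neutral substitutions per
#' site), and leaf labels are unique.
#'
#' @param text A newick string, or the path of a file containing one tree.
#' @return A `phylo` object.
#' @examples
#' tr <- parse_newick("((A:0.2,B:0.3):0.1,C:0.4);")
#' tree_size(tr)
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!grepl("\\(", text) && file.exists(text)) {
    text <- paste(readLines(text, warn = FALSE), collapse = "")
  }
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr)) {
    # locate the first structural problem for the error message
    open <- cumsum((strsplit(text, "")[[1]] == "(") -
                     (strsplit(text, "")[[1]] == ")"))
    off <- if (any(open < 0)) which(open < 0)[1] else nchar(text)
    stop("malformed newick near character offset ", off)
  }
  validate_tree(tr)
  tr
}

#' @keywords internal
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' tree")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (anyNA(tree$edge.length)) stop("missing branch length on some edge")
  if (any(tree$edge.length < 0)) stop("negative branch length")
  if (anyDuplicated(tree$tip.label)) stop("duplicate leaf labels")
  invisible(tree)
}

#' Write a tree as newick text
#'
#' @param tree A `phylo` object.
#' @param file Optional file path; if `NULL` the newick string is returned.
#' @return The newick string (invisibly when writing to a file).
#' @export
write_newick <- function(tree, file = NULL) {
  txt <- ape::write.tree(tree)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

#' Total tree size
#'
#' The sum of all branch lengths, in expected neutral substitutions per site.
#' This is also the largest attainable rejected-substitution score for a
#' gap-free invariant alignment column on the tree.
#'
#' @param tree A `phylo` object.
#' @return A single non-negative number.
#' @export
tree_size <- function(tree) {
  validate_tree(tree)
  sum(tree$edge.length)
}

#' Project a tree onto a subset of taxa
#'
#' Keeps only the given leaves, collapsing degree-2 internal nodes with branch
#' lengths summed, and dropping any stem above the common ancestor of the kept
#' taxa.  The result is the subtree a site aligned only in those species
#' effectively evolves on, so its size never exceeds the input's.
#'
#' @param tree A `phylo` object.
#' @param taxa Character vector of leaf labels to keep (at least one, all
#'   present in the tree).
#' @return A `phylo` object with `length(taxa)` leaves.
#' @export
prune_to_taxa <- function(tree, taxa) {
  validate_tree(tree)
  if (length(taxa) == 0L) stop("empty taxon set")
  missing <- setdiff(taxa, tree$tip.label)
  if (length(missing) > 0L) {
    stop("unknown taxa: ", paste(missing, collapse = ", "))
  }
  if (length(taxa) == length(tree$tip.label)) return(tree)
  ape::keep.tip(tree, taxa)
}

#' Smallest-increment species addition sequence
#'
#' Starting from a seed set of leaves, repeatedly adds the leaf whose addition
#' increases the projected tree size by the smallest amount (ties broken by
#' lexicographic leaf label), until the whole tree is covered.  The projected
#' tree size of a leaf set is the total length of the minimal subtree spanning
#' those leaves (identical to `tree_size(prune_to_taxa(tree, set))`).
#'
#' @param tree A `phylo` object.
#' @param seed_taxa At least two leaf labels to start from.
#' @return A data frame with one row per added leaf: `taxon`, `increment`, and
#'   `cumulative_size` (projected tree size after the addition).  The attribute
#'   `"seed_size"` holds the projected size of the seed set.  Zero rows when
#'   the seed already contains every leaf.
#' @export
grow_species_sequence <- function(tree, seed_taxa) {
  validate_tree(tree)
  if (length(seed_taxa) < 2L) stop("need at least two seed taxa")
  missing <- setdiff(seed_taxa, tree$tip.label)
  if (length(missing) > 0L) {
    stop("seed taxa absent from tree: ", paste(missing, collapse = ", "))
  }
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  # adjacency of the unrooted tree
  adj <- vector("list", nnode)
  for (e in seq_len(nrow(tree$edge))) {
    a <- tree$edge[e, 1]; b <- tree$edge[e, 2]; w <- tree$edge.length[e]
    adj[[a]] <- rbind(adj[[a]], c(b, w))
    adj[[b]] <- rbind(adj[[b]], c(a, w))
  }
  seed_ids <- match(seed_taxa, tree$tip.label)
  # covered = nodes of the Steiner tree of the current leaf set
  covered <- rep(FALSE, nnode)
  covered[mark_steiner(tree, seed_ids)] <- TRUE
  size <- steiner_size(tree, covered)

  out_taxon <- character(0); out_inc <- numeric(0); out_size <- numeric(0)
  remaining <- setdiff(seq_len(ntip), which(covered[seq_len(ntip)]))
  while (length(remaining) > 0L) {
    # multi-source traversal outward from the covered subtree
    dist <- rep(NA_real_, nnode); parent <- rep(NA_integer_, nnode)
    queue <- which(covered); dist[queue] <- 0
    head <- 1L
    while (head <= length(queue)) {
      v <- queue[head]; head <- head + 1L
      nb <- adj[[v]]
      if (!is.null(nb)) for (k in seq_len(nrow(nb))) {
        u <- nb[k, 1]
        if (is.na(dist[u])) {
          dist[u] <- dist[v] + nb[k, 2]
          parent[u] <- v
          queue <- c(queue, u)
        }
      }
    }
    inc <- dist[remaining]
    labs <- tree$tip.label[remaining]
    best <- remaining[order(inc, labs)[1]]
    size <- size + dist[best]
    out_taxon <- c(out_taxon, tree$tip.label[best])
    out_inc <- c(out_inc, dist[best])
    out_size <- c(out_size, size)
    v <- best
    while (!is.na(v) && !covered[v]) { covered[v] <- TRUE; v <- parent[v] }
    remaining <- setdiff(remaining, best)
  }
  res <- data.frame(taxon = out_taxon, increment = out_inc,
                    cumulative_size = out_size, stringsAsFactors = FALSE)
  attr(res, "seed_size") <- steiner_size(tree, {
    cv <- rep(FALSE, nnode); cv[mark_steiner(tree, seed_ids)] <- TRUE; cv
  })
  res
}

# nodes on the minimal spanning subtree of the given tip ids
#' @keywords internal
mark_steiner <- function(tree, tip_ids) {
  ntip <- length(tree$tip.label)
  par <- integer(ntip + tree$Nnode)
  par[tree$edge[, 2]] <- tree$edge[, 1]
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  # count, for every node, how many of the target tips lie below it
  below <- integer(ntip + tree$Nnode)
  for (t in tip_ids) {
    v <- t
    while (v != root) { below[v] <- below[v] + 1L; v <- par[v] }
    below[root] <- below[root] + 1L
  }
  k <- length(tip_ids)
  # the Steiner tree consists of nodes with 1 <= below < k, plus the MRCA
  on_path <- which(below > 0L & below < k)
  mrca <- root
  repeat {
    kids <- tree$edge[tree$edge[, 1] == mrca, 2]
    full <- kids[below[kids] == k]
    if (length(full) == 1L) mrca <- full else break
  }
  unique(c(on_path, mrca))
}

#' @keywords internal
steiner_size <- function(tree, covered) {
  sum(tree$edge.length[covered[tree$edge[, 1]] & covered[tree$edge[, 2]]])
}
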