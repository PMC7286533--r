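# column-wise maximum of a small-row-count matrix
#' @keywords internal
col_max <- function(M) {
  if (nrow(M) <= 8L) do.call(pmax, lapply(seq_len(nrow(M)), function(i) M[i, ]))
  else apply(M, 2, max)
}

# log-likelihood of every column under the model on the tree scaled by r
# cols: nstates-coded integer matrix (tips x n, no gaps), rows in
# tree$tip.label order; scale: scalar or per-site vector
#' @keywords internal
pruning_loglik <- function(tree, cols, model, scale) {
  ntip <- nrow(cols)
  n <- ncol(cols)
  scale <- rep_len(scale, n)
  scalar <- all(scale == scale[1])
  nnode <- ntip + tree$Nnode
  partial <- vector("list", nnode)
  logscale <- numeric(n)
  post <- rev(edge_preorder(tree))
  lam <- model$lambda; A <- model$A; B <- model$B
  for (e in post) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    L <- tree$edge.length[e]
    if (scalar) {
      P <- A %*% (exp(lam * (L * scale[1])) * B)
      P[P < 0] <- 0
      if (ch <= ntip) M <- P[, cols[ch, ], drop = FALSE]     # nstates x n
      else M <- P %*% partial[[ch]]
    } else {
      E <- exp(outer(lam, L * scale))                        # k x n
      if (ch <= ntip) G <- B[, cols[ch, ], drop = FALSE]
      else G <- B %*% partial[[ch]]
      M <- A %*% (G * E)
      M[M < 0] <- 0
    }
    # rescale per site against underflow on deep trees
    mx <- col_max(M)
    mx[mx <= 0] <- 1
    M <- M * rep(1 / mx, each = nrow(M))
    logscale <- logscale + log(mx)
    if (is.null(partial[[p]])) partial[[p]] <- M
    else partial[[p]] <- partial[[p]] * M
  }
  root <- ntip + 1L
  lik <- colSums(model$freqs * partial[[root]])
  log(pmax(lik, .Machine$double.xmin)) + logscale
}

# per-site ML branch-length multiplier r in [0, r_max]
#' @keywords internal
ml_scale_columns <- function(tree, cols, model, r_max = 3, tol = 1e-6,
                             grid_n = 16L) {
  n <- ncol(cols)
  invariant <- colSums(cols != rep(cols[1, ], each = nrow(cols))) == 0L
  rhat <- numeric(n)
  todo <- which(!invariant)
  if (length(todo)) {
    sub <- cols[, todo, drop = FALSE]
    grid <- seq(0, r_max, length.out = grid_n)
    ll <- vapply(grid, function(r) pruning_loglik(tree, sub, model, r),
                 numeric(length(todo)))
    if (length(todo) == 1L) ll <- matrix(ll, nrow = 1L)
    best <- max.col(ll, ties.method = "first")
    a <- grid[pmax(best - 1L, 1L)]
    b <- grid[pmin(best + 1L, grid_n)]
    gr <- (sqrt(5) - 1) / 2
    x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
    f1 <- pruning_loglik(tree, sub, model, x1)
    f2 <- pruning_loglik(tree, sub, model, x2)
    iters <- ceiling(log(tol / max(b - a)) / log(gr))
    for (it in seq_len(max(iters, 1L))) {
      left <- f1 > f2
      b[left] <- x2[left]; x2[left] <- x1[left]; f2[left] <- f1[left]
      x1[left] <- b[left] - gr * (b[left] - a[left])
      rt <- !left
      a[rt] <- x1[rt]; x1[rt] <- x2[rt]; f1[rt] <- f2[rt]
      x2[rt] <- a[rt] + gr * (b[rt] - a[rt])
      newx <- ifelse(left, x1, x2)
      fnew <- pruning_loglik(tree, sub, model, newx)
      f1[left] <- fnew[left]
      f2[rt] <- fnew[rt]
    }
    rhat[todo] <- (a + b) / 2
  }
  rhat
}

# character alignment columns -> integer codes; gaps ("-", ".", "N", NA) -> NA
#' @keywords internal
encode_columns <- function(cols, model) {
  m <- matrix(match(toupper(cols), model$levels), nrow(cols), ncol(cols),
              dimnames = dimnames(cols))
  m
}

#' Estimate substitutions for one alignment column
#'
#' Projects the tree onto the column's ungapped species, then finds the
#' branch-length multiplier `r` in `[0, r_max]` that maximizes the column's
#' phylogenetic (pruning) likelihood under the model, with base frequencies
#' fixed to the model's values.  The estimated number of substitutions is
#' `E = r * T` where `T` is the projected tree size; invariant columns give
#' `r = 0` exactly.
#'
#' @param column Named character vector (or single-column matrix) of states
#'   per species; `NA`, `"-"`, `"."` and `"N"` are gaps.
#' @param tree A `phylo` object containing the column's species.
#' @param model A `subst_model`.
#' @param r_max Upper bound of the rate-multiplier search (default 3).
#' @param tol Absolute tolerance of the scale search (default 1e-6).
#' @return A list with `tree_size` (T) and `subs` (E).
#' @export
estimate_substitutions <- function(column, tree, model, r_max = 3,
                                   tol = 1e-6) {
  if (is.matrix(column)) column <- stats::setNames(column[, 1], rownames(column))
  sc <- score_columns(matrix(column, ncol = 1,
                             dimnames = list(names(column), NULL)),
                      tree, model, r_max = r_max, tol = tol)
  list(tree_size = sc$tree_size[1], subs = sc$subs[1])
}

#' Rejected-substitution score of one column
#'
#' `RS = T - E`: the deficit of estimated substitutions relative to the
#' neutral expectation on the projected tree.  Positive scores indicate
#' constraint, negative scores faster-than-neutral evolution.  The
#' standardized score `RS / T` is 1 for perfectly conserved columns and
#' near 0 for neutral ones.
#'
#' @inheritParams estimate_substitutions
#' @return A one-row data frame with `tree_size`, `subs`, `rs`,
#'   `standardized`, `n_leaves`.
#' @export
rs_score <- function(column, tree, model, r_max = 3, tol = 1e-6) {
  if (is.matrix(column)) column <- stats::setNames(column[, 1], rownames(column))
  score_columns(matrix(column, ncol = 1,
                       dimnames = list(names(column), NULL)),
                tree, model, r_max = r_max, tol = tol)
}

#' Score many alignment columns
#'
#' Vectorized rejected-substitution scoring.  Columns are grouped by their
#' species-presence pattern; for each pattern the tree is projected onto the
#' ungapped species and the ML rate multiplier is found per column (grid
#' bracketing plus golden-section refinement).  When a focal species is
#' declared its allele is excluded from scoring, mirroring genome-browser
#' GERP tracks that omit the reference allele.
#'
#' @param cols Character matrix, species x sites; row names must match tree
#'   tip labels.  `NA`, `"-"`, `"."` and `"N"` are gaps.
#' @param tree A `phylo` object.
#' @param model A `subst_model`.
#' @param focal Optional focal species excluded from scoring.
#' @param r_max,tol Rate-multiplier search control.
#' @param min_leaves Minimum ungapped species per site (default 2); sites
#'   below it are returned as `NA` rows with a warning.
#' @return Data frame with one row per input column: `tree_size`, `subs`,
#'   `rs`, `standardized`, `n_leaves`.
#' @export
score_columns <- function(cols, tree, model, focal = NULL, r_max = 3,
                          tol = 1e-6, min_leaves = 2L) {
  validate_tree(tree)
  stopifnot(is.matrix(cols), !is.null(rownames(cols)))
  bad <- setdiff(rownames(cols), tree$tip.label)
  if (length(bad)) stop("species not in tree: ", paste(bad, collapse = ", "))
  if (!is.null(focal)) {
    if (!focal %in% rownames(cols)) stop("focal species not in alignment")
    cols <- cols[setdiff(rownames(cols), focal), , drop = FALSE]
  }
  enc <- encode_columns(cols, model)
  n <- ncol(enc)
  out <- data.frame(tree_size = rep(NA_real_, n), subs = NA_real_,
                    rs = NA_real_, standardized = NA_real_,
                    n_leaves = NA_integer_)
  present <- !is.na(enc)
  pat <- apply(present, 2, function(z) paste(which(z), collapse = ","))
  skipped <- 0L
  for (key in unique(pat)) {
    idx <- which(pat == key)
    rows <- as.integer(strsplit(key, ",")[[1]])
    out$n_leaves[idx] <- length(rows)
    if (length(rows) < min_leaves) { skipped <- skipped + length(idx); next }
    taxa <- rownames(enc)[rows]
    ptree <- prune_to_taxa(tree, taxa)
    Tsize <- tree_size(ptree)
    sub <- enc[rows, idx, drop = FALSE][match(ptree$tip.label, taxa), ,
                                        drop = FALSE]
    rhat <- ml_scale_columns(ptree, sub, model, r_max = r_max, tol = tol)
    E <- rhat * Tsize
    out$tree_size[idx] <- Tsize
    out$subs[idx] <- E
    out$rs[idx] <- Tsize - E
    out$standardized[idx] <- if (Tsize > 0) (Tsize - E) / Tsize else NA_real_
  }
  if (skipped > 0L)
    warning(skipped, " site(s) skipped: fewer than ", min_leaves,
            " ungapped species")
  out
}

#' Neutral GERP-score cutoff
#'
#' Simulates `n_sims` neutral columns on the tree, scores them, and returns
#' the requested upper quantile of the raw RS distribution — the cutoff at
#' which the neutral false-positive rate equals `1 - quantile`.
#'
#' @param tree A `phylo` object.
#' @param model A `subst_model`.
#' @param n_sims Number of neutral simulations (`>= 1000`).
#' @param quantile Upper quantile (default 0.95).
#' @param seed Optional integer seed.
#' @return The RS cutoff (a single number) with attribute `"scores"` holding
#'   the simulated neutral RS values.
#' @export
neutral_cutoff <- function(tree, model, n_sims = 10000L, quantile = 0.95,
                           seed = NULL) {
  if (n_sims < 1000L) stop("n_sims must be at least 1000")
  cols <- simulate_columns(tree, model, n_sims, seed = seed)
  sc <- score_columns(cols, tree, model)
  cut <- stats::quantile(sc$rs, probs = quantile, names = FALSE, type = 7)
  attr(cut, "scores") <- sc$rs
  cut
}

#' Detection power at a score cutoff
#'
#' @param scores Numeric vector of RS scores from sites under the
#'   alternative (selected) scenario.
#' @param cutoff RS cutoff (scores strictly above count as detected).
#' @return Fraction of scores above the cutoff.
#' @export
detection_power <- function(scores, cutoff) {
  if (length(scores) == 0L) stop("empty score list")
  mean(scores > cutoff)
}

#' Simulate standardized scores for one mixture component
#'
#' Produces the scored-site table for sites of category N (neutral on the
#' whole tree), C (constrained everywhere: no substitutions, standardized
#' score exactly 1), or TO (functional turnover: substitutions occur only on
#' nonfunctional stretches, `omega = 0` on functional ones unless
#' overridden).
#'
#' @param tree A `phylo` object (typically a tree-size bin's representative
#'   subtree).
#' @param model A `subst_model`.
#' @param component `"N"`, `"C"`, or `"TO"`.
#' @param n Number of sites.
#' @param params [turnover_params()] for the TO component.
#' @param omega Rate ratio on functional segments for TO (default 0).
#' @param seed Optional integer seed.
#' @param condition_focal,focal Optional focal-tip conditioning for TO (see
#'   [simulate_histories()]).
#' @return Data frame as from [score_columns()], with a `tip_functional`
#'   column for TO when a focal tip is named.
#' @export
simulate_component_scores <- function(tree, model, component, n,
                                      params = turnover_params(), omega = 0,
                                      seed = NULL,
                                      condition_focal = "none",
                                      focal = NULL) {
  validate_tree(tree)
  component <- match.arg(component, c("N", "C", "TO"))
  if (!is.null(seed)) set.seed(seed)
  Tsize <- tree_size(tree)
  if (component == "C") {
    return(data.frame(tree_size = rep(Tsize, n), subs = 0, rs = Tsize,
                      standardized = 1, n_leaves = length(tree$tip.label)))
  }
  if (component == "N") {
    cols <- simulate_columns(tree, model, n)
    return(score_columns(cols, tree, model))
  }
  h <- simulate_histories(tree, params, n, condition_focal = condition_focal,
                          focal = focal)
  scl <- omega * h$frac_functional + (1 - h$frac_functional)
  cols <- simulate_columns(tree, model, n, edge_scale = scl)
  sc <- score_columns(cols, tree, model)
  if (!is.null(focal)) sc$tip_functional <- h$tip_state[focal, ] == 1L
  sc
}

#' Read a gerpcol-style score table
#'
#' Two tab-separated columns, `tree_size` and `rs`, optionally preceded by
#' `chrom` and `pos` columns (1-based positions).
#'
#' @param file Path to a TSV file (no header).
#' @return Data frame with columns `tree_size`, `rs` and, when present,
#'   `chrom`, `pos`.
#' @export
read_gerp_scores <- function(file) {
  d <- utils::read.table(file, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  if (ncol(d) == 2L) {
    names(d) <- c("tree_size", "rs")
  } else if (ncol(d) == 4L) {
    names(d) <- c("chrom", "pos", "tree_size", "rs")
  } else stop("expected 2 or 4 tab-separated columns")
  d
}

#' Write a gerpcol-style score table
#'
#' @param scores Data frame with `tree_size` and `rs` (and optionally
#'   `chrom`, `pos`, written first).
#' @param file Output path.
#' @export
write_gerp_scores <- function(scores, file) {
  cols <- intersect(c("chrom", "pos", "tree_size", "rs"), names(scores))
  utils::write.table(scores[, cols], file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' Drop scored sites falling in BED exclusion regions
#'
#' Standard BED intervals (0-based, half-open) are removed from a score
#' table that carries `chrom`/`pos` columns (1-based site positions).
#'
#' @param scores Data frame with `chrom` and `pos` columns.
#' @param bed_file Path to a BED file.
#' @return The score table without excluded sites.
#' @export
filter_scores_bed <- function(scores, bed_file) {
  if (!all(c("chrom", "pos") %in% names(scores)))
    stop("score table has no chrom/pos columns")
  excl <- rtracklayer::import(bed_file, format = "BED")
  sites <- GenomicRanges::GRanges(scores$chrom,
                                  IRanges::IRanges(scores$pos, scores$pos))
  hits <- GenomicRanges::countOverlaps(sites, excl)
  scores[hits == 0L, , drop = FALSE]
}

#' Simulate and score sites with a distribution of fitness effects
#'
#' Each site draws a scaled selection coefficient from the DFE.  Without
#' turnover, the whole tree is scaled by `omega(nes)` for that site.  With
#' turnover, the site additionally follows the two-state functional process
#' and only functional stretches evolve at the reduced rate.  Sites are
#' labelled by whether they are under selection at the focal tip: with
#' turnover, functional at the focal tip and `nes < 0`; without, simply
#' `nes < 0`.
#'
#' @param tree A `phylo` object.
#' @param model A `subst_model`.
#' @param n Number of sites.
#' @param dfe A [dfe_spec()].
#' @param turnover A [turnover_params()], or `NULL` for constant selection.
#' @param focal Focal tip label used for the selection label.
#' @param seed Optional integer seed.
#' @return [score_columns()] output plus columns `nes` and
#'   `focal_selected`.
#' @export
simulate_dfe_scores <- function(tree, model, n, dfe,
                                turnover = NULL, focal = "human",
                                seed = NULL) {
  validate_tree(tree)
  if (!is.null(seed)) set.seed(seed)
  nes <- sample_dfe(dfe, n)
  om <- omega_from_nes(nes)
  n_edge <- nrow(tree$edge)
  if (is.null(turnover)) {
    scl <- matrix(om, n_edge, n, byrow = TRUE)
    focal_selected <- nes < 0
  } else {
    h <- simulate_histories(tree, turnover, n)
    omm <- matrix(om, n_edge, n, byrow = TRUE)
    scl <- omm * h$frac_functional + (1 - h$frac_functional)
    focal_selected <- (h$tip_state[focal, ] == 1L) & nes < 0
  }
  cols <- simulate_columns(tree, model, n, edge_scale = scl)
  sc <- score_columns(cols, tree, model)
  sc$nes <- nes
  sc$focal_selected <- focal_selected
  sc
}
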