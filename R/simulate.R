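#' Functional-turnover rate parameters
#'
#' Two-state Markov rates for the gain and loss of function along a
#' phylogeny, per unit branch length (i.e. per expected neutral
#' substitution): a functional site loses function at rate `b`, a
#' nonfunctional site gains function at rate `c`.  The stationary functional
#' fraction is `c / (b + c)`.  Defaults are the intergenic noncoding
#' estimates used throughout the package: `b = 2.48`, `c = 0.19`
#' (equilibrium ~7% functional).
#'
#' @param b Loss rate (`>= 0`).
#' @param c Gain rate (`>= 0`); `b + c` must be positive.
#' @return An object of class `turnover_params`.
#' @export
turnover_params <- function(b = 2.48, c = 0.19) {
  if (is.na(b) || is.na(c) || b < 0 || c < 0 || b + c <= 0)
    stop("need b >= 0, c >= 0, b + c > 0")
  structure(list(b = b, c = c, eq_functional = c / (b + c)),
            class = "turnover_params")
}

# edges ordered parents-before-children, starting at the root
#' @keywords internal
edge_preorder <- function(tree) {
  parent <- tree$edge[, 1]
  root <- length(tree$tip.label) + 1L
  ord <- integer(0)
  queue <- root
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    es <- which(parent == v)
    ord <- c(ord, es)
    queue <- c(queue, tree$edge[es, 2])
  }
  ord
}

#' Simulate one functional-turnover history along a tree
#'
#' The state at the root is functional with probability `c/(b+c)`.  Along
#' each branch, switches follow exponential waiting times with rate `b` while
#' functional and `c` while nonfunctional; a branch may contain several
#' switches or none.  Daughter branches start in the parent branch's end
#' state.
#'
#' @param tree A `phylo` object.
#' @param params A [turnover_params()].
#' @param seed Optional integer seed.
#' @return An object of class `functional_history`: `root_state` (1 =
#'   functional), and `segments`, a list parallel to the rows of `tree$edge`,
#'   each a list with `lengths` and `states` (alternating 0/1) covering the
#'   branch exactly.
#' @export
simulate_history <- function(tree, params, seed = NULL) {
  validate_tree(tree)
  stopifnot(inherits(params, "turnover_params"))
  if (!is.null(seed)) set.seed(seed)
  b <- params$b; c <- params$c
  root_state <- as.integer(stats::runif(1) < params$eq_functional)
  nnode <- length(tree$tip.label) + tree$Nnode
  node_state <- rep(NA_integer_, nnode)
  node_state[length(tree$tip.label) + 1L] <- root_state
  segs <- vector("list", nrow(tree$edge))
  for (e in edge_preorder(tree)) {
    s <- node_state[tree$edge[e, 1]]
    rem <- tree$edge.length[e]
    lens <- numeric(0); sts <- integer(0)
    repeat {
      rate <- if (s == 1L) b else c
      w <- if (rate > 0) stats::rexp(1, rate) else Inf
      if (w >= rem) {
        lens <- c(lens, rem); sts <- c(sts, s)
        break
      }
      lens <- c(lens, w); sts <- c(sts, s)
      rem <- rem - w
      s <- 1L - s
    }
    if (tree$edge.length[e] == 0) { lens <- 0; sts <- s }
    segs[[e]] <- list(lengths = lens, states = sts)
    node_state[tree$edge[e, 2]] <- s
  }
  structure(list(root_state = root_state, segments = segs,
                 edge_lengths = tree$edge.length,
                 node_state = node_state),
            class = "functional_history")
}

#' Scale branch lengths according to a functional history
#'
#' Each branch length `L` becomes `L * (omega * f + (1 - f))` where `f` is
#' the fraction of the branch spent in the functional state: functional
#' stretches evolve at the reduced rate `omega`, nonfunctional stretches at
#' the neutral rate.
#'
#' @param tree A `phylo` object.
#' @param history A [simulate_history()] result for this tree.
#' @param omega Rate ratio for functional segments; scalar or one value per
#'   branch (per-branch effective-population-size variants).
#' @return A `phylo` object with rescaled branch lengths.
#' @export
scaled_tree_from_history <- function(tree, history, omega) {
  validate_tree(tree)
  if (!inherits(history, "functional_history") ||
      length(history$segments) != nrow(tree$edge) ||
      !isTRUE(all.equal(history$edge_lengths, tree$edge.length)))
    stop("history does not match tree")
  stopifnot(all(omega >= 0))
  omega <- rep_len(omega, nrow(tree$edge))
  f <- vapply(history$segments, function(sg) {
    tot <- sum(sg$lengths)
    if (tot == 0) 0 else sum(sg$lengths[sg$states == 1L]) / tot
  }, numeric(1))
  out <- tree
  out$edge.length <- tree$edge.length * (omega * f + (1 - f))
  out
}

# vectorized two-state evolution of n sites along one branch of length L:
# returns end states, time spent functional, and switch counts
#' @keywords internal
evolve_turnover_edge <- function(start, L, b, c) {
  n <- length(start)
  s <- start
  rem <- rep(L, n)
  t1 <- numeric(n)
  switches <- integer(n)
  active <- which(rem > 0)
  while (length(active)) {
    rate <- ifelse(s[active] == 1L, b, c)
    w <- rep(Inf, length(active))
    pos <- rate > 0
    if (any(pos)) w[pos] <- stats::rexp(sum(pos), rate[pos])
    stay <- w >= rem[active]
    idx_stay <- active[stay]
    t1[idx_stay] <- t1[idx_stay] + ifelse(s[idx_stay] == 1L, rem[idx_stay], 0)
    rem[idx_stay] <- 0
    idx_sw <- active[!stay]
    if (length(idx_sw)) {
      wsw <- w[!stay]
      t1[idx_sw] <- t1[idx_sw] + ifelse(s[idx_sw] == 1L, wsw, 0)
      rem[idx_sw] <- rem[idx_sw] - wsw
      s[idx_sw] <- 1L - s[idx_sw]
      switches[idx_sw] <- switches[idx_sw] + 1L
    }
    active <- idx_sw
  }
  list(state = s, t_functional = t1, switches = switches)
}

#' Simulate many turnover histories, summarized per branch
#'
#' Vectorized version of [simulate_history()] for `n` independent sites,
#' keeping what downstream stages need: the fraction of each branch spent in
#' the functional state and the functional state at each tip.  Optionally
#' conditions, by rejection sampling, on the focal tip ending functional or
#' nonfunctional.
#'
#' @param tree A `phylo` object.
#' @param params A [turnover_params()].
#' @param n Number of sites.
#' @param seed Optional integer seed.
#' @param condition_focal `"none"` (default), `"functional"`, or
#'   `"nonfunctional"`: restrict output to sites whose focal-tip end state
#'   matches.
#' @param focal Focal tip label (required when conditioning).
#' @param max_batches Safety limit on rejection-sampling rounds.
#' @return A list: `frac_functional` (branches x n matrix, rows parallel to
#'   `tree$edge`), `tip_state` (tips x n 0/1 matrix), `root_state`,
#'   `switches` (branches x n), and `acceptance_rate` (1 when not
#'   conditioning).
#' @export
simulate_histories <- function(tree, params, n, seed = NULL,
                               condition_focal = c("none", "functional",
                                                   "nonfunctional"),
                               focal = NULL, max_batches = 200L) {
  validate_tree(tree)
  stopifnot(inherits(params, "turnover_params"), n >= 1)
  condition_focal <- match.arg(condition_focal)
  if (!is.null(seed)) set.seed(seed)
  if (condition_focal != "none") {
    if (is.null(focal) || !focal %in% tree$tip.label)
      stop("conditioning requires a focal tip present in the tree")
    want <- if (condition_focal == "functional") 1L else 0L
    kept <- NULL; tried <- 0L; drawn <- 0L
    for (i in seq_len(max_batches)) {
      batch <- simulate_histories(tree, params, n)
      drawn <- drawn + n
      ok <- which(batch$tip_state[focal, ] == want)
      sel <- list(
        frac_functional = batch$frac_functional[, ok, drop = FALSE],
        tip_state = batch$tip_state[, ok, drop = FALSE],
        root_state = batch$root_state[ok],
        switches = batch$switches[, ok, drop = FALSE])
      kept <- if (is.null(kept)) sel else list(
        frac_functional = cbind(kept$frac_functional, sel$frac_functional),
        tip_state = cbind(kept$tip_state, sel$tip_state),
        root_state = c(kept$root_state, sel$root_state),
        switches = cbind(kept$switches, sel$switches))
      if (length(kept$root_state) >= n) break
    }
    if (length(kept$root_state) < n)
      stop("rejection sampling failed to reach n within max_batches")
    keep <- seq_len(n)
    out <- list(frac_functional = kept$frac_functional[, keep, drop = FALSE],
                tip_state = kept$tip_state[, keep, drop = FALSE],
                root_state = kept$root_state[keep],
                switches = kept$switches[, keep, drop = FALSE],
                acceptance_rate = length(kept$root_state) / drawn)
    return(out)
  }
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  root_state <- as.integer(stats::runif(n) < params$eq_functional)
  node_state <- matrix(NA_integer_, nnode, n)
  node_state[ntip + 1L, ] <- root_state
  frac <- matrix(0, nrow(tree$edge), n)
  switches <- matrix(0L, nrow(tree$edge), n)
  for (e in edge_preorder(tree)) {
    start <- node_state[tree$edge[e, 1], ]
    L <- tree$edge.length[e]
    if (L == 0) {
      node_state[tree$edge[e, 2], ] <- start
      frac[e, ] <- 0
      next
    }
    ev <- evolve_turnover_edge(start, L, params$b, params$c)
    node_state[tree$edge[e, 2], ] <- ev$state
    frac[e, ] <- ev$t_functional / L
    switches[e, ] <- ev$switches
  }
  tip_state <- node_state[seq_len(ntip), , drop = FALSE]
  rownames(tip_state) <- tree$tip.label
  list(frac_functional = frac, tip_state = tip_state,
       root_state = root_state, switches = switches, acceptance_rate = 1)
}

# sample one column index per row of a row-stochastic matrix
#' @keywords internal
sample_rows <- function(P) {
  n <- nrow(P); m <- ncol(P)
  u <- stats::runif(n)
  out <- rep.int(m, n)
  cum <- numeric(n)
  undecided <- rep(TRUE, n)
  for (j in seq_len(m - 1L)) {
    cum <- cum + P[, j]
    hit <- undecided & (u <= cum)
    out[hit] <- j
    undecided[hit] <- FALSE
    if (!any(undecided)) break
  }
  out
}

# jump-chain simulation along one edge with per-site times; counts events
#' @keywords internal
evolve_edge_events <- function(model, pstates, tvec) {
  n <- length(pstates)
  rates <- -diag(model$Q)
  state <- pstates
  rem <- tvec
  events <- integer(n)
  active <- which(rem > 0 & rates[state] > 0)
  while (length(active)) {
    w <- stats::rexp(length(active), rates[state[active]])
    jump <- w < rem[active]
    idx <- active[jump]
    rem[active[!jump]] <- 0
    if (length(idx)) {
      rem[idx] <- rem[idx] - w[jump]
      J <- model$Q[state[idx], , drop = FALSE]
      J[cbind(seq_along(idx), state[idx])] <- 0
      J <- J / rowSums(J)
      state[idx] <- sample_rows(J)
      events[idx] <- events[idx] + 1L
    }
    active <- idx[rem[idx] > 0 & rates[state[idx]] > 0]
  }
  list(state = state, events = events)
}

#' Simulate alignment columns along a tree
#'
#' Draws the root state from the model's equilibrium frequencies and samples
#' states down every branch from the model's transition probabilities
#' (selection enters only through branch-length scaling).  Branch lengths may
#' be rescaled uniformly, per branch, or per branch and site, which is how
#' selected and turnover sites are produced.
#'
#' @param tree A `phylo` object.
#' @param model A `subst_model` (nucleotide or codon).
#' @param n Number of columns.
#' @param seed Optional integer seed.
#' @param edge_scale Scalar, per-branch vector (rows of `tree$edge`), or
#'   branches x n matrix of multiplicative branch-length scalings.
#' @param track_events If `TRUE`, simulate the full jump chain and attach the
#'   matrix of true substitution counts per branch and site as attribute
#'   `"events"` (slower; intended for calibration checks).
#' @return Character matrix (tips x n) of state labels, with tip labels as
#'   row names.
#' @export
simulate_columns <- function(tree, model, n, seed = NULL, edge_scale = 1,
                             track_events = FALSE) {
  validate_tree(tree)
  stopifnot(inherits(model, "subst_model"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  n_edge <- nrow(tree$edge)
  if (is.matrix(edge_scale)) {
    stopifnot(nrow(edge_scale) == n_edge, ncol(edge_scale) == n)
  } else {
    edge_scale <- matrix(rep_len(edge_scale, n_edge), n_edge, n)
  }
  if (any(edge_scale < 0)) stop("negative edge scaling")
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  states <- matrix(NA_integer_, nnode, n)
  states[ntip + 1L, ] <- sample.int(model$nstates, n, replace = TRUE,
                                    prob = model$freqs)
  events <- if (track_events) matrix(0L, n_edge, n) else NULL
  for (e in edge_preorder(tree)) {
    pst <- states[tree$edge[e, 1], ]
    tvec <- tree$edge.length[e] * edge_scale[e, ]
    if (track_events) {
      ev <- evolve_edge_events(model, pst, tvec)
      states[tree$edge[e, 2], ] <- ev$state
      events[e, ] <- ev$events
    } else if (all(tvec == tvec[1])) {
      P <- transition_matrix(model, tvec[1])
      states[tree$edge[e, 2], ] <- sample_rows(P[pst, , drop = FALSE])
    } else {
      states[tree$edge[e, 2], ] <- sample_rows(
        transition_rows(model, pst, tvec))
    }
  }
  out <- matrix(model$levels[states[seq_len(ntip), , drop = FALSE]],
                ntip, n, dimnames = list(tree$tip.label, NULL))
  if (track_events) attr(out, "events") <- events
  out
}

#' Branch scope of a clade or terminal lineage
#'
#' Returns the indices (rows of `tree$edge`) of the branches descending from
#' the most recent common ancestor of the given taxa; for a single taxon,
#' just its terminal branch.  Used to restrict purifying selection to a
#' phylogenetic scope.
#'
#' @param tree A `phylo` object.
#' @param taxa One or more tip labels.
#' @param include_stem Also include the branch leading to the clade's MRCA
#'   (default `FALSE`).
#' @return Integer vector of edge indices.
#' @export
clade_scope <- function(tree, taxa, include_stem = FALSE) {
  validate_tree(tree)
  missing <- setdiff(taxa, tree$tip.label)
  if (length(missing)) stop("unknown taxa: ", paste(missing, collapse = ", "))
  tips <- match(taxa, tree$tip.label)
  if (length(tips) == 1L) {
    return(which(tree$edge[, 2] == tips))
  }
  mrca <- ape::getMRCA(tree, tips)
  desc <- mrca
  edges <- integer(0)
  repeat {
    new <- which(tree$edge[, 1] %in% desc & !(seq_len(nrow(tree$edge)) %in% edges))
    if (!length(new)) break
    edges <- c(edges, new)
    desc <- unique(c(desc, tree$edge[new, 2]))
  }
  if (include_stem) edges <- c(which(tree$edge[, 2] == mrca), edges)
  sort(unique(edges))
}

#' Simulate columns with selection restricted to a scope
#'
#' Branches in `scope` are scaled by `omega`, all others evolve neutrally,
#' then columns are simulated as in [simulate_columns()].
#'
#' @param tree A `phylo` object.
#' @param scope Integer edge indices (see [clade_scope()]); empty scope
#'   means fully neutral simulation.
#' @param omega Rate ratio on the scoped branches.
#' @param model A `subst_model`.
#' @param n Number of columns.
#' @param seed Optional integer seed.
#' @return Character matrix as from [simulate_columns()].
#' @export
simulate_scoped_columns <- function(tree, scope, omega, model, n,
                                    seed = NULL) {
  validate_tree(tree)
  if (length(scope) && (any(scope < 1) || any(scope > nrow(tree$edge))))
    stop("scope contains invalid edge indices")
  es <- rep(1, nrow(tree$edge))
  es[scope] <- omega
  simulate_columns(tree, model, n, seed = seed, edge_scale = es)
}
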