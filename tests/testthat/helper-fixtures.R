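# shared fixtures; heavyweight objects are built once per session on demand

toy_newick <- "((A:0.2,B:0.3):0.1,C:0.4);"
toy_tree <- function() parse_newick(toy_newick)

tree5 <- function() parse_newick("((A:0.3,B:0.4):0.2,(C:0.5,D:0.3):0.2,E:0.1);")
tree3 <- function() parse_newick("((A:0.25,B:0.35):0.15,C:0.3);")

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

hky2 <- function() fixture("hky2", function() hky_model(kappa = 2))
jc_model <- function() fixture("jc", function() hky_model(kappa = 1))

# small two-bin setup on an 8-taxon subtree: used by mixture/compare tests
small_setup <- function() fixture("small_setup", function() {
  mam <- synthetic_mammal_tree()
  set.seed(4001)
  keep <- c("human", "chimp", sample(setdiff(mam$tip.label,
                                             c("human", "chimp")), 6))
  tr <- prune_to_taxa(mam, keep)
  cfg <- kde_config(n_grid = 801)
  bin_setup(tr, hky2(), bin_centers = c(0.6, 0.9) * tree_size(tr),
            n_template = 4000L, cfg = cfg, seed = 4002)
})

# genome-scale fixture shared by the recovery/threshold/aggregation checks
acc_profile <- function() fixture("acc_profile", function() {
  generate_bin_profile(n_bins = 10L, total_sites = 1e6, seed = 7)
})

acc_setup <- function() fixture("acc_setup", function() {
  cfg <- kde_config(n_grid = 1201)
  bin_setup(synthetic_mammal_tree(), hky2(), acc_profile()$center,
            n_template = 8000L, cfg = cfg, seed = 42)
})

# exact column-pattern probabilities for the 3-leaf tree by brute-force
# summation over internal states; returns a named 64-vector in the order
# produced by pattern_counts()
enum_col_probs_tree3 <- function(tree, model, edge_scale = 1) {
  stopifnot(length(tree$tip.label) == 3L, nrow(tree$edge) == 4L)
  lv <- model$levels
  edge_scale <- rep_len(edge_scale, 4L)
  Pe <- lapply(1:4, function(e)
    transition_matrix(model, tree$edge.length[e] * edge_scale[e]))
  pars <- tree$edge[, 1]; kids <- tree$edge[, 2]
  root <- 4L; inner <- 5L
  grid <- as.matrix(expand.grid(1:4, 1:4, 1:4))
  probs <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    st <- grid[g, ]
    nodestate <- function(nd) if (nd <= 3L) st[nd] else if (nd == root) ri
      else ii
    tot <- 0
    for (ri in 1:4) for (ii in 1:4) {
      pr <- model$freqs[ri]
      for (e in 1:4) pr <- pr * Pe[[e]][nodestate(pars[e]),
                                        nodestate(kids[e])]
      tot <- tot + pr
    }
    probs[g] <- tot
  }
  names(probs) <- apply(matrix(lv[grid], ncol = 3), 1, paste, collapse = "")
  probs
}

# observed pattern frequencies of simulated 3-leaf columns, aligned with
# enum_col_probs_tree3
pattern_counts <- function(cols) {
  lv <- c("A", "C", "G", "T")
  levs <- apply(expand.grid(lv, lv, lv), 1, paste, collapse = "")
  table(factor(apply(cols, 2, paste, collapse = ""), levels = levs))
}

expect_close <- function(object, expected, tol) {
  expect_true(abs(object - expected) <= tol,
              label = sprintf("%.6g within %.3g of %.6g",
                              object, tol, expected))
}
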