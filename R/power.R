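#' Detection power on one tree under one selection/turnover condition
#'
#' Computes the neutral 95% (or other quantile) RS cutoff on the tree, then
#' the fraction of simulated selected sites scoring above it.  Without
#' turnover, selection scales every branch by `omega(nes)`; with turnover,
#' sites follow the two-state functional process (rates multiplied by
#' `turnover_mult`), selection acts only on functional stretches, and sites
#' are conditioned to be functional at the focal tip — power is defined for
#' sites functional in the focal species.
#'
#' @param tree A `phylo` object.
#' @param model A `subst_model`.
#' @param nes Scaled selection coefficient.
#' @param turnover_mult Multiplier on both turnover rates (0 = no turnover).
#' @param params Base [turnover_params()].
#' @param n_sims Selected-site simulations.
#' @param cutoff_sims Neutral simulations for the cutoff (`>= 1000`).
#' @param quantile Neutral cutoff quantile (default 0.95).
#' @param focal Focal tip (required when `turnover_mult > 0`).
#' @return Named vector `c(cutoff, power)`.
#' @export
power_at <- function(tree, model, nes, turnover_mult = 0,
                     params = turnover_params(), n_sims = 2000L,
                     cutoff_sims = 3000L, quantile = 0.95, focal = NULL) {
  cut <- neutral_cutoff(tree, model, cutoff_sims, quantile)
  if (turnover_mult == 0) {
    om <- omega_from_nes(nes)
    cols <- simulate_columns(tree, model, n_sims, edge_scale = om)
    sc <- score_columns(cols, tree, model)
  } else {
    p2 <- turnover_params(params$b * turnover_mult,
                          params$c * turnover_mult)
    sc <- simulate_component_scores(tree, model, "TO", n_sims, params = p2,
                                    omega = omega_from_nes(nes),
                                    condition_focal = "functional",
                                    focal = focal)
  }
  c(cutoff = as.numeric(cut), power = detection_power(sc$rs, cut))
}

#' Power as a function of tree size
#'
#' Grows the tree from a seed pair by smallest-increment species additions
#' (see [grow_species_sequence()]) and, for a set of subtree sizes,
#' selection strengths and turnover levels, computes detection power with
#' [power_at()].
#'
#' @param full_tree The full `phylo` tree.
#' @param seed_taxa Two or more starting leaves (the first is the focal
#'   species for turnover conditioning).
#' @param nes_levels Scaled selection coefficients to evaluate.
#' @param turnover_levels Turnover rate multipliers (default `c(0, 0.5, 1)`).
#' @param sizes Target cumulative tree sizes; default `n_sizes` evenly
#'   spaced between the seed subtree and the full tree.
#' @param n_sizes Number of sizes when `sizes` is `NULL`.
#' @param model A `subst_model`.
#' @param params Base [turnover_params()].
#' @param n_sims,cutoff_sims,quantile Passed to [power_at()].
#' @param seed Optional integer seed.
#' @return Data frame: `tree_size`, `n_taxa`, `nes`, `turnover_mult`,
#'   `cutoff`, `power`.
#' @export
power_vs_tree_size <- function(full_tree, seed_taxa, nes_levels,
                               turnover_levels = c(0, 0.5, 1),
                               sizes = NULL, n_sizes = 5L,
                               model = hky_model(),
                               params = turnover_params(),
                               n_sims = 2000L, cutoff_sims = 3000L,
                               quantile = 0.95, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (length(nes_levels) == 0L || length(turnover_levels) == 0L)
    stop("need at least one selection and one turnover level")
  gs <- grow_species_sequence(full_tree, seed_taxa)
  seed_size <- attr(gs, "seed_size")
  if (is.null(sizes)) {
    sizes <- seq(seed_size, tree_size(full_tree), length.out = n_sizes + 1L)[-1]
  }
  focal <- seed_taxa[1]
  rows <- list()
  for (target in sizes) {
    k <- if (target >= max(gs$cumulative_size)) nrow(gs) else
      which(gs$cumulative_size >= target)[1]
    taxa <- c(seed_taxa, gs$taxon[seq_len(k)])
    sub <- prune_to_taxa(full_tree, taxa)
    for (nes in nes_levels) for (tm in turnover_levels) {
      pa <- power_at(sub, model, nes, turnover_mult = tm, params = params,
                     n_sims = n_sims, cutoff_sims = cutoff_sims,
                     quantile = quantile, focal = focal)
      rows[[length(rows) + 1L]] <- data.frame(
        tree_size = tree_size(sub), n_taxa = length(taxa), nes = nes,
        turnover_mult = tm, cutoff = pa[["cutoff"]], power = pa[["power"]])
    }
  }
  do.call(rbind, rows)
}

#' Conceptual star tree for species-addition experiments
#'
#' A focal species plus `n_primary` primary species at pairwise relatedness
#' `primary_relatedness` from the focal lineage, with `n_added` extra
#' species whose path length to the focal species is `added_relatedness`
#' (all distances in expected neutral substitutions per site).  Used to ask
#' how much power each added genome buys under selection and turnover.
#'
#' @param n_added Number of added species.
#' @param added_relatedness Focal-to-added path length (`> 0`).
#' @param primary_relatedness Focal-to-primary path length (default 0.4).
#' @param n_primary Number of primary species (default 4).
#' @return A `phylo` object with tips `focal`, `sp1..spk`, `add1..addn`.
#' @export
conceptual_tree <- function(n_added, added_relatedness,
                            primary_relatedness = 0.4, n_primary = 4L) {
  if (added_relatedness <= 0) stop("added_relatedness must be > 0")
  fb <- min(primary_relatedness, added_relatedness) / 2
  prim <- paste0("sp", seq_len(n_primary), ":",
                 primary_relatedness - fb)
  tips <- c(paste0("focal:", fb), prim)
  if (n_added > 0L) {
    tips <- c(tips, paste0("add", seq_len(n_added), ":",
                           added_relatedness - fb))
  }
  parse_newick(paste0("(", paste(tips, collapse = ","), ");"))
}

#' Power gained per added species on conceptual trees
#'
#' Builds [conceptual_tree()] topologies for a sequence of added-species
#' counts and evaluates detection power for the focal species under the
#' given selection strengths and turnover levels.
#'
#' @param added_relatedness Focal-to-added path length.
#' @param n_added_levels Added-species counts (default `0:6`).
#' @param nes_levels Scaled selection coefficients.
#' @param turnover_levels Turnover rate multipliers.
#' @param primary_relatedness,n_primary Passed to [conceptual_tree()].
#' @param model,params,n_sims,cutoff_sims,quantile As in [power_at()].
#' @param seed Optional integer seed.
#' @return Data frame: `n_added`, `tree_size`, `nes`, `turnover_mult`,
#'   `cutoff`, `power`.
#' @export
conceptual_power <- function(added_relatedness, n_added_levels = 0:6,
                             nes_levels = c(-100), turnover_levels = c(0, 1),
                             primary_relatedness = 0.4, n_primary = 4L,
                             model = hky_model(),
                             params = turnover_params(),
                             n_sims = 2000L, cutoff_sims = 3000L,
                             quantile = 0.95, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (na in n_added_levels) {
    tr <- conceptual_tree(na, added_relatedness,
                          primary_relatedness = primary_relatedness,
                          n_primary = n_primary)
    for (nes in nes_levels) for (tm in turnover_levels) {
      pa <- power_at(tr, model, nes, turnover_mult = tm, params = params,
                     n_sims = n_sims, cutoff_sims = cutoff_sims,
                     quantile = quantile, focal = "focal")
      rows[[length(rows) + 1L]] <- data.frame(
        n_added = na, tree_size = tree_size(tr), nes = nes,
        turnover_mult = tm, cutoff = pa[["cutoff"]], power = pa[["power"]])
    }
  }
  do.call(rbind, rows)
}
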