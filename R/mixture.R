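#' Kernel-density configuration for standardized score distributions
#'
#' Gaussian kernel with fixed bandwidth on a fixed grid over the
#' standardized-score axis.  Defaults follow the genome-scale analysis:
#' bandwidth 0.05, 5000 grid points spanning \[-2, 1\] (grid spacing
#' ~0.0006).
#'
#' @param bandwidth Kernel bandwidth in standardized-score units (`> 0`).
#' @param n_grid Number of grid points (`>= 2`).
#' @param range Grid range `c(lo, hi)`; scores below `lo` are clamped.
#' @return An object of class `kde_config`.
#' @export
kde_config <- function(bandwidth = 0.05, n_grid = 5000L, range = c(-2, 1)) {
  stopifnot(bandwidth > 0, n_grid >= 2, length(range) == 2, range[1] < range[2])
  structure(list(bandwidth = bandwidth, n_grid = as.integer(n_grid),
                 range = range,
                 dx = diff(range) / (n_grid - 1)),
            class = "kde_config")
}

#' Kernel density estimate on the fixed grid
#'
#' Gaussian KDE with the configured fixed bandwidth, evaluated on the fixed
#' grid and renormalized to integrate (rectangle rule) to one on it.  Scores
#' below the grid are clamped to the lower edge; the clamped count is kept
#' as an attribute.
#'
#' @param scores Numeric vector of standardized scores (at least 1).
#' @param cfg A [kde_config()].
#' @return An object of class `score_density`: list with `x` (grid), `y`
#'   (density values), `dx`, and attribute `"clamped"`.
#' @export
kde_density <- function(scores, cfg = kde_config()) {
  stopifnot(inherits(cfg, "kde_config"))
  scores <- scores[!is.na(scores)]
  if (length(scores) == 0L) stop("no scores to estimate a density from")
  clamped <- sum(scores < cfg$range[1])
  scores <- pmax(scores, cfg$range[1])
  d <- stats::density(scores, bw = cfg$bandwidth, kernel = "gaussian",
                      n = cfg$n_grid, from = cfg$range[1], to = cfg$range[2])
  mass <- sum(d$y) * cfg$dx   # kernel mass retained on the grid (<= 1)
  y <- d$y / mass
  structure(list(x = d$x, y = y, dx = cfg$dx, cfg = cfg, mass = mass),
            class = "score_density", clamped = clamped)
}

#' @keywords internal
check_same_grid <- function(d1, d2) {
  if (length(d1$x) != length(d2$x) ||
      abs(d1$x[1] - d2$x[1]) > 1e-9 ||
      abs(d1$dx - d2$dx) > 1e-12)
    stop("densities are not on the same grid")
  invisible(TRUE)
}

#' Overlap between two densities
#'
#' The overlap coefficient `O = sum(min(f, g)) * dx`, equivalently
#' `1 - 0.5 * sum(|f - g|) * dx` for densities normalized on the grid:
#' 0 for disjoint distributions, 1 for identical ones, symmetric in its
#' arguments.
#'
#' @param d_data,d_model Two [kde_density()] results on the same grid.
#' @return A number in `[0, 1]`.
#' @export
overlap_statistic <- function(d_data, d_model) {
  check_same_grid(d_data, d_model)
  min(max(sum(pmin(d_data$y, d_model$y)) * d_data$dx, 0), 1)
}

#' Simulated score densities for the N, C and TO mixture components
#'
#' For a tree-size bin's representative subtree, simulates the standardized
#' score distribution of neutral sites (N), constrained sites (C: a point
#' mass at standardized score 1, smoothed by the kernel), and
#' functional-turnover sites (TO: substitutions only on nonfunctional
#' stretches).  The raw simulated score vectors are kept as `"scores"`
#' attributes so downstream stages can resample sites without re-simulating
#' alignments.
#'
#' @param bin_tree The bin's representative `phylo` tree.
#' @param model A `subst_model`.
#' @param params [turnover_params()] for the TO component.
#' @param n_sims Simulated sites per stochastic component.
#' @param cfg A [kde_config()].
#' @param seed Optional integer seed.
#' @param omega_to Rate ratio on functional segments in the TO component
#'   (default 0: full constraint while functional).
#' @return Named list of `score_density` objects for `N`, `C`, `TO`.
#' @export
component_templates <- function(bin_tree, model, params = turnover_params(),
                                n_sims = 50000L, cfg = kde_config(),
                                seed = NULL, omega_to = 0) {
  if (!is.null(seed)) set.seed(seed)
  sn <- simulate_component_scores(bin_tree, model, "N", n_sims,
                                  params = params)$standardized
  sto <- simulate_component_scores(bin_tree, model, "TO", n_sims,
                                   params = params,
                                   omega = omega_to)$standardized
  dn <- kde_density(sn, cfg); attr(dn, "scores") <- sn
  dc <- kde_density(rep(1, 512L), cfg); attr(dc, "scores") <- rep(1, 512L)
  dto <- kde_density(sto, cfg); attr(dto, "scores") <- sto
  list(N = dn, C = dc, TO = dto)
}

# simplex grid over k components with the given step
#' @keywords internal
weights_grid <- function(k, step) {
  if (k == 1L) return(matrix(1, 1, 1))
  seqs <- rep(list(seq(0, 1, by = step)), k - 1L)
  W <- as.matrix(expand.grid(seqs))
  last <- 1 - rowSums(W)
  ok <- last >= -1e-9
  W <- cbind(W[ok, , drop = FALSE], pmax(last[ok], 0))
  unname(W)
}

#' Fit mixture proportions to an empirical score density
#'
#' Finds the mixing proportions of the chosen components that maximize the
#' overlap between the empirical density and the mixture of the component
#' template densities, by an exhaustive simplex grid search (step 0.02)
#' followed by a local refinement (step 0.002).
#'
#' @param empirical A [kde_density()] of the observed standardized scores.
#' @param templates Named list of component densities on the same grid
#'   (from [component_templates()]).
#' @param components Subset of `c("N", "C", "TO")` to include; absent
#'   components are fixed at proportion 0.
#' @param coarse,fine Grid steps of the two search stages.
#' @param extra_candidates Optional list of proportion vectors (over
#'   `components`) evaluated alongside the grid, e.g. a nested simpler
#'   model's optimum, so richer fits can never fall below it.
#' @return An object of class `mixture_fit`: `proportions` (named over N,
#'   C, TO, summing to 1), `overlap` (the maximized O), `components`.
#' @export
fit_mixture_bin <- function(empirical, templates,
                            components = c("N", "C", "TO"),
                            coarse = 0.02, fine = 0.002,
                            extra_candidates = NULL) {
  components <- match.arg(components, c("N", "C", "TO"),
                          several.ok = TRUE)
  if (length(components) == 0L) stop("no components selected")
  for (cp in components) check_same_grid(empirical, templates[[cp]])
  # compose mixtures from raw (mass-deficient) densities and renormalize the
  # mixture, so kernel mass clipped at the grid edges (notably the point mass
  # of C sites at standardized score 1) is treated exactly as in the
  # empirical density
  masses <- vapply(components, function(cp) {
    m <- templates[[cp]]$mass
    if (is.null(m)) 1 else m
  }, numeric(1))
  Tm <- vapply(components, function(cp) templates[[cp]]$y,
               numeric(length(empirical$y)))
  Tm <- sweep(Tm, 2, masses, "*")
  g <- empirical$y; dx <- empirical$dx
  eval_O <- function(W) {
    Fm <- Tm %*% t(W)
    mix_mass <- pmax(as.vector(W %*% masses), 1e-12)
    Fm <- sweep(Fm, 2, mix_mass, "/")
    dx * colSums(pmin(Fm, g))
  }
  W1 <- weights_grid(length(components), coarse)
  if (!is.null(extra_candidates)) {
    W1 <- rbind(W1, do.call(rbind, extra_candidates))
  }
  O1 <- eval_O(W1)
  w <- W1[which.max(O1), ]
  # local refinement on the fine lattice, recentred until no improvement
  # (the overlap is concave in the weights, so this reaches the fine-grid
  # optimum)
  k <- length(components)
  O <- max(O1)
  if (k > 1L) {
    offs <- rep(list(seq(-coarse, coarse, by = fine)), k - 1L)
    W0 <- as.matrix(expand.grid(offs))
    for (round in 1:40) {
      W2 <- sweep(W0, 2, w[seq_len(k - 1L)], "+")
      W2 <- cbind(W2, 1 - rowSums(W2))
      ok <- apply(W2, 1, function(z) all(z >= -1e-9))
      W2 <- pmax(W2[ok, , drop = FALSE], 0)
      W2 <- W2 / rowSums(W2)
      O2 <- eval_O(W2)
      if (max(O2) <= O + 1e-12) break
      O <- max(O2)
      w <- W2[which.max(O2), ]
    }
  }
  props <- stats::setNames(rep(0, 3), c("N", "C", "TO"))
  props[components] <- w
  structure(list(proportions = props, overlap = O, components = components),
            class = "mixture_fit")
}

#' Representative subtree for a tree-size bin
#'
#' Sites in a bin share a projected tree size but not a topology; templates
#' are simulated on a random leaf subset of the full tree whose projected
#' size matches the bin.  Leaves are removed at random while the size stays
#' above the target; if no subset lands within `tol`, the closest subset's
#' branch lengths are rescaled multiplicatively to the exact target (flagged
#' by attribute `"rescaled"`).
#'
#' @param tree The full `phylo` tree.
#' @param target_size Desired projected tree size.
#' @param tol Acceptance window around the target (default 0.005).
#' @param keep Tip labels that must stay in the subtree (e.g. a focal
#'   species).
#' @param seed Optional integer seed.
#' @param max_tries Random restarts before falling back to rescaling.
#' @return A `phylo` object of size `target_size` (within `tol`, or exact
#'   when rescaled).
#' @export
bin_representative_tree <- function(tree, target_size, tol = 0.005,
                                    keep = NULL, seed = NULL,
                                    max_tries = 40L) {
  validate_tree(tree)
  if (target_size <= 0 || target_size > tree_size(tree) + tol)
    stop("target size outside (0, tree size]")
  if (!is.null(seed)) set.seed(seed)
  best <- tree; best_gap <- abs(tree_size(tree) - target_size)
  for (try in seq_len(max_tries)) {
    cur <- tree
    repeat {
      sz <- tree_size(cur)
      if (abs(sz - target_size) <= tol) return(cur)
      if (sz < target_size - tol) break
      removable <- setdiff(cur$tip.label, keep)
      if (length(cur$tip.label) - 1L < max(2L, length(keep) + 1L)) break
      removable <- sample(removable)
      moved <- FALSE
      for (lab in removable) {
        cand <- ape::drop.tip(cur, lab)
        szc <- tree_size(cand)
        if (szc >= target_size - tol) { cur <- cand; moved <- TRUE; break }
        if (abs(szc - target_size) < best_gap) {
          best <- cand; best_gap <- abs(szc - target_size)
        }
      }
      if (!moved) break
    }
    if (abs(tree_size(cur) - target_size) < best_gap) {
      best <- cur; best_gap <- abs(tree_size(cur) - target_size)
    }
  }
  out <- best
  out$edge.length <- out$edge.length * target_size / tree_size(out)
  attr(out, "rescaled") <- TRUE
  out
}

#' Per-bin simulation setup for a genome-scale analysis
#'
#' For each tree-size bin, picks a representative subtree and simulates the
#' component score templates once; everything downstream (fitting, model
#' comparison, threshold tables) reuses this object.
#'
#' @param tree The full `phylo` tree.
#' @param model A `subst_model`.
#' @param bin_centers Tree sizes of the bins.
#' @param params [turnover_params()].
#' @param n_template Simulated sites per component per bin.
#' @param cfg A [kde_config()].
#' @param seed Optional integer seed.
#' @param focal Optional focal species kept in every bin tree.
#' @return A list of per-bin lists (`center`, `tree`, `templates`) of class
#'   `bin_setup`.
#' @export
bin_setup <- function(tree, model, bin_centers, params = turnover_params(),
                      n_template = 20000L, cfg = kde_config(), seed = NULL,
                      focal = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(bin_centers, function(ct) {
    bt <- bin_representative_tree(tree, ct, keep = focal)
    tm <- component_templates(bt, model, params = params,
                              n_sims = n_template, cfg = cfg)
    list(center = ct, tree = bt, templates = tm)
  })
  structure(out, class = "bin_setup", cfg = cfg)
}

#' Assign scored sites to tree-size bins
#'
#' @param scores Data frame with a `tree_size` column.
#' @param bin_centers Bin centers (tree sizes).
#' @param bin_width Bin width (default 0.01-style: full width; sites farther
#'   than `bin_width / 2` from every center are unassigned).
#' @return Integer vector of bin indices (`NA` = unassigned).
#' @export
assign_bins <- function(scores, bin_centers, bin_width) {
  idx <- vapply(scores$tree_size, function(s) {
    d <- abs(bin_centers - s)
    j <- which.min(d)
    if (d[j] <= bin_width / 2 + 1e-9) j else NA_integer_
  }, integer(1))
  idx
}

#' Fit a mixture model in every bin and genome-wide
#'
#' Splits standardized scores by bin, fits the chosen mixture components per
#' bin, and computes the genome-wide overlap between the pooled empirical
#' density and the count-weighted model density.
#'
#' @param std_by_bin List of standardized-score vectors, one per setup bin.
#' @param setup A [bin_setup()].
#' @param components Mixture components to fit.
#' @param extra_by_bin Optional list (per bin) of extra candidate proportion
#'   vectors passed to [fit_mixture_bin()].
#' @return List with `bin_fits`, `counts`, `genome_overlap`, and
#'   `genome_proportions` (count-weighted average over fitted bins).
#' @export
fit_scores_model <- function(std_by_bin, setup,
                             components = c("N", "C", "TO"),
                             extra_by_bin = NULL) {
  stopifnot(inherits(setup, "bin_setup"),
            length(std_by_bin) == length(setup))
  cfg <- attr(setup, "cfg")
  counts <- vapply(std_by_bin, length, integer(1))
  bin_fits <- vector("list", length(setup))
  model_y <- 0
  pooled <- numeric(0)
  for (i in seq_along(setup)) {
    if (counts[i] < 2L) next
    emp <- kde_density(std_by_bin[[i]], cfg)
    extra <- if (!is.null(extra_by_bin)) extra_by_bin[[i]] else NULL
    fit <- fit_mixture_bin(emp, setup[[i]]$templates, components,
                           extra_candidates = extra)
    bin_fits[[i]] <- fit
    mix <- 0; mmass <- 0
    for (cp in fit$components) {
      tpl <- setup[[i]]$templates[[cp]]
      mix <- mix + fit$proportions[[cp]] * tpl$y * tpl$mass
      mmass <- mmass + fit$proportions[[cp]] * tpl$mass
    }
    model_y <- model_y + counts[i] * mix / max(mmass, 1e-12)
    pooled <- c(pooled, std_by_bin[[i]])
  }
  if (length(pooled) < 2L) stop("no bins with enough sites to fit")
  model_y <- model_y / sum(counts)
  emp_all <- kde_density(pooled, cfg)
  dmod <- structure(list(x = emp_all$x, y = model_y, dx = emp_all$dx,
                         cfg = cfg), class = "score_density")
  gO <- overlap_statistic(emp_all, dmod)
  P <- do.call(rbind, lapply(bin_fits[counts >= 2L], `[[`, "proportions"))
  gp <- colSums(P * counts[counts >= 2L]) / sum(counts[counts >= 2L])
  list(bin_fits = bin_fits, counts = counts, genome_overlap = gO,
       genome_proportions = gp)
}

#' Genome-wide category proportions from per-bin fits
#'
#' Count-weighted average of per-bin mixture proportions; sites below the
#' minimum fitted tree size are treated as entirely neutral.
#'
#' @param fits List of `mixture_fit` objects (NULL entries are skipped).
#' @param bin_site_counts Site counts parallel to `fits`.
#' @param below_min_count Number of genome sites with tree sizes below the
#'   fitted range (all counted as neutral).
#' @return Named proportions over N, C, TO (summing to 1).
#' @export
aggregate_genome <- function(fits, bin_site_counts, below_min_count = 0) {
  stopifnot(length(fits) == length(bin_site_counts),
            all(bin_site_counts >= 0), below_min_count >= 0)
  acc <- c(N = 0, C = 0, TO = 0)
  tot <- below_min_count
  acc["N"] <- below_min_count
  for (i in seq_along(fits)) {
    if (is.null(fits[[i]]) || bin_site_counts[i] == 0) next
    acc <- acc + bin_site_counts[i] * fits[[i]]$proportions
    tot <- tot + bin_site_counts[i]
  }
  if (tot == 0) stop("no sites")
  acc / tot
}

#' Threshold performance table for raw GERP cutoffs
#'
#' Under the fitted per-bin mixture model, evaluates raw-RS thresholds:
#' false discovery rate (fraction of sites above the threshold that are
#' neutral), power (fraction of selected sites above it), the fraction of
#' the genome filtered, and the fraction of selected sites missed.  Raw RS
#' values per component are obtained from the setup's simulated score pools
#' (standardized score times bin tree size).
#'
#' @param fits Per-bin `mixture_fit` list (from [fit_scores_model()]).
#' @param setup The [bin_setup()] used for fitting.
#' @param counts Per-bin site counts.
#' @param thresholds Raw RS thresholds.
#' @param below_min_count Neutral sites outside the fitted bins included in
#'   the filtered-fraction denominator (assumed never above threshold).
#' @return Data frame with columns `threshold`, `fdr_pct`, `power_pct`,
#'   `filtered_pct`, `selected_missed_pct` (all percentages).
#' @export
threshold_table <- function(fits, setup, counts, thresholds = 0:4,
                            below_min_count = 0) {
  stopifnot(inherits(setup, "bin_setup"))
  rows <- lapply(thresholds, function(th) {
    above_neutral <- 0; above_sel <- 0; n_neutral <- below_min_count
    n_sel <- 0
    for (i in seq_along(setup)) {
      if (is.null(fits[[i]]) || counts[i] == 0) next
      Tsize <- setup[[i]]$center
      p <- fits[[i]]$proportions
      pool_n <- attr(setup[[i]]$templates$N, "scores") * Tsize
      pool_to <- attr(setup[[i]]$templates$TO, "scores") * Tsize
      pr_n <- mean(pool_n > th)
      pr_c <- as.numeric(Tsize > th)
      pr_to <- mean(pool_to > th)
      above_neutral <- above_neutral + counts[i] * p[["N"]] * pr_n
      above_sel <- above_sel +
        counts[i] * (p[["C"]] * pr_c + p[["TO"]] * pr_to)
      n_neutral <- n_neutral + counts[i] * p[["N"]]
      n_sel <- n_sel + counts[i] * (p[["C"]] + p[["TO"]])
    }
    above <- above_neutral + above_sel
    data.frame(threshold = th,
               fdr_pct = 100 * if (above > 0) above_neutral / above else 0,
               power_pct = 100 * if (n_sel > 0) above_sel / n_sel else 0,
               filtered_pct = 100 * above /
                 (n_neutral + n_sel),
               selected_missed_pct = 100 *
                 (1 - if (n_sel > 0) above_sel / n_sel else 0))
  })
  do.call(rbind, rows)
}
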