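#' Genome-like tree-size bin profile with known mixture truth
#'
#' Builds the per-bin description of a synthetic genome: bin edges over the
#' usable tree-size range, site counts per bin, and true mixture proportions
#' per bin.  Defaults emulate the qualitative features of empirical
#' genome-wide GERP tables: site counts peak at intermediate-to-large tree
#' sizes and collapse near the maximum (few sites align across all
#' species), the constrained and turnover proportions increase with tree
#' size, and the bulk of the genome sits below the minimum usable tree size
#' and is purely neutral.
#'
#' @param n_bins Number of bins (268 at bin width 0.01 over the default
#'   range).
#' @param size_range Tree-size range covered by the bins (default
#'   `c(3.5, 6.18)`).
#' @param total_sites Total sites across the bins.
#' @param proportion_model `"size-graded"` (default: constrained and
#'   turnover fractions rise smoothly with tree size) or `"neutral"` (every
#'   bin `(1, 0, 0)`).
#' @param below_min_sites Neutral genome sites below `size_range[1]`
#'   (default four times `total_sites`, so the genome-wide selected
#'   fraction lands near a few percent).
#' @param seed Optional integer seed (counts are drawn multinomially).
#' @return An object of class `bin_profile`: data frame with `bin_lower`,
#'   `bin_width`, `center`, `count`, `p_N`, `p_C`, `p_TO`, and attribute
#'   `"below_min_sites"`.
#' @export
generate_bin_profile <- function(n_bins = 268L, size_range = c(3.5, 6.18),
                                 total_sites = 1e5,
                                 proportion_model = c("size-graded",
                                                      "neutral"),
                                 below_min_sites = 4 * total_sites,
                                 seed = NULL) {
  stopifnot(n_bins >= 1, size_range[1] > 0, size_range[2] > size_range[1])
  proportion_model <- match.arg(proportion_model)
  if (!is.null(seed)) set.seed(seed)
  width <- diff(size_range) / n_bins
  lower <- size_range[1] + width * (seq_len(n_bins) - 1L)
  center <- lower + width / 2
  u <- (center - size_range[1]) / diff(size_range)
  # counts grow with tree size (well-conserved sites align well) and then
  # collapse sharply near the maximum: alignment across all species is rare
  decay_at <- size_range[2] - 0.2
  w <- stats::dbeta(u, 1.25, 1) *
    (0.02 + 0.98 * stats::plogis((decay_at - center) / 0.015))
  w <- w / sum(w)
  counts <- as.vector(stats::rmultinom(1, round(total_sites), w))
  if (proportion_model == "neutral") {
    p_to <- rep(0, n_bins); p_c <- rep(0, n_bins)
  } else {
    p_to <- 0.55 * stats::plogis((center - 5.2) / 0.35)
    p_c <- 0.25 * stats::plogis((center - 5.6) / 0.25)
  }
  out <- data.frame(bin_lower = lower, bin_width = width, center = center,
                    count = counts, p_N = 1 - p_to - p_c, p_C = p_c,
                    p_TO = p_to)
  attr(out, "below_min_sites") <- below_min_sites
  class(out) <- c("bin_profile", "data.frame")
  out
}

#' Generate a synthetic genome-like GERP score table
#'
#' For every bin of the profile, draws each site's category (N, C, TO) from
#' the true proportions and produces its rejected-substitution score on the
#' bin's representative subtree: neutral and turnover sites are simulated
#' as alignment columns and scored; constrained sites take the maximal
#' score.  Returns the gerpcol-style score table side by side with the
#' hidden truth.
#'
#' @param profile A [generate_bin_profile()].
#' @param setup A [bin_setup()] whose bin centers match the profile (when
#'   `NULL` one is built from `tree`).
#' @param tree,model,params Used to build the setup when `setup` is `NULL`.
#' @param use_pools Draw site scores from the setup's large simulated score
#'   pools instead of simulating fresh columns per site (default `FALSE`:
#'   fresh simulation).
#' @param n_template Pool size per component when building a setup.
#' @param seed Optional integer seed.
#' @return List with `scores` (data frame `tree_size`, `rs`), `truth`
#'   (row-aligned data frame with `bin`, `category`), `std_by_bin`
#'   (standardized scores split by bin, for fitting), and the `setup` used.
#' @export
generate_dataset <- function(profile, setup = NULL, tree = NULL,
                             model = hky_model(),
                             params = turnover_params(),
                             use_pools = FALSE, n_template = 20000L,
                             seed = NULL) {
  stopifnot(inherits(profile, "bin_profile"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(setup)) {
    if (is.null(tree)) stop("need a setup or a tree")
    setup <- bin_setup(tree, model, profile$center, params = params,
                       n_template = n_template)
  }
  stopifnot(length(setup) == nrow(profile))
  scores <- list(); truth <- list(); std_by_bin <- vector("list", nrow(profile))
  for (i in seq_len(nrow(profile))) {
    n <- profile$count[i]
    std_by_bin[[i]] <- numeric(0)
    if (n == 0) next
    p <- c(N = profile$p_N[i], C = profile$p_C[i], TO = profile$p_TO[i])
    cat_n <- as.vector(stats::rmultinom(1, n, p))
    names(cat_n) <- names(p)
    Tsize <- setup[[i]]$center
    std <- numeric(0); cats <- character(0)
    for (cp in c("N", "C", "TO")) {
      if (cat_n[[cp]] == 0) next
      if (cp == "C") {
        s <- rep(1, cat_n[[cp]])
      } else if (use_pools) {
        s <- sample(attr(setup[[i]]$templates[[cp]], "scores"),
                    cat_n[[cp]], replace = TRUE)
      } else {
        s <- simulate_component_scores(setup[[i]]$tree, model, cp,
                                       cat_n[[cp]],
                                       params = params)$standardized
      }
      std <- c(std, s)
      cats <- c(cats, rep(cp, cat_n[[cp]]))
    }
    std_by_bin[[i]] <- std
    scores[[length(scores) + 1L]] <-
      data.frame(tree_size = rep(Tsize, n), rs = std * Tsize)
    truth[[length(truth) + 1L]] <- data.frame(bin = i, category = cats)
  }
  list(scores = do.call(rbind, scores), truth = do.call(rbind, truth),
       std_by_bin = std_by_bin, setup = setup)
}

#' Replicated recovery experiment for mixture-proportion estimates
#'
#' Repeatedly generates synthetic genomes from a profile and refits the
#' mixture model, recording the signed estimation error (true minus
#' estimated) for each component in each bin.  Replicate score sets are
#' drawn from the setup's simulated score pools, so replication cost does
#' not grow with alignment simulation.
#'
#' @param profile A [generate_bin_profile()].
#' @param setup A matching [bin_setup()].
#' @param n_reps Number of replicates (`>= 10`).
#' @param components Mixture components fitted (default all three).
#' @param seed Optional integer seed.
#' @return Data frame: `rep`, `center`, `count`, `component`, `true`,
#'   `estimated`, `error`.
#' @export
recovery_experiment <- function(profile, setup, n_reps = 100L,
                                components = c("N", "C", "TO"),
                                seed = NULL) {
  stopifnot(inherits(profile, "bin_profile"), n_reps >= 10L,
            length(setup) == nrow(profile))
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (r in seq_len(n_reps)) {
    ds <- generate_dataset(profile, setup = setup, use_pools = TRUE)
    fit <- fit_scores_model(ds$std_by_bin, setup, components = components)
    for (i in seq_len(nrow(profile))) {
      bf <- fit$bin_fits[[i]]
      if (is.null(bf)) next
      truth <- c(N = profile$p_N[i], C = profile$p_C[i],
                 TO = profile$p_TO[i])
      for (cp in components) {
        rows[[length(rows) + 1L]] <- data.frame(
          rep = r, center = profile$center[i], count = profile$count[i],
          component = cp, true = truth[[cp]],
          estimated = bf$proportions[[cp]],
          error = truth[[cp]] - bf$proportions[[cp]])
      }
    }
  }
  do.call(rbind, rows)
}
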