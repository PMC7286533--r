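#' Lambda model-comparison statistic
#'
#' `Lambda = 2 * (log(1 - O1) - log(1 - O2))` where `O1` is the maximized
#' overlap of the null (simpler) model and `O2` of the alternative.
#' Positive values mean the alternative fits better; the statistic is
#' calibrated by simulation under the null, not by an asymptotic
#' distribution.
#'
#' @param o1 Overlap of the null model, in `[0, 1)`.
#' @param o2 Overlap of the alternative model, in `[0, 1)`.
#' @return The Lambda statistic.
#' @export
lambda_statistic <- function(o1, o2) {
  if (anyNA(c(o1, o2)) || o1 < 0 || o2 < 0 || o1 > 1 || o2 > 1)
    stop("overlaps must be in [0, 1]")
  if (o1 >= 1 || o2 >= 1) stop("degenerate perfect fit (O = 1)")
  2 * (log(1 - o1) - log(1 - o2))
}

#' Simulation p-value with exact binomial confidence interval
#'
#' The p-value estimate is the fraction of simulated null statistics at
#' least as large as the observed one (ties count as extreme).  The 95%
#' confidence interval of the true p-value is the exact Clopper-Pearson
#' binomial interval for that count.
#'
#' @param lambda_obs Observed statistic.
#' @param null_sample Numeric vector of statistics simulated under the null.
#' @return List with `p` (estimate), `ci` (length-2 vector), `x`
#'   (exceedance count) and `n`.
#' @export
p_value_with_ci <- function(lambda_obs, null_sample) {
  n <- length(null_sample)
  if (n == 0L) stop("empty null sample")
  x <- sum(null_sample >= lambda_obs)
  bt <- stats::binom.test(x, n)
  list(p = x / n, ci = as.numeric(bt$conf.int), x = x, n = n)
}

# "N+TO+C" -> c("N","TO","C") (order canonicalized to N, C, TO)
#' @keywords internal
model_components <- function(name) {
  comps <- strsplit(name, "\\+")[[1]]
  bad <- setdiff(comps, c("N", "C", "TO"))
  if (length(bad)) stop("unknown components: ", paste(bad, collapse = ", "))
  intersect(c("N", "C", "TO"), comps)
}

# fit a family of nested mixture models, seeding richer searches with the
# optima of their fitted sub-models so overlap is monotone in model size
#' @keywords internal
fit_model_family <- function(std_by_bin, setup, models) {
  comps <- lapply(models, model_components)
  ord <- order(lengths(comps))
  fits <- vector("list", length(models))
  names(fits) <- models
  for (i in ord) {
    extra <- NULL
    for (j in ord) {
      fj <- fits[[models[j]]]
      if (is.null(fj) || !all(comps[[j]] %in% comps[[i]]) ||
          length(comps[[j]]) >= length(comps[[i]])) next
      extra0 <- lapply(fj$bin_fits, function(bf) {
        if (is.null(bf)) return(NULL)
        list(bf$proportions[comps[[i]]])
      })
      extra <- if (is.null(extra)) extra0 else
        Map(function(a, b) c(a, b), extra, extra0)
    }
    fits[[models[i]]] <- fit_scores_model(std_by_bin, setup,
                                          components = comps[[i]],
                                          extra_by_bin = extra)
  }
  fits
}

# resample one synthetic standardized score set under a fitted model,
# drawing per-bin site categories from the fitted proportions and site
# scores from the setup's simulated per-component pools
#' @keywords internal
sample_model_scores <- function(setup, bin_fits, counts) {
  lapply(seq_along(setup), function(i) {
    n <- counts[i]
    if (n == 0L || is.null(bin_fits[[i]])) return(numeric(0))
    p <- bin_fits[[i]]$proportions
    cat_n <- as.vector(stats::rmultinom(1, n, p))
    out <- numeric(0)
    pools <- list(
      N = attr(setup[[i]]$templates$N, "scores"),
      C = 1,
      TO = attr(setup[[i]]$templates$TO, "scores"))
    for (k in 1:3) {
      if (cat_n[k] == 0) next
      pool <- pools[[k]]
      out <- c(out, if (length(pool) == 1L) rep(pool, cat_n[k])
               else sample(pool, cat_n[k], replace = TRUE))
    }
    out
  })
}

#' Null distribution of Lambda by simulation
#'
#' Repeatedly simulates a full synthetic score set under the fitted null
#' model — mimicking the observed per-bin site counts — refits every model
#' involved in the requested comparisons, and records Lambda for each
#' comparison.
#'
#' @param null_fit A [fit_scores_model()] result: the fitted null model
#'   whose per-bin proportions generate the replicates.
#' @param setup The [bin_setup()] shared by all models.
#' @param counts Per-bin site counts to mimic.
#' @param comparisons List of `c(null_model, alt_model)` character pairs,
#'   e.g. `list(c("N", "N+C"), c("N+C", "N+C+TO"))`.
#' @param n_reps Number of replicates (`>= 10`; 500 for a final analysis).
#' @param seed Optional integer seed.
#' @return Matrix `n_reps x length(comparisons)` of Lambda values, with
#'   comparison labels as column names.
#' @export
null_lambda_distribution <- function(null_fit, setup, counts, comparisons,
                                     n_reps = 500L, seed = NULL) {
  if (n_reps < 10L) stop("n_reps must be at least 10")
  if (!is.null(seed)) set.seed(seed)
  models <- unique(unlist(comparisons))
  labs <- vapply(comparisons, paste, character(1), collapse = " vs ")
  out <- matrix(NA_real_, n_reps, length(comparisons),
                dimnames = list(NULL, labs))
  for (r in seq_len(n_reps)) {
    std <- sample_model_scores(setup, null_fit$bin_fits, counts)
    fits <- fit_model_family(std, setup, models)
    for (ci in seq_along(comparisons)) {
      out[r, ci] <- lambda_statistic(
        fits[[comparisons[[ci]][1]]]$genome_overlap,
        fits[[comparisons[[ci]][2]]]$genome_overlap)
    }
  }
  out
}

#' Simulation-calibrated Lambda test
#'
#' Fits the null and alternative mixture models to the observed scores,
#' computes the observed Lambda for each comparison, simulates its null
#' distribution under the fitted null model, and returns p-values with
#' exact binomial confidence intervals.
#'
#' @param std_by_bin Observed standardized scores split by setup bin.
#' @param setup A [bin_setup()].
#' @param null_model Model generating the null replicates (e.g. `"N"` or
#'   `"N+C"`).
#' @param comparisons List of `c(null_model, alt_model)` pairs to evaluate.
#' @param n_reps Null replicates (default 500).
#' @param seed Optional integer seed.
#' @return An object of class `lambda_test`: per-comparison list with
#'   `lambda_obs`, `null_sample`, `p`, `ci`, plus the fitted `models`.
#' @export
lambda_test <- function(std_by_bin, setup, null_model = "N",
                        comparisons = list(c("N", "N+TO"), c("N", "N+C"),
                                           c("N", "N+C+TO"),
                                           c("N+C", "N+C+TO")),
                        n_reps = 500L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  models <- unique(c(null_model, unlist(comparisons)))
  obs_fits <- fit_model_family(std_by_bin, setup, models)
  counts <- vapply(std_by_bin, length, integer(1))
  nulls <- null_lambda_distribution(obs_fits[[null_model]], setup, counts,
                                    comparisons, n_reps = n_reps)
  res <- lapply(seq_along(comparisons), function(ci) {
    lam <- lambda_statistic(
      obs_fits[[comparisons[[ci]][1]]]$genome_overlap,
      obs_fits[[comparisons[[ci]][2]]]$genome_overlap)
    pv <- p_value_with_ci(lam, nulls[, ci])
    c(list(comparison = paste(comparisons[[ci]], collapse = " vs "),
           lambda_obs = lam, null_sample = nulls[, ci]), pv)
  })
  structure(list(comparisons = res, models = obs_fits,
                 null_model = null_model),
            class = "lambda_test")
}
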