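#' Substitution-rate ratio under purifying selection
#'
#' Ratio of the fixation-driven substitution rate of a selected mutation to
#' the neutral rate, as a function of the scaled selection coefficient
#' `Nes` (haploid effective population size times the heterozygous selection
#' coefficient).  With `S = 2 * Nes` the ratio is `S / (1 - exp(-S))`,
#' continuous at neutrality (`omega(0) = 1`), strictly increasing, and in
#' `(0, 1]` for deleterious mutations.  Computed overflow-safely for any
#' magnitude of `Nes`.
#'
#' @param nes Numeric vector of scaled selection coefficients (typically
#'   `<= 0`; positive values are accepted numerically).
#' @return Numeric vector of rate ratios.
#' @examples
#' omega_from_nes(c(0, -1, -4))
#' @export
omega_from_nes <- function(nes) {
  if (anyNA(nes) || any(!is.finite(nes))) stop("nes must be finite")
  s <- 2 * nes
  out <- numeric(length(s))
  small <- abs(s) < 1e-8
  out[small] <- 1 + s[small] / 2           # series limit at neutrality
  neg <- !small & s < 0
  # s/(1-e^-s) = s * e^s / (e^s - 1); for very negative s, e^s underflows -> 0
  out[neg] <- -s[neg] * exp(s[neg]) / (1 - exp(s[neg]))
  pos <- !small & s > 0
  out[pos] <- s[pos] / (1 - exp(-s[pos]))
  out
}

#' HKY85 nucleotide substitution model
#'
#' Builds an HKY85 rate matrix (states A, C, G, T) with
#' transition/transversion ratio `kappa` and the given equilibrium base
#' frequencies, normalized so that one unit of branch length corresponds to
#' one expected substitution at equilibrium.  The spectral decomposition of
#' the generator is precomputed so transition probabilities can be evaluated
#' cheaply for per-site branch lengths.
#'
#' @param kappa Transition/transversion rate ratio (default 2).
#' @param base_freqs Equilibrium frequencies for A, C, G, T (default equal).
#' @return An object of class `subst_model`.
#' @export
hky_model <- function(kappa = 2, base_freqs = rep(0.25, 4)) {
  stopifnot(kappa >= 0, length(base_freqs) == 4, all(base_freqs > 0))
  base_freqs <- base_freqs / sum(base_freqs)
  lv <- c("A", "C", "G", "T")
  Q <- matrix(0, 4, 4, dimnames = list(lv, lv))
  is_transition <- function(i, j) {
    (lv[i] %in% c("A", "G") && lv[j] %in% c("A", "G")) ||
      (lv[i] %in% c("C", "T") && lv[j] %in% c("C", "T"))
  }
  for (i in 1:4) for (j in 1:4) if (i != j) {
    Q[i, j] <- base_freqs[j] * if (is_transition(i, j)) kappa else 1
  }
  diag(Q) <- -rowSums(Q)
  mu <- -sum(base_freqs * diag(Q))
  Q <- Q / mu
  new_subst_model(Q, base_freqs, lv,
                  extra = list(kappa = kappa, type = "hky"))
}

# shared constructor: spectral decomposition of a reversible generator
#' @keywords internal
new_subst_model <- function(Q, freqs, levels, extra = list()) {
  d <- sqrt(freqs)
  S <- Q * (d %o% (1 / d))                 # diag(d) Q diag(1/d), symmetric
  S <- (S + t(S)) / 2
  es <- eigen(S, symmetric = TRUE)
  A <- (1 / d) * es$vectors                # rows scaled
  B <- t(es$vectors) * rep(d, each = length(d))
  m <- c(list(Q = Q, freqs = freqs, levels = levels, nstates = length(freqs),
              lambda = es$values, A = A, B = B), extra)
  class(m) <- "subst_model"
  m
}

#' Transition probability matrix
#'
#' `P(t) = exp(Q t)` for a reversible substitution model, via the model's
#' precomputed spectral decomposition.  Rows sum to one; `t = 0` gives the
#' identity; the Chapman-Kolmogorov property `P(s) P(t) = P(s + t)` holds.
#'
#' @param model A `subst_model`.
#' @param t Non-negative branch length (scalar).
#' @return A stochastic matrix with the model's states as dimnames.
#' @export
transition_matrix <- function(model, t) {
  stopifnot(inherits(model, "subst_model"), length(t) == 1L)
  if (is.na(t) || t < 0) stop("branch length t must be >= 0")
  P <- model$A %*% (exp(model$lambda * t) * model$B)
  P[P < 0] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- list(model$levels, model$levels)
  P
}

# transition probabilities P[state_i -> j](t_i) for per-site times;
# returns an n x nstates matrix of rows of P
#' @keywords internal
transition_rows <- function(model, states, tvec) {
  E <- exp(outer(tvec, model$lambda))            # n x k
  V <- model$A[states, , drop = FALSE] * E       # n x k
  P <- V %*% model$B                             # n x nstates
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Distribution of fitness effects specification
#'
#' A point mass at neutrality plus a gamma distribution of deleterious scaled
#' selection coefficients.  The default is the coding DFE used for the codon
#' simulations: 17.4% neutral mutations and 82.6% with `|Nes|` drawn from
#' Gamma(shape = 0.343, scale = 334); sampled values are reported as
#' `Nes <= 0`.
#'
#' @param neutral_mass Probability of a strictly neutral mutation, in `[0,1]`.
#' @param shape,scale Gamma parameters of `|Nes|` for selected mutations
#'   (both `> 0`).
#' @return An object of class `dfe_spec`.
#' @export
dfe_spec <- function(neutral_mass = 0.174, shape = 0.343, scale = 334) {
  if (is.na(neutral_mass) || neutral_mass < 0 || neutral_mass > 1)
    stop("neutral_mass must be in [0, 1]")
  if (shape <= 0 || scale <= 0) stop("shape and scale must be > 0")
  structure(list(neutral_mass = neutral_mass, shape = shape, scale = scale),
            class = "dfe_spec")
}

#' Sample scaled selection coefficients from a DFE
#'
#' @param spec A [dfe_spec()].
#' @param n Number of draws.
#' @param seed Optional integer seed.
#' @return Numeric vector of `n` values `<= 0` (zeros are the neutral mass).
#' @export
sample_dfe <- function(spec, n, seed = NULL) {
  stopifnot(inherits(spec, "dfe_spec"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  neutral <- stats::runif(n) < spec$neutral_mass
  out <- numeric(n)
  k <- sum(!neutral)
  if (k > 0) {
    out[!neutral] <- -stats::rgamma(k, shape = spec$shape, scale = spec$scale)
  }
  out
}

#' Synthetic noncoding distribution of fitness effects
#'
#' A stand-in DFE for mutations at functional noncoding sites, chosen on the
#' usual qualitative grounds for such elements: a large effectively-neutral
#' fraction and a wide, weak-shifted gamma of deleterious effects (shape
#' 0.25, scale 40; mean `|Nes| = 10`), so that most selected mutations either
#' fix at nearly the neutral rate or essentially never fix.  Published
#' noncoding DFE parameter sets can be substituted via [dfe_spec()].
#'
#' @return A [dfe_spec()].
#' @export
noncoding_dfe <- function() {
  dfe_spec(neutral_mass = 0.4, shape = 0.25, scale = 40)
}
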