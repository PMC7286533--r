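NUC <- c("A", "C", "G", "T")

# 61 sense codons of the standard genetic code, with amino acids
#' @keywords internal
sense_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  gc[gc != "*"]
}

#' Codon degeneracy class
#'
#' Counts, for a codon position, how many of the three alternative nucleotides
#' yield a synonymous codon, and maps the count to the usual fold classes
#' (0 -> 0-fold, 1 -> 2-fold, 2 -> 3-fold, 3 -> 4-fold).  Changes to stop
#' codons count as nonsynonymous.  Four first-position classes (CTC, CTT,
#' CGT, CGC) whose synonymous exchange runs through the leucine/arginine
#' six-fold blocks are reported as 2-fold rather than 0-fold, because at
#' these sites even strongly selected mutations need not produce maximal
#' conservation scores.
#'
#' @param codon A sense codon, e.g. `"ATG"`.
#' @param position Codon position, 1, 2 or 3.
#' @return Integer fold class: one of 0, 2, 3, 4.
#' @examples
#' classify_degeneracy("GGG", 3)  # 4
#' classify_degeneracy("ATG", 1)  # 0
#' @export
classify_degeneracy <- function(codon, position) {
  codon <- toupper(codon)
  sc <- sense_codons()
  if (!codon %in% names(sc)) stop("not a sense codon: ", codon)
  if (!position %in% 1:3) stop("position must be 1, 2 or 3")
  override <- list("1" = c("CTC", "CTT", "CGT", "CGC"))
  if (position == 1 && codon %in% override[["1"]]) return(2L)
  aa <- sc[[codon]]
  n_syn <- 0L
  for (b in setdiff(NUC, substr(codon, position, position))) {
    alt <- codon
    substr(alt, position, position) <- b
    if (alt %in% names(sc) && sc[[alt]] == aa) n_syn <- n_syn + 1L
  }
  c(0L, 2L, 3L, 4L)[n_syn + 1L]
}

#' GY-style codon substitution model
#'
#' Builds a Goldman-Yang-type rate matrix over the 61 sense codons: only
#' single-nucleotide exchanges have positive rate, proportional to the target
#' codon's equilibrium frequency, multiplied by `kappa` for transitions and by
#' `omega` (dN/dS) for nonsynonymous changes.  With `neutral_scaling` the
#' generator is rescaled so one unit of branch length yields one expected
#' *synonymous* substitution at equilibrium, matching trees whose branch
#' lengths are calibrated on neutral (synonymous) evolution; otherwise the
#' total flux is scaled to one.
#'
#' @param kappa Transition/transversion ratio.
#' @param omega Nonsynonymous/synonymous rate ratio (`>= 0`).
#' @param codon_freqs Equilibrium frequencies over the 61 sense codons
#'   (default uniform).
#' @param neutral_scaling Scale to unit synonymous flux (default `TRUE`).
#' @return A `subst_model` over 61 codon states with attributes
#'   `syn_flux` and `total_flux` giving the expected synonymous and total
#'   substitutions per unit branch length after scaling.
#' @export
build_codon_matrix <- function(kappa = 2, omega = 1, codon_freqs = NULL,
                               neutral_scaling = TRUE) {
  stopifnot(omega >= 0, kappa >= 0)
  sc <- sense_codons()
  codons <- names(sc)
  n <- length(codons)
  if (is.null(codon_freqs)) codon_freqs <- rep(1 / n, n)
  stopifnot(length(codon_freqs) == n, all(codon_freqs > 0))
  codon_freqs <- codon_freqs / sum(codon_freqs)
  cm <- do.call(rbind, strsplit(codons, ""))
  Q <- matrix(0, n, n, dimnames = list(codons, codons))
  syn <- matrix(FALSE, n, n)
  transitions <- c(A = "G", G = "A", C = "T", T = "C")
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j) {
    diff <- which(cm[i, ] != cm[j, ])
    if (length(diff) != 1L) next
    r <- codon_freqs[j]
    if (transitions[[cm[i, diff]]] == cm[j, diff]) r <- r * kappa
    is_syn <- sc[[i]] == sc[[j]]
    syn[i, j] <- is_syn
    if (!is_syn) r <- r * omega
    Q[i, j] <- r
  }
  diag(Q) <- -rowSums(Q)
  flux <- function(M, mask) sum(codon_freqs * rowSums(M * mask))
  off <- matrix(TRUE, n, n); diag(off) <- FALSE
  syn_flux <- flux(Q, syn)
  total_flux <- flux(Q, off)
  scl <- if (neutral_scaling) syn_flux else total_flux
  if (scl <= 0) {
    if (neutral_scaling) stop("zero synonymous flux; cannot neutral-scale")
    scl <- 1
  }
  Q <- Q / scl
  m <- new_subst_model(Q, codon_freqs, codons,
                       extra = list(kappa = kappa, omega = omega,
                                    type = "codon",
                                    neutral_scaling = neutral_scaling,
                                    syn_flux = syn_flux / scl,
                                    total_flux = total_flux / scl,
                                    syn_mask = syn))
  m
}

#' Simulate codon alignment columns with per-codon selection
#'
#' For each simulated codon site, a scaled selection coefficient is drawn
#' from `dfe` (or taken from `nes`), converted to a dN/dS ratio with
#' [omega_from_nes()], and a neutral-scaled GY codon model with that omega is
#' used to simulate one codon column down the tree.  Codon states are emitted
#' as three nucleotide rows per species.
#'
#' @param tree A `phylo` object (branch lengths in expected neutral
#'   substitutions per site).
#' @param n_codons Number of codon sites.
#' @param kappa Transition/transversion ratio.
#' @param dfe A [dfe_spec()] to draw `Nes` from (ignored when `nes` given).
#' @param nes Optional vector of `Nes` values, recycled to `n_codons`.
#' @param seed Optional integer seed.
#' @return A list with `columns` (character matrix, species x (3*n_codons)),
#'   `nes` (length `n_codons`), and `codon_states` (species x n_codons codon
#'   strings).
#' @export
simulate_codon_columns <- function(tree, n_codons, kappa = 2,
                                   dfe = dfe_spec(), nes = NULL, seed = NULL) {
  validate_tree(tree)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(nes)) nes <- sample_dfe(dfe, n_codons)
  nes <- rep_len(nes, n_codons)
  ntip <- length(tree$tip.label)
  codon_states <- matrix(NA_character_, ntip, n_codons,
                         dimnames = list(tree$tip.label, NULL))
  nuc <- matrix(NA_character_, ntip, 3 * n_codons,
                dimnames = list(tree$tip.label, NULL))
  # group sites by omega to share the (costly) 61-state decomposition
  om <- omega_from_nes(nes)
  grp <- split(seq_len(n_codons), signif(om, 12))
  for (g in grp) {
    model <- build_codon_matrix(kappa = kappa, omega = om[g[1]],
                                neutral_scaling = TRUE)
    cols <- simulate_columns(tree, model, n = length(g))
    codon_states[, g] <- cols
  }
  for (site in seq_len(n_codons)) {
    trip <- do.call(rbind, strsplit(codon_states[, site], ""))
    nuc[, (3 * site - 2):(3 * site)] <- trip
  }
  list(columns = nuc, nes = nes, codon_states = codon_states)
}
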