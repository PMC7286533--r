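---
title: "Models and methods behind gerpmix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind gerpmix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`gerpmix` studies how rejected-substitution (GERP) conservation scores
behave under explicit population-genetic models — purifying selection of
varying strength, and gain and loss of function along the phylogeny — and
uses those models to deconvolve a genome-wide score distribution into
neutral (N), constantly constrained (C) and functional-turnover (TO) site
classes.  This vignette documents the models, the estimators, the numerical
choices, and the limits of what the test suite demonstrates.

# Selection and substitution

The substitution rate of a deleterious mutation relative to the neutral
rate is governed by the classical fixation-probability ratio.  Writing
`Nes` for the product of the haploid effective population size and the
heterozygous selection coefficient, and `S = 2 Nes`,

    omega(Nes) = S / (1 - exp(-S)),

implemented overflow-safely in `omega_from_nes()`.  This form has the
neutral limit `omega(0) = 1` and is strictly increasing; the variant
sometimes printed with `S = Nes` in the exponent has neutral limit 2 and is
not a rate ratio.  A useful check of the chosen form: on a tree of total
size 6.18, `exp(-omega(-4) * 6.18) = 0.983`, i.e. a weakly deleterious site
(`Nes = -4`) already shows the maximal score ~98% of the time — matching
the simulation experiments.

Selection enters simulations purely as branch-length scaling: a site under
constant selection evolves on the tree with every branch multiplied by
`omega`; a turnover site has each branch scaled by
`omega * f + (1 - f)` where `f` is the fraction of that branch spent in the
functional state.

Nucleotide evolution is HKY85 (`hky_model()`), default
transition/transversion ratio 2 and equal base frequencies, normalized to
one expected substitution per unit branch length; `kappa` and the
frequencies are configurable for robustness checks (a full GTR family is
out of scope).  Codon evolution (`build_codon_matrix()`) is a GY-style
61-state model with uniform sense-codon frequencies (the nucleotide-level
analysis fixes equal nucleotide frequencies; the codon analogue is the
uniform choice), `kappa` on transitions, `omega` on nonsynonymous changes,
and optional neutral scaling so branch lengths track the synonymous rate.

# Functional turnover

Turnover is a two-state Markov process per site: loss rate `b` while
functional, gain rate `c` while nonfunctional, both per expected neutral
substitution of branch length.  Defaults `b = 2.48`, `c = 0.19` are the
intergenic noncoding estimates this literature uses, giving an equilibrium
functional fraction `c/(b+c) ~ 7%`.  The root state is drawn at
equilibrium and waiting times are exponential; branches can carry several
switches.  `simulate_history()` returns a full per-branch segment record;
`simulate_histories()` is the vectorized form used by everything
downstream, and supports rejection-sampling conditioning on the focal tip's
state (power for a focal species is defined over sites functional in that
species).

# Rejected-substitution scoring

For each alignment column the tree is projected onto the ungapped species
(`prune_to_taxa()`; gap characters never enter the likelihood).  With `T`
the projected tree size, the estimated number of substitutions is
`E = r_hat * T`, where `r_hat` in `[0, 3]` maximizes the column's
Felsenstein pruning likelihood on the tree scaled by `r`, with base
frequencies fixed to the model's configured values rather than re-estimated
per alignment.  The score is `RS = T - E` (negative values mean
faster-than-neutral evolution) and the standardized score is `RS / T`.
When a focal species is declared, its allele is dropped before scoring, as
genome-browser GERP tracks do for the reference genome.

Numerics: the likelihood is evaluated by a vectorized pruning pass whose
per-branch transition probabilities come from the spectral decomposition of
the reversible generator, so thousands of sites with site-specific branch
scalings are scored in a handful of matrix products; invariant columns are
detected and assigned `r_hat = 0` exactly (the boundary optimum); all other
columns are bracketed on a 16-point grid over `[0, 3]` and refined by
golden-section search to an absolute tolerance of `1e-6`.  The rate cap
`r_max = 3` is a declared choice — roughly three times the neutral rate —
not an empirical fact about any external scorer.

Two estimator properties are worth knowing.  First, per-column ML rate
estimation is upward-biased on information-poor trees: a two-leaf mismatch
always drives `r_hat` to the cap, and on a 5-leaf tree of size 2 about a
fifth of neutral columns hit it, so the mean of `E` exceeds `T` there (by
~5% even at 36 taxa).  The mixture machinery is immune to this because the
same estimator generates both the empirical and the template score
distributions.  Second, on trees smaller than about size 3.5 the
invariant-column probability exceeds 5%, so the "95% upper quantile"
neutral cutoff collides with the score maximum and detection power
degenerates; this is a real property of quantile cutoffs on shallow trees,
and the reason genome analyses bin sites at tree size 3.5 and above.

# Mixture deconvolution per tree-size bin

Sites are grouped into tree-size bins (genome scale: width 0.01 over
[3.5, 6.18], 268 bins).  Because sites in a bin share a size but not a
topology, each bin gets a representative subtree: random leaf subsets of
the full tree whose projected size lands within 0.005 of the bin, with a
multiplicative rescale as fallback (`bin_representative_tree()`).  On that
subtree, `component_templates()` simulates the standardized-score
distribution of each class: N is neutral simulation; C is a point mass at
standardized score 1 (constraint strong enough that no substitutions
occur); TO is unconditional turnover simulation with `omega = 0` on
functional segments.

Distributions are compared through fixed-bandwidth Gaussian kernel
densities (bandwidth 0.05, 5000 grid points by default) on the grid
[-2, 1]; scores below -2 are clamped with a logged count.  Model fit is the
overlap coefficient

    O = integral min(f_data, f_model) = 1 - 0.5 * integral |f - g|,

which is symmetric, lies in [0, 1], and equals 1 only for identical
densities.  (An equivalent printed form of the same statistic, "two minus
the summed absolute difference times the grid spacing", is off by a factor
of two as stated; the overlap-area definition is the one implemented.)
Mixing proportions per bin maximize O by an exhaustive simplex grid at step
0.02 refined on a 0.002 lattice, recentred until no improvement — O is
concave in the weights, so this reaches the fine-lattice optimum, which the
tests verify against a full exhaustive search.  One subtlety matters at the
upper grid edge: the C class sits exactly at standardized score 1, where
the kernel loses half its mass beyond the grid.  Mixtures are therefore
composed from raw (mass-deficient) component densities and renormalized as
a whole, exactly as the kernel density of a pooled simulated score set
would be; renormalizing each component separately halves the apparent C
proportion.

Genome-wide proportions are the count-weighted average of per-bin
proportions, with sites below the minimum usable tree size counted as
entirely neutral.  `threshold_table()` converts a fitted model into raw-RS
threshold performance (FDR, power, fraction filtered) using the simulated
per-component score pools.

# Model comparison

Nested mixture models (N, N+C, N+TO, N+C+TO) are compared with

    Lambda = 2 * (log(1 - O_null) - log(1 - O_alt)),

calibrated by simulation: replicates are generated under the fitted null
model with the observed per-bin site counts, all models are refit, and the
p-value is the fraction of null Lambdas at least as large as the observed
one (ties count as extreme — the conservative choice), with an exact
Clopper-Pearson binomial interval.  Richer models' grid searches are seeded
with their nested sub-models' optima, so the maximized per-bin overlap is
monotone in the component set.  The genome-level O used in Lambda compares
the pooled empirical density with the count-weighted model density; since
that pooled quantity is not itself the maximized objective, null Lambdas
can dip a hair below zero.  Replicate score sets are drawn from the large
simulated per-bin score pools rather than re-simulating alignments, which
is what makes 100-500 replicates tractable; the pools are large enough
(10^4 per component per bin by default) that pool-resampling noise is
negligible next to replicate sampling noise.  A per-bin testing mode falls
out of the same machinery by running a one-bin setup.

One calibration caveat: under a pure-neutral truth the fitted extra
component often lands exactly on the simplex boundary (proportion zero),
making null and alternative fits identical and Lambda exactly zero.  That
atom, combined with ties counting as extreme, makes the test conservative
— its realized type-I error at alpha = 0.05 can sit well below 5% at small
problem sizes.  Conservative is the safe direction for the claims the test
supports (a rejection is trustworthy), but realized size should not be
expected to equal the nominal level.

# Synthetic genomes and what the tests show

`generate_bin_profile()` defines the study conditions for a synthetic
genome: bin counts rise mildly with tree size and collapse sharply above
~6 (alignment across all 36 species is rare), constrained and turnover
proportions grow smoothly with tree size (logistic ramps reaching ~25% and
~55% at the top), and four times as many sites sit below the minimum tree
size as inside the bins, all purely neutral — so the genome-wide selected
fraction lands at a few percent, as genome analyses report.
`generate_dataset()` draws each site's class, simulates and scores its
column on the bin subtree (or resamples the score pools for replicate
studies), and emits a gerpcol-style `(tree_size, RS)` table beside a hidden
truth table.  `recovery_experiment()` repeats generate-and-refit to measure
estimation error; at the shipped scale the estimates are unbiased (mean
signed error within 0.02) below tree size 6, with visibly inflated
variance above it where sites are scarce.

The bundled trees are synthetic stand-ins: a 36-taxon mammal-like tree of
total size 6.18 with a human/chimp pair (short, realistic terminal
branches) inside an 18-taxon supraprimate-like clade, and a 100-taxon
vertebrate-like tree of size 18.5.  Their topologies and non-focal branch
lengths are random; only the totals and the focal pair are calibrated.
Quantities that depend mainly on total tree size (maximal-score
probabilities, power-versus-size shapes, equilibrium occupancy) transfer
directly; quantities that depend on the detailed topology (for instance
the power of a specific clade scope) should be read qualitatively.

The noncoding DFE used for turnover-versus-constant-selection comparisons
is the package's own synthetic choice (`noncoding_dfe()`: 40% neutral,
gamma shape 0.25, scale 40): published noncoding DFE parameter sets used in
the literature are not reproduced here, so fractions that depend on the DFE
are reported for this stand-in and any published set can be supplied via
`dfe_spec()`.

What passing tests do *not* show about real data: no alignment error, no
indels, no context-dependent mutation, no linkage or spatial
autocorrelation of conservation, and missingness enters only through
random leaf subsets per tree-size bin rather than the empirical
phylogenetic pattern of alignability.

# Problem sizes

The shipped experiments use scaled-down sizes chosen for precision per CPU
minute: 8,000-20,000 simulated sites per component template, 10 tree-size
bins for the genome workflow, 40-60 recovery replicates, 100-replicate null
distributions for Lambda (500 is the recommendation for a final analysis),
and 20,000-30,000 columns for the selection experiments.  Every stochastic
entry point takes a `seed` and is exactly reproducible.

# Known limitations

The per-column ML substitution estimate is biased upward on small trees
(see above); detection power is undefined in practice for trees below size
~3.5; the N and TO components are nearly collinear in bins with little
evolutionary time, so their split carries more variance than the selected
total; and the turnover model is time-homogeneous with a single global
`(b, c)` pair.
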