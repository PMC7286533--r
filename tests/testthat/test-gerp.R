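test_that("invariant columns take the maximal score", {
  m <- hky2()
  mam <- synthetic_mammal_tree()
  inv <- matrix("G", nrow = 36, ncol = 2,
                dimnames = list(mam$tip.label, NULL))
  sc <- score_columns(inv, mam, m)
  expect_equal(sc$subs, c(0, 0))
  expect_equal(sc$rs, rep(tree_size(mam), 2), tolerance = 1e-9)
  expect_equal(sc$standardized, c(1, 1))
  es <- estimate_substitutions(inv[, 1], mam, m)
  expect_equal(es$subs, 0)
  expect_equal(es$tree_size, 6.18, tolerance = 1e-6)
})

test_that("the ML scale matches a dense grid-search oracle on 3-leaf trees", {
  m <- hky2()
  tr <- tree3()
  set.seed(41)
  cols <- simulate_columns(tr, m, 150)
  sc <- score_columns(cols, tr, m)
  rhat <- sc$subs / tree_size(tr)
  enc <- matrix(match(cols, m$levels), nrow(cols), dimnames = dimnames(cols))
  grid <- seq(0, 3, by = 1e-4)
  oracle <- vapply(seq_len(ncol(enc)), function(s) {
    reps <- enc[, rep(s, length(grid)), drop = FALSE]
    grid[which.max(gerpmix:::pruning_loglik(tr, reps, m, grid))]
  }, numeric(1))
  expect_lt(max(abs(rhat - oracle)), 1e-4)
})

test_that("scoring is consistent with the exact pattern expectation", {
  # oracle: expected estimated substitutions and the invariant-column
  # probability, both computed by exhaustive enumeration of all 64 columns
  m <- jc_model()
  tr <- tree3()
  probs <- enum_col_probs_tree3(tr, m, 1)
  pats <- do.call(rbind, strsplit(names(probs), ""))
  cols_all <- t(pats)
  rownames(cols_all) <- tr$tip.label
  sc_all <- score_columns(cols_all, tr, m)
  exp_mean_E <- sum(probs * sc_all$subs)
  p_inv <- sum(probs[sc_all$standardized == 1])
  expect_equal(sum(sc_all$standardized == 1), 4L)  # exactly the 4 constant

  set.seed(42)
  cols <- simulate_columns(tr, m, 20000)
  sc <- score_columns(cols, tr, m)
  expect_close(mean(sc$subs), exp_mean_E, 3 * sd(sc$subs) / sqrt(20000))
  phat <- mean(sc$standardized == 1)
  expect_close(phat, p_inv, 3 * sqrt(p_inv * (1 - p_inv) / 20000))
})

test_that("adding a substitution to an invariant column lowers RS", {
  m <- hky2()
  tr <- tree5()
  inv <- matrix("A", 5, 1, dimnames = list(tr$tip.label, NULL))
  base_rs <- score_columns(inv, tr, m)$rs
  for (leaf in tr$tip.label) for (alt in c("C", "G", "T")) {
    mut <- inv
    mut[leaf, 1] <- alt
    expect_lt(score_columns(mut, tr, m)$rs, base_rs)
  }
})

test_that("gaps project the tree and sparse sites are skipped", {
  m <- hky2()
  tr <- tree5()
  col <- matrix(c("A", "A", "-", "A", NA), 5, 1,
                dimnames = list(tr$tip.label, NULL))
  sc <- score_columns(col, tr, m)
  expect_equal(sc$n_leaves, 3L)
  expect_equal(sc$tree_size,
               tree_size(prune_to_taxa(tr, c("A", "B", "D"))),
               tolerance = 1e-12)
  expect_equal(sc$standardized, 1)
  sparse <- matrix(c("A", rep(NA, 4)), 5, 1,
                   dimnames = list(tr$tip.label, NULL))
  expect_warning(out <- score_columns(sparse, tr, m), "skipped")
  expect_true(is.na(out$rs))
})

test_that("declaring a focal species excludes its allele", {
  m <- hky2()
  tr <- tree5()
  set.seed(43)
  cols <- simulate_columns(tr, m, 30)
  with_focal <- score_columns(cols, tr, m, focal = "A")
  dropped <- score_columns(cols[setdiff(rownames(cols), "A"), ], tr, m)
  expect_equal(with_focal, dropped)
  expect_lt(max(with_focal$tree_size), tree_size(tr))
})

test_that("neutral cutoff is deterministic and self-consistent", {
  m <- hky2()
  # a tree large enough that the invariant-column atom at the maximal RS
  # stays below 5%, so the 95% quantile is a genuine interior cutoff
  tr <- tree5()
  tr$edge.length <- tr$edge.length * 2.25   # size 4.5
  cut1 <- neutral_cutoff(tr, m, n_sims = 2000, seed = 44)
  cut2 <- neutral_cutoff(tr, m, n_sims = 2000, seed = 44)
  expect_identical(as.numeric(cut1), as.numeric(cut2))
  expect_error(neutral_cutoff(tr, m, n_sims = 200), "1000")
  # maximum quantile returns the largest simulated neutral score
  cmax <- neutral_cutoff(tr, m, n_sims = 1000, quantile = 1, seed = 45)
  expect_equal(as.numeric(cmax), max(attr(cmax, "scores")))
  # held-out neutral false-positive rate matches the nominal 5%
  set.seed(46)
  held <- score_columns(simulate_columns(tr, m, 4000), tr, m)
  fp <- detection_power(held$rs, cut1)
  expect_close(fp, 0.05, 0.02)
})

test_that("detection power counts strict exceedances", {
  expect_equal(detection_power(c(1, 2, 3), 5), 0)
  expect_equal(detection_power(c(1, 2, 3), 1.5), 2 / 3)
  expect_equal(detection_power(c(1, 2), 2), 0)  # exceedance is strict
  expect_error(detection_power(numeric(0), 1), "empty")
})

test_that("score tables round-trip through the gerpcol dialect", {
  d <- data.frame(tree_size = c(4.5, 5.1), rs = c(1.2, -0.4))
  f <- tempfile(fileext = ".tsv")
  write_gerp_scores(d, f)
  expect_equal(read_gerp_scores(f), d, tolerance = 1e-12)
  d2 <- cbind(data.frame(chrom = c("chr1", "chr2"), pos = c(100L, 5L)), d)
  write_gerp_scores(d2, f)
  back <- read_gerp_scores(f)
  expect_equal(back, d2, tolerance = 1e-12)
  # BED exclusion is 0-based half-open
  bed <- tempfile(fileext = ".bed")
  writeLines("chr1\t90\t100", bed)   # covers 1-based positions 91..100
  kept <- filter_scores_bed(back, bed)
  expect_equal(kept$chrom, "chr2")
  writeLines("chr1\t100\t110", bed)  # covers 101..110: keeps pos 100
  expect_equal(nrow(filter_scores_bed(back, bed)), 2L)
})

test_that("alignment columns round-trip through FASTA", {
  tr <- tree5()
  set.seed(47)
  cols <- simulate_columns(tr, hky2(), 20)
  f <- tempfile(fileext = ".fa")
  write_alignment(cols, f)
  expect_equal(read_alignment(f), cols)
})
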