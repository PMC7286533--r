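test_that("turnover parameters and equilibrium behave as defined", {
  p <- turnover_params()
  expect_equal(p$b, 2.48)
  expect_equal(p$c, 0.19)
  expect_equal(p$eq_functional, 0.19 / 2.67, tolerance = 1e-12)
  expect_error(turnover_params(0, 0))
  expect_error(turnover_params(-1, 1))
})

test_that("single histories respect the branch segment contract", {
  tr <- tree5()
  h <- simulate_history(tr, turnover_params(), seed = 5)
  expect_s3_class(h, "functional_history")
  for (e in seq_len(nrow(tr$edge))) {
    sg <- h$segments[[e]]
    expect_equal(sum(sg$lengths), tr$edge.length[e], tolerance = 1e-12)
    if (length(sg$states) > 1) {
      expect_true(all(abs(diff(sg$states)) == 1L))  # states alternate
    }
  }
  # child branch starts in parent's end state
  for (e in seq_len(nrow(tr$edge))) {
    par_node <- tr$edge[e, 1]
    pe <- which(tr$edge[, 2] == par_node)
    start <- h$segments[[e]]$states[1]
    if (length(pe) == 1) {
      expect_equal(start, h$segments[[pe]]$states[
        length(h$segments[[pe]]$states)])
    } else {
      expect_equal(start, h$root_state)
    }
  }
  # b = 0: function is never lost once present
  h0 <- simulate_history(tr, turnover_params(b = 0, c = 5), seed = 6)
  expect_equal(h0$root_state, 1L)  # equilibrium c/(b+c) = 1
  for (sg in h0$segments) expect_true(all(diff(sg$states) >= 0))
})

test_that("vectorized histories match the two-state closed form", {
  # tip occupancy converges to c/(b+c)
  tr <- parse_newick("(A:4.0,B:4.0);")
  p <- turnover_params()
  h <- simulate_histories(tr, p, 20000, seed = 7)
  eq <- p$eq_functional
  se <- sqrt(eq * (1 - eq) / 20000)
  expect_close(mean(h$tip_state["A", ]), eq, 3 * se + 1e-4)

  # expected switch count on one branch, conditioned on the start state:
  # integral of b*p1(t) + c*p0(t) with p1(t) the closed-form occupancy
  b <- 1.3; c <- 0.6; L <- 1.7
  pp <- turnover_params(b, c)
  one <- parse_newick("(A:1.7,B:0.0);")
  hh <- simulate_histories(one, pp, 40000, seed = 8)
  edge_a <- which(one$edge[, 2] == which(one$tip.label == "A"))
  pi1 <- c / (b + c)
  for (s0 in 0:1) {
    idx <- hh$root_state == s0
    expected <- c * L + (b - c) *
      (pi1 * L + (s0 - pi1) * (1 - exp(-(b + c) * L)) / (b + c))
    got <- mean(hh$switches[edge_a, idx])
    expect_close(got, expected, 4 * sd(hh$switches[edge_a, idx]) /
                   sqrt(sum(idx)))
  }

  # conditioning on the focal tip accepts roughly the equilibrium fraction
  hc <- simulate_histories(tr, p, 2000, seed = 9,
                           condition_focal = "functional", focal = "A")
  expect_equal(ncol(hc$tip_state), 2000L)
  expect_true(all(hc$tip_state["A", ] == 1L))
  expect_close(hc$acceptance_rate, eq, 0.02)
})

test_that("history-based tree scaling follows omega and occupancy", {
  tr <- tree5()
  h <- simulate_history(tr, turnover_params(), seed = 10)
  expect_equal(scaled_tree_from_history(tr, h, omega = 1)$edge.length,
               tr$edge.length, tolerance = 1e-12)
  # fully functional history with omega 0 collapses the tree
  hfull <- h
  hfull$segments <- lapply(seq_len(nrow(tr$edge)), function(e)
    list(lengths = tr$edge.length[e], states = 1L))
  hfull$root_state <- 1L
  expect_true(all(scaled_tree_from_history(tr, hfull, 0)$edge.length == 0))
  # half-functional branch with omega 0.5 gives 0.75 of its length
  one <- parse_newick("(A:1.0,B:0.2);")
  hhalf <- list(root_state = 1L,
                segments = list(list(lengths = c(0.5, 0.5),
                                     states = c(1L, 0L)),
                                list(lengths = 0.2, states = 0L)),
                edge_lengths = one$edge.length)
  class(hhalf) <- "functional_history"
  segs <- if (one$edge[1, 2] == 1) hhalf$segments else rev(hhalf$segments)
  hhalf$segments <- segs
  st <- scaled_tree_from_history(one, hhalf, 0.5)
  ea <- which(one$edge[, 2] == which(one$tip.label == "A"))
  expect_equal(st$edge.length[ea], 0.75)
  expect_error(scaled_tree_from_history(tree3(), h, 1), "match")
})

test_that("column simulation matches closed-form substitution laws", {
  m <- jc_model()
  tr <- tree3()
  zero <- tr; zero$edge.length[] <- 0
  cols <- simulate_columns(zero, m, 50, seed = 20)
  expect_true(all(apply(cols, 2, function(z) length(unique(z))) == 1L))

  # single branch: P(child differs) = 3/4 (1 - exp(-4t/3)) under JC
  t <- 0.3
  one <- parse_newick(sprintf("(A:%f,B:0.0);", t))
  cols <- simulate_columns(one, m, 40000, seed = 21)
  pdiff <- mean(cols["A", ] != cols["B", ])
  expected <- 0.75 * (1 - exp(-4 * t / 3))
  expect_close(pdiff, expected, 3 * sqrt(expected * (1 - expected) / 40000))

  # true event counts on the tree average to its size
  tr5 <- tree5()
  cc <- simulate_columns(tr5, hky2(), 20000, seed = 22, track_events = TRUE)
  ev <- colSums(attr(cc, "events"))
  expect_close(mean(ev), tree_size(tr5), 3 * sd(ev) / sqrt(20000))

  # endpoint sampling and the jump chain agree in distribution
  cols2 <- simulate_columns(one, m, 40000, seed = 23, track_events = TRUE)
  pdiff2 <- mean(cols2["A", ] != cols2["B", ])
  expect_close(pdiff2, expected, 3 * sqrt(expected * (1 - expected) / 40000))
})

test_that("scoped simulation reduces to uniform scaling at the limits", {
  m <- hky2()
  tr <- tree3()
  # empty scope equals neutral simulation in distribution: compare both to
  # the exhaustive column-pattern oracle by total variation
  n <- 30000
  oracle_neutral <- enum_col_probs_tree3(tr, m, 1)
  c_neu <- pattern_counts(simulate_columns(tr, m, n, seed = 30))
  c_emp <- pattern_counts(simulate_scoped_columns(tr, integer(0), 0, m, n,
                                                  seed = 31))
  expect_lt(sum(abs(c_neu / n - oracle_neutral)) / 2, 0.02)
  expect_lt(sum(abs(c_emp / n - oracle_neutral)) / 2, 0.02)

  # scope = all branches at omega ~ 0 freezes the column
  sall <- seq_len(nrow(tr$edge))
  cols <- simulate_scoped_columns(tr, sall, 1e-9, m, 200, seed = 32)
  expect_true(all(apply(cols, 2, function(z) length(unique(z))) == 1L))
  expect_error(simulate_scoped_columns(tr, 99L, 0.5, m, 10), "invalid")

  # terminal-branch scope changes only that lineage: exhaustive 4-state
  # enumeration oracle for the leaf-pattern distribution
  sc <- clade_scope(tr, "A")
  escale <- rep(1, 4); escale[sc] <- 0
  n2 <- 40000
  obs <- pattern_counts(simulate_scoped_columns(tr, sc, 0, m, n2,
                                                seed = 33))
  oracle <- enum_col_probs_tree3(tr, m, escale)
  expect_lt(sum(abs(obs / n2 - oracle)) / 2, 0.02)   # total variation
})
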