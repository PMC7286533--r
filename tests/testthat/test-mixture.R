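make_density <- function(y, cfg, mass = 1) {
  x <- seq(cfg$range[1], cfg$range[2], length.out = cfg$n_grid)
  y <- y / (sum(y) * cfg$dx)
  structure(list(x = x, y = y, dx = cfg$dx, cfg = cfg, mass = mass),
            class = "score_density")
}

test_that("kernel density estimates are normalized and faithful", {
  cfg <- kde_config(bandwidth = 0.05, n_grid = 2001)
  d <- kde_density(rep(0.5, 100), cfg)
  expect_equal(sum(d$y) * d$dx, 1, tolerance = 1e-9)
  expect_equal(d$x[which.max(d$y)], 0.5, tolerance = 2 * d$dx)
  # sd of the smoothed point mass equals the bandwidth
  mu <- sum(d$x * d$y) * d$dx
  sdv <- sqrt(sum((d$x - mu)^2 * d$y) * d$dx)
  expect_equal(sdv, 0.05, tolerance = 1e-3)
  expect_error(kde_density(numeric(0), cfg), "no scores")
  # clamping below the grid is counted
  d2 <- kde_density(c(-5, -3, 0.2), cfg)
  expect_equal(attr(d2, "clamped"), 2L)

  # L1 distance to the analytic gaussian convolution
  set.seed(51)
  x <- stats::rnorm(1e5, 0, 0.2)
  dk <- kde_density(x, cfg)
  truth <- stats::dnorm(dk$x, 0, sqrt(0.2^2 + 0.05^2))
  expect_lt(sum(abs(dk$y - truth)) * dk$dx, 0.02)
})

test_that("overlap statistic has its analytic values and symmetry", {
  cfg <- kde_config(n_grid = 3001)
  x <- seq(cfg$range[1], cfg$range[2], length.out = cfg$n_grid)
  f <- make_density(as.numeric(x >= 0 & x <= 1), cfg)
  g <- make_density(as.numeric(x >= -0.5 & x <= 0.5), cfg)
  h <- make_density(as.numeric(x < -1), cfg)
  expect_equal(overlap_statistic(f, f), 1, tolerance = 1e-9)
  expect_equal(overlap_statistic(f, g), 0.5, tolerance = 2e-3)
  expect_equal(overlap_statistic(f, h), 0, tolerance = 1e-9)
  expect_equal(overlap_statistic(f, g), overlap_statistic(g, f))
  cfg2 <- kde_config(n_grid = 1001)
  expect_error(overlap_statistic(f, make_density(rep(1, 1001), cfg2)),
               "grid")
})

test_that("mixture fitting recovers pure and constructed mixtures", {
  setup <- small_setup()
  cfg <- attr(setup, "cfg")
  tm <- setup[[2]]$templates
  fitN <- fit_mixture_bin(tm$N, tm, components = c("N", "C", "TO"))
  expect_gte(fitN$proportions[["N"]], 0.96)
  # constructed 50/50 N+C mixture (mass-weighted, as pooled scores would be)
  mix_y <- 0.5 * tm$N$y * tm$N$mass + 0.5 * tm$C$y * tm$C$mass
  emp <- make_density(mix_y, cfg, mass = 0.5 * tm$N$mass + 0.5 * tm$C$mass)
  fit <- fit_mixture_bin(emp, tm, components = c("N", "C"))
  expect_close(fit$proportions[["N"]], 0.5, 0.021)
  expect_close(fit$proportions[["C"]], 0.5, 0.021)
  expect_equal(fit$proportions[["TO"]], 0)
  expect_gt(fit$overlap, 0.99)
  expect_error(fit_mixture_bin(emp, tm, components = character(0)))
})

test_that("two-stage search equals the exhaustive fine-grid oracle", {
  cfg <- kde_config(n_grid = 301)
  x <- seq(cfg$range[1], cfg$range[2], length.out = cfg$n_grid)
  set.seed(52)
  for (i in 1:20) {
    tmpl <- lapply(1:3, function(k) {
      mu <- stats::runif(1, -1, 1); s <- stats::runif(1, 0.05, 0.4)
      make_density(stats::dnorm(x, mu, s) + 0.02, cfg)
    })
    names(tmpl) <- c("N", "C", "TO")
    w <- as.vector(stats::rmultinom(1, 50, rep(1, 3))) / 50
    noise <- stats::runif(cfg$n_grid, 0.9, 1.1)
    emp <- make_density((w[1] * tmpl$N$y + w[2] * tmpl$C$y +
                           w[3] * tmpl$TO$y) * noise, cfg)
    fit <- fit_mixture_bin(emp, tmpl)
    # exhaustive step-0.002 simplex search (chunked)
    Tm <- cbind(tmpl$N$y, tmpl$C$y, tmpl$TO$y)
    W <- gerpmix:::weights_grid(3, 0.002)
    best <- -Inf
    for (ch in split(seq_len(nrow(W)), ceiling(seq_len(nrow(W)) / 4000))) {
      Fm <- Tm %*% t(W[ch, , drop = FALSE])
      o <- cfg$dx * colSums(pmin(Fm, emp$y))
      best <- max(best, max(o))
    }
    expect_equal(fit$overlap, best, tolerance = 1e-8)
  }
})

test_that("bin representative trees hit their target size", {
  mam <- synthetic_mammal_tree()
  set.seed(53)
  for (target in c(4.0, 5.2, 6.1)) {
    bt <- bin_representative_tree(mam, target, keep = "human")
    expect_equal(tree_size(bt), target, tolerance = 0.0051)
    expect_true("human" %in% bt$tip.label)
  }
  expect_error(bin_representative_tree(mam, 7.0), "target size")
  full <- bin_representative_tree(mam, 6.18)
  expect_equal(tree_size(full), 6.18, tolerance = 0.0051)
})

test_that("bin assignment and genome aggregation are exact arithmetic", {
  sc <- data.frame(tree_size = c(4.01, 4.49, 5.0, 9.9))
  idx <- assign_bins(sc, bin_centers = c(4.0, 4.5, 5.0), bin_width = 0.1)
  expect_equal(idx, c(1L, 2L, 3L, NA))
  f1 <- structure(list(proportions = c(N = 0.8, C = 0, TO = 0.2)),
                  class = "mixture_fit")
  f2 <- structure(list(proportions = c(N = 0.6, C = 0, TO = 0.4)),
                  class = "mixture_fit")
  gp <- aggregate_genome(list(f1, f2), c(100, 100))
  expect_equal(gp[["TO"]], 0.3)
  expect_equal(sum(gp), 1)
  expect_equal(aggregate_genome(list(f1), 50)[["TO"]], 0.2)
  # sites below the minimum tree size count as pure neutral
  gp2 <- aggregate_genome(list(f1, f2), c(100, 100), below_min_count = 200)
  expect_equal(gp2[["TO"]], 0.15)
  expect_equal(sum(gp2), 1)
})

test_that("threshold tables are internally consistent", {
  setup <- small_setup()
  fits <- list(
    structure(list(proportions = c(N = 0.9, C = 0.05, TO = 0.05)),
              class = "mixture_fit"),
    structure(list(proportions = c(N = 0.7, C = 0.1, TO = 0.2)),
              class = "mixture_fit"))
  counts <- c(5000, 5000)
  tab <- threshold_table(fits, setup, counts, thresholds = c(-999, 0, 1, 2))
  expect_equal(tab$power_pct + tab$selected_missed_pct, rep(100, 4))
  expect_true(all(tab$fdr_pct >= 0 & tab$fdr_pct <= 100))
  # a threshold below any attainable score captures everything
  expect_equal(tab$power_pct[1], 100)
  expect_equal(tab$filtered_pct[1], 100)
  expect_true(all(diff(tab$filtered_pct) <= 0))   # monotone in threshold
  # adding below-minimum neutral sites dilutes the filtered fraction
  tab2 <- threshold_table(fits, setup, counts, thresholds = 0,
                          below_min_count = 10000)
  expect_lt(tab2$filtered_pct, tab$filtered_pct[2])
})
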