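test_that("the Lambda statistic follows its definition", {
  expect_equal(lambda_statistic(0.5, 0.5), 0)
  expect_equal(lambda_statistic(0.9, 0.99), 2 * log(10), tolerance = 1e-12)
  expect_equal(lambda_statistic(0.9, 0.99), 4.6052, tolerance = 1e-4)
  expect_equal(lambda_statistic(0.99, 0.9), -2 * log(10), tolerance = 1e-12)
  expect_error(lambda_statistic(1, 0.5), "degenerate")
  expect_error(lambda_statistic(0.5, 1.2))
})

test_that("simulation p-values carry exact binomial intervals", {
  pv <- p_value_with_ci(10, null_sample = rep(0, 500))
  expect_equal(pv$p, 0)
  expect_equal(pv$ci, as.numeric(stats::binom.test(0, 500)$conf.int),
               tolerance = 1e-12)
  expect_equal(pv$ci[2], 0.00735, tolerance = 1e-4)
  # ties count as extreme; everything larger gives p = 1
  expect_equal(p_value_with_ci(0, rep(0, 10))$p, 1)
  pv2 <- p_value_with_ci(1, c(rep(2, 25), rep(0, 475)))
  expect_equal(pv2$p, 0.05)
  expect_true(pv2$ci[1] < 0.05 && 0.05 < pv2$ci[2])
  expect_error(p_value_with_ci(1, numeric(0)), "empty")
})

test_that("overlap is monotone over nested mixture models", {
  setup <- small_setup()
  set.seed(61)
  null_fit0 <- list(bin_fits = lapply(seq_along(setup), function(i)
    structure(list(proportions = c(N = 0.75, C = 0.1, TO = 0.15)),
              class = "mixture_fit")))
  std <- gerpmix:::sample_model_scores(setup, null_fit0$bin_fits,
                                       c(3000, 3000))
  fits <- gerpmix:::fit_model_family(std, setup,
                                     c("N", "N+C", "N+TO", "N+C+TO"))
  # the maximized per-bin overlap is monotone in the component set because
  # richer searches are seeded with the nested optimum
  for (i in seq_along(setup)) {
    ob <- vapply(fits, function(f) f$bin_fits[[i]]$overlap, numeric(1))
    expect_lte(ob[["N"]], ob[["N+C"]] + 1e-9)
    expect_lte(ob[["N"]], ob[["N+TO"]] + 1e-9)
    expect_lte(ob[["N+C"]], ob[["N+C+TO"]] + 1e-9)
    expect_lte(ob[["N+TO"]], ob[["N+C+TO"]] + 1e-9)
  }
  # the pooled genome-wide overlap (not itself maximized) tracks the same
  # ordering up to small slack
  o <- vapply(fits, `[[`, numeric(1), "genome_overlap")
  expect_gte(o[["N+C+TO"]], o[["N"]] - 0.02)
})

test_that("null Lambda distributions are reproducible and centred low", {
  setup <- small_setup()
  # fit a pure-neutral model to neutral data as the null
  set.seed(62)
  std <- lapply(seq_along(setup), function(i)
    sample(attr(setup[[i]]$templates$N, "scores"), 1500, replace = TRUE))
  nf <- fit_scores_model(std, setup, components = "N")
  comps <- list(c("N", "N+C"))
  l1 <- null_lambda_distribution(nf, setup, c(1500, 1500), comps,
                                 n_reps = 12, seed = 63)
  l2 <- null_lambda_distribution(nf, setup, c(1500, 1500), comps,
                                 n_reps = 12, seed = 63)
  expect_identical(l1, l2)
  expect_true(all(is.finite(l1)))
  # per-bin fits are nested-monotone; the pooled genome overlap can dip
  # marginally below, so null Lambda sits at or just below zero
  expect_true(all(l1 >= -0.1))
  expect_lt(stats::median(l1), 0.5)    # concentrated near zero
  expect_error(null_lambda_distribution(nf, setup, c(10, 10), comps,
                                        n_reps = 5), "n_reps")
})

test_that("a constrained component is detected against a neutral null", {
  setup <- small_setup()
  set.seed(64)
  # observed data truly contain 30% constrained sites
  std <- lapply(seq_along(setup), function(i) {
    c(sample(attr(setup[[i]]$templates$N, "scores"), 1400, replace = TRUE),
      rep(1, 600))
  })
  lt <- lambda_test(std, setup, null_model = "N",
                    comparisons = list(c("N", "N+C")), n_reps = 60,
                    seed = 65)
  cmp <- lt$comparisons[[1]]
  expect_gt(cmp$lambda_obs, max(cmp$null_sample))
  expect_equal(cmp$p, 0)
  expect_lt(cmp$ci[2], 0.07)   # binom.test(0, 60) upper bound
  # fitted alternative recovers the constrained fraction
  pC <- lt$models[["N+C"]]$bin_fits[[1]]$proportions[["C"]]
  expect_close(pC, 0.3, 0.04)
})
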