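test_that("categorization respects the half-open bin convention", {
  sch <- category_scheme()
  expect_equal(categorize(c(0.0299, 0.030, 0.05, 0.0099, 0.01), sch),
               c(5L, 6L, 7L, 1L, 2L))
  # partition: every risk maps to exactly one category
  risks <- seq(0.001, 0.999, by = 0.001)
  idx <- categorize(risks, sch)
  expect_true(all(idx >= 1 & idx <= 7))
  edges <- c(0, sch$edges, 1)
  expect_true(all(risks >= edges[idx] & risks < edges[idx + 1]))
  expect_error(category_scheme(c(0.02, 0.01)), "increasing")
  expect_error(categorize(0, sch), "\\(0, 1\\)")
})

test_that("the reclassification matrix is a joint distribution with correct marginals", {
  co <- ref_cohort()
  m <- reclass_matrix(co, category_scheme())
  expect_equal(sum(m), 1, tolerance = 1e-9)
  expect_true(all(m >= 0))
  marg <- bcsc_pretest_marginals()
  pre <- attr(m, "pre_marginal")
  se <- sqrt(marg$mass * (1 - marg$mass) / nrow(co$subjects))
  expect_true(all(abs(pre - marg$mass) <= 3 * se + 1e-9))
  # null panel: nobody moves, the matrix is diagonal
  co0 <- sample_cohort(marg, 20000, null_panel(3), fh_rate = 0, seed = 15)
  m0 <- reclass_matrix(co0, category_scheme())
  expect_equal(sum(diag(unclass(m0))), 1, tolerance = 1e-12)
})

test_that("strategy tallies are consistent with the reclassification matrix", {
  co <- ref_cohort()
  sch <- category_scheme()
  m <- reclass_matrix(co, sch)
  all_tested <- apply_strategy(co, 0)
  expect_equal(all_tested$pct_tested, 1)
  expect_equal(all_tested$benefit_fraction, 1)
  # cells (pre < 3%, post >= 3%) sum to the strategy's upward crossings
  high <- which(sch$edges >= 0.03)[1] + 1L # first category at/above 3%
  up_cells <- sum(unclass(m)[seq_len(high - 1), high:ncol(m)])
  down_cells <- sum(unclass(m)[high:nrow(m), seq_len(high - 1)])
  expect_equal(up_cells, all_tested$pct_up, tolerance = 1e-12)
  expect_equal(down_cells, all_tested$pct_down, tolerance = 1e-12)
})

test_that("band edges and degenerate bands behave structurally", {
  co <- ref_cohort()
  # a band entirely above the treatment threshold can only move women down
  above <- apply_strategy(co, 0.035)
  expect_equal(above$pct_up, 0)
  expect_gt(above$pct_down, 0)
  # an empty band tests and reclassifies no one
  empty <- apply_strategy(co, 0.95)
  expect_equal(empty$pct_tested, 0)
  expect_equal(empty$pct_up + empty$pct_down, 0)
  # crossings never exceed the test-everyone reference
  all_tested <- apply_strategy(co, 0)
  for (lo in c(0.01, 0.02, 0.03)) {
    s <- apply_strategy(co, lo)
    expect_lte(s$pct_up, all_tested$pct_up)
    expect_lte(s$pct_down, all_tested$pct_down)
  }
  expect_error(apply_strategy(co, 0.03, 0.02), "exceed")
})

test_that("downward crossings are identical once the band covers all high priors", {
  co <- ref_cohort()
  downs <- vapply(c(0.025, 0.02, 0.015, 0.01, 0),
                  function(lo) apply_strategy(co, lo)$pct_down, numeric(1))
  expect_true(all(downs == downs[1]))
})

test_that("the benefit curve is monotone for nested strategies", {
  co <- ref_cohort()
  curve <- benefit_curve(co, list(
    list(test_lower = 0.025), list(test_lower = 0.02),
    list(test_lower = 0.015), list(test_lower = 0.01),
    list(test_lower = 0)
  ))
  expect_true(all(diff(curve$pct_tested) > 0))
  expect_true(all(diff(curve$benefit_fraction) >= 0))
  expect_equal(curve$benefit_fraction[nrow(curve)], 1)
  expect_equal(curve$pct_tested[nrow(curve)], 1)
})

test_that("threshold summaries stratify and agree with the sampler input", {
  co <- ref_cohort()
  marg <- bcsc_pretest_marginals()
  s <- summarize_above_threshold(co, 0.03)
  target <- sum(marg$mass[marg$lower >= 0.03])
  se <- sqrt(target * (1 - target) / nrow(co$subjects))
  expect_lt(abs(s$pct_pre[1] - target), 3 * se)
  # null panel: pre and post proportions coincide
  co0 <- sample_cohort(marg, 20000, null_panel(2), fh_rate = 0, seed = 16)
  s0 <- summarize_above_threshold(co0, 0.03)
  expect_equal(s0$pct_pre, s0$pct_post)
  # stratification by family history reports both strata
  cofh <- sample_cohort(marg, 20000, ref_panel(), fh_rate = 0.114, seed = 17)
  sf <- summarize_above_threshold(cofh, 0.03, by = "fh_positive")
  expect_equal(nrow(sf), 3)
  expect_error(summarize_above_threshold(cofh, 0.03, by = "prior"), "logical")
})
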