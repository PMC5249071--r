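test_that("single-SNP likelihood ratios match direct arithmetic", {
  d <- genotype_dist(list(risk_allele_freq = 0.3, odds_ratio = 1.2), 0.05)
  expect_equal(snp_lr(2, d), 1.30087485736, tolerance = 1e-10)
  expect_error(snp_lr(3, d), "0, 1 or 2")
  d0 <- genotype_dist(list(risk_allele_freq = 0.3, odds_ratio = 1), 0.05)
  for (g in 0:2) expect_equal(snp_lr(g, d0), 1, tolerance = 1e-14)
})

test_that("the control-expected likelihood ratio is exactly one per SNP", {
  grid <- expand.grid(p = c(0.1, 0.3, 0.5, 0.9),
                      gamma = c(1.05, 1.3, 2), K = c(0.01, 0.05, 0.1))
  for (i in seq_len(nrow(grid))) {
    d <- genotype_dist(list(risk_allele_freq = grid$p[i],
                            odds_ratio = grid$gamma[i]), grid$K[i])
    e_lr <- sum(d$controls * (d$cases / d$controls))
    expect_equal(e_lr, 1, tolerance = 1e-12)
  }
})

test_that("panel LR is the product of per-SNP LRs", {
  panel <- snp_panel(data.frame(
    snp_id = c("a", "b"),
    risk_allele_freq = c(0.2, 0.4),
    odds_ratio = c(1.15, 1.3)
  ))
  model <- panel_genotype_model(panel, 0.05)
  d1 <- genotype_dist(as.list(panel[1, ]), 0.05)
  d2 <- genotype_dist(as.list(panel[2, ]), 0.05)
  for (g1 in 0:2) for (g2 in 0:2) {
    expect_equal(panel_lr(c(g1, g2), model),
                 snp_lr(g1, d1) * snp_lr(g2, d2), tolerance = 1e-12)
  }
  expect_error(panel_lr(c(1, 1, 1), model), "does not match panel size")
  expect_error(panel_lr(c(1, 3), model), "\\{0, 1, 2\\}")
})

test_that("log-space accumulation agrees with the naive product at 70 SNPs", {
  panel <- ref_panel()
  model <- panel_genotype_model(panel, 0.05)
  g <- simulate_genotypes(panel, "population", 1000, seed = 21)
  log_space <- panel_log_lr(g, model)
  lr_table <- model$cases / model$controls
  naive <- apply(g, 1, function(row) {
    prod(lr_table[cbind(seq_len(ncol(g)), row + 1L)])
  })
  expect_equal(exp(log_space), naive, tolerance = 1e-9)
})

test_that("the posterior update is Bayes on the odds scale", {
  expect_equal(posterior_risk(0.03, 1), 0.03, tolerance = 1e-15)
  expect_equal(posterior_risk(0.02, 2), 0.0392156862745, tolerance = 1e-12)
  expect_error(posterior_risk(0, 2), "\\(0, 1\\)")
  expect_error(posterior_risk(1, 2), "\\(0, 1\\)")
  expect_error(posterior_risk(0.5, -1), "positive")
  # strictly increasing in the LR at any fixed prior
  priors <- seq(0.005, 0.2, by = 0.01)
  expect_true(all(posterior_risk(priors, 2) > posterior_risk(priors, 1.5)))
  # round trip: posterior -> odds -> / LR -> risk recovers the prior
  for (lr in c(0.3, 1, 2.7, 11)) {
    post <- posterior_risk(priors, lr)
    odds <- post / (1 - post) / lr
    expect_equal(odds / (1 + odds), priors, tolerance = 1e-12)
  }
})

test_that("family-history attenuation deflates prior odds as specified", {
  adj0 <- fh_adjustment(fh_relative_risk = 2, proportion_explained = 0)
  priors <- c(0.01, 0.03, 0.1)
  for (lr in c(0.5, 1, 3)) {
    expect_equal(fh_adjusted_posterior(priors, lr, adj0),
                 posterior_risk(priors, lr), tolerance = 1e-14)
  }
  adj <- fh_adjustment(fh_relative_risk = 2, proportion_explained = 0.3)
  post <- fh_adjusted_posterior(priors, 1, adj)
  expect_equal(post / (1 - post),
               priors / (1 - priors) / 2^0.3, tolerance = 1e-12)
  expect_error(fh_adjustment(0.5, 0.3), ">= 1")
  expect_error(fh_adjustment(2, 1.5), "\\[0, 1\\]")
})

test_that("proportion explained is clamped, null at gamma = 1, monotone in effect size", {
  expect_identical(estimate_proportion_explained(null_panel(5), 2, 0.05), 0)
  base <- ref_panel()
  prop <- estimate_proportion_explained(base, 2, 0.05)
  expect_gt(prop, 0)
  expect_lt(prop, 1)
  # uniformly inflating panel odds ratios increases the share explained
  scale_panel <- function(f) {
    snp_panel(transform(as.data.frame(base),
                        odds_ratio = 1 + f * (odds_ratio - 1)))
  }
  props <- vapply(c(0.5, 1, 2, 4),
                  function(f) estimate_proportion_explained(scale_panel(f)),
                  numeric(1))
  expect_true(all(diff(props) > 0))
  expect_true(all(props >= 0 & props <= 1))
})

test_that("the adjusted update is mean-preserving over FH-conditioned genotypes", {
  # a modest panel keeps the Monte-Carlo error small at n = 100,000
  panel <- generate_reference_panel(n_snps = 10, seed = 13)
  prop <- estimate_proportion_explained(panel, 2, 0.05)
  adj <- fh_adjustment(2, prop)
  model <- panel_genotype_model(panel, 0.05)
  p_fh <- vapply(seq_len(nrow(panel)), function(i) {
    fh_conditioned_freq(as.list(panel[i, ]), 0.05)
  }, numeric(1))
  fh_panel <- snp_panel(transform(as.data.frame(panel),
                                  risk_allele_freq = p_fh))
  g <- simulate_genotypes(fh_panel, "population", 100000, seed = 14)
  lr <- exp(panel_log_lr(g, model))
  prior <- 0.02
  post <- fh_adjusted_posterior(prior, lr, adj)
  se <- stats::sd(post) / sqrt(length(post))
  expect_lt(abs(mean(post) - prior), 4 * se)
})
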