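test_that("Hardy-Weinberg triples are correct and sum to one", {
  expect_equal(hwe_genotype_freqs(0.5), c(0.25, 0.5, 0.25))
  expect_equal(hwe_genotype_freqs(0.3), c(0.49, 0.42, 0.09))
  for (p in seq(0.01, 0.99, by = 0.07)) {
    expect_equal(sum(hwe_genotype_freqs(p)), 1, tolerance = 1e-15)
  }
  expect_error(hwe_genotype_freqs(0), "range")
  expect_error(hwe_genotype_freqs(1), "range")
})

test_that("case and control genotype distributions match direct arithmetic", {
  snp <- list(snp_id = "rs1", risk_allele_freq = 0.3, odds_ratio = 1.2)
  d <- genotype_dist(snp, prevalence = 0.05)
  # frozen from independent evaluation of the reweighting formulas
  expect_equal(unname(d$cases),
               c(0.436098255607, 0.448558205767, 0.115343538626),
               tolerance = 1e-10)
  expect_equal(unname(d$controls),
               c(0.492836933915, 0.418496936539, 0.088666129546),
               tolerance = 1e-10)
  expect_equal(unname(d$population), c(0.49, 0.42, 0.09))
  expect_error(genotype_dist(snp, prevalence = 0.2), "prevalence")
  expect_error(genotype_dist(snp, prevalence = 0), "prevalence")
})

test_that("a null SNP has identical distributions in every arm", {
  for (K in c(0.01, 0.05, 0.10)) {
    d <- genotype_dist(list(risk_allele_freq = 0.3, odds_ratio = 1), K)
    expect_equal(d$cases, d$population, tolerance = 1e-15)
    expect_equal(d$controls, d$population, tolerance = 1e-15)
  }
})

test_that("mixture identity and normalization hold across the parameter grid", {
  grid <- expand.grid(p = c(0.05, 0.2, 0.5, 0.8, 0.95),
                      gamma = c(1, 1.05, 1.2, 1.5, 2.5),
                      K = c(0.001, 0.01, 0.05, 0.10))
  for (i in seq_len(nrow(grid))) {
    d <- genotype_dist(list(risk_allele_freq = grid$p[i],
                            odds_ratio = grid$gamma[i]), grid$K[i])
    expect_equal(sum(d$cases), 1, tolerance = 1e-12)
    expect_equal(sum(d$controls), 1, tolerance = 1e-12)
    mix <- grid$K[i] * d$cases + (1 - grid$K[i]) * d$controls
    expect_equal(mix, d$population, tolerance = 1e-12)
    if (grid$gamma[i] > 1) {
      # risk-genotype enrichment in cases, depletion in controls
      expect_gt(d$cases[3], d$population[3])
      expect_gt(d$population[3], d$controls[3])
    }
  }
})

test_that("simulated genotype frequencies converge to the model triples", {
  panel <- snp_panel(data.frame(
    snp_id = c("a", "b", "c"),
    risk_allele_freq = c(0.1, 0.3, 0.45),
    odds_ratio = c(1.05, 1.2, 1.12)
  ))
  n <- 100000
  model <- panel_genotype_model(panel, 0.05)
  for (status in c("population", "case", "control")) {
    g <- simulate_genotypes(panel, status, n, 0.05, seed = 11)
    probs <- switch(status, population = model$population,
                    case = model$cases, control = model$controls)
    for (j in 1:3) {
      emp <- tabulate(g[, j] + 1L, 3L) / n
      se <- sqrt(probs[j, ] * (1 - probs[j, ]) / n)
      expect_true(all(abs(emp - probs[j, ]) <= 3 * se + 1e-9),
                  label = sprintf("%s SNP %d within 3 SE", status, j))
    }
  }
})

test_that("genotype simulation is deterministic and validates inputs", {
  panel <- null_panel(2)
  a <- simulate_genotypes(panel, "case", 50, seed = 5)
  b <- simulate_genotypes(panel, "case", 50, seed = 5)
  expect_identical(a, b)
  expect_error(simulate_genotypes(panel, "sick", 50, seed = 5))
  expect_error(simulate_genotypes(panel, "case", 0, seed = 5), "positive")
  # null effect: case arm reduces to Hardy-Weinberg population frequencies
  g <- simulate_genotypes(null_panel(), "case", 100000, seed = 6)
  emp <- tabulate(g[, 1] + 1L, 3L) / 100000
  expect_true(all(abs(emp - c(0.25, 0.5, 0.25)) <= 3 * sqrt(0.25 * 0.75 / 1e5)))
})

test_that("family-history conditioning enriches risk alleles as expected", {
  snp <- list(risk_allele_freq = 0.3, odds_ratio = 1.2)
  # frozen: p_case = P(g1|D+)/2 + P(g2|D+); p_FH halfway back to p
  expect_equal(fh_conditioned_freq(snp, 0.05), 0.319811320755,
               tolerance = 1e-10)
  expect_equal(fh_conditioned_freq(list(risk_allele_freq = 0.3,
                                        odds_ratio = 1), 0.05), 0.3,
               tolerance = 1e-15)
  # monotone increasing in the odds ratio at fixed frequency
  gammas <- seq(1, 2, by = 0.1)
  pfh <- vapply(gammas, function(g) {
    fh_conditioned_freq(list(risk_allele_freq = 0.3, odds_ratio = g), 0.05)
  }, numeric(1))
  expect_true(all(diff(pfh) > 0))
  expect_true(all(pfh >= 0.3))
})
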