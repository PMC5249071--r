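# Shared fixtures, built in code at load time.

# Small hand-written panel used by parser / round-trip tests.
toy_panel_df <- function() {
  data.frame(
    snp_id = c("rs0001", "rs0002", "rs0003"),
    risk_allele_freq = c(0.25, 0.4, 0.1),
    odds_ratio = c(1.10, 1.07, 1.21),
    risk_allele = c("A", "G", "T"),
    stringsAsFactors = FALSE
  )
}

# One-SNP panel with an effectively null effect.
null_panel <- function(n = 1) {
  snp_panel(data.frame(
    snp_id = sprintf("null_%02d", seq_len(n)),
    risk_allele_freq = rep(0.5, n),
    odds_ratio = rep(1, n)
  ))
}

# The calibrated 70-SNP reference panel, built once per test run.
ref_panel <- local({
  panel <- NULL
  function() {
    if (is.null(panel)) panel <<- generate_reference_panel(seed = 1)
    panel
  }
})

# Reference cohort (no family history machinery): priors from the coarse
# published marginals, population genotypes, posterior via the LR update.
# Built once and reused by the reclassification and acceptance tests.
ref_cohort <- local({
  cohort <- NULL
  function() {
    if (is.null(cohort)) {
      cohort <<- sample_cohort(bcsc_pretest_marginals(), 200000, ref_panel(),
                               fh_rate = 0, seed = 42)
    }
    cohort
  }
})
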