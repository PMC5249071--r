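#' Likelihood ratio of a single-SNP genotype
#'
#' `P(g | case) / P(g | control)` for a genotype carrying `genotype_count`
#' risk alleles. Averaged over the control genotype distribution the LR is
#' exactly 1, so a panel of such ratios never inflates risk on average in
#' unaffected women.
#'
#' @param genotype_count risk-allele count, 0, 1 or 2.
#' @param dist a `genotype_dist` from [genotype_dist()].
#' @return positive scalar likelihood ratio.
#' @export
snp_lr <- function(genotype_count, dist) {
  stopifnot(inherits(dist, "genotype_dist"))
  if (!genotype_count %in% 0:2) {
    stop("`genotype_count` must be 0, 1 or 2", call. = FALSE)
  }
  unname(dist$cases[genotype_count + 1] / dist$controls[genotype_count + 1])
}

#' Likelihood ratio of a multi-SNP genotype vector
#'
#' Under linkage equilibrium and no SNP-by-SNP interaction, the likelihood
#' ratio of the full genotype is the product of per-SNP ratios. The product
#' is accumulated in log space (sum of per-SNP log LRs, exponentiated once)
#' for numerical robustness over many loci; tests confirm agreement with the
#' naive product to relative 1e-9.
#'
#' @param genotypes integer vector of risk-allele counts, one per panel SNP.
#' @param model a [panel_genotype_model()].
#' @return positive scalar likelihood ratio.
#' @export
panel_lr <- function(genotypes, model) {
  exp(panel_log_lr(matrix(as.integer(genotypes), nrow = 1), model))
}

#' Log likelihood ratios for a matrix of genotype vectors
#'
#' Vectorized scorer: each row of `genotypes` is one individual's
#' risk-allele counts across the panel.
#'
#' @param genotypes integer matrix, individuals x SNPs, entries in
#'   \{0, 1, 2\}.
#' @param model a [panel_genotype_model()].
#' @return numeric vector of log likelihood ratios, one per row.
#' @export
panel_log_lr <- function(genotypes, model) {
  stopifnot(inherits(model, "panel_genotype_model"))
  if (!is.matrix(genotypes)) genotypes <- matrix(genotypes, nrow = 1)
  m <- length(model$snp_id)
  if (ncol(genotypes) != m) {
    stop("genotype vector length (", ncol(genotypes),
         ") does not match panel size (", m, ")", call. = FALSE)
  }
  if (any(!genotypes %in% 0:2)) {
    stop("genotype entries must be risk-allele counts in {0, 1, 2}",
         call. = FALSE)
  }
  score <- numeric(nrow(genotypes))
  for (j in seq_len(m)) {
    score <- score + unname(model$log_lr[j, genotypes[, j] + 1L])
  }
  score
}

#' Posterior absolute risk after genotyping
#'
#' Bayesian update on the odds scale: posterior odds = prior odds x LR,
#' mapped back to a probability. With `lr = 1` the prior is returned
#' unchanged; the update is strictly increasing in both arguments and
#' exactly invertible (dividing the posterior odds by the LR recovers the
#' prior).
#'
#' @param prior prior 5-year absolute risk(s), in (0, 1). Vectorized.
#' @param lr likelihood ratio(s), positive. Recycled against `prior`.
#' @return posterior probability vector.
#' @examples
#' posterior_risk(0.02, 2) # ~0.0392
#' @export
posterior_risk <- function(prior, lr) {
  if (!is.numeric(prior) || any(is.na(prior) | prior <= 0 | prior >= 1)) {
    stop("`prior` must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (!is.numeric(lr) || any(is.na(lr) | lr <= 0)) {
    stop("`lr` must be positive", call. = FALSE)
  }
  odds <- prior / (1 - prior) * lr
  odds / (1 + odds)
}

#' Family-history adjustment parameters
#'
#' When the prior risk already incorporates a positive first-degree family
#' history (as clinical risk-model output does) and the SNP panel itself
#' explains part of the familial risk, applying the panel LR on top of the
#' FH-inflated prior double-counts that shared component. The adjustment
#' removes the panel-explained share of the family-history relative risk
#' from the prior before the genotype update.
#'
#' @param fh_relative_risk marginal relative risk of a positive first-degree
#'   family history, >= 1 (default 2, the standard epidemiological figure).
#' @param proportion_explained fraction of `log(fh_relative_risk)` accounted
#'   for by the SNP panel, in \[0, 1\]; see
#'   [estimate_proportion_explained()].
#' @return an object of class `fh_adjustment`.
#' @export
fh_adjustment <- function(fh_relative_risk = 2, proportion_explained) {
  if (!is.numeric(fh_relative_risk) || length(fh_relative_risk) != 1L ||
      is.na(fh_relative_risk) || fh_relative_risk < 1) {
    stop("`fh_relative_risk` must be a single number >= 1", call. = FALSE)
  }
  if (!is.numeric(proportion_explained) || length(proportion_explained) != 1L ||
      is.na(proportion_explained) || proportion_explained < 0 ||
      proportion_explained > 1) {
    stop("`proportion_explained` must lie in [0, 1]", call. = FALSE)
  }
  structure(list(fh_relative_risk = fh_relative_risk,
                 proportion_explained = proportion_explained),
            class = "fh_adjustment")
}

#' Posterior risk for a woman with positive family history
#'
#' Deflates the prior odds by `fh_relative_risk ^ proportion_explained` —
#' the share of the family-history risk the panel itself carries — and then
#' applies the genotype likelihood ratio as in [posterior_risk()]. With
#' `proportion_explained = 0` this reduces exactly to [posterior_risk()].
#' The attenuation acts on the odds scale, matching the scale on which the
#' LR multiplies.
#'
#' @param prior_with_fh prior risk(s) that already include the
#'   family-history relative risk. Vectorized.
#' @param lr likelihood ratio(s) from the panel genotype.
#' @param adj an [fh_adjustment()].
#' @return posterior probability vector.
#' @export
fh_adjusted_posterior <- function(prior_with_fh, lr, adj) {
  stopifnot(inherits(adj, "fh_adjustment"))
  deflate <- adj$fh_relative_risk^adj$proportion_explained
  if (!is.numeric(prior_with_fh) ||
      any(is.na(prior_with_fh) | prior_with_fh <= 0 | prior_with_fh >= 1)) {
    stop("`prior_with_fh` must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (!is.numeric(lr) || any(is.na(lr) | lr <= 0)) {
    stop("`lr` must be positive", call. = FALSE)
  }
  odds <- prior_with_fh / (1 - prior_with_fh) * lr / deflate
  odds / (1 + odds)
}

#' Proportion of family-history risk explained by the panel
#'
#' Quantifies how much of the familial relative risk the SNP panel itself
#' accounts for: the log of the mean panel likelihood ratio among
#' family-history-positive women (whose genotypes follow the FH-conditioned
#' allele frequencies of [fh_conditioned_freq()], in Hardy-Weinberg
#' proportions), divided by `log(fh_relative_risk)`, clamped to \[0, 1\].
#' A null panel gives 0; a panel carrying the entire familial risk gives 1.
#'
#' The mean LR (not the mean log LR) is the right numerator: deflating the
#' prior odds by `fh_relative_risk^proportion_explained = E[LR | FH+]`
#' makes the genotype update mean-preserving in FH-positive women — their
#' average posterior equals the FH-inclusive prior, so the familial risk
#' the panel carries is counted exactly once.
#'
#' @param panel a [snp_panel].
#' @param fh_relative_risk marginal family-history relative risk, > 1.
#' @param prevalence disease prevalence K in (0, 0.10].
#' @return scalar in \[0, 1\].
#' @export
estimate_proportion_explained <- function(panel, fh_relative_risk = 2,
                                          prevalence = 0.05) {
  stopifnot(inherits(panel, "snp_panel"))
  if (!is.numeric(fh_relative_risk) || length(fh_relative_risk) != 1L ||
      fh_relative_risk <= 1) {
    stop("`fh_relative_risk` must be > 1", call. = FALSE)
  }
  model <- panel_genotype_model(panel, prevalence)
  p_fh <- fh_conditioned_freqs(panel, prevalence)
  hwe_fh <- cbind((1 - p_fh)^2, 2 * p_fh * (1 - p_fh), p_fh^2)
  # E[LR | FH+] over independent SNPs: product of per-SNP expectations
  log_mean_lr <- sum(log(rowSums(hwe_fh * exp(model$log_lr))))
  min(1, max(0, log_mean_lr / log(fh_relative_risk)))
}

#' Export per-subject risk-update results
#'
#' Writes the per-subject table of a cohort (see [sample_cohort()]) as
#' delimited text: subject_id, prior, log_lr, posterior, fh_positive.
#'
#' @param cohort a `prs_cohort`.
#' @param path output path (`.csv` comma, otherwise tab).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "prs_cohort"))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(cohort$subjects, path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
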