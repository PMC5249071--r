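#' Hardy-Weinberg genotype frequencies
#'
#' Genotype probabilities for 0, 1 and 2 copies of the risk allele at a
#' biallelic locus in Hardy-Weinberg equilibrium:
#' `((1-p)^2, 2p(1-p), p^2)`.
#'
#' @param p risk-allele frequency, strictly inside (0, 1).
#' @return numeric vector of length 3 summing to 1.
#' @examples
#' hwe_genotype_freqs(0.3) # c(0.49, 0.42, 0.09)
#' @export
hwe_genotype_freqs <- function(p) {
  check_prob(p, "p")
  c((1 - p)^2, 2 * p * (1 - p), p^2)
}

#' Per-SNP genotype distributions in population, cases and controls
#'
#' Under the multiplicative per-allele model, the relative risks of the
#' three genotypes are `(1, gamma, gamma^2)` where `gamma` is the per-allele
#' odds ratio (taken as a relative risk; the approximation is good while
#' disease prevalence is below ~10%). Case genotype probabilities are then
#' population probabilities reweighted by relative risk,
#' `P(g|D+) = P(g) gamma_g / sum_g P(g) gamma_g`, and control probabilities
#' follow from decomposing the population as a prevalence-K mixture of cases
#' and controls: `P(g|D-) = (P(g) - K P(g|D+)) / (1 - K)`. The mixture
#' identity `K P(g|D+) + (1-K) P(g|D-) = P(g)` therefore holds exactly.
#'
#' @param snp one-row [snp_panel] or a list with `risk_allele_freq` and
#'   `odds_ratio` (and optionally `snp_id`).
#' @param prevalence disease prevalence K, in (0, 0.10]; the case/control
#'   decomposition (and the OR-as-RR reading) assumes a rare-ish disease.
#' @return an object of class `genotype_dist`: list with `snp_id`,
#'   `prevalence`, and length-3 probability vectors `population`, `cases`,
#'   `controls` (indices = 0, 1, 2 risk-allele copies).
#' @examples
#' genotype_dist(list(snp_id = "rs1", risk_allele_freq = 0.3,
#'                    odds_ratio = 1.2), prevalence = 0.05)
#' @export
genotype_dist <- function(snp, prevalence = 0.05) {
  p <- snp$risk_allele_freq
  gamma <- snp$odds_ratio
  check_prob(p, "risk_allele_freq")
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0) {
    stop("`odds_ratio` must be a single positive number", call. = FALSE)
  }
  check_prevalence(prevalence)
  pop <- hwe_genotype_freqs(p)
  w <- c(1, gamma, gamma^2)
  cases <- pop * w / sum(pop * w)
  controls <- (pop - prevalence * cases) / (1 - prevalence)
  structure(
    list(snp_id = if (is.null(snp$snp_id)) NA_character_ else snp$snp_id,
         prevalence = prevalence,
         population = pop, cases = cases, controls = controls),
    class = "genotype_dist"
  )
}

check_prevalence <- function(K) {
  if (!is.numeric(K) || length(K) != 1L || is.na(K) || K <= 0 || K > 0.10) {
    stop("`prevalence` must lie in (0, 0.10]: the case/control ",
         "decomposition assumes a low-prevalence disease", call. = FALSE)
  }
  invisible(K)
}

#' Genotype model for a whole panel
#'
#' Vectorized form of [genotype_dist()]: per-SNP genotype probability
#' matrices for the population, cases and controls, plus the per-genotype
#' log likelihood ratios `log P(g|D+)/P(g|D-)` used to score genotype
#' vectors.
#'
#' @param panel a [snp_panel].
#' @param prevalence disease prevalence K in (0, 0.10].
#' @return an object of class `panel_genotype_model`: list with `snp_id`,
#'   `prevalence`, and n_snp x 3 matrices `population`, `cases`, `controls`,
#'   `log_lr`.
#' @export
panel_genotype_model <- function(panel, prevalence = 0.05) {
  stopifnot(inherits(panel, "snp_panel"))
  check_prevalence(prevalence)
  p <- panel$risk_allele_freq
  gamma <- panel$odds_ratio
  pop <- cbind((1 - p)^2, 2 * p * (1 - p), p^2)
  w <- cbind(1, gamma, gamma^2)
  cases <- pop * w / rowSums(pop * w)
  controls <- (pop - prevalence * cases) / (1 - prevalence)
  dimn <- list(panel$snp_id, c("g0", "g1", "g2"))
  dimnames(pop) <- dimnames(cases) <- dimnames(controls) <- dimn
  structure(
    list(snp_id = panel$snp_id, prevalence = prevalence,
         population = pop, cases = cases, controls = controls,
         log_lr = log(cases) - log(controls)),
    class = "panel_genotype_model"
  )
}

#' @export
print.panel_genotype_model <- function(x, ...) {
  cat(sprintf("panel genotype model: %d SNPs, prevalence K = %g\n",
              length(x$snp_id), x$prevalence))
  invisible(x)
}

# Draw an n x m genotype matrix, column j from the length-3 probability
# row probs[j, ]. Plain inverse-CDF sampling, one runif block per SNP.
sim_from_triples <- function(probs, n) {
  m <- nrow(probs)
  g <- matrix(0L, n, m)
  for (j in seq_len(m)) {
    u <- stats::runif(n)
    g[, j] <- (u > probs[j, 1]) + (u > probs[j, 1] + probs[j, 2])
  }
  colnames(g) <- rownames(probs)
  g
}

#' Simulate genotype vectors for a panel
#'
#' Each SNP is drawn independently from its genotype distribution in the
#' requested arm: Hardy-Weinberg population frequencies, the case
#' distribution `P(g|D+)`, or the control distribution `P(g|D-)` (see
#' [genotype_dist()]). Rows are individuals, columns are SNPs, entries are
#' risk-allele counts in \{0, 1, 2\}.
#'
#' @param panel a [snp_panel].
#' @param status one of `"population"`, `"case"`, `"control"`.
#' @param n number of individuals.
#' @param prevalence disease prevalence K in (0, 0.10].
#' @param seed integer seed; output is a pure function of the arguments.
#' @return integer matrix `n` x `nrow(panel)` with SNP ids as column names.
#' @export
simulate_genotypes <- function(panel, status = c("population", "case", "control"),
                               n, prevalence = 0.05, seed) {
  status <- match.arg(status)
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop("`n` must be a positive integer", call. = FALSE)
  }
  model <- panel_genotype_model(panel, prevalence)
  probs <- switch(status,
                  population = model$population,
                  case = model$cases,
                  control = model$controls)
  with_seed(seed, sim_from_triples(probs, as.integer(n)))
}

#' Risk-allele frequency conditional on positive family history
#'
#' Women with an affected first-degree relative are enriched for risk
#' alleles. The construction here treats the relative as case-like and
#' halves the enrichment through the kinship coefficient of a first-degree
#' pair: the case-allele frequency is
#' `p_case = P(g1|D+)/2 + P(g2|D+)`, and the proband's conditional frequency
#' is `p_FH = p + (p_case - p)/2`. For a null SNP (`gamma = 1`) this reduces
#' to `p` exactly, and `p_FH` is monotone increasing in `gamma`.
#'
#' @param snp one-row [snp_panel] or list as in [genotype_dist()].
#' @param prevalence disease prevalence K in (0, 0.10].
#' @return adjusted risk-allele frequency `p_FH`.
#' @examples
#' fh_conditioned_freq(list(risk_allele_freq = 0.3, odds_ratio = 1.2))
#' @export
fh_conditioned_freq <- function(snp, prevalence = 0.05) {
  d <- genotype_dist(snp, prevalence)
  p <- snp$risk_allele_freq
  p_case <- unname(d$cases[2] / 2 + d$cases[3])
  p + (p_case - p) / 2
}

# Vectorized p_FH over a panel (same construction as fh_conditioned_freq).
fh_conditioned_freqs <- function(panel, prevalence = 0.05) {
  model <- panel_genotype_model(panel, prevalence)
  p <- model$population[, 2] / 2 + model$population[, 3]
  p_case <- model$cases[, 2] / 2 + model$cases[, 3]
  unname(p + (p_case - p) / 2)
}

#' Export a genotype matrix as delimited text
#'
#' Debug convenience: writes individuals x SNPs risk-allele counts with a
#' header of SNP ids.
#'
#' @param genotypes integer matrix from [simulate_genotypes()].
#' @param path output path (`.csv` comma, otherwise tab).
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(genotypes, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(genotypes, path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
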