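---
title: "Methods: genotype likelihood ratios, risk updating and testing strategies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genotype likelihood ratios, risk updating and testing strategies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prsreclass)
```

## The risk-update model

Each woman enters with a prior 5-year absolute risk of invasive breast
cancer, `P(D+)`, produced by a clinical risk model from non-genetic
factors. Her multilocus genotype `G` is treated as a diagnostic test
result: Bayes' theorem on the odds scale gives

$$\text{posterior odds} = \frac{P(D^+)}{1 - P(D^+)} \cdot LR(G),
\qquad LR(G) = \prod_i \frac{P(g_i \mid D^+)}{P(g_i \mid D^-)},$$

where the product runs over panel SNPs, assumed to be in linkage
equilibrium and to act without interaction. Genotypes are risk-allele
counts $g \in \{0, 1, 2\}$, in Hardy-Weinberg proportions at each locus.

Per-genotype probabilities in cases and controls come from reweighting the
population frequencies by genotype relative risk. We use the
multiplicative per-allele model, $\gamma_g = (1, \gamma, \gamma^2)$, with
the per-allele odds ratio $\gamma$ standing in for the relative risk —
the standard reading for a disease whose prevalence $K$ stays below about
10%, and the convention under which published per-allele odds ratios
compose into a polygenic score. Cases are
$P(g \mid D^+) = P(g)\gamma_g / \sum_g P(g)\gamma_g$ and controls follow
from the exact mixture decomposition
$P(g) = K\,P(g \mid D^+) + (1-K)\,P(g \mid D^-)$, which the implementation
satisfies to machine precision. Two consequences are load-bearing and
tested: per-locus $E[LR \mid D^-] = 1$ exactly, and the posterior update
inverts exactly (posterior odds divided by the LR recover the prior).

### Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `prevalence` (K) | 0.05 | probability | Mid-range of the `< 0.10` regime in which the odds-ratio-as-relative-risk and mixture approximations are accurate; results are insensitive across 0.01–0.10 (the control triples change in third decimals). Values above 0.10 are rejected rather than silently extrapolated. |
| `treat_threshold` | 0.03 | 5-year risk | Guideline threshold for discussing chemoprevention; applied as `>=`. |
| `fh_relative_risk` | 2.0 | relative risk | Conventional marginal risk of one affected first-degree relative. |
| `fh_rate` | 0.114 | probability | Fraction of a screening population with a positive first-degree family history. |
| `freq_range` | (0.05, 0.5) | allele freq. | Common-variant range for GWAS panels in European-ancestry populations. |
| `or_range` | (1.03, 1.15) | per-allele OR | Calibrated; see below. |

## The reference panel generator

Per-SNP allele frequencies and odds ratios of real panels are tied to
specific publications; the generator instead draws them uniformly from the
ranges above, which were chosen once so that the induced discrimination
matches what validated 70-ish-SNP panels achieve empirically: an AUC near
0.63. The calibration argument is closed-form. The panel log likelihood
ratio is a sum of 70 independent locus terms, so it is approximately
normal in each arm with per-arm variance
$\sigma^2 = \sum_i 2 p_i (1-p_i) \log^2\gamma_i$ and case-minus-control
separation $\sigma^2$, giving $AUC = \Phi(\sigma/\sqrt2)$. The expectation
of $\sigma^2$ over the default ranges is about 0.21
($\sigma \approx 0.46$), hence AUC $\approx 0.63$. A naive use of the full
GWAS literature range (up to odds ratios of ~1.26) overshoots the
variance and the observed panel AUC; the calibrated upper bound of 1.15 is
a deliberate design choice, not an estimate of any single variant's
effect. Across generator seeds 1–100, at least 95% of panels land in AUC
0.60–0.65, and this is asserted in the test suite.

`closed_form_auc()` exposes two variants. The `small_effect` formula above
is the calibration yardstick. The `moments` variant evaluates the same
normal approximation at the *exact* per-arm mean and variance of the log
LR; at the reference effect sizes it sits about 0.008 above the
small-effect formula (which drops the prevalence and $\gamma^2$-curvature
terms), and it — not the small-effect formula — is the quantity the
simulated Mann-Whitney AUC converges to. Simulation tests therefore
compare against `moments` (tolerance 0.015 at 5000 + 5000 arms, about
2.8 Monte-Carlo standard errors), and separately pin the gap between the
two closed forms below 0.01.

## Family history

Priors from clinical models already include family history, and a SNP
panel explains part of the same familial signal, so applying the LR
unadjusted would count that share twice. Two quantities implement the
correction.

**FH-conditioned genotypes.** A woman with an affected first-degree
relative shares half her genome with a case-like individual. We therefore
set her risk-allele frequency to
$p_{FH} = p + \tfrac12 (p_{case} - p)$ with
$p_{case} = \tfrac12 P(g_1 \mid D^+) + P(g_2 \mid D^+)$, and draw her
genotypes in Hardy-Weinberg proportions at $p_{FH}$. This kinship-½
construction is the simplest model consistent with the qualitative
requirement (risk-allele enrichment among FH-positive women, vanishing for
null SNPs, monotone in effect size); it deliberately ignores the
relative's age, multiple affected relatives, and the distinction between
maternal and paternal history.

**Proportion explained.** The attenuation deflates the prior odds by
$RR_{FH}^{\,\theta}$ where
$\theta = \log E[LR \mid FH^+] / \log RR_{FH}$, clamped to $[0, 1]$. The
numerator is the log of the *mean* likelihood ratio over FH-conditioned
genotypes (a product of per-locus expectations, by independence). The mean
LR — not the mean log LR — is the right numerator: with this deflator the
genotype update is exactly mean-preserving in FH-positive women, so on
average their posterior equals their FH-inclusive prior and the familial
risk carried by the panel is counted once. The mean *log* LR would be the
wrong statistic here: under the kinship-½ construction the FH enrichment
($+\sigma^2/2$) almost exactly cancels the lognormal baseline
($-\sigma^2/2$), so it is near zero regardless of panel strength, and
using it would leave an uncorrected inflation of order
$e^{\sigma^2/2} \approx 1.11$ in FH-positive posteriors. A property test
verifies mean-preservation by simulation at $n = 10^5$. Whether the
attenuation should act on the odds or the probability scale is not
determined by first principles; we chose odds because that is the scale on
which the LR composes, and at risks of a few percent the difference is
second-order.

## The synthetic screening population

Published prior-risk distributions come as binned marginals. The sampler
reconstructs a continuous population in three steps:

1. **Bins.** Subjects are assigned to bins multinomially by bin mass.
2. **Within closed bins**, priors are uniform — the maximum-entropy choice;
   placing everyone at bin midpoints creates spurious steps exactly at the
   3% decision threshold.
3. **The open top bin** is filled from the conditional tail of a smooth
   parametric fit, truncated at a risk cap of 0.30 (5-year risks above 30%
   are not plausible screening-model output).

The smooth fit is a truncated lognormal, with location and scale chosen by
weighted least squares between model and observed bin masses using
inverse-mass (chi-square-style) weights, multi-start Nelder-Mead plus a
BFGS polish. The weighting matters: an unweighted fit lets the large
sub-1% bin dominate and overstates the tail above 3% by about 1.3
percentage points, while the inverse-mass fit reproduces that tail within
0.3 points. A two-parameter lognormal cannot reproduce every bin of the
published coarse marginals exactly — the documented residual bound is 3
percentage points per bin (observed maximum ~2.6 in the 1.0–1.4% bin) —
but only the tail beyond the top published cut is ever sampled from the
fit, so bulk-bin misfit does not propagate into threshold crossings.
Self-consistency is tested separately: refitting marginals generated from
a known lognormal recovers both parameters within 5%.

The published coarse marginals bundled as `bcsc_pretest_marginals()` sum
to 100.1% as printed; we normalize proportionally, treating the excess as
rounding noise, and keep the raw values alongside. Bins are half-open
`[lower, upper)` throughout, so a printed category "3.0–3.9%" is
`[0.030, 0.040)` and boundary risks land in the upper category.

The family-history flag is drawn independently of the prior. This is a
simplification (in reality FH-positive women concentrate in the upper risk
bins, since FH feeds the prior); its consequence is that stratified
FH summaries from `sample_cohort()` understate the pre-test risk of the
FH-positive stratum. The attenuation mechanism and the population-level
reclassification results do not depend on this coupling, because the
genotype update is mean-preserving within each stratum.

### What the generator does and does not emulate

The cohort emulates: the marginal prior-risk distribution, Hardy-Weinberg
and linkage-equilibrium genotypes with case/control/FH-appropriate
frequencies, and the exact posterior arithmetic. It does not emulate:
correlation between SNPs and the non-genetic risk factors inside the prior
(assumed independent apart from family history), residual LD between
panel loci (panels are declared pre-pruned), subtype-specific effects,
measurement error in the prior, or secular drift in risk-factor
prevalence. Passing tests therefore demonstrate internal consistency of
the model under its stated assumptions, not calibration against an
external cohort.

## Reclassification and testing strategies

Risk categories are half-open intervals from a `category_scheme()`; the
default seven categories cut at 1.0, 1.5, 2.0, 2.5, 3.0 and 4.0% and the
treatment threshold is applied as ≥ 3%. A testing strategy genotypes only
women whose *prior* falls in a band `[test_lower, test_upper)`; untested
women keep their prior. Strategy yield is summarized by the fraction
tested, the population fractions crossing the treatment threshold upward
and downward, and the benefit fraction — crossings achieved relative to
genotyping everyone, computed on the *same* simulated cohort so that the
comparison is paired and strategy rankings carry no between-run
Monte-Carlo noise. Structural consequences follow and are tested: the
downward-crossing fraction is identical for every strategy whose band
covers all priors at or above the threshold, and the benefit fraction is
monotone along nested bands.

## Numerical choices

- The 70-term LR product is accumulated as a sum of log LRs and
  exponentiated once; agreement with the naive product is tested to
  relative 1e-9.
- The AUC is the Mann-Whitney estimator from midranks, ties counted ½ —
  exact, binning-free, and identical to brute-force pair counting (tested,
  including against an independent ROC implementation). Single-SNP score
  distributions with three atoms make tie handling non-optional.
- All simulation entry points take an explicit integer seed, restore the
  caller's RNG state, and are bitwise-reproducible. The pipeline derives
  per-stage seeds from one root seed by a fixed affine map into the 32-bit
  range, so stages can be rerun independently.
- Degenerate inputs fail loudly: prevalence outside (0, 0.10], priors or
  thresholds on the boundary of (0, 1), non-contiguous bins, single-bin
  fits, genotype codes outside {0, 1, 2}, and band specifications with
  `test_upper <= test_lower` are all rejected with specific messages. An
  empty tested band is not an error; it returns a zero-yield result.

## Problem sizes

Default study conditions — and the sizes used throughout the tests and
the acceptance script — are a 70-SNP panel, 5000 + 5000 case/control arms
for discrimination, and cohorts of 200,000 women for reclassification
(100,000 for convergence property tests). At these sizes the binomial
standard error on a reported percentage near 5% is about 0.05 points, well
inside the 1-point tolerances used for the stochastic checks, and a full
end-to-end run completes in seconds.

## Known limitations

- The kinship-½ FH construction and the mean-LR proportion-explained
  statistic are principled stand-ins; different defensible constructions
  (e.g. conditioning on multiple affected relatives) would change
  FH-stratum results, though not the FH-negative pipeline.
- Odds ratios are treated as per-allele relative risks; above K ≈ 0.10
  this breaks down, which is why the prevalence argument is range-checked.
- The within-bin uniform assumption is unverifiable from binned input; it
  matters most for bins adjacent to the treatment threshold, and coarser
  input bins make threshold-crossing estimates correspondingly cruder.
- No confidence intervals are attached to individual posteriors; the
  package quantifies population-level reclassification, not personal
  uncertainty.
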