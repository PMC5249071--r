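# prsreclass

Bayesian SNP likelihood-ratio risk updating and chemoprevention
reclassification for breast-cancer screening populations.

## The problem

Chemoprevention with SERMs or aromatase inhibitors is recommended for women
whose 5-year invasive breast-cancer risk is at or above 3%, as estimated by
a clinical risk model (age, family history, breast density, biopsy
history). Dozens of common SNPs each shift that risk a little; together
they shift it enough to move some women across the 3% treatment threshold
in either direction. Because genotyping costs money, the practical question
is *who to test*: how much of the total reclassification benefit is
captured by testing only women whose pre-genotype risk is already near the
threshold?

`prsreclass` answers that question by simulation. It is aimed at
biostatisticians and epidemiologists modelling two-step risk-stratification
policies: it takes a panel of independent risk SNPs (allele frequency and
per-allele odds ratio per locus) and a binned distribution of prior 5-year
risks, and produces post-genotyping risk distributions, a pre/post
reclassification matrix, and the yield of tiered testing strategies.

## The model

Genotypes are counts of risk alleles, with each locus in Hardy-Weinberg
equilibrium and loci in linkage equilibrium. Under the multiplicative
per-allele model the genotype relative risks at a locus with per-allele
odds ratio γ are (1, γ, γ²), so with population genotype frequencies P(g),

- cases:    P(g | D⁺) = P(g) γ_g / Σ_g P(g) γ_g,
- controls: P(g | D⁻) = (P(g) − K·P(g | D⁺)) / (1 − K),

where K is the disease prevalence (valid for K below ~10%). The multilocus
genotype G acts as a diagnostic test with likelihood ratio

LR(G) = Π_i P(g_i | D⁺) / P(g_i | D⁻),

and each woman's risk is updated on the odds scale:

posterior odds = prior odds × LR(G).

Averaged over the control genotype distribution, E[LR] = 1 per locus — the
update cannot systematically inflate risk in unaffected women. For women
whose prior already includes a positive family history, the prior odds are
first deflated by the share of the familial relative risk the panel itself
carries (`estimate_proportion_explained()`), so that shared signal is
counted once.

Panel discrimination has the closed form AUC = Φ(σ/√2) with
σ² = Σ 2p(1−p)(log γ)² under the small-effect normal approximation; the
bundled reference-panel generator (70 loci, frequencies U(0.05, 0.5), odds
ratios U(1.03, 1.15)) is calibrated to AUC ≈ 0.63, matching the
discrimination reported for current GWAS panels.

## Worked example

```r
library(prsreclass)

panel <- generate_reference_panel(seed = 1)
assess_discrimination(panel, seed = 2)
#> panel discrimination: AUC 0.6441 (closed form 0.6291) | 5000 cases vs 5000 controls
#> mean log-LR: cases +0.1345, controls -0.1279

cohort <- sample_cohort(bcsc_pretest_marginals(), n = 200000, panel = panel,
                        fh_rate = 0, seed = 3)
cohort
#> PRS cohort: 200000 subjects, 70-SNP panel, 0.0% FH+
#>   prior mean 0.0137 | posterior mean 0.0138

apply_strategy(cohort, test_lower = 0.02)
#> strategy: test priors >=2.0% | tested 20.8% | up 3.52% down 2.62% | benefit 74.9%

benefit_curve(cohort, list(list(test_lower = 0.02),
                           list(test_lower = 0.015),
                           list(test_lower = 0)))
#>   test_lower test_upper pct_tested pct_up pct_down benefit_fraction
#> 1      0.020         NA      0.208 0.0352   0.0262            0.749
#> 2      0.015         NA      0.365 0.0500   0.0262            0.930
#> 3      0.000         NA      1.000 0.0557   0.0262            1.000
```

Reading the strategy line: genotyping only the ~21% of women whose prior
risk exceeds 2% moves 3.5% of the population up across the 3% threshold
and 2.6% down — about 75% of the crossings achieved by genotyping
everyone. The `pct_down` column is constant across strategies whose band
covers all priors ≥ 3%, because downward reclassification only ever comes
from that group.

The full pipeline (panel → discrimination → cohort → reclassification
tables → manifest) runs from one seeded configuration:

```r
run_pipeline(run_config(seed = 1), "out/")   # table1-3.csv, fig2.csv, auc.csv, manifest.yaml
```

or from the shell via `inst/scripts/run-pipeline.R`.

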