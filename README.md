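# compg — compound-genotype pairwise SNP interaction analysis

`compg` is an R package for case-control genetic association studies that
screens all SNP pairs of a gene panel for joint effects that single-variant
scans miss. It targets the analyst who has per-cohort genotype (VCF or
dosage TSV) and phenotype/covariate tables for several independent
case-control cohorts — the design typical of Alzheimer's disease genetics,
where consortium, sequencing, family-based and biobank collections are
meta-analyzed together.

## The method

Every SNP is dominant-coded (carrier of the minor allele = 1). For a pair,
the two carrier indicators define the four-level **compound genotype**

|              | SNP2 = 0 | SNP2 carrier |
|--------------|----------|--------------|
| **SNP1 = 0** | MM       | Mm           |
| **SNP1 carrier** | mM   | mm           |

Three logistic model families are fit per cohort, each adjusted for age,
sex, APOE ε2/ε4 carrier status, and a family random intercept where the
cohort has pedigree structure:

* single SNP: `logit P(AD) = α + β·carrier + γ'x`
* compound genotype: indicators for Mm, mM, mm against the MM reference
* multiplicative interaction: `b1·c1 + b2·c2 + b12·c1c2`

Per-cohort estimates are pooled by fixed-effects inverse-variance
meta-analysis (`w_i = 1/se_i²`) and FDR-adjusted (Benjamini–Hochberg) within
analysis-type families. Differences between pooled coefficients — the three
level differences, level vs single-SNP main effect, and main effect vs main
effect — are tested with the 1-df chi-square

```
χ² = (b1 − b2)² / (se1² + se2²)
```

which drives the classification of each pair as **novel-compg** (significant
pair, no individually significant SNP), **partial-interaction** (the mM−Mm
difference is significant and more extreme than the main-effect difference),
**main-effect-explained**, or **null**. Case/control differences in pairwise
LD (genotypic r, Fisher-z chi-square test, Bonferroni family threshold) are
reported alongside. A latent-Gaussian simulator with tetrachoric-calibrated
LD generates multi-cohort datasets for validation, since the real cohorts
of such studies are access-controlled.

See `vignettes/compound-genotype-analysis.Rmd` for the full model
description, default parameters and design rationale.

## Worked example

Simulate four cohorts of 4,000 subjects over a 6-SNP panel with one injected
compound-genotype effect (β_mm = 0.4 on the pair snp02–snp05, all other
genetic effects zero), then run the full pipeline:

```r
library(compg)
cfg <- sim_config(n_snps = 6, maf = 0.25, n_per_cohort = rep(4000, 4),
                  compg_effects = list(list(pair = c(2, 5),
                                            beta = c(Mm = 0, mM = 0, mm = 0.4))),
                  seed = 11)
cohorts <- generate_multi_cohort(cfg)
res <- run_full_analysis(cohorts, gene_label = "demo")
summary(res)
```

```
<compg_analysis> demo
  cohorts: cohort1, cohort2, cohort3, cohort4
  SNPs retained: 6; pairs: 15
  significant single SNPs (q < 0.05): 2
  significant pairs: 9 (novel-compg: 0, partial interaction: 0)

classification counts:

main-effect-explained                  null 
                    9                     6 

LD case/control differences significant at Bonferroni 0.00333: 1 of 15 pairs
```

The strongest signal is the injected cell itself:

```r
subset(res$pair_levels, q < 0.05)[, c("snp1", "snp2", "level", "beta", "se", "p", "q", "effects")]
#  snp1  snp2 level  beta     se        p        q effects
# snp02 snp05    mm 0.425 0.0486 2.31e-18 1.04e-16    ++++   <- injected 0.4
# ... (other rows are pairs sharing snp02 or snp05)
```

The `effects` column gives the per-cohort direction of each pooled estimate
(`++++` = adverse in all four cohorts). Note what the classification shows:
a β_mm of this size makes both comprising SNPs marginally significant
(carriers of snp02 are enriched for the risk-carrying mm cell), so the pair
is labelled `main-effect-explained`, and every pair sharing snp02 or snp05
inherits significant levels through the same marginal signal. Genuinely
`novel-compg` pairs arise in the small-effect regime, where the induced
marginal signal stays below the significance threshold.

All tables (`single_snp`, `pair_levels`, `interactions`, `contrasts`,
`level_vs_main`, `classification`, `ld`, volcano data) are plain data frames
and can be written as TSV plus a JSON run manifest with
`run_full_analysis(..., out_dir = "out")`. A thin command-line wrapper over
the same functions is provided in `inst/scripts/run_compg.R`.

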