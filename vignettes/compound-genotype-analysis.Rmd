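---
title: "Compound-genotype analysis of pairwise SNP interactions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compound-genotype analysis of pairwise SNP interactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(compg)
```

## The problem

Case-control association panels for polygenic diseases such as late-onset
Alzheimer's disease are usually screened one variant at a time. Pairs of
variants in the same gene region can, however, carry risk signal that neither
member shows marginally: the effect of one minor allele may depend on whether
the minor allele of a neighbouring SNP is present. `compg` implements a
systematic pairwise screen built on *compound genotypes* and provides
everything around it — per-cohort QC, covariate-adjusted logistic fits,
multi-cohort meta-analysis, FDR control, coefficient contrasts, case/control
LD comparison, and a calibrated simulator — so the full pipeline can be
exercised and validated without access-controlled cohort data.

## The model

Each SNP enters under a **dominant allelic-effect coding**: carriers of the
minor allele (heterozygous or homozygous) are coded 1, non-carriers 0. This
sidesteps unstable estimates from the small minor-homozygote cells of
low-frequency variants.

For a SNP pair, the two carrier indicators define the four-level
**compound genotype** factor

| | SNP2 non-carrier | SNP2 carrier |
|---|---|---|
| **SNP1 non-carrier** | MM | Mm |
| **SNP1 carrier** | mM | mm |

with SNP1 the lower-positioned SNP of the pair (this fixes the mM/Mm
orientation reproducibly). Three per-cohort logistic model families are fit,
all adjusted for age, sex and the APOE $\varepsilon2$/$\varepsilon4$ carrier
indicators (the rs7412 and rs429358 dominant codings), plus a family random
intercept in cohorts with pedigree structure:

* **single SNP**: $\mathrm{logit}\,P(Y=1) = \alpha + \beta\,c + \gamma'x$,
  one carrier indicator $c$;
* **compound genotype**: indicators for Mm, mM and mm with MM as the
  reference level;
* **multiplicative interaction**: $\beta_1 c_1 + \beta_2 c_2 + \beta_{12}c_1c_2$.

The last two span the same column space; at the maximum likelihood
$\beta_{mM} = b_1$, $\beta_{Mm} = b_2$ and
$\beta_{mm} = b_1 + b_2 + b_{12}$, and their log-likelihoods coincide. This
reparameterization identity is asserted to $10^{-6}$ in the test suite and is
the package's strongest internal consistency check.

Per-cohort estimates of each term are pooled by **fixed-effects
inverse-variance meta-analysis** ($w_i = 1/se_i^2$), and
**Benjamini–Hochberg q-values** are computed within families: all single-SNP
p-values of a panel form one family, all compound-genotype level p-values
another, interaction terms, level contrasts and level-vs-main comparisons
each their own. Which family definition the original multi-cohort analyses
used is not derivable from the reported results; the per-analysis-type family
is recorded in the run manifest so users can audit it, and `bh_fdr()` accepts
any grouping.

Differences between two pooled coefficients are tested with the
one-degree-of-freedom chi-square
$$\chi^2 = \frac{(b_1-b_2)^2}{se_1^2+se_2^2},$$
applied to the three level differences (mM−Mm, mM−mm, Mm−mm), to
level-vs-main-effect comparisons, and to the difference of two single-SNP
main effects. The two estimates are treated as independent even when they
come from the same samples (level vs main effect); the ignored covariance
makes these contrasts conservative in some configurations and anticonservative
in others, and is retained deliberately to match how such comparisons are
made in practice.

A pair is then classified:

* **novel-compg** — some level is FDR-significant while neither comprising
  SNP is individually significant;
* **partial-interaction** — some level is significant, at least one SNP is
  significant, and the mM−Mm contrast is both FDR-significant and more
  extreme (smaller p) than the contrast of the two main effects;
* **main-effect-explained** — significant pair, significant SNP(s), no
  partial interaction;
* **null** — otherwise; pairs whose mM−Mm contrast alone is significant are
  flagged `contrast_only` and retained in reports.

Where a pair satisfies both the novel and the partial conditions the category
stays novel-compg and the partial condition is reported in its own field —
the categories overlap in real data and a single label cannot carry both.

Finally, linkage disequilibrium between pair members is summarized by the
genotypic (composite) Pearson correlation of additive counts — computable
without phase — separately in cases and controls, and compared with the
squared Fisher-z difference statistic on 1 df at a Bonferroni threshold of
$0.05/(\text{number of pairs tested})$. An EM-based haplotype $r$ would
differ slightly from the composite $r$ when genotypes deviate from
Hardy–Weinberg proportions; that divergence is a known approximation here.

## Quality control

Defaults, applied per cohort by `apply_qc()`:

| rule | default | note |
|---|---|---|
| sample missingness | ≤ 5% | applied first |
| SNP missingness | ≤ 5% | recomputed on retained samples |
| MAF | ≥ 5% | minor allele defined per cohort |
| exact HWE p | ≥ 1e−6 | controls only by default |
| imputation r² | ≥ 0.9 | only where the column exists |
| LD pruning | r² ≤ 0.7 | greedy, position-ordered |

The HWE test is the conditional exact test rather than the 1-df chi-square,
for validity at modest counts; it is computed on controls by default because
true association signal distorts genotype proportions in cases. The pruning
rule is deterministic: SNPs are visited in ascending position order and the
later-positioned member of an offending pair is dropped — simpler than
windowed heuristics and exactly reproducible. Sample filtering precedes SNP
metric recomputation; the reverse order is defensible too, but an order had
to be fixed and this one matches common GWAS practice.

## The simulator

`generate_multi_cohort()` draws, per individual, two independent haplotypes
from a latent-Gaussian copula: SNP $j$'s minor allele on a haplotype is the
indicator $Z_j < \Phi^{-1}(\mathrm{MAF}_j)$, and the latent correlation of
each pair is calibrated by numerically inverting the tetrachoric relation so
the *allelic* correlation matches the target LD (`calibrate_latent_correlation()`
validates this against a Monte-Carlo oracle at $10^6$ haplotypes in the test
suite). This construction supports arbitrary sparse low-LD target matrices —
the regime of pruned association panels — which Markov-chain haplotype models
handle poorly. If pairwise calibration leaves the latent matrix slightly
indefinite it is repaired by eigenvalue clipping with the diagonal restored;
for the low-LD targets used here the adjustment is numerically negligible.

Disease status follows a logistic model with dominant main effects,
compound-genotype cell effects (added on the log-odds scale when several
configured pairs overlap, with no renormalization), covariate effects and an
optional shared family intercept; the global intercept is tuned by root
finding so the expected case fraction hits its target.

Defaults were chosen once to describe a realistic four-cohort AD-style
design and are not tuning knobs:

* cohort sizes `c(15000, 10000, 4000, 30000)` — the relative magnitudes of a
  genotyping consortium, a sequencing project, a family study and a biobank;
* MAF 0.25 — a typical common-variant panel after the 5% floor;
* case fraction 0.40 — characteristic of enriched case-control designs;
* covariate log-odds: age +0.5 per decade, sex +0.2, $\varepsilon2$ −0.5,
  $\varepsilon4$ +1.2 — the protective/adverse APOE pattern and a rising age
  gradient of the field's literature, with carrier frequencies 0.15 and 0.30;
* age $\sim N(75, 6)$, controls truncated at 65 — the biobank age-matching
  exclusion. Note this truncation deliberately attenuates the *observed*
  age-status association relative to the generating coefficient.

What the simulator does **not** emulate: realistic coalescent haplotype
structure, genotyping batch effects, population stratification,
non-random missingness, or phenotype misclassification. Passing tests
therefore demonstrate the statistical machinery is correct under the stated
generative model, not that the pipeline is robust to those real-data
complications.

## Numerical choices

* Logistic fits: IRLS (`stats::glm.fit`) with deviance tolerance $10^{-10}$
  and at most 100 iterations; non-converged fits are excluded from pooling.
* Separation / empty cells: a term whose estimate exceeds 15 in absolute
  value, or whose design column is constant among complete cases, is flagged
  not estimable and simply omitted from meta-analysis — no penalization,
  since the downstream pooling assumes plain ML estimates.
* Family random intercepts use the Laplace approximation
  (`lme4::glmer`, nAGQ = 1); with all-singleton clusters the estimates
  coincide with the plain fit to $10^{-4}$ (asserted). Cluster-robust
  sandwich standard errors are available as a configuration fallback.
* Age is centered at 70 and scaled to decades inside the fits for
  conditioning; reported age effects are rescaled to per-year.
* An exactly zero pooled estimate prints as `+` in direction strings.
* Exact HWE p-values are discrete; uniformity checks treat ties accordingly.

## Validation problem sizes

The packaged test suite validates operating characteristics at sizes chosen
to make the Monte-Carlo error of each check small relative to its acceptance
band: null calibration over eight 10-SNP, four-cohort panels of 2000
subjects each (1080 pooled level tests); coverage and end-to-end
classification over 500 replicates of a two-SNP, four-cohort design of 5000
subjects per cohort; simulator fidelity at 10000 subjects and a 200-SNP
Hardy–Weinberg panel.

One documented operating characteristic deserves emphasis: a *pure*
compound-genotype mm effect $\beta_{mm}$ necessarily induces marginal
single-SNP signal of size roughly $\beta_{mm}\,P(\text{carrier of the other
SNP})$, with a Wald statistic about $\sqrt{p_2}$ times that of the mm level
itself. Effect sizes large enough to give near-certain mm detection at
moderate sample sizes therefore also make the comprising SNPs individually
significant much of the time, moving such pairs out of the novel-compg
category and into main-effect-explained. Genuinely novel pairs are the
small-effect regime — which is precisely where they are observed in real
panels.

## Known limitations

* Contrast tests ignore the covariance between compared estimates.
* Composite LD, not haplotype LD; no D′, no EM phasing.
* No multi-allelic sites, no sex-chromosome handling, no imputation,
  no cross-panel (between-gene) pairs.
* The FDR family definition is a configuration choice, not an inference.

## A worked run

```{r, eval = FALSE}
cfg <- sim_config(n_snps = 6, maf = 0.25, n_per_cohort = rep(4000, 4),
                  compg_effects = list(list(pair = c(2, 5),
                                            beta = c(Mm = 0, mM = 0, mm = 0.4))),
                  seed = 7)
cohorts <- generate_multi_cohort(cfg)
res <- run_full_analysis(cohorts, gene_label = "demo", out_dir = "demo_out")
summary(res)
subset(res$pair_levels, q < 0.05)
```
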