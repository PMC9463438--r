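---
title: "Decomposing socioeconomic and genomic influences on verbal ability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing socioeconomic and genomic influences on verbal ability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gnurture)
```

## The problem

Socioeconomic status (SES) and polygenic scores (PGS) both predict
cognitive outcomes, but their estimated effects contaminate each other.
Parents transmit half of their alleles to each child, and the same
parental genomes also shape the SES environment the child grows up in
("genetic nurture"). Consequently:

* a PGS coefficient estimated without SES controls is biased upward,
  because the score proxies not only direct genetic effects but also the
  genetically-influenced family environment;
* an SES coefficient estimated without genomic controls is biased
  upward, because part of the SES association is carried by the
  parental genomes rather than by the environment SES is meant to
  represent.

`gnurture` implements an accounting scheme that separates three
contributions to a two-wave verbal-ability phenotype in a
sibling-clustered cohort: the offspring genome, the genomic component
embedded in parental SES, and the environmental component of parental
SES. Because the study data this design targets are restricted-access,
the package ships a first-class synthetic-cohort generator with full
ground-truth bookkeeping, so every stage can be validated by parameter
recovery and closed-form oracles.

## The model

The phenotype model is a three-level Gaussian random-intercept model
over person-wave observations (waves 1 and 3):

$$Y_{tij} = \beta_0 + \mathbf{SES}_{ij}'B_1 + \mathbf{G}_{ij}'B_2 +
\mathbf{C}_{ij}'B_3 + \mu_j + \nu_{ij} + e_{tij},$$

with variance components $\sigma^2_u$ (family $j$), $\sigma^2_v$
(person $i$) and $\sigma^2_e$ (wave $t$, the residual). $\mathbf{G}$
holds the standardized polygenic scores, $\mathbf{C}$ demographics and
ancestry principal components. `fit_lmm()` estimates this by REML or ML
(lme4 under the hood), always reporting variance components on the
variance scale, the $-2\log L$, and a companion single-level OLS
$R^2$ — a multilevel model has no unique $R^2$, so the package adopts
the single-level convention and isolates it in `ols_r2()` where it can
be redefined. A conditional specification regresses the wave-3 score on
the wave-1 score with family random intercepts on the subsample
observed at both waves (`wave3_conditional_data()`).

Polygenic scores are plain weighted dosage sums
$PGS_i = \sum_j \beta_j X_{ij}$ over *all* SNPs in the weight file (no
thresholding), Z-standardized within a stratum with the sample
($n-1$) standard deviation. Dosage files use the PLINK `.raw` dialect;
when the counted allele differs from the weight file's effect allele
the dosage is reflected ($d \to 2-d$), missing entries are imputed to
$2p$, and strand-ambiguous (A/T, C/G) pairs are flagged with a warning
rather than resolved — the simulator never produces them.

### The decomposition

Writing $R^2_\text{full}$, $R^2_\text{SES+PC}$, $R^2_\text{PGS+PC}$
for the companion OLS $R^2$ of the three nested designs,
`build_ledger()` computes

* net-PGS incremental $R^2$ = $R^2_\text{full} - R^2_\text{SES+PC}$
  (offspring genome net of SES and stratification);
* SES incremental $R^2$ = $R^2_\text{full} - R^2_\text{PGS+PC}$, which
  still contains roughly half of the genomic component in parental SES;
* an upper bound for the genomic-in-SES contribution, set equal to the
  net-PGS increment: transmitted-allele effects are empirically about
  three times the non-transmitted ones, so the genomic component in
  parental SES should not out-explain the offspring genome itself. The
  bound is surfaced as its own field so users can substitute another.

The environmental-SES $R^2$ follows by the exact identity
$R^2_\text{env} = R^2_\text{SES incr} - \text{bound}$, and the total
genomic contribution is the sum of the net-PGS increment and the bound.

At the coefficient level, the x2 correction
(`envses_correction()`) is

$$\text{enviSES} = \text{ParentalSES} - 2 \times \text{ReducedSES},$$

where ReducedSES is the shrinkage of an SES coefficient once the
offspring PGS enters the model. The factor 2 encodes the Mendelian
fact that conditioning on the offspring genome can only remove the
transmitted half of the parental-genome signal. The rule presupposes
(i) the transmitted and non-transmitted score components have about the
same variance — guaranteed by Mendelian segregation and verified in the
simulator's truth record — and (ii) the measured score captures about
half of the relevant parental-genome signal. Under random mating and a
linear SES pathway the correction moves the SES estimate strictly
toward the true environmental effect whenever the PGS removes some but
not all of the confounding (the realistic regime); with a perfectly
measured score it overshoots symmetrically, and under assortative
mating or nonlinear SES formation no guarantee is claimed.

## The synthetic cohort generator

`simulate_cohort()` draws, per family: four phased parental haplotypes
at `n_snps` independent biallelic loci (allele frequencies uniform on
`allele_freq_range`; optional Balding–Nichols substructure via
`n_strata`/`fst`), Mendelian transmission masks per child (MZ co-twins
copy the first twin's masks; DZ twins and full siblings transmit
independently), the parental-SES latent
$S^* = \gamma (U_m + U_f) + \varepsilon_S$, SES indicators cut from
noisy copies of $S^*$ (parental education, income quintile, 16-category
occupations, reported sibship size, family structure, six tract
measures per wave), and the two-wave phenotype

$$Y_{tij} = \beta_0 + b_\text{child} Z(U_o) + c_\text{env} Z(S^*) +
\text{demographics} + \mu_j + \nu_{ij} + e_{tij}.$$

No linkage, dominance, epistasis or assortative mating is simulated:
the decomposition's algebra operates on aggregate scores, so
independent loci suffice, and those omissions delimit what passing
tests show about real data. True per-SNP weights are
Normal$(0, \tau^2/K)$, making the score variance K-invariant. The
analyst-visible weight files add per-SNP noise: the primary
(education-like) file with sd `gwas_noise_sd`, a secondary
(cognitive-ability-like) file with twice that, mimicking a pair of
correlated scores of unequal precision.

### Default parameters and why

Defaults were fixed once from a closed-form analysis of the implied
covariance matrix (see `implied_slopes()`), chosen so the simulated
regime reproduces the qualitative landscape the method was built for:

| parameter | default | rationale |
|---|---|---|
| `b_child` | 2.3 | per-SD PGS effect on a test-score scale (IQ-like units) |
| `c_env` | 3.1 | per-SD SES effect, comparable to published SES composites |
| `gamma` | 0.45 | with `var_ses_env = 0.55` gives PGS–SES correlation ~0.3 |
| `var_family/person/wave` | 30 / 25 / 40 | phenotype SD ~11 with fixed-effect $R^2$ in the 0.15–0.25 range |
| `gwas_noise_sd` | $\sqrt{2/3}\,\tau/\sqrt{K}$ | measured-score reliability 0.6, putting the net-PGS incremental $R^2$ in the small-percent regime of education/cognition scores |
| `sibship_mix` | 85/9/4/2% singleton/full-sib/DZ/MZ | a mostly-unrelated cohort with a genetically informative minority |
| `missing_rate` | 0.1 | typical SES item-nonresponse, handled by missing-category coding |

Under these defaults the population algebra gives a net-PGS incremental
$R^2$ near 2%, an SES incremental $R^2$ near 9%, and a genomic share
of the SES effect near 22% — and the paper-style bound assumption
(genomic-in-SES increment no larger than the net-PGS increment) holds,
which is exactly the condition under which the ledger's upper-bound
rule is conservative rather than wrong.

### Analytic oracles

With independent loci the transmitted half-score $T$ of a parent has
variance $v = \sum_k w_k^2 p_k(1-p_k)$ and is independent of the
non-transmitted half-score $NT$, so $\mathrm{Var}(T) =
\mathrm{Var}(NT)$, $\mathrm{Var}(U_o) = 2v$, $\mathrm{Cov}(U_o, S^*) =
2\gamma v$, and on standardized scales the single-predictor population
slopes are $c + b\rho$ (SES only) and $b + c\rho$ (true score only)
with $\rho = 2\gamma v / \sqrt{2v \,\mathrm{Var}(S^*)}$; a measured
score with correlation $a$ to the true score attenuates the latter to
$a(b + c\rho)$. The acceptance suite fits these slopes on a cohort of
60,000 persons in independent families — independence chosen because
the oracle concerns cross-sectional moments, and sibling clustering
only inflates the moment noise — and requires 2% agreement.

## Design choices worth knowing

* **Missing data.** Categorical SES predictors get an explicit,
  always-present `missing` level (`encode_categoricals()`), so the
  design schema is stable and no rows are lost; the continuous SES
  summary PC instead mean-substitutes within stratum, because a
  missing-category device has no analog for a composite score.
  Multiple imputation is out of scope.
* **SES summary PC inputs** are ordinal scores (education 1–3, income
  quintile, 11-level occupational prestige via the packaged editable
  lookup, sibship size, family-structure flag, neighborhood index)
  rather than indicator columns; the component is oriented so parental
  education loads positively and is standardized.
* **Neighborhood disadvantage** is the first PC of the six
  column-standardized tract measures, computed separately per wave,
  oriented so the poverty share loads positively, standardized to mean
  0 / sd 1 — hence invariant to affine rescaling of any input.
* **Estimation.** ML is enforced wherever fits feed an LRT; REML is
  the default otherwise. Non-convergence triggers up to 3 jittered
  restarts. Singular fixed-effect designs error naming the collinear
  columns; the pipeline pre-drops structurally empty indicator levels.
* **Sibling fixed effects** use family-demeaned least squares on
  person-mean responses, MZ pairs excluded (no within-pair genotype
  variance), with family-clustered sandwich standard errors.
* **Twin descriptive.** Falconer's $h^2 = 2(r_{MZ} - r_{DZ})$ with
  double-entry within-pair correlations of wave-standardized scores,
  truncated to [0, 1]; reported as a descriptive, not an estimate of
  the simulated architecture.
* **PC sign conventions.** All principal components fix their sign by
  the largest-magnitude-loading-positive rule (ancestry PCs) or a
  substantive orientation rule (poverty / education), making outputs
  reproducible across BLAS implementations.
* **Determinism.** Every stochastic element of a simulated study is a
  function of `seed`; `run_pipeline()` stamps artifacts with the
  config hash and rerunning a config reproduces them byte-for-byte.

## Problem sizes used in validation

The shipped test suite validates parameter recovery at 2,000 two-sib
families (fixed effects within 3 SE, variance components within 10%),
Mendelian bookkeeping at 5,000 persons (T/NT variance symmetry within
10%, parent–offspring dosage correlation at its theoretical 0.5, MZ
score correlation exactly 1), the covariance oracle at 60,000 persons
(2%), the null-confounding case (`gamma = 0`) over 50 replicates, and
the enviSES correction on a 6,000-family default-regime cohort, where
the ledger's environmental $R^2$ must fall within ±30% of the
truth-record semi-partial $R^2$ — the method's own authors would call
these rough estimates, and the band reflects that.

## Limitations

The upper-bound rule is an assumption, not an estimate; the package
surfaces the bound separately so sensitivity analyses can replace it.
The x2 correction is calibrated for a measured score capturing about
half the relevant parental-genome signal and degrades gracefully, not
provably, away from that regime. The simulator's SES indicators are
quantile cuts of one latent — adequate for exercising the coding and
PCA machinery, silent about multidimensional SES. And nothing here
estimates non-transmitted-allele effects directly; that requires
parental genotypes by design.
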