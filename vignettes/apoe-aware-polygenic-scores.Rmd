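---
title: "APOE-aware polygenic scores and longitudinal dementia models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{APOE-aware polygenic scores and longitudinal dementia models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adpgs)
```

## The problem

Alzheimer's disease has one overwhelming common-variant locus — the
APOE/TOMM40/APOC1 linkage-disequilibrium block on chromosome 19 — and a long
tail of small effects spread across the genome. A polygenic score (PGS) that
simply sums weighted variants over the whole genome mixes these two signals:
the handful of block variants carry effect sizes an order of magnitude larger
than anything else, yet even so they summarize the locus worse than the
ε4 haplotype itself, because ε4 is defined by the *joint* genotype at
rs429358 and rs7412 and no additive single-variant weighting captures it
fully. The analysis this package implements therefore (i) builds scores at a
grid of discovery p-value thresholds both with and without the APOE region,
(ii) measures ε4 directly as a diplotype-derived covariate, and (iii) relates
both to longitudinal dementia status in a repeated-measures logistic model.

`adpgs` implements that pipeline end to end — summary-statistics and dosage
ingestion, allele alignment, thresholded scoring with region excision,
diplotype calling, Langa–Weir cognition classification, panel assembly with
auditable exclusions, and GEE model fitting — plus a synthetic-cohort
generator with the statistical structure the analysis assumes, so every stage
is testable without access to restricted cohort data.

## Score construction

For individual $i$ the raw score at threshold $p_T$ is

$$\mathrm{PGS}_i(p_T) \;=\; \sum_{j\,:\,p_j < p_T} w_j \, d_{ij},$$

where $w_j$ is the discovery-GWAS log-odds weight for the effect allele of
variant $j$, $p_j$ its discovery p-value, and $d_{ij} \in [0,2]$ the dosage of
the counted allele after alignment. Conventions, each of which is a test
target:

* **Threshold membership is strict** ($p_j < p_T$); $p_T = 1$ means the
  all-variant score and keeps records with $p_j = 1$. The other common
  dialect ($p \le p_T$) differs only at ties but is worth stating.
* **No LD clumping or pruning** anywhere. The intended variant universe is a
  genotyping array's tag SNPs, already an LD-filtered set; a clumping stage
  is deliberately not provided.
* **Allele alignment**: a weight enters as $+\beta_j$ when the genotype's
  counted allele is the effect allele, as $-\beta_j$ when it is the other
  allele, and the variant is excluded (and reported) when the allele pair
  matches in neither orientation. Strand-ambiguous A/T and C/G pairs are
  aligned by identity like any other variant — appropriate for same-build
  array data — but they are counted in the alignment report and can be
  dropped with `drop_palindromic = TRUE`.
* **Missing dosages** are mean-imputed per variant at scoring time.
* **Region excision**: the APOE region is chr19:45,384,477–45,432,606 (build
  37), i.e. the TOMM40 start (45,394,477) minus 10 kb through the APOC1 stop
  (45,422,606) plus 10 kb, inclusive on both ends. `default_apoe_region()`
  exposes the flank as a parameter; coordinates are 1-based.
* **Standardization** uses the sample mean and SD of the analytic sample
  (the individuals surviving the panel exclusions), so every reported score
  has mean 0, SD 1 there; odds ratios are per SD. When a sensitivity
  analysis changes the sample (cohort exclusion), scores are re-standardized
  over the reduced sample.

A decomposition identity pins down an interpretation the source analysis
leaves open: at every threshold, the raw region-included score equals the
region-excluded score plus the score computed on region-only variants,
exactly, per individual. All region variants passing the threshold
contribute to the "with APOE" score, not just the two defining SNPs.

## APOE-ε4 calling

The isoform haplotypes are ε4 = (rs429358 C, rs7412 C), ε3 = (T, C),
ε2 = (T, T). Every unphased two-site genotype resolves to a unique diplotype
except the double heterozygote (C/T at both sites), which is consistent with
ε2/ε4 or ε1/ε3; it is assigned ε2/ε4, the standard convention given the
rarity of ε1 (the caller flags these calls `ambiguous_e2e4`). Genotypes that
would require an ε1 haplotype (e.g. hard calls of CC at rs429358 with TT at
rs7412) are flagged invalid rather than forced into a category. Imputed
dosages are hard-called within a ±0.1 band around 0/1/2 (configurable);
out-of-band dosages become flagged no-calls. The modeling indicators are two
dummies — any one ε4 copy, and two copies — never a linear allele count,
because the risk increment from the second copy is much larger than from
the first.

## Cognition classification and panel assembly

Langa–Weir cut points, by the wave's own respondent type: self-respondents
(0–27 scale) 0–6 dementia, 7–11 CIND, 12–27 normal; proxy respondents (0–11
scale) 6–11 dementia, 3–5 CIND, 0–2 normal. The analytic contrast is
dementia (1) versus normal cognition (0); CIND is excluded.

`build_panel()` applies the exclusion cascade in a fixed order — missing
cognition, then CIND, then missing stroke, then individuals left with no
observations — and returns exact counts for each step, satisfying
$m_\mathrm{input} = m_\mathrm{retained} + m_\mathrm{miss.cog} +
m_\mathrm{CIND} + m_\mathrm{miss.stroke}$. Exclusion is observation-level
first and individual-level second: an individual stays as long as one
dementia-or-normal observation with complete stroke data survives. "First
visit" in the descriptive table means each individual's earliest retained
wave.

## The repeated-measures model

Dementia status across waves is modeled marginally with generalized
estimating equations: binomial family, logit link, and a working
within-subject correlation (unstructured by default, with exchangeable and
independence available). Fixed covariates are sex, years of education and
five ancestry principal components; age, calendar year and stroke history
are time-varying; the ε4 indicators and one standardized PGS complete the
Table-2-style model, with optional PGS-by-ε4 product terms. Calendar year is
centered at the first panel year and entered per year — centering moves only
the intercept, so the per-year odds ratio is unaffected.

No GEE solver in the runtime environment fit this design, so the package
implements the estimator directly: Fisher scoring on
$\sum_i D_i' V_i^{-1} (y_i - \mu_i) = 0$ with
$V_i = \phi A_i^{1/2} R(\alpha) A_i^{1/2}$, moment re-estimation of $\phi$
and of $R$ between steps, and wave-rank indexing of $R$ so unequal visit
counts align each subject's occasions. The unstructured estimate of $R$ is
clamped to valid correlations and ridged toward independence if it loses
positive definiteness; a non-convergent unstructured fit falls back to
exchangeable with an explicit flag. The implementation is verified three
ways: single-wave independence fits reproduce the ordinary logistic MLE to
1e-6; coefficients and plain-sandwich SEs match an independent GEE
implementation (Python statsmodels) frozen into the test suite; and a
200-replicate parameter-recovery study confirms centered estimates with
nominal CI coverage.

**Standard errors.** Robust (sandwich) covariance is always reported. The
default is the Mancl–DeRouen bias-corrected sandwich rather than the plain
one: with rare covariates — two-copy ε4 carriers are ~2% of subjects — the
information for a term sits in a few dozen clusters, where the plain
sandwich is known to run small (in the recovery study its SEs averaged 84%
of the empirical SD for the two-copy term, giving 91% coverage; the
corrected sandwich restores 92–95%). The plain sandwich and the model-based
covariance remain available (`vcov(fit, bias_correction = FALSE)`,
`tidy(fit, robust = FALSE)`). Confidence intervals use the normal 1.96
multiplier; significance is two-sided at α = 0.05. Odds-ratio tables also
carry `se_factor = exp(se)`, the SE expressed as a multiplicative factor,
since published tables sometimes print that next to the OR.

## The synthetic cohort

`simulate_cohort()` generates the three inputs with the dependence structure
the analysis assumes. Defaults are chosen once to mirror the observed
conditions of a large population-based panel of older adults and are not
tuning knobs:

| parameter | default | what it emulates |
|---|---|---|
| `n_individuals`, `n_waves` | 2000, 5 | cohort with biennial visits from 2000 |
| `age_mean` (SD), floor | 63.3 (10.3), 50 | first-visit age distribution |
| `edu_mean` (SD) | 13.2 (2.5) | years of education |
| `male_prob` | 0.42 | 57.8% female sample |
| `apoe_hap_freqs` | (.08, .77, .15) | ~24% one-copy, ~2% two-copy carriers |
| `baseline_prev` | 0.036 | observation-level dementia rate |
| `effects` | log(1.08), log(2.1), log(4.4), log(1.15), log(1.13), log(0.76), log(1.12), log(3.36) | per-SD PGS, one/two ε4 copies, age/yr, male, education/yr, year, stroke |
| `cind_rate`, `miss_cognition_rate`, `miss_stroke_rate` | .100, .159, .0002 | sample-flow exclusion proportions |
| `stroke_baseline`, `stroke_hazard` | .043, .012 | baseline stroke and absorbing per-wave hazard |
| `ld_block_size`, `ld_rho` | 10, 0.3 | tag-SNP LD blocks |
| `within_subject_rho` | 0.5 | latent within-person outcome correlation |

Genotypes are drawn haplotype-wise: genome-wide blocks from a latent
Gaussian copula at `ld_rho`, and an APOE-like block from the isoform
frequencies under random mating, with neighboring block variants carrying
their alternate allele with probability 0.8 on ε4 haplotypes versus 0.1
otherwise. Summary statistics give a causal subset (2% of genome-wide
variants) effect sizes N(0, 0.08) with p-values below 1e-3, null variants
N(0, 0.02) with uniform p-values, and APOE-block variants large effects with
p < 1e-8 — reproducing the dominant association peak and making the
threshold grid meaningful. Effect/other alleles are emitted in random
orientation so allele alignment is always exercised.

**Outcomes are generated on the marginal scale.** The dementia indicator for
subject $i$ at wave $t$ is drawn by thresholding a subject-shared latent
Gaussian, $Y_{it} = 1\{\Phi(\sqrt{\rho}\,Z_i + \sqrt{1-\rho}\,\varepsilon_{it})
< p_{it}\}$ with $p_{it} = \mathrm{logit}^{-1}(\beta_0 + x_{it}'\beta)$.
This Gaussian-copula construction induces within-subject correlation while
leaving every marginal probability — hence every generating log odds ratio —
exact. The alternative, a conditional random-intercept model, attenuates the
marginal coefficients and would need an approximate numeric correction; the
copula makes the marginal recovery targets exact by construction, which is
why it was chosen. The intercept $\beta_0$ is calibrated numerically
(uniroot on the mean marginal probability over the realized covariates) to
hit `baseline_prev`. Cognition scores are back-generated uniformly within
the Langa–Weir band of the drawn class — the analysis uses only the class,
so the within-band distribution is immaterial — and CIND and missingness are
injected at the configured rates, independently of the outcome (MCAR).

**What the simulator does not emulate.** Realistic recombination maps and
allele-frequency spectra; imputation error at the two APOE SNPs (simulated
dosages are integers, so the hard-call band is only exercised by dedicated
tests); mortality selection and informative dropout — visits are complete
and missingness is MCAR, so the exclusion cascade is unbiased by
construction here while in real panels it need not be; genotyping batch or
ancestry structure (the five PCs are null covariates). Passing tests
therefore demonstrate the pipeline's correctness and the estimator's
frequentist calibration under the stated data-generating process, not
robustness to the selection processes of a real panel study. One visible
consequence: with ~1,000 simulated variants the APOE block dominates the
region-included scores at stringent thresholds, so ε4-residualizing those
scores changes them substantially (r ≈ 0.55 with the original), whereas on a
real array the block is a negligible share of the variant count and
residualized scores correlate above 0.97 with their originals. The
region-excluded scores behave like the real ones (r > 0.95 after
residualization) at any panel size.

## Problem sizes and numerical choices

* Recovery studies run 200 replicates of 2,000 subjects × 5 waves with a
  300-variant panel and no injected missingness: the generating PGS effect
  applies to the standardized score, so the variant count is irrelevant to
  recovery, and turning missingness off makes the study measure estimation
  rather than MCAR thinning (the exclusion cascade has its own exact tests).
* GEE scoring iterates to a 1e-8 max coefficient update with a 50-iteration
  cap; coefficients beyond ±30 or fitted probabilities at 0/1 raise a
  separation diagnostic instead of drifting.
* The unstructured working correlation needs its off-diagonal moments from
  pairs of occasions; entries are clamped to ±0.99 and the matrix ridged
  toward independence when its smallest eigenvalue drops below 1e-4.
* The degenerate inputs all error loudly rather than defaulting: zero usable
  variants in a score, zero-variance raw scores, pT outside (0, 1], region
  masks with start > stop, duplicate individual-wave rows, dosages outside
  [0, 2].
* Standardization is idempotent and its contract (|mean| < 1e-10,
  |sd − 1| < 1e-8) is asserted on every grid cell in the tests.

## Known limitations

* The GEE solver covers the binomial/logit marginal model this analysis
  needs; it is not a general-purpose GEE replacement (no other links or
  families, no user-supplied correlation structures).
* Survey weights, mixed-effects formulations, and survival-style models of
  dementia onset are out of scope, as are LD-aware scoring methods
  (clumping+thresholding pipelines, shrinkage estimators) and genotype QC.
* Variant matching between summary statistics and genotypes defaults to
  rs-ID equality with a chromosome:position fallback; no liftover between
  genome builds is attempted, and all coordinates are build 37.
* ε1 and other rare APOE isoforms are not called; family-based phasing is
  not supported.
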