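# adpgs

APOE-aware polygenic scores and repeated-measures dementia models.

`adpgs` is for epidemiologists and statistical geneticists who relate an
Alzheimer's disease polygenic score (PGS) to longitudinal dementia status in
population-based panel studies. Alzheimer's disease is dominated by one
locus — the APOE/TOMM40/APOC1 linkage-disequilibrium block on chromosome 19 —
so a genome-wide weighted sum both under-captures that locus and contaminates
the "polygenic background" signal. The package implements the comparison
that motivates treating the locus separately: scores at a grid of discovery
p-value thresholds, with and without the APOE region excised, modeled
alongside directly-measured APOE-ε4 carrier status.

## What it computes

**Scores.** For individual *i* at threshold *p<sub>T</sub>*,

> PGS<sub>i</sub>(p<sub>T</sub>) = Σ<sub>j : p\_j < p\_T</sub> w<sub>j</sub> d<sub>ij</sub>,

with discovery-GWAS weights *w<sub>j</sub>*, aligned counted-allele dosages
*d<sub>ij</sub>* ∈ [0, 2], strict threshold membership, no LD clumping or
pruning, and z-standardization over the analytic sample. Region-excised
scores first drop all variants in chr19:45,384,477–45,432,606 (build 37):
TOMM40 start − 10 kb through APOC1 stop + 10 kb, inclusive. The default grid
p<sub>T</sub> ∈ {0.001, 0.01, 0.05, 0.1, 0.3, 1.0} × {region in, region out}
yields 12 scores.

**APOE-ε4.** Diplotypes from rs429358/rs7412 (ε4 = C–C haplotype; the
unphased double heterozygote resolves to ε2/ε4), with one-copy and two-copy
indicator variables and a configurable hard-call band for imputed dosages.

**Cognition.** Langa–Weir classification (self: 0–6 dementia, 7–11 CIND,
12–27 normal; proxy: 6–11 / 3–5 / 0–2), a dementia-vs-normal panel with an
exactly accounted exclusion cascade (missing cognition → CIND → missing
stroke → empty individuals), and sex-stratified descriptive tables.

**Models.** Marginal logistic GEE (binomial, logit, unstructured working
correlation by default) with repeated measures on the individual, fixed
(sex, education, ancestry PCs) and time-varying (age, year, stroke)
covariates, ε4 indicators, one score per model, optional PGS×ε4 interaction
terms, and Mancl–DeRouen bias-corrected sandwich standard errors. The GEE
solver is implemented in the package and is verified against the ordinary
logistic MLE (single-wave case), an independent implementation, and a
parameter-recovery simulation study.

**Synthetic cohorts.** `simulate_cohort()` generates genotypes with LD
blocks and an APOE-like haplotype block, discovery summary statistics with a
dominant chr19 peak, and a longitudinal dementia process whose generating
log odds ratios are exactly marginal (subject-level Gaussian copula), so the
whole pipeline is testable without restricted cohort data.

## Worked example

```r
library(adpgs)

cfg  <- sim_config(n_individuals = 1000, n_variants = 500, n_waves = 4)
sim  <- simulate_cohort(cfg, seed = 7)

grid <- build_score_grid(sim$stats, sim$geno, thresholds = c(0.01, 1.0))
glance(grid)
#>      pT region_excluded n_variants_used raw_mean raw_sd n_individuals
#> 1  0.01 FALSE                        34   0.800   0.781          1000
#> 2  0.01 TRUE                         12  -0.0119  0.129          1000
#> 3  1    FALSE                       522   0.656   0.835          1000
#> 4  1    TRUE                        500  -0.156   0.320          1000

bp <- build_panel(sim$phenotypes)
bp$report
#>   m_input m_missing_cognition m_cind m_missing_stroke m_retained n_input
#> 1    4000                 692    341                0       2967    1000

panel <- join_scores(bp$panel, grid, sim$apoe)
res   <- run_model_grid(panel, score_cols = "pT0.01_noAPOE")
res[res$term %in% c("stroke", "one_e4", "two_e4", "PGS"),
    c("term", "OR", "robust_se", "ci_low", "ci_high", "p_value")]
#>   term      OR robust_se ci_low ci_high p_value
#> 1 stroke  3.56     0.415  1.58     8.04 0.00221
#> 2 one_e4  2.10     0.287  1.20     3.70 0.00963
#> 3 two_e4  4.62     0.619  1.37    15.5  0.0134
#> 4 PGS     1.16     0.133  0.895    1.51 0.258
```

Reading the output: each grid cell records how many variants entered the
score (12 variants survive p < 0.01 once the APOE region is excised, versus
34 with it) and the raw moments before z-standardization. The exclusion
report shows 4,000 contributed observations reduced to 2,967 after dropping
missing-cognition and CIND waves. The model table gives per-term odds ratios
for dementia versus normal cognition with bias-corrected robust SEs (log-odds
scale) and 95% CIs: here one ε4 copy roughly doubles the odds and two copies
nearly quintuple them — close to this cohort's generating values of 2.1 and
4.4 — while the region-free score at p<sub>T</sub> = 0.01 shows its small
per-SD effect (generating value 1.08) with a CI that spans 1 at this sample
size.

`run_pipeline()` wraps the whole chain (simulate or ingest → score →
call-ε4 → classify → fit) and writes scores, calls, the panel, the exclusion
report, descriptive and results tables, the score-correlation matrix, and a
run manifest; `inst/cli/adpgs.R` is a thin Rscript wrapper with flags for
thresholds, region override, working correlation, cohort exclusion and
ε4-residualized scores. Sensitivity analyses (cohort exclusion,
residualized-score grid, PGS-only and ε4-only models) are in
`run_sensitivity_suite()`; `plot_or_grid()` and `plot_score_by_e4()` give
the standard figures.

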