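#' Simulation configuration
#'
#' Defaults describe a cohort with the structure the analysis assumes:
#' biennial waves starting in 2000; baseline age 63.3 (SD 10.3, floored at
#' 50); 42% male; 13.2 (2.5) years of education; APOE haplotype frequencies
#' (e2, e3, e4) = (0.08, 0.77, 0.15), which give roughly 24% one-copy and 2%
#' two-copy carriers under random mating; observation-level dementia
#' prevalence 3.6%; and marginal effect sizes at the point estimates the
#' adjusted dementia models report (per-SD PGS OR 1.08, one-copy e4 OR 2.1,
#' two-copy OR 4.4, per-year age OR 1.15, year OR 1.12, stroke OR 3.36,
#' education OR 0.76, male OR 1.13). Missing-cognition, CIND and
#' missing-stroke rates default to the observed sample-flow proportions
#' (15.9%, 10.0%, 0.02% of contributed observations).
#'
#' @param ... overrides of any default field.
#' @return A `sim_config` list.
#' @export
sim_config <- function(...) {
  cfg <- list(
    n_individuals = 2000,
    n_variants = 1000,          # genome-wide variants outside the APOE block
    n_waves = 5,
    seed = NULL,
    maf_range = c(0.05, 0.5),
    ld_block_size = 10,
    ld_rho = 0.3,
    apoe_hap_freqs = c(e2 = 0.08, e3 = 0.77, e4 = 0.15),
    n_apoe_block_variants = 20, # besides rs429358/rs7412
    apoe_ld_hi = 0.8,           # allele prob on an e4 haplotype for block variants
    apoe_ld_lo = 0.1,
    causal_fraction = 0.02,
    causal_beta_sd = 0.08,
    null_beta_sd = 0.02,
    apoe_beta_mean = 0.35,
    effects = c(pgs = log(1.08), one_e4 = log(2.1), two_e4 = log(4.4),
                age = log(1.15), sex = log(1.13), education = log(0.76),
                year = log(1.12), stroke = log(3.36)),
    baseline_prev = 0.036,
    within_subject_rho = 0.5,
    pgs_threshold = 0.01,       # threshold of the generating (region-free) score
    start_year = 2000, wave_spacing = 2,
    age_mean = 63.3, age_sd = 10.3, age_min = 50, age_max = 95,
    edu_mean = 13.2, edu_sd = 2.5,
    male_prob = 0.42,
    stroke_baseline = 0.043, stroke_hazard = 0.012,
    proxy_rate = 0.05,
    cind_rate = 0.100,
    miss_cognition_rate = 0.159,
    miss_stroke_rate = 0.0002
  )
  cfg <- modifyList(cfg, list(...))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  probs <- c(cfg$male_prob, cfg$stroke_baseline, cfg$stroke_hazard,
             cfg$proxy_rate, cfg$cind_rate, cfg$miss_cognition_rate,
             cfg$miss_stroke_rate, cfg$baseline_prev, cfg$causal_fraction,
             cfg$within_subject_rho, cfg$maf_range)
  if (any(probs < 0 | probs > 1)) abort("sim_config: probabilities must be in [0, 1]")
  if (abs(sum(cfg$apoe_hap_freqs) - 1) > 1e-8)
    abort("sim_config: APOE haplotype frequencies must sum to 1")
  if (cfg$n_individuals < 2 || cfg$n_waves < 1) abort("sim_config: invalid sizes")
  invisible(cfg)
}

#' Read a simulation configuration from YAML
#'
#' @param path YAML file whose keys override [sim_config()] defaults.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$apoe_hap_freqs)) y$apoe_hap_freqs <- unlist(y$apoe_hap_freqs)
  if (!is.null(y$effects)) y$effects <- unlist(y$effects)
  if (!is.null(y$maf_range)) y$maf_range <- as.numeric(unlist(y$maf_range))
  do.call(sim_config, y)
}

#' Simulate a genotype-dosage matrix
#'
#' Genome-wide variants are drawn haplotype-wise with allele frequencies
#' uniform on `maf_range`, with within-block linkage disequilibrium induced
#' by a latent Gaussian copula at correlation `ld_rho` (block size
#' `ld_block_size`). An APOE-like block on chromosome 19 inside the default
#' exclusion region is generated haplotype-wise from the isoform frequencies,
#' so rs429358/rs7412 follow the e2/e3/e4 system under random mating, and the
#' remaining block variants carry their alternate allele with probability
#' `apoe_ld_hi` on e4 haplotypes versus `apoe_ld_lo` otherwise (strong LD
#' with e4 dosage).
#'
#' @param config a [sim_config()].
#' @param seed optional seed set before drawing.
#' @return A [geno_matrix()] whose last columns are the APOE block
#'   (rs429358, rs7412 and the block variants), plus attribute
#'   `apoe_haplotypes`: the true per-individual isoform pair.
#' @export
simulate_genotypes <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_individuals
  ids <- sprintf("ind%05d", seq_len(n))

  # genome-wide blocks via latent Gaussian copula per haplotype
  k <- config$n_variants
  maf <- runif(k, config$maf_range[1], config$maf_range[2])
  blocks <- split(seq_len(k), ceiling(seq_len(k) / config$ld_block_size))
  hap_draw <- function() {
    h <- matrix(0L, n, k)
    for (ix in blocks) {
      shared <- rnorm(n)
      z <- sqrt(config$ld_rho) * shared +
        sqrt(1 - config$ld_rho) * matrix(rnorm(n * length(ix)), n)
      h[, ix] <- (z < matrix(qnorm(maf[ix]), n, length(ix), byrow = TRUE)) + 0L
    }
    h
  }
  dos_gw <- hap_draw() + hap_draw()

  # chromosome/position layout: spread blocks over chr 1-18, 20-22
  chroms <- rep(rep(c(1:18, 20:22), length.out = length(blocks)), lengths(blocks))
  pos <- unlist(lapply(lengths(blocks), function(m) sort(sample.int(5e7, m))))
  pair <- replicate(k, sample(c("A", "C", "G", "T"), 2))
  gw_variants <- tibble(
    variant_id = sprintf("rs9%06d", seq_len(k)),
    chromosome = as.character(chroms), position = as.integer(pos),
    counted_allele = pair[1, ], alt_allele = pair[2, ]
  )

  # APOE block: haplotype isoforms, then the two defining SNPs + LD partners
  f <- config$apoe_hap_freqs
  hap <- matrix(sample(names(f), 2 * n, replace = TRUE, prob = f), n, 2)
  e4h <- hap == "e4"
  d429358 <- rowSums(e4h)                 # C allele count at rs429358
  d7412 <- rowSums(hap != "e2")           # C allele count at rs7412
  m <- config$n_apoe_block_variants
  p_blk <- ifelse(e4h, config$apoe_ld_hi, config$apoe_ld_lo)
  dos_blk <- matrix(0L, n, m)
  for (j in seq_len(m))
    dos_blk[, j] <- rbinom(n, 1, p_blk[, 1]) + rbinom(n, 1, p_blk[, 2])
  region <- default_apoe_region()
  blk_pos <- sort(sample(seq(region$start, region$stop), m + 2))
  apoe_variants <- tibble(
    variant_id = c("rs429358", "rs7412", sprintf("rs19%05d", seq_len(m))),
    chromosome = "19",
    position = as.integer(c(blk_pos[1], blk_pos[2], blk_pos[-(1:2)])),
    counted_allele = c("C", "C", rep("A", m)),
    alt_allele = c("T", "T", rep("G", m))
  )

  dosages <- cbind(dos_gw, d429358, d7412, dos_blk)
  rownames(dosages) <- ids
  out <- geno_matrix(dosages, bind_rows(gw_variants, apoe_variants))
  attr(out, "apoe_haplotypes") <- hap
  out
}

#' Simulate discovery-GWAS summary statistics for a genotype set
#'
#' A random causal fraction of the genome-wide variants receives effect sizes
#' N(0, `causal_beta_sd`) and discovery p-values below 0.001; the remainder
#' get small N(0, `null_beta_sd`) effects with uniform p-values. APOE-block
#' variants (including rs429358/rs7412) receive large effects and p-values
#' below 1e-8, emulating the dominant association peak at the locus. Effect
#' and other alleles are emitted in random orientation relative to the
#' genotype's counted allele, so allele alignment is always exercised.
#'
#' @param config a [sim_config()].
#' @param geno the [simulate_genotypes()] output.
#' @param seed optional seed.
#' @return A summary-statistics tibble with attribute `causal_ids`.
#' @export
simulate_summary_stats <- function(config, geno, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  v <- geno$variants
  in_blk <- in_region(v, default_apoe_region())
  k <- nrow(v)
  beta <- rnorm(k, 0, config$null_beta_sd)
  p <- runif(k)
  n_causal <- round(config$causal_fraction * sum(!in_blk))
  causal <- sample(which(!in_blk), n_causal)
  beta[causal] <- rnorm(n_causal, 0, config$causal_beta_sd)
  p[causal] <- 10^(-runif(n_causal, 3.2, 10))
  beta[in_blk] <- rnorm(sum(in_blk), config$apoe_beta_mean, 0.05) *
    sample(c(-1, 1), sum(in_blk), replace = TRUE)
  p[in_blk] <- 10^(-runif(sum(in_blk), 8.5, 40))

  flip <- runif(k) < 0.5
  out <- tibble(
    variant_id = v$variant_id,
    chromosome = v$chromosome,
    position = v$position,
    effect_allele = ifelse(flip, v$alt_allele, v$counted_allele),
    other_allele = ifelse(flip, v$counted_allele, v$alt_allele),
    beta = ifelse(flip, -beta, beta),
    p_value = p
  )
  attr(out, "causal_ids") <- v$variant_id[causal]
  out
}

#' Simulate a longitudinal phenotype table
#'
#' Draws fixed covariates (sex, education, baseline age and hence birth
#' cohort, five null ancestry PCs), evolves stroke as an absorbing per-wave
#' hazard, and generates the dementia indicator from the marginal logistic
#' model \eqn{logit P(Y_{it}=1) = \beta_0 + x_{it}'\beta} at the configured
#' effect sizes, with \eqn{\beta_0} calibrated so the average marginal
#' probability equals `baseline_prev`. Within-subject dependence is induced
#' by a subject-level Gaussian copula (a shared latent normal with weight
#' `within_subject_rho`), which leaves every marginal probability — and hence
#' every generating logOR — exact. Cognition scores are then back-generated
#' uniformly within the Langa-Weir band of the drawn class (dementia/normal,
#' with CIND injected at `cind_rate`), and cognition/stroke missingness is
#' injected at the configured rates.
#'
#' @param config a [sim_config()].
#' @param pgs standardized per-individual score: a `pgs_result` tibble or a
#'   named numeric vector.
#' @param apoe APOE call tibble with `one_e4`, `two_e4`.
#' @param seed optional seed.
#' @return Phenotype tibble (one row per individual-wave) with attribute
#'   `true_intercept`.
#' @export
simulate_phenotypes <- function(config, pgs, apoe, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (inherits(pgs, "data.frame")) pgs <- setNames(pgs$score, pgs$individual_id)
  ids <- names(pgs)
  n <- length(ids)
  tt <- config$n_waves
  ef <- config$effects

  sex <- rbinom(n, 1, config$male_prob)
  education <- pmin(pmax(round(rnorm(n, config$edu_mean, config$edu_sd)), 0), 17)
  age0 <- pmin(pmax(round(rnorm(n, config$age_mean, config$age_sd)),
                    config$age_min), config$age_max)
  birth <- config$start_year - age0
  birth_cohort <- cut(birth, c(-Inf, 1923, 1930, 1941, 1947, 1953, Inf),
                      labels = c("AHEAD", "CODA", "HRS", "WB", "EBB", "MBB"))
  pcs <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("PC", 1:5)))
  j <- match(ids, apoe$individual_id)
  one_e4 <- apoe$one_e4[j]; two_e4 <- apoe$two_e4[j]
  one_e4[is.na(one_e4)] <- 0L; two_e4[is.na(two_e4)] <- 0L

  # long layout: individual-major, waves within individual
  wave <- rep(seq_len(tt) - 1L, times = n)
  idx <- rep(seq_len(n), each = tt)
  year <- config$start_year + config$wave_spacing * wave
  age <- age0[idx] + config$wave_spacing * wave

  stroke <- integer(n * tt)
  s <- rbinom(n, 1, config$stroke_baseline)
  for (w in seq_len(tt)) {
    if (w > 1) s <- pmax(s, rbinom(n, 1, config$stroke_hazard))
    stroke[wave == (w - 1L)] <- s
  }

  lp <- ef[["age"]] * (age - mean(age)) +
    ef[["sex"]] * sex[idx] +
    ef[["education"]] * (education[idx] - mean(education)) +
    ef[["year"]] * (year - config$start_year) +
    ef[["stroke"]] * stroke +
    ef[["one_e4"]] * one_e4[idx] + ef[["two_e4"]] * two_e4[idx] +
    ef[["pgs"]] * pgs[idx]
  b0 <- calibrate_intercept(lp, config$baseline_prev)
  p_marg <- plogis(b0 + lp)

  rho <- config$within_subject_rho
  z_subj <- rnorm(n)
  u <- pnorm(sqrt(rho) * z_subj[idx] + sqrt(1 - rho) * rnorm(n * tt))
  dementia <- as.integer(u < p_marg)

  respondent_type <- ifelse(runif(n * tt) < config$proxy_rate, "proxy", "self")
  class <- ifelse(runif(n * tt) < config$cind_rate, "CIND",
                  ifelse(dementia == 1, "dementia", "normal"))
  cognition_score <- draw_score_in_band(class, respondent_type)
  cognition_score[runif(n * tt) < config$miss_cognition_rate] <- NA_integer_
  stroke[runif(n * tt) < config$miss_stroke_rate] <- NA_integer_

  out <- tibble(
    individual_id = ids[idx], wave_year = year,
    cognition_score = cognition_score, respondent_type = respondent_type,
    age = age, sex = sex[idx], education = education[idx],
    birth_cohort = as.character(birth_cohort)[idx], stroke = stroke
  )
  out <- bind_cols(out, as_tibble(pcs[idx, , drop = FALSE]))
  attr(out, "true_intercept") <- b0
  out
}

# shift the linear predictor so the mean marginal probability hits the target
calibrate_intercept <- function(lp, target) {
  stats::uniroot(function(b0) mean(plogis(b0 + lp)) - target,
                 lower = -30, upper = 30, tol = 1e-10)$root
}

bands <- list(
  self = list(dementia = c(0L, 6L), CIND = c(7L, 11L), normal = c(12L, 27L)),
  proxy = list(dementia = c(6L, 11L), CIND = c(3L, 5L), normal = c(0L, 2L))
)

draw_score_in_band <- function(class, respondent_type) {
  m <- length(class)
  out <- integer(m)
  for (rt in c("self", "proxy")) for (cls in c("dementia", "CIND", "normal")) {
    sel <- respondent_type == rt & class == cls
    if (any(sel)) {
      b <- bands[[rt]][[cls]]
      out[sel] <- sample(seq(b[1], b[2]), sum(sel), replace = TRUE)
    }
  }
  out
}

#' Simulate a complete analysis-ready cohort
#'
#' Runs the full generative chain: genotypes, summary statistics, APOE calls
#' from the simulated rs429358/rs7412 dosages, the generating polygenic score
#' (region-excluded, at `pgs_threshold`), and the longitudinal phenotype
#' table. A single seed fixes the whole chain.
#'
#' @param config a [sim_config()].
#' @param seed seed for the full chain (defaults to `config$seed`).
#' @return List with `geno`, `stats`, `apoe`, `true_pgs` (a `pgs_result`),
#'   `phenotypes`, `config`.
#' @export
simulate_cohort <- function(config = sim_config(), seed = config$seed) {
  if (!is.null(seed)) set.seed(seed)
  geno <- simulate_genotypes(config)
  stats <- simulate_summary_stats(config, geno)
  apoe <- call_apoe(geno)
  ss_out <- apply_region_mask(stats, default_apoe_region())
  w <- align_alleles(filter_by_threshold(ss_out, config$pgs_threshold), geno)
  if (nrow(w$weights) == 0) {
    # tiny variant panels may leave the threshold empty; fall back to the
    # all-variant region-free score as the generating PGS
    w <- align_alleles(ss_out, geno)
  }
  true_pgs <- standardize_score(compute_score(geno, w$weights),
                                pT = config$pgs_threshold, region_excluded = TRUE)
  phenotypes <- simulate_phenotypes(config, true_pgs, apoe)
  list(geno = geno, stats = stats, apoe = apoe, true_pgs = true_pgs,
       phenotypes = phenotypes, config = config)
}
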