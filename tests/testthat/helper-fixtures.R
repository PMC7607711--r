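# Small in-code fixtures shared across test files.

toy_sumstats <- function() {
  tibble::tibble(
    variant_id = c("rs1", "rs2", "rs3", "rs19a", "rs19b"),
    chromosome = c("1", "2", "3", "19", "19"),
    position = c(100L, 200L, 300L, 45400000L, 45432607L),
    effect_allele = c("A", "A", "C", "C", "G"),
    other_allele = c("G", "G", "T", "T", "A"),
    beta = c(0.3, -0.2, 0.5, 0.8, 0.1),
    p_value = c(0.005, 0.02, 0.5, 1e-10, 0.04)
  )
}

toy_geno <- function() {
  d <- rbind(c(0, 1, 2, 1, 0), c(2, 2, 0, 0, 1))
  rownames(d) <- c("i1", "i2")
  adpgs::geno_matrix(d, tibble::tibble(
    variant_id = c("rs1", "rs2", "rs3", "rs19a", "rs19b"),
    chromosome = c("1", "2", "3", "19", "19"),
    position = c(100L, 200L, 300L, 45400000L, 45432607L),
    counted_allele = c("A", "G", "C", "C", "G"),
    alt_allele = c("G", "A", "T", "T", "A")
  ))
}

# deterministic GEE test-bed: subject-level and time-varying covariates,
# outcome with a conditional random intercept (any within-subject dependence
# will do for solver checks)
gee_testbed <- function(n = 60, tt = 4, seed = 7, sigma_b = 0.8) {
  set.seed(seed)
  id <- rep(sprintf("s%02d", seq_len(n)), each = tt)
  x1 <- rep(rnorm(n), each = tt)
  x2 <- rnorm(n * tt)
  b <- rep(rnorm(n, 0, sigma_b), each = tt)
  y <- rbinom(n * tt, 1, plogis(-0.5 + 0.6 * x1 - 0.4 * x2 + b))
  tibble::tibble(individual_id = id, wave_year = rep(seq_len(tt), n),
                 y = y, x1 = x1, x2 = x2)
}

quiet_cohort <- function(cfg, seed) {
  suppressMessages(adpgs::simulate_cohort(cfg, seed = seed))
}

small_sim_config <- function(...) {
  args <- utils::modifyList(
    list(n_individuals = 300, n_variants = 120, n_waves = 3,
         n_apoe_block_variants = 8),
    list(...))
  do.call(adpgs::sim_config, args)
}

# 5 individuals x 3 waves; hand-counted: 2 missing-cognition, 3 CIND,
# 1 missing-stroke; individual E loses all three waves
panel_fixture <- function() {
  tibble::tibble(
    individual_id = rep(c("A", "B", "C", "D", "E"), each = 3),
    wave_year = rep(c(2000, 2002, 2004), 5),
    cognition_score = c(
      15, NA, 20,    # A: one missing-cognition
      5, 14, 13,     # B: dementia then normal
      22, 25, 13,    # C: all normal (one missing stroke below)
      18, NA, 16,    # D: one missing-cognition
      8, 9, 10       # E: all CIND -> individual removed
    ),
    respondent_type = "self",
    age = rep(c(60, 62, 64), 5) + rep(0:4, each = 3),
    sex = rep(c(1, 0, 0, 1, 0), each = 3),
    education = rep(c(12, 16, 13, 10, 14), each = 3),
    birth_cohort = rep(c("HRS", "HRS", "WB", "AHEAD", "CODA"), each = 3),
    stroke = c(0, 0, 0,  0, 0, 0,  NA, 0, 1,  0, 0, 0,  0, 0, 0)
  )
}

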