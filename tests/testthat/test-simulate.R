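test_that("the full simulation chain is deterministic under a fixed seed", {
  cfg <- small_sim_config()
  a <- quiet_cohort(cfg, seed = 101)
  b <- quiet_cohort(cfg, seed = 101)
  expect_identical(a$geno$dosages, b$geno$dosages)
  expect_identical(a$stats, b$stats)
  expect_identical(a$phenotypes, b$phenotypes)
  expect_identical(a$true_pgs$score, b$true_pgs$score)
  c <- quiet_cohort(cfg, seed = 102)
  expect_false(identical(a$phenotypes$cognition_score, c$phenotypes$cognition_score))
})

test_that("config validation rejects impossible settings", {
  expect_error(sim_config(cind_rate = 1.4), "probabilities")
  expect_error(sim_config(apoe_hap_freqs = c(e2 = 0.5, e3 = 0.4, e4 = 0.3)),
               "sum to 1")
  expect_error(sim_config(n_individuals = 1), "sizes")
})

test_that("YAML configs override defaults field by field", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_individuals: 50", "n_waves: 2",
               "apoe_hap_freqs:", "  e2: 0.1", "  e3: 0.7", "  e4: 0.2"), path)
  cfg <- read_sim_config(path)
  expect_equal(cfg$n_individuals, 50)
  expect_equal(cfg$apoe_hap_freqs[["e4"]], 0.2)
  expect_equal(cfg$n_variants, sim_config()$n_variants)  # untouched default
})

test_that("LD blocks induce within-block correlation that vanishes at rho = 0", {
  cfg0 <- sim_config(n_individuals = 1500, n_variants = 40, n_waves = 1,
                     ld_block_size = 10, ld_rho = 0)
  g0 <- simulate_genotypes(cfg0, seed = 51)
  cors0 <- cor(g0$dosages[, 1:10])
  off0 <- cors0[upper.tri(cors0)]
  expect_lt(abs(mean(off0)), 0.02)

  cfg1 <- sim_config(n_individuals = 1500, n_variants = 40, n_waves = 1,
                     ld_block_size = 10, ld_rho = 0.6)
  g1 <- simulate_genotypes(cfg1, seed = 51)
  within <- cor(g1$dosages[, 1:10])
  between <- cor(g1$dosages[, 1:10], g1$dosages[, 11:20])
  expect_gt(mean(within[upper.tri(within)]), 0.15)
  expect_lt(abs(mean(between)), 0.03)
})

test_that("APOE-block variants sit inside the default mask and tag the e4 haplotype", {
  cfg <- small_sim_config()
  g <- simulate_genotypes(cfg, seed = 52)
  blk <- adpgs:::in_region(g$variants, default_apoe_region())
  expect_equal(sum(blk), 2 + cfg$n_apoe_block_variants)
  expect_true(all(c("rs429358", "rs7412") %in% g$variants$variant_id[blk]))
  e4_dosage <- g$dosages[, "rs429358"]
  partner <- g$dosages[, g$variants$variant_id[blk][3]]
  expect_gt(cor(e4_dosage, partner), 0.3)  # LD with the e4-defining allele
})

test_that("summary statistics concentrate causal and APOE-block p-values below the grid", {
  cfg <- small_sim_config(causal_fraction = 0.05)
  g <- simulate_genotypes(cfg, seed = 53)
  ss <- simulate_summary_stats(cfg, g, seed = 54)
  causal <- attr(ss, "causal_ids")
  expect_equal(length(causal), round(0.05 * cfg$n_variants))
  kept <- filter_by_threshold(ss, 0.01)
  expect_true(all(causal %in% kept$variant_id))
  blk <- adpgs:::in_region(ss, default_apoe_region())
  expect_true(all(ss$p_value[blk] < 1e-8))
  # region-in vs region-out scores must differ at every threshold
  grid <- build_score_grid(ss, g, thresholds = c(0.001, 0.01, 1.0))
  for (pt in c("pT0.001", "pT0.01", "pT1")) {
    expect_gt(max(abs(grid[[paste0(pt, "_withAPOE")]]$score -
                        grid[[paste0(pt, "_noAPOE")]]$score)), 1e-6)
  }
})

test_that("a null outcome model hits the target prevalence", {
  cfg <- sim_config(n_individuals = 4000, n_variants = 20, n_waves = 3,
                    n_apoe_block_variants = 2,
                    effects = setNames(rep(0, 8), names(sim_config()$effects)),
                    baseline_prev = 0.05,
                    cind_rate = 0, miss_cognition_rate = 0, miss_stroke_rate = 0)
  sim <- quiet_cohort(cfg, seed = 55)
  bp <- build_panel(sim$phenotypes)
  rate <- mean(bp$panel$dementia)
  n <- nrow(bp$panel)
  # within-subject correlation inflates the variance of the rate; bound with
  # the cluster-level (conservative) standard error
  se <- sqrt(0.05 * 0.95 / cfg$n_individuals)
  expect_lt(abs(rate - 0.05), 3 * se)
})

test_that("marginal effect sizes are preserved: crude odds ratio for two e4 copies", {
  eff <- setNames(rep(0, 8), names(sim_config()$effects))
  eff[["two_e4"]] <- log(4)
  cfg <- sim_config(n_individuals = 12000, n_variants = 20, n_waves = 1,
                    n_apoe_block_variants = 2, effects = eff,
                    baseline_prev = 0.08,
                    cind_rate = 0, miss_cognition_rate = 0, miss_stroke_rate = 0)
  sim <- quiet_cohort(cfg, seed = 56)
  bp <- build_panel(sim$phenotypes)
  p <- join_scores(bp$panel, NULL, sim$apoe)
  tab <- table(two_e4 = p$two_e4, dementia = p$dementia)
  crude_or <- (tab["1", "1"] * tab["0", "0"]) / (tab["1", "0"] * tab["0", "1"])
  expect_lt(abs(log(crude_or) - log(4)), 0.4)
})

test_that("back-generated cognition scores land in the intended Langa-Weir band", {
  cfg <- small_sim_config(cind_rate = 0.2, miss_cognition_rate = 0)
  sim <- quiet_cohort(cfg, seed = 57)
  ph <- sim$phenotypes
  cls <- classify_cognition(ph$cognition_score, ph$respondent_type)
  expect_setequal(unique(cls), c("dementia", "CIND", "normal"))
  expect_gt(mean(cls == "CIND"), 0.1)  # injected CIND present
  expect_true(all(ph$cognition_score[ph$respondent_type == "proxy"] <= 11))
})

test_that("stroke is absorbing across waves", {
  cfg <- small_sim_config(miss_stroke_rate = 0)
  sim <- quiet_cohort(cfg, seed = 58)
  drops <- sim$phenotypes |>
    dplyr::arrange(individual_id, wave_year) |>
    dplyr::group_by(individual_id) |>
    dplyr::summarise(nondecreasing = !is.unsorted(stroke))
  expect_true(all(drops$nondecreasing))
})
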