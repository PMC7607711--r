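test_that("default APOE exclusion region is the TOMM40-10kb / APOC1+10kb block", {
  r <- default_apoe_region()
  expect_equal(r$chromosome, "19")
  expect_equal(r$start, 45384477L)
  expect_equal(r$stop, 45432606L)
  r0 <- default_apoe_region(flank = 0)
  expect_equal(c(r0$start, r0$stop), c(45394477L, 45422606L))
  expect_error(default_apoe_region(flank = -2e7), "start > stop")
})

test_that("threshold filtering is strict with pT = 1 meaning all variants", {
  ss <- tibble::tibble(variant_id = c("a", "b", "c"), chromosome = "1",
                       position = 1:3, effect_allele = "A", other_allele = "G",
                       beta = 0.1, p_value = c(0.005, 0.02, 0.5))
  expect_equal(filter_by_threshold(ss, 0.01)$variant_id, "a")
  expect_equal(filter_by_threshold(ss, 0.02)$variant_id, "a")  # strict <
  expect_equal(nrow(filter_by_threshold(ss, 1.0)), 3)
  ss$p_value[3] <- 1.0
  expect_equal(nrow(filter_by_threshold(ss, 1.0)), 3)          # p = 1 kept at pT = 1
  expect_error(filter_by_threshold(ss, 0), "in \\(0, 1\\]")
  expect_error(filter_by_threshold(ss, 1.5), "in \\(0, 1\\]")
})

test_that("region mask is inclusive on both ends and chromosome-specific", {
  mk <- function(chrom, pos) tibble::tibble(
    variant_id = paste0(chrom, ":", pos), chromosome = chrom, position = pos,
    effect_allele = "A", other_allele = "G", beta = 0.1, p_value = 0.5)
  ss <- dplyr::bind_rows(mk("19", 45384477L), mk("19", 45384476L),
                         mk("19", 45432606L), mk("19", 45432607L),
                         mk("18", 45400000L), mk("chr19", 45400000L))
  out <- apply_region_mask(ss, default_apoe_region())
  expect_setequal(out$variant_id,
                  c("19:45384476", "19:45432607", "18:45400000"))
})

test_that("raw scores equal the weighted dosage sum, with mean imputation", {
  g <- toy_geno()
  w1 <- tibble::tibble(variant_id = "rs1", weight = 0.5)
  s1 <- compute_score(subset_variants(g, "rs1"), w1)
  expect_equal(unname(s1$scores), c(0 * 0.5, 2 * 0.5))

  w0 <- tibble::tibble(variant_id = c("rs1", "rs2"), weight = c(0, 0))
  expect_equal(unname(compute_score(g, w0)$scores), c(0, 0))

  w <- tibble::tibble(variant_id = c("rs1", "rs2", "rs3"),
                      weight = c(0.1, -0.2, 0.4))
  s <- compute_score(g, w)
  expect_equal(unname(s$scores), c(0.6, -0.2))
  expect_equal(s$n_variants_used, 3L)

  expect_error(compute_score(g, tibble::tibble(variant_id = "nope", weight = 1)),
               "no usable variants")
})

test_that("scoring matches a brute-force double loop on random instances", {
  set.seed(42)
  for (rep in 1:5) {
    n <- sample(2:10, 1); k <- sample(1:10, 1)
    d <- matrix(runif(n * k, 0, 2), n, k,
                dimnames = list(paste0("i", 1:n), NULL))
    d[runif(n * k) < 0.15] <- NA
    v <- tibble::tibble(variant_id = paste0("v", 1:k), chromosome = "1",
                        position = 1:k, counted_allele = "A", alt_allele = "G")
    g <- geno_matrix(d, v)
    w <- tibble::tibble(variant_id = v$variant_id, weight = rnorm(k))
    got <- compute_score(g, w)$scores
    # oracle: explicit double loop with per-variant mean imputation
    want <- numeric(n)
    for (i in 1:n) for (j in 1:k) {
      dij <- d[i, j]
      if (is.na(dij)) dij <- mean(d[, j], na.rm = TRUE)
      if (is.nan(dij)) dij <- 0
      want[i] <- want[i] + w$weight[j] * dij
    }
    expect_equal(unname(got), want, tolerance = 1e-12)
  }
})

test_that("standardization yields exact z-scores and rejects degenerate input", {
  z <- standardize_score(setNames(c(1, 2, 3), c("a", "b", "c")))
  expect_equal(mean(z$score), 0, tolerance = 1e-12)
  expect_equal(sd(z$score), 1, tolerance = 1e-12)
  expect_error(standardize_score(setNames(rep(2, 3), letters[1:3])), "zero variance")
  expect_error(standardize_score(setNames(1, "a")), "at least 2")
  z2 <- standardize_score(setNames(z$score, z$individual_id))
  expect_equal(z2$score, z$score, tolerance = 1e-12)  # idempotent
})

test_that("score grid covers thresholds x region states with monotone variant counts", {
  cfg <- small_sim_config()
  sim <- quiet_cohort(cfg, seed = 5)
  grid <- build_score_grid(sim$stats, sim$geno)
  expect_length(grid, 12)
  meta <- glance(grid)
  expect_true(all(abs(purrr::map_dbl(grid, ~ mean(.x$score))) < 1e-10))
  expect_true(all(abs(purrr::map_dbl(grid, ~ sd(.x$score)) - 1) < 1e-8))
  for (rx in c(TRUE, FALSE)) {
    nv <- meta$n_variants_used[meta$region_excluded == rx][order(meta$pT[meta$region_excluded == rx])]
    expect_true(all(diff(nv) >= 0))
  }
  # variants used at pT1 are a subset of those at pT2 >= pT1 (monotone inclusion)
  al <- align_alleles(sim$stats, sim$geno)$weights
  used <- function(pt) al$variant_id[al$p_value < pt]
  expect_true(all(used(0.01) %in% used(0.3)))
})

test_that("region-in raw score decomposes exactly into region-out plus region-only", {
  cfg <- small_sim_config()
  sim <- quiet_cohort(cfg, seed = 6)
  al <- align_alleles(sim$stats, sim$geno)$weights
  mask <- default_apoe_region()
  for (pt in c(0.001, 0.05, 1.0)) {
    w <- if (pt == 1) al else al[al$p_value < pt, ]
    w_out <- w[!adpgs:::in_region(w, mask), ]
    w_in <- w[adpgs:::in_region(w, mask), ]
    tot <- compute_score(sim$geno, w)$scores
    part <- compute_score(sim$geno, w_out)$scores +
      compute_score(sim$geno, w_in)$scores
    expect_equal(tot, part, tolerance = 1e-12)
  }
})

test_that("score correlation matrix is symmetric with unit diagonal", {
  cfg <- small_sim_config()
  sim <- quiet_cohort(cfg, seed = 7)
  grid <- build_score_grid(sim$stats, sim$geno, thresholds = c(0.01, 1.0))
  cm <- score_correlation_matrix(grid)
  expect_equal(diag(cm), setNames(rep(1, 4), colnames(cm)))
  expect_equal(cm, t(cm))
  dup <- grid[c(1, 1, 2)]
  names(dup) <- c("a", "b", "c")
  cm2 <- score_correlation_matrix(dup)
  expect_equal(cm2["a", "b"], 1)

  bad <- grid
  bad[[2]] <- bad[[2]][-1, ]
  expect_error(score_correlation_matrix(bad), "individual sets differ")
})

test_that("residualization removes e4 loading and re-standardizes", {
  set.seed(9)
  n <- 500
  e4 <- sample(0:2, n, replace = TRUE, prob = c(0.74, 0.24, 0.02))
  apoe <- tibble::tibble(individual_id = as.character(1:n),
                         one_e4 = as.integer(e4 == 1),
                         two_e4 = as.integer(e4 == 2))
  raw <- setNames(rnorm(n) + 0.25 * e4, apoe$individual_id)  # moderate loading
  sc <- standardize_score(raw, pT = 0.01, region_excluded = FALSE)
  rs <- residualize_on_apoe(sc, apoe)
  expect_equal(mean(rs$score), 0, tolerance = 1e-10)
  expect_equal(sd(rs$score), 1, tolerance = 1e-8)
  expect_lt(abs(cor(rs$score, apoe$one_e4)), 1e-10)
  expect_lt(abs(cor(rs$score, apoe$two_e4)), 1e-10)
  expect_gt(cor(rs$score, sc$score), 0.95)

  # a score orthogonal to the indicators is unchanged up to re-standardization
  orth <- setNames(residuals(lm(rnorm(n) ~ apoe$one_e4 + apoe$two_e4)),
                   apoe$individual_id)
  so <- standardize_score(orth)
  ro <- residualize_on_apoe(so, apoe)
  expect_equal(ro$score, so$score, tolerance = 1e-10)
})
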