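test_that("summary-stats reader handles well-formed files, drops, and duplicates", {
  path <- withr::local_tempfile(fileext = ".txt")
  hdr <- "MarkerName Chromosome Position Effect_allele Non_Effect_allele Beta Pvalue"
  writeLines(c(hdr,
               "rs1 1 100 A G 0.30 0.005",
               "rs2 2 200 a g -0.20 0.02",
               "rs3 chr3 300 C T 0.50 0.5"), path)
  ss <- read_summary_stats(path)
  expect_equal(nrow(ss), 3)
  expect_equal(ss$effect_allele, c("A", "A", "C"))   # upper-cased
  expect_equal(ss$chromosome, c("1", "2", "3"))      # chr prefix stripped

  writeLines(c(hdr, "rs1 1 100 A G 0.30 0.005", "rs2 2 200 A G NA 0.02"), path)
  expect_message(ss2 <- read_summary_stats(path), "dropped 1")
  expect_equal(ss2$variant_id, "rs1")

  writeLines(c(hdr, "rs1 1 100 A G 0.3 0.005", "rs1 1 100 A G 0.3 0.005"), path)
  expect_error(read_summary_stats(path), "duplicate variant_id.*rs1")

  writeLines(c("SNP CHR BP A1 A2 B P", "rs1 1 100 A G 0.3 0.005"), path)
  expect_error(read_summary_stats(path), "lacks mapped columns")
  ss3 <- read_summary_stats(path, dialect = sumstats_dialect(
    variant_id = "SNP", chromosome = "CHR", position = "BP",
    effect_allele = "A1", other_allele = "A2", beta = "B", p_value = "P"))
  expect_equal(ss3$beta, 0.3)
})

test_that("summary-stats invariants are enforced", {
  ss <- toy_sumstats()
  bad <- ss; bad$p_value[1] <- 0
  expect_error(adpgs:::validate_summary_stats(bad), "p_value")
  bad <- ss; bad$other_allele[2] <- bad$effect_allele[2]
  expect_error(adpgs:::validate_summary_stats(bad), "effect_allele")
})

test_that("VCF genotypes convert to ALT-allele counts and DS field is preferred", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2\ts3",
    "19\t45411941\trs429358\tT\tC\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0|1\t./.\t1|1"), path)
  g <- read_dosages(path, format = "vcf")
  expect_equal(dim(g), c(3L, 2L))
  expect_equal(unname(g$dosages[, "rs429358"]), c(0, 1, 2))
  expect_equal(unname(g$dosages[, "rs1"]), c(1, NA, 2))
  expect_equal(g$variants$counted_allele, c("C", "G"))  # ALT counted

  path2 <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2",
    "19\t45412079\trs7412\tC\tT\t.\tPASS\t.\tGT:DS\t0/0:0.12\t0/1:0.98"), path2)
  g2 <- read_dosages(path2, format = "vcf")
  expect_equal(unname(g2$dosages[, 1]), c(0.12, 0.98))
})

test_that("dosage-table round-trips exactly and rejects out-of-range values", {
  g <- toy_geno()
  g$dosages[1, 2] <- NA
  dt <- withr::local_tempfile(fileext = ".tsv")
  vt <- withr::local_tempfile(fileext = ".tsv")
  write_dosage_table(g, dt, vt)
  g2 <- read_dosages(dt, format = "dosage-table", variants = vt)
  expect_equal(g2$dosages, g$dosages)
  expect_equal(g2$variants, g$variants)

  tab <- readr::read_tsv(dt, show_col_types = FALSE)
  tab$rs1[1] <- 2.5
  readr::write_tsv(tab, dt)
  expect_error(read_dosages(dt, format = "dosage-table", variants = vt),
               "out of \\[0, 2\\]")
})

test_that("allele alignment orients, flips, and excludes as reported", {
  stats <- tibble::tibble(
    variant_id = c("v1", "v2", "v3", "v4"),
    chromosome = "1", position = 1:4 * 100L,
    effect_allele = c("A", "A", "A", "A"),
    other_allele = c("G", "G", "G", "T"),
    beta = c(0.3, 0.3, 0.3, 0.2), p_value = rep(0.01, 4))
  d <- matrix(rep(c(0, 1, 2), 4), nrow = 3,
              dimnames = list(c("i1", "i2", "i3"), NULL))
  geno <- geno_matrix(d, tibble::tibble(
    variant_id = c("v1", "v2", "v3", "v4"), chromosome = "1",
    position = 1:4 * 100L,
    counted_allele = c("A", "G", "C", "A"),
    alt_allele = c("G", "A", "T", "T")))
  al <- align_alleles(stats, geno)
  expect_equal(al$weights$weight[al$weights$variant_id == "v1"], 0.3)
  expect_equal(al$weights$weight[al$weights$variant_id == "v2"], -0.3)
  expect_false("v3" %in% al$weights$variant_id)
  expect_equal(al$report$n_shared, 4)
  expect_equal(al$report$n_direct + al$report$n_flipped + al$report$n_excluded,
               al$report$n_shared)
  expect_equal(al$report$n_excluded, 1)
  expect_equal(al$report$n_palindromic, 1)  # v4 is A/T

  al2 <- align_alleles(stats, geno, drop_palindromic = TRUE)
  expect_false("v4" %in% al2$weights$variant_id)
  expect_equal(al2$report$n_excluded, 2)
})

test_that("alignment is orientation-symmetric: flipping alleles and dosages preserves contributions", {
  set.seed(11)
  cfg <- small_sim_config()
  sim <- quiet_cohort(cfg, seed = 3)
  al <- align_alleles(sim$stats, sim$geno)
  contrib <- compute_score(sim$geno, al$weights)$scores

  # flip every other variant's orientation in the genotype input
  g2 <- sim$geno
  flip <- seq(1, nrow(g2$variants), by = 2)
  tmp <- g2$variants$counted_allele[flip]
  g2$variants$counted_allele[flip] <- g2$variants$alt_allele[flip]
  g2$variants$alt_allele[flip] <- tmp
  g2$dosages[, flip] <- 2 - g2$dosages[, flip]
  al2 <- align_alleles(sim$stats, g2)
  contrib2 <- compute_score(g2, al2$weights)$scores

  expect_equal(al2$report$n_shared, al$report$n_shared)
  expect_equal(al2$report$n_excluded, al$report$n_excluded)
  # weighted contributions shift by a constant offset sum(2w) over flipped
  # variants; centered contributions are identical
  expect_equal(contrib2 - mean(contrib2), contrib - mean(contrib), tolerance = 1e-12)
})

test_that("position-based matching joins on chromosome:position", {
  stats <- toy_sumstats()
  stats$variant_id <- paste0("x", seq_len(nrow(stats)))  # break rs-ID matching
  geno <- toy_geno()
  expect_equal(align_alleles(stats, geno)$report$n_shared, 0)
  al <- align_alleles(stats, geno, match_by = "position")
  expect_equal(al$report$n_shared, 5)
})
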