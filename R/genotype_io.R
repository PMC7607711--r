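#' Column map for GWAS summary-statistics files
#'
#' Returns the mapping from the pipeline's canonical summary-statistics field
#' names to the column names found in a delimited file. The default mirrors
#' the NIAGADS NG00075 layout used for the Kunkle et al. Alzheimer's disease
#' meta-analysis; any field can be overridden, or a whole map loaded from a
#' YAML file with one `field: column` entry per line.
#'
#' @param ... named overrides, e.g. `variant_id = "SNP"`.
#' @param yaml optional path to a YAML file with the full or partial map.
#' @return Named character vector with elements `variant_id`, `chromosome`,
#'   `position`, `effect_allele`, `other_allele`, `beta`, `p_value`.
#' @export
#' @examples
#' sumstats_dialect(beta = "BETA", p_value = "P")
sumstats_dialect <- function(..., yaml = NULL) {
  map <- c(
    variant_id    = "MarkerName",
    chromosome    = "Chromosome",
    position      = "Position",
    effect_allele = "Effect_allele",
    other_allele  = "Non_Effect_allele",
    beta          = "Beta",
    p_value       = "Pvalue"
  )
  if (!is.null(yaml)) {
    y <- yaml::read_yaml(yaml)
    map[names(y)] <- unlist(y)
  }
  dots <- c(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(map))
    if (length(bad)) abort(paste0("unknown summary-stats fields: ", toString(bad)))
    map[names(dots)] <- dots
  }
  map
}

validate_summary_stats <- function(stats) {
  stopifnot(is.data.frame(stats))
  need <- c("variant_id", "chromosome", "position", "effect_allele",
            "other_allele", "beta", "p_value")
  miss <- setdiff(need, names(stats))
  if (length(miss)) abort(paste0("summary stats missing columns: ", toString(miss)))
  dup <- stats$variant_id[duplicated(stats$variant_id)]
  if (length(dup)) abort(paste0("duplicate variant_id in summary stats: ",
                                toString(unique(head(dup, 5)))))
  if (any(stats$position < 1)) abort("summary stats: position must be >= 1")
  if (any(stats$effect_allele == stats$other_allele))
    abort("summary stats: effect_allele equals other_allele for some variants")
  if (any(stats$p_value <= 0 | stats$p_value > 1))
    abort("summary stats: p_value must lie in (0, 1]")
  invisible(stats)
}

#' Read GWAS summary statistics
#'
#' Reads a whitespace- or tab-delimited summary-statistics file into the
#' canonical tibble used for scoring. Rows whose effect size or p-value do
#' not parse as numbers (e.g. literal `NA`) are dropped with a message giving
#' the count; structural problems (missing columns, duplicated variant IDs,
#' out-of-range p-values) are errors.
#'
#' @param path file path.
#' @param dialect column map from [sumstats_dialect()].
#' @return A tibble with columns `variant_id`, `chromosome`, `position`,
#'   `effect_allele`, `other_allele`, `beta`, `p_value`.
#' @export
read_summary_stats <- function(path, dialect = sumstats_dialect()) {
  if (!file.exists(path)) abort(paste0("summary-stats file not found: ", path))
  raw <- readr::read_table(path, col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  miss <- setdiff(unname(dialect), names(raw))
  if (length(miss))
    abort(paste0("summary-stats file lacks mapped columns: ", toString(miss)))
  out <- tibble(
    variant_id    = raw[[dialect[["variant_id"]]]],
    chromosome    = norm_chrom(raw[[dialect[["chromosome"]]]]),
    position      = suppressWarnings(as.integer(raw[[dialect[["position"]]]])),
    effect_allele = toupper(raw[[dialect[["effect_allele"]]]]),
    other_allele  = toupper(raw[[dialect[["other_allele"]]]]),
    beta          = suppressWarnings(as.numeric(raw[[dialect[["beta"]]]])),
    p_value       = suppressWarnings(as.numeric(raw[[dialect[["p_value"]]]]))
  )
  ok <- !is.na(out$beta) & !is.na(out$p_value) & !is.na(out$position)
  if (any(!ok))
    inform(paste0("read_summary_stats: dropped ", sum(!ok),
                  " row(s) with unparseable beta/p-value/position"))
  out <- out[ok, , drop = FALSE]
  validate_summary_stats(out)
  out
}

#' Construct a genotype-dosage matrix object
#'
#' Container pairing an individuals-by-variants dosage matrix with its variant
#' annotations. Dosages count copies of `counted_allele` and must lie in
#' \[0, 2\] or be `NA`.
#'
#' @param dosages numeric matrix, individuals in rows (rownames = IDs),
#'   variants in columns (colnames = variant IDs).
#' @param variants tibble with columns `variant_id`, `chromosome`, `position`,
#'   `counted_allele`, `alt_allele` in column order of `dosages`.
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(dosages, variants) {
  dosages <- as.matrix(dosages)
  variants <- as_tibble(variants)
  if (ncol(dosages) != nrow(variants))
    abort("geno_matrix: variant annotation count != dosage column count")
  if (is.null(rownames(dosages))) abort("geno_matrix: dosages need rownames (individual IDs)")
  if (anyDuplicated(rownames(dosages))) abort("geno_matrix: duplicate individual IDs")
  rng <- range(dosages, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2)
    abort("geno_matrix: dosages outside [0, 2]")
  variants$chromosome <- norm_chrom(variants$chromosome)
  colnames(dosages) <- variants$variant_id
  structure(list(dosages = dosages, variants = variants), class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("<geno_matrix> ", nrow(x$dosages), " individuals x ",
      ncol(x$dosages), " variants\n", sep = "")
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosages)

#' Individual IDs of a genotype matrix
#' @param geno a `geno_matrix`.
#' @return Character vector of individual IDs.
#' @export
individual_ids <- function(geno) rownames(geno$dosages)

#' Subset a genotype matrix by variant ID
#' @param geno a `geno_matrix`.
#' @param variant_ids variants to keep, in the order given.
#' @return A `geno_matrix` restricted to those variants.
#' @export
subset_variants <- function(geno, variant_ids) {
  idx <- match(variant_ids, geno$variants$variant_id)
  if (anyNA(idx))
    abort(paste0("variants absent from genotype matrix: ",
                 toString(head(variant_ids[is.na(idx)], 5))))
  geno_matrix(geno$dosages[, idx, drop = FALSE], geno$variants[idx, ])
}

#' Read genotype dosages from VCF or a dosage table
#'
#' For VCF input the per-sample `DS` field is used when present; otherwise
#' hard genotypes (`GT`) are converted to ALT-allele counts. The counted
#' allele is the VCF ALT allele. The dosage-table dialect is tab-delimited
#' with a header `individual_id` followed by variant IDs, one row per
#' individual, missing values as `NA`; variant annotations for that dialect
#' come from a sidecar annotation table (see `variants`).
#'
#' @param path file path.
#' @param format `"vcf"` or `"dosage-table"`.
#' @param variants for `format = "dosage-table"`, a tibble of variant
#'   annotations (`variant_id`, `chromosome`, `position`, `counted_allele`,
#'   `alt_allele`), or path to a tab-delimited file with those columns.
#' @return A [geno_matrix()].
#' @export
read_dosages <- function(path, format = c("vcf", "dosage-table"), variants = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("genotype file not found: ", path))
  if (format == "vcf") read_dosages_vcf(path) else read_dosage_table(path, variants)
}

read_dosages_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- t(fix)  # single-variant VCFs drop to a vector
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  fmt <- unique(unlist(strsplit(vcf@gt[, "FORMAT"], ":")))
  if ("DS" %in% fmt) {
    ds <- vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE)
  } else {
    gt <- vcfR::extract.gt(vcf, element = "GT")
    ds <- apply(gt, c(1, 2), gt_to_count)
  }
  if (any(ds < 0 | ds > 2, na.rm = TRUE))
    abort("VCF dosages outside [0, 2]")
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- paste0(norm_chrom(fix$CHROM), ":", fix$POS)[is.na(ids) | ids == "."]
  variants <- tibble(
    variant_id = ids,
    chromosome = norm_chrom(fix$CHROM),
    position = as.integer(fix$POS),
    counted_allele = toupper(fix$ALT),
    alt_allele = toupper(fix$REF)
  )
  geno_matrix(t(ds), variants)
}

gt_to_count <- function(g) {
  if (is.na(g) || g %in% c(".", "./.", ".|.")) return(NA_real_)
  alleles <- strsplit(g, "[/|]")[[1]]
  if (any(alleles == ".")) return(NA_real_)
  sum(alleles != "0")
}

read_dosage_table <- function(path, variants) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    individual_id = "c", .default = "d"), na = "NA", progress = FALSE)
  if (names(tab)[1] != "individual_id")
    abort("dosage table must start with an 'individual_id' column")
  dos <- as.matrix(tab[, -1, drop = FALSE])
  rownames(dos) <- tab$individual_id
  if (any(dos < 0 | dos > 2, na.rm = TRUE)) {
    bad <- which(dos < 0 | dos > 2, arr.ind = TRUE)[1, ]
    abort(paste0("dosage out of [0, 2] at individual ", rownames(dos)[bad[1]],
                 ", variant ", colnames(dos)[bad[2]]))
  }
  if (is.null(variants))
    abort("dosage-table format needs a variant annotation table ('variants')")
  if (is.character(variants))
    variants <- readr::read_tsv(variants, col_types = readr::cols(
      variant_id = "c", chromosome = "c", position = "i",
      counted_allele = "c", alt_allele = "c"), progress = FALSE)
  variants <- as_tibble(variants)
  idx <- match(colnames(dos), variants$variant_id)
  if (anyNA(idx))
    abort(paste0("annotations missing for variants: ",
                 toString(head(colnames(dos)[is.na(idx)], 5))))
  geno_matrix(dos, variants[idx, ])
}

#' Write a genotype matrix in the dosage-table dialect
#'
#' @param geno a [geno_matrix()].
#' @param path output path for the dosage table.
#' @param variants_path optional path for the sidecar annotation table.
#' @return `path`, invisibly.
#' @export
write_dosage_table <- function(geno, path, variants_path = NULL) {
  tab <- bind_cols(tibble(individual_id = individual_ids(geno)),
                   as_tibble(geno$dosages))
  readr::write_tsv(tab, path, na = "NA", progress = FALSE)
  if (!is.null(variants_path))
    readr::write_tsv(geno$variants, variants_path, progress = FALSE)
  invisible(path)
}

#' Align summary-statistic effect alleles to genotype counted alleles
#'
#' Intersects the summary statistics with the genotype variants (rs-ID match
#' by default, chromosome:position fallback available) and orients the weight
#' for each shared variant: if the genotype's counted allele is the effect
#' allele the weight is `beta`; if it is the other allele the weight is
#' `-beta`; if the allele pair matches in neither orientation the variant is
#' excluded. Strand-ambiguous (A/T, C/G) pairs are aligned by allele identity
#' like any other variant but counted in the report, and can be excluded.
#'
#' @param stats summary-statistics tibble ([read_summary_stats()]).
#' @param geno a [geno_matrix()].
#' @param match_by `"id"` (default) or `"position"` (chromosome:position).
#' @param drop_palindromic drop A/T and C/G variants instead of aligning them.
#' @return A list with `weights` (tibble: `variant_id`, `weight`, `p_value`,
#'   `chromosome`, `position`, `flipped`, `palindromic`) and `report`
#'   (tibble: `n_shared`, `n_direct`, `n_flipped`, `n_excluded`,
#'   `n_palindromic`).
#' @export
align_alleles <- function(stats, geno, match_by = c("id", "position"),
                          drop_palindromic = FALSE) {
  match_by <- match.arg(match_by)
  validate_summary_stats(stats)
  gv <- geno$variants
  if (match_by == "id") {
    idx <- match(stats$variant_id, gv$variant_id)
  } else {
    key_s <- paste0(norm_chrom(stats$chromosome), ":", stats$position)
    key_g <- paste0(gv$chromosome, ":", gv$position)
    idx <- match(key_s, key_g)
  }
  shared <- which(!is.na(idx))
  s <- stats[shared, ]
  g <- gv[idx[shared], ]
  direct <- g$counted_allele == s$effect_allele & g$alt_allele == s$other_allele
  flip   <- g$counted_allele == s$other_allele  & g$alt_allele == s$effect_allele
  pal <- paste0(pmin(s$effect_allele, s$other_allele),
                pmax(s$effect_allele, s$other_allele)) %in% c("AT", "CG")
  keep <- (direct | flip) & !(drop_palindromic & pal)
  weights <- tibble(
    variant_id = g$variant_id[keep],
    weight = ifelse(direct[keep], s$beta[keep], -s$beta[keep]),
    p_value = s$p_value[keep],
    chromosome = g$chromosome[keep],
    position = g$position[keep],
    flipped = flip[keep],
    palindromic = pal[keep]
  )
  report <- tibble(
    n_shared = length(shared),
    n_direct = sum(direct & keep),
    n_flipped = sum(flip & keep),
    n_excluded = length(shared) - sum(keep),
    n_palindromic = sum(pal)
  )
  list(weights = weights, report = report)
}
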