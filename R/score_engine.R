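#' Genomic region mask
#'
#' 1-based, both-ends-inclusive interval on one chromosome (build 37
#' coordinates throughout the package).
#'
#' @param chromosome chromosome label ("19"; any "chr" prefix is stripped).
#' @param start,stop 1-based bp, inclusive.
#' @return A `region_mask` object.
#' @export
region_mask <- function(chromosome, start, stop) {
  start <- as.integer(start); stop <- as.integer(stop)
  if (is.na(start) || is.na(stop) || start < 1)
    abort("region_mask: start must be a positive integer")
  if (start > stop) abort("region_mask: start > stop")
  structure(list(chromosome = norm_chrom(chromosome), start = start, stop = stop),
            class = "region_mask")
}

#' @export
print.region_mask <- function(x, ...) {
  cat(sprintf("<region_mask> chr%s:%s-%s\n", x$chromosome,
              format(x$start, big.mark = ","), format(x$stop, big.mark = ",")))
  invisible(x)
}

#' Default APOE exclusion region
#'
#' The dense LD block on chromosome 19 spanning TOMM40, APOE and APOC1:
#' TOMM40 start (45,394,477) minus the flank to APOC1 stop (45,422,606) plus
#' the flank, build 37. With the default 10 kb flank this is
#' chr19:45,384,477-45,432,606.
#'
#' @param flank flank in bp added on each side (default 10,000).
#' @return A [region_mask()].
#' @export
#' @examples
#' default_apoe_region()
default_apoe_region <- function(flank = 10000) {
  region_mask("19", 45394477L - flank, 45422606L + flank)
}

#' Retain variants passing a discovery p-value threshold
#'
#' Membership is strict (`p_value < pT`), matching the usual
#' thresholded-score convention; `pT = 1` is the all-variant score and
#' retains every record (including any with p exactly 1).
#'
#' @param stats summary-statistics tibble.
#' @param pT threshold in (0, 1].
#' @return The retained subset, same columns.
#' @export
filter_by_threshold <- function(stats, pT) {
  if (!is.numeric(pT) || length(pT) != 1 || is.na(pT) || pT <= 0 || pT > 1)
    abort("pT must be a single number in (0, 1]")
  if (pT == 1) return(stats)
  stats[stats$p_value < pT, , drop = FALSE]
}

#' Remove variants inside a region mask
#'
#' Drops records with the mask's chromosome and
#' `start <= position <= stop` (both ends inclusive).
#'
#' @param stats summary-statistics tibble.
#' @param mask a [region_mask()].
#' @return The subset outside the region.
#' @export
apply_region_mask <- function(stats, mask) {
  stopifnot(inherits(mask, "region_mask"))
  inside <- norm_chrom(stats$chromosome) == mask$chromosome &
    stats$position >= mask$start & stats$position <= mask$stop
  stats[!inside, , drop = FALSE]
}

in_region <- function(variants, mask) {
  norm_chrom(variants$chromosome) == mask$chromosome &
    variants$position >= mask$start & variants$position <= mask$stop
}

#' Raw weighted-sum score
#'
#' Per-individual sum of aligned weights times dosages. Missing dosages are
#' imputed to the variant's sample mean dosage. Zero usable variants is an
#' error, not a silent all-zero score.
#'
#' @param geno a [geno_matrix()].
#' @param weights tibble from [align_alleles()] (`variant_id`, `weight`), or
#'   any tibble with those columns.
#' @return A list: `scores` (named numeric, one per individual),
#'   `n_variants_used`.
#' @export
compute_score <- function(geno, weights) {
  w <- weights[weights$variant_id %in% geno$variants$variant_id, , drop = FALSE]
  if (nrow(w) == 0) abort("compute_score: no usable variants")
  g <- subset_variants(geno, w$variant_id)
  d <- g$dosages
  if (anyNA(d)) {
    mu <- colMeans(d, na.rm = TRUE)
    mu[is.nan(mu)] <- 0  # variant entirely missing: contributes its mean, 0 dosage information
    na_idx <- which(is.na(d))
    d[na_idx] <- mu[((na_idx - 1) %/% nrow(d)) + 1]
  }
  list(scores = drop(d %*% w$weight), n_variants_used = nrow(w))
}

#' Standardize raw scores to a z-score
#'
#' Centers and scales with the sample mean and sample standard deviation of
#' the supplied individuals (the analytic sample), recording the raw moments.
#'
#' @param raw named numeric vector of raw scores (or list from
#'   [compute_score()]).
#' @param pT,region_excluded,n_variants_used provenance recorded on the
#'   result.
#' @return A `pgs_result`: tibble with `individual_id`, `score`, plus
#'   attributes `pT`, `region_excluded`, `n_variants_used`, `raw_mean`,
#'   `raw_sd`.
#' @export
standardize_score <- function(raw, pT = NA_real_, region_excluded = NA,
                              n_variants_used = NA_integer_) {
  if (is.list(raw) && !is.null(raw$scores)) {
    if (is.na(n_variants_used)) n_variants_used <- raw$n_variants_used
    raw <- raw$scores
  }
  if (length(raw) < 2) abort("standardize_score: need at least 2 individuals")
  m <- mean(raw); s <- sd(raw)
  if (!is.finite(s) || s == 0)
    abort("standardize_score: zero variance (degenerate score)")
  out <- tibble(individual_id = names(raw) %||% as.character(seq_along(raw)),
                score = (raw - m) / s)
  structure(out, class = c("pgs_result", class(out)),
            pT = pT, region_excluded = region_excluded,
            n_variants_used = as.integer(n_variants_used),
            raw_mean = m, raw_sd = s)
}

#' @export
print.pgs_result <- function(x, ...) {
  cat(sprintf("<pgs_result> pT=%s, region_excluded=%s, n_variants=%s, n=%d\n",
              attr(x, "pT"), attr(x, "region_excluded"),
              attr(x, "n_variants_used"), nrow(x)))
  NextMethod()
}

#' @rdname standardize_score
#' @param x a `pgs_result`.
#' @param ... unused.
#' @method glance pgs_result
#' @export
glance.pgs_result <- function(x, ...) {
  tibble(pT = attr(x, "pT"), region_excluded = attr(x, "region_excluded"),
         n_variants_used = attr(x, "n_variants_used"),
         raw_mean = attr(x, "raw_mean"), raw_sd = attr(x, "raw_sd"),
         n_individuals = nrow(x))
}

#' Build the threshold-by-region score grid
#'
#' One standardized score per (p-value threshold x region-in/region-out)
#' cell: the default six thresholds give 12 scores. Region-in scores include
#' every variant passing the threshold; region-out scores first excise the
#' mask from the summary statistics.
#'
#' @param stats summary-statistics tibble.
#' @param geno a [geno_matrix()].
#' @param thresholds numeric vector of pT values.
#' @param mask region to excise (default [default_apoe_region()]).
#' @param region_states region states to build; default both `FALSE`
#'   (region in) and `TRUE` (region excised).
#' @param match_by,drop_palindromic passed to [align_alleles()].
#' @return A `pgs_grid`: named list of `pgs_result` (names like
#'   `pT0.01_withAPOE` / `pT0.01_noAPOE`), with the alignment report as
#'   attribute `alignment`.
#' @export
build_score_grid <- function(stats, geno,
                             thresholds = c(0.001, 0.01, 0.05, 0.1, 0.3, 1.0),
                             mask = default_apoe_region(),
                             region_states = c(FALSE, TRUE),
                             match_by = "id", drop_palindromic = FALSE) {
  if (!length(thresholds)) abort("build_score_grid: thresholds must be nonempty")
  aligned <- align_alleles(stats, geno, match_by = match_by,
                           drop_palindromic = drop_palindromic)
  w <- aligned$weights
  cells <- tidyr::expand_grid(pT = sort(thresholds), region_excluded = region_states)
  res <- purrr::pmap(cells, function(pT, region_excluded) {
    wi <- if (pT == 1) w else w[w$p_value < pT, , drop = FALSE]
    if (region_excluded) wi <- wi[!in_region(wi, mask), , drop = FALSE]
    raw <- compute_score(geno, wi)
    standardize_score(raw, pT = pT, region_excluded = region_excluded)
  })
  names(res) <- paste0("pT", cells$pT, ifelse(cells$region_excluded, "_noAPOE", "_withAPOE"))
  structure(res, class = "pgs_grid", alignment = aligned$report, mask = mask)
}

#' @export
print.pgs_grid <- function(x, ...) {
  cat("<pgs_grid> ", length(x), " scores:\n", sep = "")
  print(tidy_pgs_grid_meta(x))
  invisible(x)
}

tidy_pgs_grid_meta <- function(grid) {
  purrr::map_dfr(unname(grid), glance)
}

#' Long tibble of all scores in a grid
#'
#' @param x a `pgs_grid`.
#' @param ... unused.
#' @return Tibble with `individual_id`, `score`, `pT`, `region_excluded`,
#'   `n_variants_used`.
#' @method tidy pgs_grid
#' @export
tidy.pgs_grid <- function(x, ...) {
  purrr::map_dfr(unname(x), function(r)
    mutate(as_tibble(r), pT = attr(r, "pT"),
           region_excluded = attr(r, "region_excluded"),
           n_variants_used = attr(r, "n_variants_used")))
}

#' @rdname tidy.pgs_grid
#' @method glance pgs_grid
#' @export
glance.pgs_grid <- function(x, ...) tidy_pgs_grid_meta(x)

#' Wide per-individual score table for joining onto a panel
#'
#' @param grid a `pgs_grid`.
#' @return Tibble with `individual_id` and one column per grid cell.
#' @export
score_wide <- function(grid) {
  out <- tibble(individual_id = grid[[1]]$individual_id)
  for (nm in names(grid)) {
    stopifnot(identical(grid[[nm]]$individual_id, out$individual_id))
    out[[nm]] <- grid[[nm]]$score
  }
  out
}

#' Pairwise Pearson correlations between scores
#'
#' @param results a `pgs_grid` or list of `pgs_result` over the same
#'   individuals.
#' @return Symmetric correlation matrix with grid-cell labels.
#' @export
score_correlation_matrix <- function(results) {
  ids <- results[[1]]$individual_id
  ok <- purrr::map_lgl(results, ~ identical(.x$individual_id, ids))
  if (!all(ok)) abort("score_correlation_matrix: individual sets differ across scores")
  m <- do.call(cbind, purrr::map(results, "score"))
  colnames(m) <- names(results)
  cor(m)
}

#' Regress epsilon-4 carrier status out of a score
#'
#' OLS residuals of the score on the one-copy and two-copy indicators (plus
#' intercept), re-standardized. Isolates the polygenic signal orthogonal to
#' directly measured APOE-e4 carrier status.
#'
#' @param score a `pgs_result`.
#' @param apoe tibble with `individual_id`, `one_e4`, `two_e4` (see
#'   [call_apoe()]).
#' @return A `pgs_result` of residualized, re-standardized scores.
#' @export
residualize_on_apoe <- function(score, apoe) {
  j <- match(score$individual_id, apoe$individual_id)
  if (anyNA(j)) abort("residualize_on_apoe: APOE calls missing for some individuals")
  fit <- lm(score$score ~ apoe$one_e4[j] + apoe$two_e4[j])
  res <- setNames(residuals(fit), score$individual_id)
  standardize_score(res, pT = attr(score, "pT"),
                    region_excluded = attr(score, "region_excluded"),
                    n_variants_used = attr(score, "n_variants_used"))
}

#' Residualize every score in a grid
#'
#' @param grid a `pgs_grid`.
#' @param apoe APOE call tibble.
#' @return A `pgs_grid` of residualized scores.
#' @export
residualize_grid <- function(grid, apoe) {
  out <- purrr::map(grid, residualize_on_apoe, apoe = apoe)
  structure(out, class = "pgs_grid", alignment = attr(grid, "alignment"),
            mask = attr(grid, "mask"))
}

#' Write a score grid as a long tab-delimited table
#'
#' @param grid a `pgs_grid`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(grid, path) {
  readr::write_tsv(tidy.pgs_grid(grid), path, progress = FALSE)
  invisible(path)
}

#' @describeIn tidy.pgs_grid density of each standardized score across the
#'   grid, faceted by threshold and coloured by region state.
#' @param object a `pgs_grid`.
#' @export
autoplot.pgs_grid <- function(object, ...) {
  d <- tidy.pgs_grid(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$score,
                                  colour = .data$region_excluded)) +
    ggplot2::geom_density() +
    ggplot2::facet_wrap(~pT, labeller = ggplot2::label_both) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "#1b6ca8", `TRUE` = "#c0392b"),
                                 labels = c(`FALSE` = "with APOE region",
                                            `TRUE` = "APOE region removed"),
                                 name = NULL) +
    ggplot2::labs(x = "standardized score") +
    ggplot2::theme_minimal()
}
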