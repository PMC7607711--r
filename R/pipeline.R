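#' Column map for longitudinal phenotype tables
#'
#' @param ... named overrides mapping canonical field -> file column.
#' @param yaml optional YAML file with `field: column` entries.
#' @return Named character vector of column mappings.
#' @export
phenotype_dialect <- function(..., yaml = NULL) {
  map <- c(individual_id = "individual_id", wave_year = "wave_year",
           cognition_score = "cognition_score",
           respondent_type = "respondent_type", age = "age", sex = "sex",
           education = "education", birth_cohort = "birth_cohort",
           stroke = "stroke")
  if (!is.null(yaml)) { y <- yaml::read_yaml(yaml); map[names(y)] <- unlist(y) }
  dots <- c(...)
  if (length(dots)) map[names(dots)] <- dots
  map
}

#' Read a long-format phenotype table
#'
#' Tab-delimited, one row per individual-wave; columns renamed to canonical
#' names via the dialect; extra columns (e.g. PCs) pass through unchanged.
#'
#' @param path file path.
#' @param dialect from [phenotype_dialect()].
#' @return Phenotype tibble for [build_panel()].
#' @export
read_phenotypes <- function(path, dialect = phenotype_dialect()) {
  if (!file.exists(path)) abort(paste0("phenotype file not found: ", path))
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  miss <- setdiff(unname(dialect), names(tab))
  if (length(miss)) abort(paste0("phenotype table lacks columns: ", toString(miss)))
  idx <- match(unname(dialect), names(tab))
  names(tab)[idx] <- names(dialect)
  tab
}

#' Run the end-to-end pipeline
#'
#' Orchestrates simulate/ingest -> score grid -> APOE calls -> panel assembly
#' -> model grid (plus optional sensitivity analyses), writing the artifact
#' set (scores, APOE calls, panel, exclusion report, descriptive table,
#' results table, score-correlation matrix, score-by-carrier summary,
#' manifest) when `out_dir` is given. Fixed seed and config give
#' reproducible artifacts.
#'
#' @param config a [sim_config()] used when simulating.
#' @param inputs optional list of file inputs instead of simulation:
#'   `summary_stats`, `dosages`, `dosage_format` ("vcf"/"dosage-table"),
#'   `variants` (annotation table for the dosage-table format),
#'   `phenotypes`, plus optional `sumstats_dialect`/`phenotype_dialect`.
#' @param seed seed for the simulated branch.
#' @param out_dir output directory (created); `NULL` returns results only.
#' @param thresholds p-value threshold grid.
#' @param mask APOE exclusion region; `NULL` for [default_apoe_region()].
#' @param region_states score-grid region states (see [build_score_grid()]);
#'   set to `FALSE` to skip region removal entirely.
#' @param corstr working correlation for all models.
#' @param exclude_cohorts birth cohorts to drop before modeling (sensitivity).
#' @param residualize use e4-residualized scores in the model grid
#'   (sensitivity).
#' @param sensitivity also run the full sensitivity suite.
#' @param stages `"all"` or a subset of
#'   `c("simulate", "score", "call-apoe", "classify", "fit")`; later stages
#'   need earlier ones.
#' @return List with `grid`, `apoe`, `panel`, `exclusion_report`, `results`,
#'   `table1`, `correlations`, `score_by_e4`, `manifest` (and `sensitivity`
#'   when requested); stages not run are `NULL`.
#' @export
run_pipeline <- function(config = sim_config(), inputs = NULL, seed = NULL,
                         out_dir = NULL,
                         thresholds = c(0.001, 0.01, 0.05, 0.1, 0.3, 1.0),
                         mask = NULL, region_states = c(FALSE, TRUE),
                         corstr = "unstructured",
                         exclude_cohorts = NULL, residualize = FALSE,
                         sensitivity = FALSE, stages = "all") {
  mask <- mask %||% default_apoe_region()
  all_stages <- c("simulate", "score", "call-apoe", "classify", "fit")
  stages <- if (identical(stages, "all")) all_stages else match.arg(stages, all_stages, several.ok = TRUE)
  counts <- list()

  if (is.null(inputs)) {
    sim <- simulate_cohort(config, seed = seed)
    geno <- sim$geno; stats <- sim$stats; phenotypes <- sim$phenotypes
    source_desc <- "simulated"
  } else {
    for (f in c("summary_stats", "dosages", "phenotypes"))
      if (is.null(inputs[[f]]) || !file.exists(inputs[[f]]))
        abort(paste0("run_pipeline: missing input file for '", f, "'"))
    stats <- read_summary_stats(inputs$summary_stats,
                                dialect = inputs$sumstats_dialect %||% sumstats_dialect())
    geno <- read_dosages(inputs$dosages,
                         format = inputs$dosage_format %||% "dosage-table",
                         variants = inputs$variants)
    phenotypes <- read_phenotypes(inputs$phenotypes,
                                  dialect = inputs$phenotype_dialect %||% phenotype_dialect())
    source_desc <- "files"
  }
  counts$n_individuals_genotyped <- nrow(geno$dosages)
  counts$n_variants <- ncol(geno$dosages)
  counts$n_summary_stats <- nrow(stats)
  counts$m_phenotype_rows <- nrow(phenotypes)

  grid <- apoe <- panel <- report <- results <- table1 <- cors <- fig3 <- NULL
  sens <- NULL

  if ("score" %in% stages) {
    grid <- build_score_grid(stats, geno, thresholds = thresholds, mask = mask,
                             region_states = region_states)
    counts$alignment <- as.list(attr(grid, "alignment"))
    counts$n_scores <- length(grid)
  }
  if ("call-apoe" %in% stages) {
    apoe <- call_apoe(geno)
    counts$n_apoe_no_call <- sum(apoe$call_flag == "no_call")
  }
  if ("classify" %in% stages) {
    bp <- build_panel(phenotypes)
    report <- bp$report
    panel <- join_scores(bp$panel, grid, apoe)
    if (!is.null(exclude_cohorts)) {
      panel <- cohort_filter(panel, exclude_cohorts)
      score_cols <- grep("^pT", names(panel), value = TRUE)
      one <- !duplicated(panel$individual_id)
      for (cl in score_cols)
        panel[[cl]] <- (panel[[cl]] - mean(panel[[cl]][one])) / sd(panel[[cl]][one])
    }
    counts$m_retained <- nrow(panel)
    counts$n_retained <- dplyr::n_distinct(panel$individual_id)
    table1 <- descriptive_table(panel)
    if (!is.null(grid)) {
      cors <- score_correlation_matrix(grid)
      fig3 <- score_by_e4_summary(panel)
    }
  }
  if ("fit" %in% stages) {
    if (is.null(panel)) abort("run_pipeline: 'fit' needs the 'classify' stage")
    fit_panel <- panel
    if (residualize && !is.null(grid) && !is.null(apoe)) {
      score_cols <- grep("^pT", names(panel), value = TRUE)
      base <- panel[, setdiff(names(panel), score_cols)]
      fit_panel <- join_scores(base, residualize_grid(grid, apoe))
    }
    results <- run_model_grid(fit_panel, corstr = corstr)
    counts$n_models <- dplyr::n_distinct(results$model_id)
    if (sensitivity)
      sens <- run_sensitivity_suite(panel, grid = grid, apoe = apoe, corstr = corstr)
  }

  manifest <- list(
    source = source_desc,
    seed = seed,
    config_hash = rlang::hash(config),
    thresholds = thresholds,
    region = sprintf("chr%s:%d-%d", mask$chromosome, mask$start, mask$stop),
    corstr = corstr, stages = stages, counts = counts,
    package_version = as.character(utils::packageVersion("adpgs"))
  )

  out <- list(grid = grid, apoe = apoe, panel = panel,
              exclusion_report = report, results = results, table1 = table1,
              correlations = cors, score_by_e4 = fig3,
              sensitivity = sens, manifest = manifest)
  if (!is.null(out_dir)) write_artifacts(out, out_dir)
  out
}

write_artifacts <- function(out, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  if (!is.null(out$grid)) write_scores(out$grid, p("scores.tsv"))
  if (!is.null(out$apoe)) write_apoe_calls(out$apoe, p("apoe_calls.tsv"))
  if (!is.null(out$panel)) readr::write_tsv(out$panel, p("panel.tsv"), na = "NA", progress = FALSE)
  if (!is.null(out$exclusion_report))
    jsonlite::write_json(as.list(out$exclusion_report), p("exclusion_report.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(out$results)) readr::write_tsv(out$results, p("results.tsv"), progress = FALSE)
  if (!is.null(out$table1)) {
    readr::write_tsv(out$table1$individuals, p("table1_individuals.tsv"), progress = FALSE)
    readr::write_tsv(out$table1$observations, p("table1_observations.tsv"), progress = FALSE)
  }
  if (!is.null(out$correlations)) {
    cm <- as_tibble(out$correlations, rownames = "score")
    readr::write_tsv(cm, p("score_correlations.tsv"), progress = FALSE)
  }
  if (!is.null(out$score_by_e4))
    readr::write_tsv(out$score_by_e4, p("score_by_e4.tsv"), progress = FALSE)
  if (!is.null(out$sensitivity))
    for (nm in names(out$sensitivity))
      readr::write_tsv(out$sensitivity[[nm]], p(paste0("sensitivity_", nm, ".tsv")),
                       progress = FALSE)
  jsonlite::write_json(out$manifest, p("manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
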