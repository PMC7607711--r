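default_covariates <- function(panel) {
  pcs <- grep("^PC[0-9]+$", names(panel), value = TRUE)
  c("age", "sex", "education", "year_c", "stroke", pcs)
}

prepare_model_panel <- function(panel) {
  # year centered at the first panel year: the per-year OR is unchanged,
  # centering only moves the intercept
  if (!"year_c" %in% names(panel))
    panel$year_c <- panel$wave_year - min(panel$wave_year)
  panel
}

model_formula <- function(outcome, terms) {
  as.formula(paste(outcome, "~", paste(terms, collapse = " + ")))
}

#' Fit the threshold-by-region model grid
#'
#' One GEE per score in the grid: dementia on the score plus the one- and
#' two-copy APOE-e4 indicators and the covariate set (age, sex, education,
#' centered year, stroke, ancestry PCs by default). Emits one long
#' results table across all models.
#'
#' @param panel analytic panel with scores and APOE columns joined
#'   (see [join_scores()]).
#' @param score_cols character vector of score column names; defaults to all
#'   `pT*` columns in the panel.
#' @param covariates covariate term names; default [default_covariates()].
#' @param apoe_terms APOE adjustment terms (set `character(0)` for
#'   PGS-only models).
#' @param corstr working correlation passed to [fit_gee()].
#' @param interaction also include score-by-e4 product terms.
#' @return Tibble: `model_id`, `pT`, `region_excluded`, `term`, `OR`,
#'   `robust_se`, `se_factor`, `ci_low`, `ci_high`, `p_value`,
#'   `n_individuals`, `n_observations`, `structure_used`, `converged`.
#' @export
run_model_grid <- function(panel, score_cols = NULL, covariates = NULL,
                           apoe_terms = c("one_e4", "two_e4"),
                           corstr = "unstructured", interaction = FALSE) {
  panel <- prepare_model_panel(panel)
  score_cols <- score_cols %||% grep("^pT", names(panel), value = TRUE)
  if (!length(score_cols)) abort("run_model_grid: no score columns found")
  covariates <- covariates %||% default_covariates(panel)
  purrr::map_dfr(score_cols, function(sc) {
    terms <- c(covariates, apoe_terms, sc)
    if (interaction && length(apoe_terms))
      terms <- c(terms, paste0(sc, ":", apoe_terms))
    fit <- fit_gee(panel, model_formula("dementia", terms), corstr = corstr)
    meta <- parse_score_col(sc)
    or_table(fit) |>
      mutate(model_id = sc, pT = meta$pT, region_excluded = meta$region_excluded,
             term = sub(sc, "PGS", .data$term, fixed = TRUE),
             n_individuals = fit$n_individuals,
             n_observations = fit$n_observations,
             structure_used = fit$structure_used,
             converged = fit$converged) |>
      select("model_id", "pT", "region_excluded", everything())
  })
}

parse_score_col <- function(sc) {
  m <- regmatches(sc, regexec("^pT([0-9.eE+-]+)_(withAPOE|noAPOE)$", sc))[[1]]
  if (length(m) == 3)
    list(pT = as.numeric(m[2]), region_excluded = m[3] == "noAPOE")
  else list(pT = NA_real_, region_excluded = NA)
}

#' Score-by-carrier interaction model
#'
#' Adds PGS-by-one-copy and PGS-by-two-copy product terms to the standard
#' adjusted model for a single score column.
#'
#' @param panel analytic panel with the score and APOE columns joined.
#' @param score_col score column name.
#' @param covariates covariate terms (default [default_covariates()]).
#' @param corstr working correlation.
#' @return The fitted `gee_fit`.
#' @export
run_interaction_model <- function(panel, score_col, covariates = NULL,
                                  corstr = "unstructured") {
  panel <- prepare_model_panel(panel)
  covariates <- covariates %||% default_covariates(panel)
  terms <- c(covariates, "one_e4", "two_e4", score_col,
             paste0(score_col, ":one_e4"), paste0(score_col, ":two_e4"))
  fit_gee(panel, model_formula("dementia", terms), corstr = corstr)
}

#' Sensitivity-analysis suite
#'
#' Reruns the model grid under the four standard perturbations:
#' (a) excluding the oldest birth cohorts, (b) with e4-residualized scores,
#' (c) PGS-only models without the e4 indicators, and (d) a single
#' e4-only model without any PGS.
#'
#' @param panel analytic panel with scores and APOE columns joined.
#' @param grid the `pgs_grid` used to build the panel's score columns
#'   (needed to residualize); may be `NULL` to skip (b).
#' @param apoe APOE call tibble (needed to residualize).
#' @param excluded_cohorts cohorts removed in (a); default AHEAD and CODA,
#'   the two oldest.
#' @param corstr working correlation.
#' @return Named list of results tables: `cohort_excluded`, `residualized`,
#'   `pgs_only`, `e4_only`.
#' @export
run_sensitivity_suite <- function(panel, grid = NULL, apoe = NULL,
                                  excluded_cohorts = c("AHEAD", "CODA"),
                                  corstr = "unstructured") {
  panel <- prepare_model_panel(panel)
  out <- list()

  sub <- cohort_filter(panel, excluded_cohorts)
  # re-standardize scores over the reduced analytic sample
  score_cols <- grep("^pT", names(panel), value = TRUE)
  one_per_id <- !duplicated(sub$individual_id)
  for (cl in score_cols)
    sub[[cl]] <- (sub[[cl]] - mean(sub[[cl]][one_per_id])) / sd(sub[[cl]][one_per_id])
  out$cohort_excluded <- run_model_grid(sub, corstr = corstr)

  if (!is.null(grid) && !is.null(apoe)) {
    resid_grid <- residualize_grid(grid, apoe)
    base <- panel[, setdiff(names(panel), score_cols)]
    panel_resid <- join_scores(base, resid_grid, apoe = NULL)
    out$residualized <- run_model_grid(panel_resid, corstr = corstr)
  }

  out$pgs_only <- run_model_grid(panel, apoe_terms = character(0), corstr = corstr)

  covariates <- default_covariates(panel)
  e4_fit <- fit_gee(panel, model_formula("dementia",
                                         c(covariates, "one_e4", "two_e4")),
                    corstr = corstr)
  out$e4_only <- or_table(e4_fit) |>
    mutate(model_id = "e4_only", n_individuals = e4_fit$n_individuals,
           n_observations = e4_fit$n_observations,
           structure_used = e4_fit$structure_used)
  out
}

#' Forest plot of odds ratios across the score grid
#'
#' @param results long results table from [run_model_grid()].
#' @param term which term to plot (default `"PGS"`).
#' @return A ggplot object.
#' @export
plot_or_grid <- function(results, term = "PGS") {
  d <- results[results$term == term, ]
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$pT), y = .data$OR,
                                  colour = .data$region_excluded)) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low,
                                          ymax = .data$ci_high),
                             position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "#1b6ca8", `TRUE` = "#c0392b"),
                                 labels = c(`FALSE` = "with APOE region",
                                            `TRUE` = "APOE region removed"),
                                 name = NULL) +
    ggplot2::labs(x = "p-value threshold (pT)", y = paste("Odds ratio:", term)) +
    ggplot2::theme_minimal()
}

#' Score distributions by APOE-e4 copy number
#'
#' Violin/box summary of a standardized score by e4 copies, the usual check
#' that carrier status loads on the score when the APOE region is included.
#'
#' @param panel analytic panel (or any tibble) with the score column and
#'   `e4_count`.
#' @param score_col score column name.
#' @return A ggplot object.
#' @export
plot_score_by_e4 <- function(panel, score_col) {
  d <- panel[!duplicated(panel$individual_id) & !is.na(panel$e4_count), ]
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$e4_count),
                                  y = .data[[score_col]])) +
    ggplot2::geom_violin(fill = "grey85", colour = NA) +
    ggplot2::geom_boxplot(width = 0.15, outlier.size = 0.4) +
    ggplot2::labs(x = "copies of APOE-e4", y = score_col) +
    ggplot2::theme_minimal()
}

#' Per-carrier-group score summaries
#'
#' @param panel analytic panel with scores and `e4_count` joined.
#' @param score_cols score columns to summarize (default all `pT*`).
#' @return Tibble: `score`, `e4_count`, `n`, `mean`, `sd`.
#' @export
score_by_e4_summary <- function(panel, score_cols = NULL) {
  score_cols <- score_cols %||% grep("^pT", names(panel), value = TRUE)
  d <- panel[!duplicated(panel$individual_id) & !is.na(panel$e4_count), ]
  purrr::map_dfr(score_cols, function(sc)
    d |> group_by(e4_count = .data$e4_count) |>
      summarise(n = dplyr::n(), mean = mean(.data[[sc]]),
                sd = sd(.data[[sc]]), .groups = "drop") |>
      mutate(score = sc) |> select("score", everything()))
}

#' @describeIn or_table forest plot of a fitted model's odds ratios with
#'   95% CIs (intercept omitted).
#' @param object a `gee_fit`.
#' @param ... unused.
#' @export
autoplot.gee_fit <- function(object, ...) {
  d <- or_table(object)
  d <- d[d$term != "(Intercept)", ]
  d$term <- factor(d$term, levels = rev(d$term))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$OR, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_low,
                                          xmax = .data$ci_high)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "odds ratio (log scale)", y = NULL) +
    ggplot2::theme_minimal()
}
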