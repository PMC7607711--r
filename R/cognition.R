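#' Langa-Weir cognition classification
#'
#' Maps summary cognition scores to dementia / CIND (cognitively impaired,
#' non-dementia) / normal using the respondent-type-specific cut points:
#' self-respondents (27-point test) 0-6 dementia, 7-11 CIND, 12-27 normal;
#' proxy respondents (11-point composite) 6-11 dementia, 3-5 CIND, 0-2
#' normal. Missing scores classify as `"missing"`.
#'
#' @param score integer score(s); NA allowed.
#' @param respondent_type `"self"` or `"proxy"`, recycled or vectorized.
#' @return Character vector in \{"dementia", "CIND", "normal", "missing"\}.
#' @export
#' @examples
#' classify_cognition(c(6, 7, 12), "self")
#' classify_cognition(c(2, 3, 6), "proxy")
classify_cognition <- function(score, respondent_type) {
  n <- max(length(score), length(respondent_type))
  score <- rep_len(score, n)
  rt <- rep_len(respondent_type, n)
  if (!all(rt %in% c("self", "proxy")))
    abort("respondent_type must be 'self' or 'proxy'")
  miss <- is.na(score)
  bad_range <- !miss & ((rt == "self" & (score < 0 | score > 27)) |
                          (rt == "proxy" & (score < 0 | score > 11)))
  if (any(bad_range))
    abort(paste0("cognition score out of range for respondent type at row(s): ",
                 toString(head(which(bad_range), 5))))
  out <- character(n)
  out[miss] <- "missing"
  s <- !miss & rt == "self"
  out[s & score <= 6] <- "dementia"
  out[s & score >= 7 & score <= 11] <- "CIND"
  out[s & score >= 12] <- "normal"
  p <- !miss & rt == "proxy"
  out[p & score >= 6] <- "dementia"
  out[p & score >= 3 & score <= 5] <- "CIND"
  out[p & score <= 2] <- "normal"
  out
}

#' Assemble the dementia-vs-normal analytic panel
#'
#' Classifies every person-wave cognition record, then applies the exclusion
#' cascade in order: (1) drop observations with missing cognition, (2) drop
#' observations classified CIND, (3) drop observations with missing stroke
#' status, (4) drop individuals left with zero observations. The retained
#' panel codes `dementia` 1 vs normal cognition 0.
#'
#' @param phenotypes long tibble with one row per individual-wave:
#'   `individual_id`, `wave_year`, `cognition_score`, `respondent_type`,
#'   `age`, `sex`, `education`, `birth_cohort`, `stroke`, and any further
#'   covariate columns (e.g. `PC1`..`PC5`) carried through untouched.
#' @return A list: `panel` (tibble with `dementia` added, exclusions applied)
#'   and `report` (tibble: `m_input`, `m_missing_cognition`, `m_cind`,
#'   `m_missing_stroke`, `m_retained`, `n_input`, `n_removed`, `n_retained`).
#' @export
build_panel <- function(phenotypes) {
  need <- c("individual_id", "wave_year", "cognition_score", "respondent_type",
            "stroke")
  miss <- setdiff(need, names(phenotypes))
  if (length(miss)) abort(paste0("phenotype table missing columns: ", toString(miss)))
  if (anyDuplicated(phenotypes[, c("individual_id", "wave_year")]))
    abort("build_panel: duplicate individual-wave rows")
  ph <- as_tibble(phenotypes)
  ph$class <- classify_cognition(ph$cognition_score, ph$respondent_type)
  m_input <- nrow(ph)
  n_input <- dplyr::n_distinct(ph$individual_id)

  keep1 <- ph$class != "missing"
  m_missing_cognition <- sum(!keep1)
  ph <- ph[keep1, ]
  keep2 <- ph$class != "CIND"
  m_cind <- sum(!keep2)
  ph <- ph[keep2, ]
  keep3 <- !is.na(ph$stroke)
  m_missing_stroke <- sum(!keep3)
  ph <- ph[keep3, ]

  ph$dementia <- as.integer(ph$class == "dementia")
  ph$class <- NULL
  n_retained <- dplyr::n_distinct(ph$individual_id)
  report <- tibble(
    m_input = m_input,
    m_missing_cognition = m_missing_cognition,
    m_cind = m_cind,
    m_missing_stroke = m_missing_stroke,
    m_retained = nrow(ph),
    n_input = n_input,
    n_removed = n_input - n_retained,
    n_retained = n_retained
  )
  list(panel = arrange(ph, .data$individual_id, .data$wave_year), report = report)
}

#' Drop birth cohorts from a panel
#'
#' @param panel panel tibble with a `birth_cohort` column.
#' @param excluded_cohorts character vector of cohort labels to remove
#'   (e.g. `c("AHEAD", "CODA")`). Unknown labels warn rather than error.
#' @return Filtered panel tibble.
#' @export
cohort_filter <- function(panel, excluded_cohorts) {
  if (!"birth_cohort" %in% names(panel)) abort("panel lacks a birth_cohort column")
  unknown <- setdiff(excluded_cohorts, unique(panel$birth_cohort))
  if (length(unknown))
    warn(paste0("cohort_filter: cohort label(s) not present: ", toString(unknown)))
  out <- panel[!(panel$birth_cohort %in% excluded_cohorts), , drop = FALSE]
  inform(sprintf("cohort_filter: removed %d observation(s) from %d individual(s)",
                 nrow(panel) - nrow(out),
                 dplyr::n_distinct(panel$individual_id) - dplyr::n_distinct(out$individual_id)))
  out
}

first_visit <- function(panel) {
  panel |>
    group_by(.data$individual_id) |>
    slice_min(.data$wave_year, n = 1, with_ties = FALSE) |>
    ungroup()
}

#' Sex-stratified descriptive summaries
#'
#' Individual-level summaries (visits, first-visit age/dementia/stroke,
#' education, cohort, APOE-e4 copies, mean scores) and observation-level
#' summaries (dementia, age, stroke, year), stratified by sex and overall.
#' "First visit" is each individual's earliest retained wave.
#'
#' @param panel panel tibble from [build_panel()], with scores/APOE columns
#'   already joined (see [join_scores()]).
#' @return A list of two tibbles, `individuals` and `observations`, in long
#'   form: `level`, `variable`, `stratum` (`male`/`female`/`overall`),
#'   `stat` (`mean`, `sd`, `n`, `pct`), `value`.
#' @export
descriptive_table <- function(panel) {
  if (!nrow(panel)) abort("descriptive_table: empty panel")
  panel$stratum <- ifelse(panel$sex == 1, "male", "female")
  fv <- first_visit(panel)
  strata <- function(d) list(male = d[d$stratum == "male", ],
                             female = d[d$stratum == "female", ],
                             overall = d)

  num_stats <- function(d, var) {
    x <- d[[var]]
    tibble(variable = var, stat = c("mean", "sd", "n"),
           value = c(mean(x, na.rm = TRUE), sd(x, na.rm = TRUE), sum(!is.na(x))))
  }
  bin_stats <- function(d, var) {
    x <- d[[var]]
    tibble(variable = var, stat = c("n", "pct"),
           value = c(sum(x == 1, na.rm = TRUE),
                     100 * mean(x == 1, na.rm = TRUE)))
  }
  cat_stats <- function(d, var) {
    tab <- table(d[[var]])
    tibble(variable = paste0(var, "=", names(tab)),
           stat = "n", value = as.numeric(tab)) |>
      bind_rows(tibble(variable = paste0(var, "=", names(tab)), stat = "pct",
                       value = 100 * as.numeric(tab) / nrow(d)))
  }

  visits <- panel |> count(.data$individual_id, .data$stratum, name = "visits")
  indiv_one <- function(d, ids) {
    dd <- d[d$individual_id %in% ids, ]
    v <- visits[visits$individual_id %in% ids, ]
    score_cols <- grep("^pT", names(d), value = TRUE)
    bind_rows(
      num_stats(v, "visits"),
      bin_stats(dd, "dementia") |> mutate(variable = "dementia_first_visit"),
      num_stats(dd, "age") |> mutate(variable = "age_first_visit"),
      num_stats(dd, "education"),
      bin_stats(dd, "stroke") |> mutate(variable = "stroke_first_visit"),
      if ("birth_cohort" %in% names(dd)) cat_stats(dd, "birth_cohort"),
      if ("e4_count" %in% names(dd)) cat_stats(dd, "e4_count"),
      purrr::map_dfr(score_cols, ~ num_stats(dd, .x))
    )
  }
  indiv <- purrr::imap_dfr(strata(fv), function(d, nm)
    indiv_one(fv, d$individual_id) |> mutate(stratum = nm))

  obs_one <- function(d) {
    bind_rows(bin_stats(d, "dementia"), num_stats(d, "age"),
              bin_stats(d, "stroke"), cat_stats(d, "wave_year"))
  }
  obs <- purrr::imap_dfr(strata(panel), function(d, nm)
    obs_one(d) |> mutate(stratum = nm))

  list(
    individuals = indiv |> mutate(level = "individual") |>
      select("level", "variable", "stratum", "stat", "value"),
    observations = obs |> mutate(level = "observation") |>
      select("level", "variable", "stratum", "stat", "value")
  )
}

#' Join score and APOE columns onto a panel
#'
#' Scores are re-standardized over the analytic sample after the join, so the
#' per-column mean is 0 and SD is 1 over the distinct retained individuals
#' (the standardization population the descriptives refer to).
#'
#' @param panel panel tibble.
#' @param grid a `pgs_grid`, or a wide per-individual tibble from
#'   [score_wide()].
#' @param apoe APOE call tibble from [call_apoe()] (optional).
#' @param restandardize re-standardize score columns over the panel's
#'   individuals (default TRUE).
#' @return Panel tibble with one column per score plus APOE columns.
#' @export
join_scores <- function(panel, grid = NULL, apoe = NULL, restandardize = TRUE) {
  out <- as_tibble(panel)
  if (!is.null(grid)) {
    wide <- if (inherits(grid, "pgs_grid")) score_wide(grid) else as_tibble(grid)
    out <- left_join(out, wide, by = "individual_id")
    if (restandardize) {
      score_cols <- setdiff(names(wide), "individual_id")
      one_per_id <- !duplicated(out$individual_id)
      for (cl in score_cols) {
        m <- mean(out[[cl]][one_per_id], na.rm = TRUE)
        s <- sd(out[[cl]][one_per_id], na.rm = TRUE)
        out[[cl]] <- (out[[cl]] - m) / s
      }
    }
  }
  if (!is.null(apoe))
    out <- left_join(out, select(apoe, "individual_id", "diplotype",
                                 "e4_count", "one_e4", "two_e4"),
                     by = "individual_id")
  out
}
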