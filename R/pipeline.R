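#' Run the full beam-model audit analysis
#'
#' End-to-end pipeline: fit community distributions from the survey, score
#' each audited institution's report (percentiles + atypicality flags),
#' predict each institution's aggregate systematic TPS error from the
#' anchor effect models, classify audit outcomes, apply the localization
#' exclusion, and run the association battery. All thresholds live here as
#' arguments with the study's values as defaults; stage logic hard-codes
#' nothing.
#'
#' @param survey Survey tibble or CSV path ([read_survey()] schema). Must
#'   contain the audited institutions' own responses.
#' @param audit TLD-level audit tibble or CSV path ([read_audit()] schema).
#' @param anchors Anchor catalog ([load_anchors()]).
#' @param truth Optional ground-truth tibble/CSV (`institution_id`,
#'   `true_error_pct`) from [generate_study()], enabling the
#'   estimated-vs-true recovery correlation.
#' @param fail_tld_pct,poor_tld_pct,film_pass_min Outcome thresholds
#'   ([classify_outcomes()]).
#' @param low_cut,high_cut Atypicality percentile cuts ([classify_atypical()]).
#' @param impactful_cut_pct Impactful-parameter threshold in percent dose.
#' @param max_offset_mm Localization exclusion cut in mm.
#' @param min_sample_size Minimum community stratum size.
#' @return An object of class `audit_analysis`: a list with tibbles
#'   `scores`, `outcomes` (flagged, pre-exclusion), `estimates`,
#'   `associations`, `summary`, `recovery` (estimated vs true/measured
#'   scatter data) and the `config` used. Has [tidy()], [glance()] and
#'   [autoplot()] methods.
#' @export
run_audit_analysis <- function(survey, audit, anchors = load_anchors(),
                               truth = NULL,
                               fail_tld_pct = 7, poor_tld_pct = 5,
                               film_pass_min = 85,
                               low_cut = 10, high_cut = 90,
                               impactful_cut_pct = 1, max_offset_mm = 3,
                               min_sample_size = 5) {
  if (is.character(survey)) survey <- read_survey(survey)
  if (is.character(audit)) audit <- read_audit(audit)
  if (is.character(truth)) truth <- readr::read_csv(truth, show_col_types = FALSE)
  validate_anchors(anchors)

  fitted <- fit_survey(survey, min_sample_size = min_sample_size)
  audited_ids <- unique(audit$institution_id)
  reports <- dplyr::filter(survey, .data$institution_id %in% audited_ids)
  if (nrow(reports) == 0) {
    abort("no survey rows found for the audited institutions",
          class = "beamaudit_invalid")
  }
  scores <- score_report(reports, fitted, catalog = anchors,
                         low_cut = low_cut, high_cut = high_cut)

  models <- build_effect_models(anchors)
  effects <- suppressWarnings(predict_effects(reports, models))
  estimates <- aggregate_error(effects)

  outcomes <- classify_outcomes(audit, fail_tld_pct = fail_tld_pct,
                                poor_tld_pct = poor_tld_pct,
                                film_pass_min = film_pass_min)
  associations <- run_association_analysis(
    scores, outcomes, estimates = estimates, anchors = anchors,
    impactful_cut_pct = impactful_cut_pct, max_offset_mm = max_offset_mm)

  recovery <- dplyr::left_join(
    dplyr::select(outcomes, dplyr::any_of(c("institution_id", "tps",
                                            "mean_tld_error_pct",
                                            "localization_offset_mm"))),
    dplyr::select(estimates, "institution_id", estimated_error_pct = "total_pct"),
    by = "institution_id")
  if (!is.null(truth)) {
    recovery <- dplyr::left_join(
      recovery, dplyr::select(truth, "institution_id", "true_error_pct"),
      by = "institution_id")
  }
  if ("localization_offset_mm" %in% names(recovery)) {
    exclude_localization(recovery, max_offset_mm) # validates offsets
    recovery <- dplyr::mutate(recovery,
      excluded_for_localization = .data$localization_offset_mm > max_offset_mm)
  }

  structure(list(
    scores = scores,
    outcomes = outcomes,
    estimates = estimates,
    associations = associations,
    recovery = recovery,
    summary = summarize_cohort(outcomes),
    config = list(fail_tld_pct = fail_tld_pct, poor_tld_pct = poor_tld_pct,
                  film_pass_min = film_pass_min, low_cut = low_cut,
                  high_cut = high_cut, impactful_cut_pct = impactful_cut_pct,
                  max_offset_mm = max_offset_mm,
                  min_sample_size = min_sample_size)
  ), class = "audit_analysis")
}

#' Summarize a phantom-audit cohort
#'
#' Counts and percentages of irradiations by TPS, linac class, beam energy
#' and phantom type (whichever columns are present), one block per
#' category. Percentages are raw; round for presentation.
#'
#' @param records Per-irradiation tibble.
#' @return Tibble with `block`, `category`, `n`, `pct`.
#' @export
summarize_cohort <- function(records) {
  blocks <- intersect(c("tps", "linac_class", "beam_energy", "phantom"),
                      names(records))
  purrr::map_dfr(blocks, function(b) {
    records |>
      dplyr::count(category = as.character(.data[[b]])) |>
      dplyr::mutate(block = b, pct = 100 * .data$n / sum(.data$n)) |>
      dplyr::select("block", "category", "n", "pct")
  })
}

#' @export
print.audit_analysis <- function(x, ...) {
  n <- nrow(x$outcomes)
  cat(sprintf("<audit_analysis> %d irradiations\n", n))
  cat(sprintf("  failing: %d (%.1f%%)   poor: %d (%.1f%%)\n",
              sum(x$outcomes$failing), 100 * mean(x$outcomes$failing),
              sum(x$outcomes$poor), 100 * mean(x$outcomes$poor)))
  if ("excluded_for_localization" %in% names(x$recovery)) {
    cat(sprintf("  excluded for localization (> %g mm): %d\n",
                x$config$max_offset_mm,
                sum(x$recovery$excluded_for_localization)))
  }
  cat("  association tests:", nrow(x$associations), "rows (see tidy())\n")
  invisible(x)
}

#' @method tidy audit_analysis
#' @export
tidy.audit_analysis <- function(x, ...) {
  x$associations
}

#' @method glance audit_analysis
#' @export
glance.audit_analysis <- function(x, ...) {
  kept <- if ("excluded_for_localization" %in% names(x$recovery)) {
    dplyr::filter(x$recovery, !.data$excluded_for_localization)
  } else {
    x$recovery
  }
  target <- if ("true_error_pct" %in% names(kept)) "true_error_pct" else "mean_tld_error_pct"
  ok <- is.finite(kept$estimated_error_pct) & is.finite(kept[[target]])
  r <- if (sum(ok) >= 3 && sd(kept$estimated_error_pct[ok]) > 0 &&
           sd(kept[[target]][ok]) > 0) {
    pearson_correlation(kept$estimated_error_pct[ok], kept[[target]][ok])$estimate
  } else {
    NA_real_
  }
  tibble(
    n_irradiations = nrow(x$outcomes),
    n_failing = sum(x$outcomes$failing),
    n_poor = sum(x$outcomes$poor),
    failing_rate = mean(x$outcomes$failing),
    poor_rate = mean(x$outcomes$poor),
    n_excluded_localization = if ("excluded_for_localization" %in% names(x$recovery))
      sum(x$recovery$excluded_for_localization) else NA_integer_,
    estimated_vs_error_r = r
  )
}

#' Plot estimated versus observed dose error
#'
#' Scatter of the aggregate model-predicted TPS error against the true
#' systematic error (when ground truth is available) or the measured mean
#' TLD error, localization-excluded audits greyed out, with the identity
#' line.
#'
#' @param object An `audit_analysis`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot audit_analysis
#' @export
autoplot.audit_analysis <- function(object, ...) {
  rec <- object$recovery
  target <- if ("true_error_pct" %in% names(rec)) "true_error_pct" else "mean_tld_error_pct"
  rec$excluded <- rec$excluded_for_localization %||% FALSE
  ggplot2::ggplot(rec, ggplot2::aes(x = .data$estimated_error_pct,
                                    y = .data[[target]],
                                    colour = .data$excluded)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "steelblue",
                                            `TRUE` = "grey70"),
                                 name = "> localization cut") +
    ggplot2::labs(x = "Estimated TPS error (%)",
                  y = sprintf("%s (%%)",
                              if (target == "true_error_pct") "True systematic error"
                              else "Measured mean TLD error")) +
    ggplot2::theme_minimal()
}

#' Plot percentile scores by outcome
#'
#' Distribution of community percentile scores per parameter, split by
#' audit outcome — the visual counterpart of the per-parameter association
#' tests.
#'
#' @param analysis An `audit_analysis`.
#' @param outcome `"failing"` or `"poor"`.
#' @return A ggplot.
#' @export
plot_score_distribution <- function(analysis, outcome = c("failing", "poor")) {
  outcome <- match.arg(outcome)
  df <- dplyr::inner_join(analysis$scores, analysis$outcomes,
                          by = "institution_id", suffix = c("", ".o"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$parameter, y = .data$percentile,
                                   fill = .data[[outcome]])) +
    ggplot2::geom_boxplot(outlier.alpha = 0.4) +
    ggplot2::geom_hline(yintercept = c(10, 90), linetype = "dotted") +
    ggplot2::coord_flip() +
    ggplot2::labs(y = "Community percentile", x = NULL, fill = outcome) +
    ggplot2::theme_minimal()
}
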