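#' Build a 2x2 contingency table of atypicality vs outcome
#'
#' Rows: atypical yes/no; columns: outcome (e.g. failing) yes/no, so
#' `a = atypical & outcome`, `b = atypical & !outcome`, `c = typical &
#' outcome`, `d = typical & !outcome`.
#'
#' @param flag,outcome Logical vectors of equal length (no NA).
#' @return A 2x2 integer matrix with informative dimnames.
#' @export
build_table <- function(flag, outcome) {
  if (length(flag) == 0 || length(flag) != length(outcome)) {
    abort("flag and outcome must be non-empty logical vectors of equal length",
          class = "beamaudit_invalid")
  }
  if (any(is.na(flag)) || any(is.na(outcome))) {
    abort("flag/outcome must not contain NA (drop incomplete records first)",
          class = "beamaudit_invalid")
  }
  matrix(c(sum(flag & outcome), sum(flag & !outcome),
           sum(!flag & outcome), sum(!flag & !outcome)),
         nrow = 2, byrow = TRUE,
         dimnames = list(atypical = c("yes", "no"),
                         outcome = c("yes", "no")))
}

check_table <- function(table) {
  if (!is.matrix(table) || !identical(dim(table), c(2L, 2L)) ||
      any(table < 0) || any(table != round(table))) {
    abort("expected a 2x2 matrix of non-negative counts", class = "beamaudit_invalid")
  }
  if (sum(table) == 0) {
    abort("contingency table has zero grand total", class = "beamaudit_invalid")
  }
  invisible(table)
}

test_result <- function(method, statistic, p_value, n, estimate = NA_real_,
                        note = NA_character_) {
  tibble(method = method, statistic = statistic, p_value = p_value,
         n = as.integer(n), estimate = estimate, note = note)
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value by probability-mass ordering (the sum of hypergeometric
#' probabilities, margins fixed, of all tables no more probable than the
#' observed one). The reported estimate is the sample odds ratio `ad / bc`
#' (`Inf` or 0 with a zero cell, noted in `note`), not the conditional MLE.
#'
#' @param table 2x2 count matrix ([build_table()]).
#' @return A one-row `TestResult` tibble: `method`, `statistic` (NA for an
#'   exact test), `p_value`, `n`, `estimate`, `note`.
#' @examples
#' fisher_exact(matrix(c(2, 0, 0, 2), 2))  # p = 1/3
#' @export
fisher_exact <- function(table) {
  check_table(table)
  p <- stats::fisher.test(table)$p.value
  a <- table[1, 1]; b <- table[1, 2]; c <- table[2, 1]; d <- table[2, 2]
  or <- (a * d) / (b * c)
  note <- if (b * c == 0 || a * d == 0) "odds ratio degenerate (zero cell)" else NA_character_
  test_result("fisher_exact", NA_real_, min(p, 1), sum(table), or, note)
}

#' Pearson chi-square test on a 2x2 table
#'
#' @param table 2x2 count matrix.
#' @param continuity_correction Apply the Yates correction (default FALSE).
#' @return A one-row `TestResult` tibble; `statistic` is the chi-square
#'   statistic on 1 df.
#' @examples
#' chi_square(matrix(c(30, 20, 20, 30), 2, byrow = TRUE))  # X2 = 4, p ~ 0.0455
#' @export
chi_square <- function(table, continuity_correction = FALSE) {
  check_table(table)
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  if (any(expected == 0)) {
    abort("chi-square test undefined: an expected count is zero",
          class = "beamaudit_invalid")
  }
  fit <- suppressWarnings(stats::chisq.test(table, correct = continuity_correction))
  test_result("chi_square", unname(fit$statistic), unname(fit$p.value), sum(table))
}

#' Pearson correlation with a t-based two-sided p-value
#'
#' @param x,y Numeric vectors of equal length >= 3 with nonzero variance.
#' @return A one-row `TestResult` tibble; `estimate` is r, `statistic` the
#'   t statistic on n - 2 df.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    abort("need equal-length vectors with at least 3 pairs", class = "beamaudit_invalid")
  }
  check_finite(x, "x"); check_finite(y, "y")
  if (sd(x) == 0 || sd(y) == 0) {
    abort("correlation undefined: an input has zero variance",
          class = "beamaudit_zero_variance")
  }
  fit <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  test_result("pearson", unname(fit$statistic), unname(fit$p.value),
              length(x), unname(fit$estimate))
}

not_computed <- function(method, n, note) {
  test_result(method, NA_real_, NA_real_, n, note = note)
}

#' Association analysis between atypical beam modeling and audit outcome
#'
#' Reproduces the study's battery of comparisons on a scored cohort:
#' \itemize{
#'   \item overall: any-atypical-parameter vs failing and vs poor
#'     (chi-square, with the Fisher p alongside);
#'   \item the same restricted to *impactful* parameters (dose impact > 1%);
#'   \item per-parameter Fisher tests for failing and for poor;
#'   \item Pearson correlation of each parameter's percentile score with the
#'     mean TLD error;
#'   \item Pearson correlation of the aggregate estimated TPS error with the
#'     mean TLD error, on localization-filtered records, stratified by TPS.
#' }
#' Tests whose cell sizes make them meaningless (fewer than 3 usable
#' records, or a degenerate margin) are reported as not-computed rows, never
#' errors. Raw per-test p-values are reported (matching the study's
#' convention); a Benjamini-Hochberg column `p_adjusted` is added within the
#' per-parameter family for transparency.
#'
#' @param scores Per-institution-parameter tibble from [score_report()].
#' @param outcomes Per-irradiation tibble from [classify_outcomes()], with
#'   `localization_offset_mm` when estimation correlations are wanted.
#' @param estimates Optional per-institution tibble with `total_pct`
#'   ([aggregate_error()]); enables the estimated-vs-measured correlation.
#' @param anchors Anchor catalog for the impactful-parameter subset.
#' @param impactful_cut_pct Impact threshold (percent dose, default 1).
#' @param max_offset_mm Localization exclusion for correlation tests.
#' @return Tibble, one row per test: `scope`, `parameter`, `outcome`,
#'   `method`, `a`, `b`, `c`, `d`, `n`, `statistic`, `estimate`, `p_value`,
#'   `p_adjusted`, `computed`, `note`.
#' @export
run_association_analysis <- function(scores, outcomes, estimates = NULL,
                                     anchors = load_anchors(),
                                     impactful_cut_pct = 1,
                                     max_offset_mm = 3) {
  scored <- if ("scored" %in% names(scores)) {
    dplyr::filter(scores, .data$scored)
  } else {
    scores
  }
  imp <- impactful_parameters(anchors, impactful_cut_pct)
  imp_key <- paste(norm_field(imp$tps), norm_field(imp$parameter), sep = "|")
  flags <- scored |>
    dplyr::group_by(.data$institution_id) |>
    dplyr::summarise(
      any_atypical = any(.data$atypical),
      any_atypical_impactful = any(.data$atypical &
        paste(norm_field(.data$tps), norm_field(.data$parameter), sep = "|") %in% imp_key),
      .groups = "drop")
  joined <- dplyr::inner_join(outcomes, flags, by = "institution_id")

  contingency_row <- function(flag, outcome, scope, param, outcome_name) {
    ok <- !is.na(flag) & !is.na(outcome)
    flag <- flag[ok]; outcome <- outcome[ok]
    base <- tibble(scope = scope, parameter = param, outcome = outcome_name)
    if (length(flag) < 3 || length(unique(flag)) < 2 || length(unique(outcome)) < 2) {
      return(dplyr::bind_cols(base,
        a = NA_integer_, b = NA_integer_, c = NA_integer_, d = NA_integer_,
        not_computed("fisher_exact", length(flag),
                     "not computed: <3 records or degenerate margin"),
        computed = FALSE))
    }
    tab <- build_table(flag, outcome)
    res <- if (scope == "parameter") fisher_exact(tab) else chi_square(tab)
    dplyr::bind_cols(base, a = tab[1, 1], b = tab[1, 2], c = tab[2, 1],
                     d = tab[2, 2], res, computed = TRUE)
  }

  rows <- list(
    contingency_row(joined$any_atypical, joined$failing, "overall", "any", "failing"),
    contingency_row(joined$any_atypical, joined$poor, "overall", "any", "poor"),
    contingency_row(joined$any_atypical_impactful, joined$failing, "impactful", "any impactful", "failing"),
    contingency_row(joined$any_atypical_impactful, joined$poor, "impactful", "any impactful", "poor")
  )

  per_param <- dplyr::inner_join(scored, outcomes, by = "institution_id",
                                 suffix = c("", ".outcome"))
  for (g in dplyr::group_split(dplyr::group_by(per_param, .data$tps, .data$parameter))) {
    pname <- g$parameter[1]
    rows <- c(rows, list(
      contingency_row(g$atypical, g$failing, "parameter", pname, "failing"),
      contingency_row(g$atypical, g$poor, "parameter", pname, "poor")
    ))
    base <- tibble(scope = "percentile_correlation", parameter = pname,
                   outcome = "mean_tld_error_pct")
    ok <- is.finite(g$percentile) & is.finite(g$mean_tld_error_pct)
    res <- if (sum(ok) >= 3 && sd(g$percentile[ok]) > 0 && sd(g$mean_tld_error_pct[ok]) > 0) {
      dplyr::bind_cols(pearson_correlation(g$percentile[ok], g$mean_tld_error_pct[ok]),
                       computed = TRUE)
    } else {
      dplyr::bind_cols(not_computed("pearson", sum(ok),
                                    "not computed: <3 records or zero variance"),
                       computed = FALSE)
    }
    rows <- c(rows, list(dplyr::bind_cols(base, a = NA_integer_, b = NA_integer_,
                                          c = NA_integer_, d = NA_integer_, res)))
  }

  if (!is.null(estimates)) {
    est <- dplyr::inner_join(joined, estimates, by = "institution_id")
    if ("localization_offset_mm" %in% names(est)) {
      est <- exclude_localization(est, max_offset_mm)$kept
    }
    if (!"tps" %in% names(est)) est$tps <- "all"
    for (g in dplyr::group_split(dplyr::group_by(est, .data$tps))) {
      base <- tibble(scope = "estimated_vs_measured", parameter = "aggregate",
                     outcome = paste0("mean_tld_error_pct [", g$tps[1], "]"))
      ok <- is.finite(g$total_pct) & is.finite(g$mean_tld_error_pct)
      res <- if (sum(ok) >= 3 && sd(g$total_pct[ok]) > 0 && sd(g$mean_tld_error_pct[ok]) > 0) {
        dplyr::bind_cols(pearson_correlation(g$total_pct[ok], g$mean_tld_error_pct[ok]),
                         computed = TRUE)
      } else {
        dplyr::bind_cols(not_computed("pearson", sum(ok),
                                      "not computed: <3 records or zero variance"),
                         computed = FALSE)
      }
      rows <- c(rows, list(dplyr::bind_cols(base, a = NA_integer_, b = NA_integer_,
                                            c = NA_integer_, d = NA_integer_, res)))
    }
  }

  out <- dplyr::bind_rows(rows)
  out$p_adjusted <- NA_real_
  pp <- out$scope == "parameter" & out$computed
  out$p_adjusted[pp] <- p.adjust(out$p_value[pp], method = "BH")
  out
}
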