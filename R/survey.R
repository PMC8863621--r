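#' Read a community beam-model parameter survey
#'
#' One row per institution and parameter, with the equipment stratum spelled
#' out. Percentile scoring is only meaningful within an equipment stratum
#' (same TPS, linac class, beam energy and MLC make/model), so the stratum
#' columns are required.
#'
#' @param path CSV path with columns `institution_id`, `tps`, `linac_class`,
#'   `beam_energy`, `mlc_model`, `parameter`, `value`, `units` (UTF-8,
#'   header, `.` decimal separator).
#' @return A tibble.
#' @export
read_survey <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("institution_id", "tps", "linac_class", "beam_energy",
                "mlc_model", "parameter", "value")
  missing <- setdiff(required, names(out))
  if (length(missing) > 0) {
    abort(paste0("survey file lacks columns: ", paste(missing, collapse = ", ")),
          class = "beamaudit_invalid")
  }
  out$value <- as.numeric(out$value)
  out
}

#' Build one empirical community distribution
#'
#' Holds the sorted community sample of one parameter within one equipment
#' stratum and supports percentile lookups in both directions. Strata with
#' fewer than `min_sample_size` responses are refused outright: percentile
#' ranks from tiny samples would be scored as if they meant something.
#'
#' @param samples Numeric vector of community parameter values.
#' @param parameter Parameter name.
#' @param tps,linac_class,beam_energy,mlc_model Stratum fields (non-empty).
#' @param units Units string.
#' @param min_sample_size Minimum community sample size (default 5).
#' @return An object of class `survey_dist` with sorted `values` and `n`.
#' @export
fit_distribution <- function(samples, parameter,
                             tps = "unspecified", linac_class = "unspecified",
                             beam_energy = "unspecified", mlc_model = "unspecified",
                             units = "", min_sample_size = 5) {
  if (length(samples) == 0) {
    abort(sprintf("no survey samples supplied for %s", parameter),
          class = "beamaudit_invalid")
  }
  check_finite(samples, sprintf("survey samples for %s", parameter))
  if (length(samples) < min_sample_size) {
    abort(sprintf(
      "stratum %s / %s / %s / %s has %d responses for %s; need at least %d",
      tps, linac_class, beam_energy, mlc_model, length(samples), parameter,
      min_sample_size), class = "beamaudit_small_stratum")
  }
  structure(
    list(parameter = parameter, units = units,
         tps = tps, linac_class = linac_class,
         beam_energy = beam_energy, mlc_model = mlc_model,
         values = sort(samples), n = length(samples)),
    class = "survey_dist"
  )
}

#' @export
print.survey_dist <- function(x, ...) {
  cat(sprintf("<survey_dist> %s (n = %d) in %s / %s / %s / %s\n",
              x$parameter, x$n, x$tps, x$linac_class, x$beam_energy, x$mlc_model))
  print(quantile(x$values, c(0.025, 0.1, 0.5, 0.9, 0.975), type = 7))
  invisible(x)
}

#' Fit community distributions for every stratum and parameter
#'
#' @param survey Survey tibble ([read_survey()] schema).
#' @param min_sample_size Minimum responses per stratum-parameter.
#' @return Tibble with stratum columns, `parameter`, `n` and a `dist`
#'   list-column of `survey_dist` objects. Under-sized strata are dropped
#'   with a warning rather than an error, so a mixed survey can still be
#'   fitted; scoring against a dropped stratum then fails loudly.
#' @export
fit_survey <- function(survey, min_sample_size = 5) {
  grouped <- survey |>
    dplyr::group_by(.data$tps, .data$linac_class, .data$beam_energy,
                    .data$mlc_model, .data$parameter)
  sizes <- dplyr::summarise(grouped, n = dplyr::n(), .groups = "drop")
  small <- dplyr::filter(sizes, .data$n < min_sample_size)
  if (nrow(small) > 0) {
    warn(sprintf("%d stratum-parameter combinations below min_sample_size = %d were dropped",
                 nrow(small), min_sample_size))
  }
  grouped |>
    dplyr::filter(dplyr::n() >= min_sample_size) |>
    dplyr::group_modify(function(.x, .y) {
      tibble(n = nrow(.x), units = (.x$units %||% "")[1] %||% "",
             dist = list(fit_distribution(
               .x$value, parameter = .y$parameter, tps = .y$tps,
               linac_class = .y$linac_class, beam_energy = .y$beam_energy,
               mlc_model = .y$mlc_model, units = (.x$units %||% "")[1] %||% "",
               min_sample_size = min_sample_size)))
    }) |>
    dplyr::ungroup()
}

#' Empirical percentile of a value in a community distribution
#'
#' Inverse of the linear-interpolation (type-7) quantile convention: the
#' percentile `p` such that the type-7 sample quantile at `p` equals the
#' queried value. Values below the sample minimum score 0, above the maximum
#' 100; ties take the midrank percentile.
#'
#' @param dist A `survey_dist`.
#' @param value Numeric vector of parameter values.
#' @return Numeric vector of percentiles in \[0, 100\].
#' @export
percentile_of <- function(dist, value) {
  stopifnot(inherits(dist, "survey_dist"))
  if (length(value) == 0 || any(!is.finite(value))) {
    abort(sprintf("values scored against %s must be finite", dist$parameter),
          class = "beamaudit_invalid")
  }
  x <- dist$values
  n <- length(x)
  vapply(value, function(v) {
    if (v < x[1]) return(0)
    if (v > x[n]) return(100)
    if (n == 1) return(50)
    idx <- which(x == v)
    h <- if (length(idx) > 0) mean(range(idx)) else {
      j <- findInterval(v, x)
      j + (v - x[j]) / (x[j + 1] - x[j])
    }
    100 * (h - 1) / (n - 1)
  }, numeric(1))
}

#' Quantile lookup in a fitted distribution
#'
#' Generic quantile accessor: type-7 sample quantiles for empirical
#' [fit_distribution()] objects, the piecewise-linear inverse CDF for
#' [community_model()] objects.
#'
#' @param dist A `survey_dist` or `community_model`.
#' @param percentile Numeric vector in \[0, 100\].
#' @param ... Passed to methods.
#' @return Numeric vector of parameter values.
#' @export
quantile_of <- function(dist, percentile, ...) UseMethod("quantile_of")

#' @export
quantile_of.survey_dist <- function(dist, percentile, ...) {
  if (any(!is.finite(percentile) | percentile < 0 | percentile > 100)) {
    abort("percentiles must lie in [0, 100]", class = "beamaudit_invalid")
  }
  quantile(dist$values, percentile / 100, type = 7, names = FALSE)
}

#' Flag a percentile as atypical
#'
#' Atypical = the outer 20% of the community: strictly below the low cut or
#' strictly above the high cut (defaults 10 and 90), so a value exactly at
#' the 10th or 90th percentile is typical.
#'
#' @param percentile Numeric vector in \[0, 100\].
#' @param low_cut,high_cut Percentile cuts, `0 <= low_cut < high_cut <= 100`.
#' @return Logical vector.
#' @export
classify_atypical <- function(percentile, low_cut = 10, high_cut = 90) {
  if (!(low_cut >= 0 && low_cut < high_cut && high_cut <= 100)) {
    abort("cuts must satisfy 0 <= low_cut < high_cut <= 100",
          class = "beamaudit_invalid")
  }
  if (any(!is.finite(percentile) | percentile < 0 | percentile > 100)) {
    abort("percentiles must lie in [0, 100]", class = "beamaudit_invalid")
  }
  percentile < low_cut | percentile > high_cut
}

#' Score an institution's beam model against the community
#'
#' Looks up each reported parameter in the matching stratum's community
#' distribution, returns its percentile and atypicality flag. Parameters in
#' the catalog but lacking a community distribution in that stratum are an
#' error (the report cannot be scored); parameters absent from the anchor
#' catalog are carried through unscored (`percentile = NA`) with a warning.
#'
#' @param report Tibble, one row per reported parameter: `institution_id`,
#'   stratum columns, `parameter`, `value`.
#' @param survey Fitted survey ([fit_survey()]) or raw survey tibble.
#' @param catalog Anchor catalog used to decide which parameters are
#'   scoreable; defaults to the shipped catalog. `NULL` scores everything.
#' @param low_cut,high_cut Atypicality cuts (see [classify_atypical()]).
#' @param min_sample_size Passed to [fit_survey()] when `survey` is raw.
#' @return Tibble: `institution_id`, stratum columns, `parameter`, `value`,
#'   `percentile`, `atypical`, `scored`. Institution-level "any atypical"
#'   flags are one `dplyr::summarise()` away (see [run_audit_analysis()]).
#' @export
score_report <- function(report, survey, catalog = load_anchors(),
                         low_cut = 10, high_cut = 90, min_sample_size = 5) {
  if (!"dist" %in% names(survey)) {
    survey <- fit_survey(survey, min_sample_size = min_sample_size)
  }
  report <- as_tibble(report)
  if (!is.null(catalog)) {
    ckey <- unique(paste(norm_field(catalog$tps), norm_field(catalog$parameter), sep = "|"))
    in_catalog <- paste(norm_field(report$tps), norm_field(report$parameter), sep = "|") %in% ckey
    if (any(!in_catalog)) {
      warn(paste0("parameters not in the catalog are carried through unscored: ",
                  paste(unique(report$parameter[!in_catalog]), collapse = ", ")))
    }
  } else {
    in_catalog <- rep(TRUE, nrow(report))
  }
  skey <- stratum_key(survey$tps, survey$linac_class, survey$beam_energy, survey$mlc_model)
  skey <- paste(skey, norm_field(survey$parameter), sep = "|")
  rkey <- paste(stratum_key(report$tps, report$linac_class, report$beam_energy,
                            report$mlc_model), norm_field(report$parameter), sep = "|")
  match_idx <- match(rkey, skey)
  unmatched <- in_catalog & is.na(match_idx)
  if (any(unmatched)) {
    abort(paste0("no community distribution in the matching stratum for: ",
                 paste(unique(report$parameter[unmatched]), collapse = ", ")),
          class = "beamaudit_missing_distribution")
  }
  report$scored <- in_catalog
  report$percentile <- NA_real_
  idx <- which(in_catalog)
  if (length(idx) > 0) {
    report$percentile[idx] <- purrr::map2_dbl(
      match_idx[idx], report$value[idx],
      function(i, v) percentile_of(survey$dist[[i]], v)
    )
  }
  report$atypical <- ifelse(report$scored,
                            classify_atypical(dplyr::coalesce(report$percentile, 50),
                                              low_cut, high_cut),
                            NA)
  report
}

#' Correlation between two parameters across institutions
#'
#' Pearson correlation of two parameters over the institutions reporting
#' both (complete pairs), e.g. to check whether institutions using a high
#' DLG also tend to use a high MLC transmission factor.
#'
#' @param reports Long tibble with `institution_id`, `parameter`, `value`.
#' @param param_a,param_b Parameter names.
#' @return A one-row `TestResult` tibble (see [pearson_correlation()]).
#' @export
parameter_correlation <- function(reports, param_a, param_b) {
  wide <- reports |>
    dplyr::filter(norm_field(.data$parameter) %in% norm_field(c(param_a, param_b))) |>
    dplyr::mutate(which = ifelse(norm_field(.data$parameter) == norm_field(param_a), "a", "b")) |>
    dplyr::distinct(.data$institution_id, .data$which, .keep_all = TRUE) |>
    tidyr::pivot_wider(id_cols = "institution_id", names_from = "which",
                       values_from = "value") |>
    tidyr::drop_na()
  if (!all(c("a", "b") %in% names(wide)) || nrow(wide) < 3) {
    abort(sprintf("need at least 3 institutions reporting both %s and %s",
                  param_a, param_b), class = "beamaudit_invalid")
  }
  pearson_correlation(wide$a, wide$b)
}
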