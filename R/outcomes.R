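#' Read a phantom-audit CSV
#'
#' One row per TLD measurement. Film results enter as a precomputed
#' `film_pass_pct` column (as audit exports provide); full film grids are
#' analysed separately with [gamma_pass_rate()].
#'
#' @param path CSV with columns `institution_id`, `phantom`, `tld_label`,
#'   `measured_dose_gy`, `calculated_dose_gy`, optional `film_pass_pct`,
#'   `localization_offset_mm`, plus stratum columns when available.
#' @return A tibble.
#' @export
read_audit <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("institution_id", "phantom", "measured_dose_gy", "calculated_dose_gy")
  missing <- setdiff(required, names(out))
  if (length(missing) > 0) {
    abort(paste0("audit file lacks columns: ", paste(missing, collapse = ", ")),
          class = "beamaudit_invalid")
  }
  out
}

#' Signed TLD dose-calculation error
#'
#' `100 * (calculated - measured) / measured`: the percent by which the TPS
#' calculation exceeds the delivered (measured) dose. Positive = the TPS
#' overestimates dose.
#'
#' @param measured,calculated Positive doses in Gy (vectorized).
#' @return Signed percent error.
#' @examples
#' tld_error(2.00, 2.14)  # +7
#' @export
tld_error <- function(measured, calculated) {
  check_finite(calculated, "calculated doses")
  if (length(measured) == 0 || any(!is.finite(measured)) || any(measured <= 0)) {
    abort("measured doses must be finite and positive", class = "beamaudit_invalid")
  }
  100 * (calculated - measured) / measured
}

#' Global gamma-index pass rate of a film dose comparison
#'
#' For every measured point above the low-dose threshold (a fraction of the
#' calculated grid's maximum), the gamma index is the minimum over nearby
#' calculated points of `sqrt((dose difference / DD)^2 + (distance / DTA)^2)`
#' with the dose tolerance `DD = dose_diff_pct` of the calculated maximum
#' (global normalization). A point passes when gamma <= 1; the pass rate is
#' the percentage of evaluated points passing. The search is discrete over
#' grid points within a 3 x DTA radius (no subpixel interpolation), which is
#' adequate at the <= 1 mm spacings used here.
#'
#' @param measured,calculated Same-shaped numeric vectors (1-D profiles) or
#'   matrices (2-D planes) of dose in Gy.
#' @param spacing_mm Grid spacing in mm (> 0).
#' @param dose_diff_pct Dose-difference criterion in percent (e.g. 5 or 7).
#' @param dta_mm Distance-to-agreement criterion in mm (e.g. 3 or 4).
#' @param low_dose_threshold Fraction of the calculated maximum below which
#'   measured points are not evaluated (default 0.20).
#' @return Pass rate in percent, in \[0, 100\].
#' @examples
#' gamma_pass_rate(rep(1.94, 25), rep(2, 25), spacing_mm = 1,
#'                 dose_diff_pct = 5, dta_mm = 3)  # 100: gamma ~ 0.6
#' @export
gamma_pass_rate <- function(measured, calculated, spacing_mm,
                            dose_diff_pct, dta_mm,
                            low_dose_threshold = 0.20) {
  if (!identical(dim(measured) %||% length(measured),
                 dim(calculated) %||% length(calculated))) {
    abort("measured and calculated grids must have the same shape",
          class = "beamaudit_invalid")
  }
  if (spacing_mm <= 0 || dose_diff_pct <= 0 || dta_mm <= 0) {
    abort("spacing and gamma criteria must be positive", class = "beamaudit_invalid")
  }
  check_finite(measured, "measured grid")
  check_finite(calculated, "calculated grid")
  dmax <- max(calculated)
  dd <- dose_diff_pct / 100 * dmax
  eval_mask <- measured > low_dose_threshold * dmax
  if (!any(eval_mask)) {
    abort("all measured points fall below the low-dose threshold",
          class = "beamaudit_invalid")
  }
  two_d <- is.matrix(measured)
  k <- floor(3 * dta_mm / spacing_mm)
  offsets <- if (two_d) {
    expand.grid(dx = -k:k, dy = -k:k)
  } else {
    data.frame(dx = -k:k, dy = 0L)
  }
  offsets$dist <- spacing_mm * sqrt(offsets$dx^2 + offsets$dy^2)
  offsets <- offsets[offsets$dist <= 3 * dta_mm, , drop = FALSE]
  gamma2 <- array(Inf, dim = dim(measured) %||% length(measured))
  nr <- if (two_d) nrow(measured) else length(measured)
  nc <- if (two_d) ncol(measured) else 1L
  for (o in seq_len(nrow(offsets))) {
    dx <- offsets$dx[o]; dy <- offsets$dy[o]
    shifted <- array(NA_real_, dim = dim(gamma2))
    src_r <- seq_len(nr) + dx
    ok_r <- src_r >= 1 & src_r <= nr
    if (two_d) {
      src_c <- seq_len(nc) + dy
      ok_c <- src_c >= 1 & src_c <= nc
      shifted[ok_r, ok_c] <- calculated[src_r[ok_r], src_c[ok_c]]
    } else {
      shifted[ok_r] <- calculated[src_r[ok_r]]
    }
    cand <- ((shifted - measured) / dd)^2 + (offsets$dist[o] / dta_mm)^2
    gamma2 <- pmin(gamma2, cand, na.rm = TRUE)
  }
  100 * mean(gamma2[eval_mask] <= 1 + 1e-12)
}

#' Classify phantom-audit outcomes per irradiation
#'
#' Aggregates TLD rows per irradiation and applies the audit criteria:
#' *failing* when any TLD error magnitude exceeds `fail_tld_pct` (default
#' 7%) or, if film results are present, the film gamma pass rate falls below
#' `film_pass_min` (default 85%); *poor* when any TLD error magnitude
#' exceeds `poor_tld_pct` (default 5%) or the irradiation fails. Failing
#' therefore always implies poor.
#'
#' @param audit TLD-level tibble ([read_audit()] schema).
#' @param fail_tld_pct,poor_tld_pct TLD error thresholds (percent).
#' @param film_pass_min Minimum film gamma pass rate (percent).
#' @param use_film Include the film criterion in `failing` (default TRUE;
#'   set FALSE to reproduce a TLD-only failing definition).
#' @param id_cols Columns identifying one irradiation.
#' @return One row per irradiation with `n_tld`, `mean_tld_error_pct`,
#'   `max_abs_tld_error_pct`, `film_pass_pct`, `failing`, `poor`, plus any
#'   stratum/localization columns constant within the irradiation.
#' @export
classify_outcomes <- function(audit, fail_tld_pct = 7, poor_tld_pct = 5,
                              film_pass_min = 85, use_film = TRUE,
                              id_cols = "institution_id") {
  if (fail_tld_pct < poor_tld_pct) {
    abort("fail_tld_pct must be >= poor_tld_pct", class = "beamaudit_invalid")
  }
  audit <- dplyr::mutate(audit,
                         .err = tld_error(.data$measured_dose_gy, .data$calculated_dose_gy))
  carry <- intersect(c("phantom", "tps", "linac_class", "beam_energy", "mlc_model",
                       "localization_offset_mm", "film_pass_pct"), names(audit))
  audit |>
    dplyr::group_by(dplyr::across(dplyr::all_of(id_cols))) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(carry), dplyr::first),
      n_tld = dplyr::n(),
      mean_tld_error_pct = mean(.data$.err),
      max_abs_tld_error_pct = max(abs(.data$.err)),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      film_pass_pct = if ("film_pass_pct" %in% carry) .data$film_pass_pct else NA_real_,
      film_fail = use_film & !is.na(.data$film_pass_pct) & .data$film_pass_pct < film_pass_min,
      failing = .data$max_abs_tld_error_pct > fail_tld_pct | .data$film_fail,
      poor = .data$max_abs_tld_error_pct > poor_tld_pct | .data$failing
    ) |>
    dplyr::select(-"film_fail")
}

#' Partition audits by localization error
#'
#' Irradiations whose film-derived setup offset exceeds `max_offset_mm`
#' (strictly; default 3 mm) are excluded from dose-error estimation, since
#' their phantom error is dominated by mispositioning rather than dose
#' calculation.
#'
#' @param records Per-irradiation tibble with `localization_offset_mm`.
#' @param max_offset_mm Exclusion threshold in mm.
#' @return `list(kept = ..., excluded = ...)`, both tibbles, input order
#'   preserved.
#' @export
exclude_localization <- function(records, max_offset_mm = 3) {
  off <- records$localization_offset_mm
  if (is.null(off)) {
    abort("records lack a localization_offset_mm column", class = "beamaudit_invalid")
  }
  if (any(!is.finite(off)) || any(off < 0)) {
    abort("localization offsets must be finite and >= 0", class = "beamaudit_invalid")
  }
  out <- off > max_offset_mm
  list(kept = records[!out, , drop = FALSE],
       excluded = records[out, , drop = FALSE])
}
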