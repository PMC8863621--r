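#' Load the per-parameter dose-effect anchor catalog
#'
#' Reads the anchor catalog shipped with the package (or a user override) into
#' a long tibble: one row per TPS, parameter and percentile anchor. Each
#' anchor ties a community percentile of a beam-model parameter to the
#' parameter value at that percentile and to the systematic dose effect (in
#' percent, relative to the community-median beam model) that value produces
#' in a head-and-neck IMRT phantom plan. The dose effect at the 50th
#' percentile is 0 by definition; because published tables omit the median
#' parameter value itself, the shipped file carries a configured
#' `median_value` per parameter (`median_source = "configured"`), which an
#' override file may replace with a site- or survey-specific median.
#'
#' Parameters surveyed as linked pairs (e.g. source size X and Y) appear as
#' two catalog entries sharing one anchor table, identified by
#' `shared_group`.
#'
#' @param path Path to an anchor JSON file. Defaults to the catalog shipped
#'   in `inst/extdata/beam_anchor_catalog.json`.
#' @return A tibble with columns `tps`, `parameter`, `units`, `shared_group`,
#'   `median_source`, `percentile`, `value`, `effect_pct`, validated by
#'   [validate_anchors()].
#' @examples
#' anchors <- load_anchors()
#' dplyr::filter(anchors, parameter == "Dosimetric Leaf Gap")
#' @export
load_anchors <- function(path = default_anchor_path()) {
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  out <- purrr::map_dfr(raw, function(rec) {
    anc <- purrr::map_dfr(rec$anchors, as_tibble)
    tibble(
      tps = rec$tps,
      parameter = rec$parameter,
      units = rec$units %||% "",
      shared_group = (rec$shared_group %||% NA_character_) %||% NA_character_,
      median_source = rec$median_source %||% "configured",
      percentile = anc$percentile,
      value = anc$value,
      effect_pct = anc$effect_pct
    )
  })
  out$shared_group <- as.character(out$shared_group)
  validate_anchors(out)
}

default_anchor_path <- function() {
  system.file("extdata", "beam_anchor_catalog.json", package = "beamaudit",
              mustWork = TRUE)
}

#' Validate an anchor catalog
#'
#' Checks the invariants every anchor table must satisfy before it can back
#' an effect model: the five percentiles 2.5/10/50/90/97.5 present for each
#' (TPS, parameter), anchors sorted by percentile with parameter values
#' non-decreasing, all values finite, and the 50th-percentile dose effect
#' exactly 0 (the community median is the baseline of the effect scale).
#'
#' @param anchors A long anchor tibble as returned by [load_anchors()].
#' @return The input, invisibly unchanged, for piping.
#' @export
validate_anchors <- function(anchors) {
  required <- c("tps", "parameter", "percentile", "value", "effect_pct")
  missing <- setdiff(required, names(anchors))
  if (length(missing) > 0) {
    abort(paste0("anchor table lacks columns: ", paste(missing, collapse = ", ")),
          class = "beamaudit_invalid")
  }
  check_finite(anchors$value, "anchor values")
  check_finite(anchors$effect_pct, "anchor effects")
  split_df <- dplyr::group_split(dplyr::group_by(anchors, .data$tps, .data$parameter))
  for (g in split_df) {
    id <- sprintf("%s / %s", g$tps[1], g$parameter[1])
    g <- dplyr::arrange(g, .data$percentile)
    need <- c(2.5, 10, 50, 90, 97.5)
    if (!all(need %in% g$percentile)) {
      abort(sprintf("anchor table for %s must include percentiles 2.5, 10, 50, 90, 97.5", id),
            class = "beamaudit_invalid")
    }
    if (is.unsorted(g$value)) {
      abort(sprintf("anchor values for %s must be non-decreasing with percentile", id),
            class = "beamaudit_invalid")
    }
    e50 <- g$effect_pct[g$percentile == 50]
    if (any(e50 != 0)) {
      abort(sprintf("the 50th-percentile dose effect for %s must be 0 (median baseline)", id),
            class = "beamaudit_invalid")
    }
  }
  invisible(anchors)
}

#' Identify parameters with a dose impact exceeding a threshold
#'
#' A parameter is *impactful* when the magnitude of its dose effect exceeds
#' `threshold_pct` somewhere over the community spread, i.e.
#' `max(|effect_pct|)` over its anchors is greater than the threshold
#' (default 1% dose).
#'
#' @param anchors Anchor catalog tibble ([load_anchors()]).
#' @param threshold_pct Impact threshold on `|effect_pct|`, in percent dose.
#' @return Tibble with one row per impactful (TPS, parameter):
#'   `tps`, `parameter`, `max_abs_effect_pct`.
#' @examples
#' impactful_parameters(load_anchors())
#' @export
impactful_parameters <- function(anchors, threshold_pct = 1) {
  validate_anchors(anchors)
  anchors |>
    dplyr::group_by(.data$tps, .data$parameter) |>
    dplyr::summarise(max_abs_effect_pct = max(abs(.data$effect_pct)), .groups = "drop") |>
    dplyr::filter(.data$max_abs_effect_pct > threshold_pct)
}
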