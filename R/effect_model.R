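#' Build a piecewise-linear dose-effect model for one parameter
#'
#' Turns the percentile anchors of one (TPS, parameter) into a callable dose
#' response: the predicted systematic dose effect (percent, positive = the
#' TPS overestimates delivered dose) as a piecewise-linear function of the
#' parameter *value*, anchored at the 2.5th/10th/50th/90th/97.5th community
#' percentiles with 0% at the median. Outside the 2.5th–97.5th value range
#' the effect is clamped to the terminal anchor effects: dose effects are
#' characterized only over the reported community spread, so no
#' extrapolation is attempted. Degenerate segments (equal values at adjacent
#' percentiles) collapse to a single point carrying the lower-percentile
#' anchor's effect.
#'
#' @param anchors Anchor tibble rows for exactly one TPS/parameter
#'   combination (columns `percentile`, `value`, `effect_pct`, plus `tps`,
#'   `parameter`, `units`).
#' @return An object of class `effect_model`.
#' @examples
#' dlg <- load_anchors() |>
#'   dplyr::filter(tps == "Eclipse AAA", parameter == "Dosimetric Leaf Gap") |>
#'   build_effect_model()
#' effect_at_value(dlg, 0.2000)  # +1.2
#' @export
build_effect_model <- function(anchors) {
  if (length(unique(paste(anchors$tps, anchors$parameter))) != 1) {
    abort("build_effect_model() expects anchors for exactly one TPS/parameter",
          class = "beamaudit_invalid")
  }
  validate_anchors(anchors)
  anchors <- dplyr::arrange(anchors, .data$percentile)
  if (!50 %in% anchors$percentile || !is.finite(anchors$value[anchors$percentile == 50])) {
    abort(sprintf("missing 50th-percentile anchor value for %s", anchors$parameter[1]),
          class = "beamaudit_invalid")
  }
  # collapse degenerate segments, keeping the lower-percentile anchor
  keep <- !duplicated(anchors$value)
  structure(
    list(
      tps = anchors$tps[1],
      parameter = anchors$parameter[1],
      units = anchors$units[1] %||% "",
      percentile = anchors$percentile,
      value = anchors$value,
      effect_pct = anchors$effect_pct,
      node_value = anchors$value[keep],
      node_effect = anchors$effect_pct[keep]
    ),
    class = "effect_model"
  )
}

#' @export
print.effect_model <- function(x, ...) {
  cat(sprintf("<effect_model> %s / %s [%s]\n", x$tps, x$parameter, x$units))
  print(tidy(x))
  invisible(x)
}

#' @method tidy effect_model
#' @export
tidy.effect_model <- function(x, ...) {
  tibble(tps = x$tps, parameter = x$parameter, units = x$units,
         percentile = x$percentile, value = x$value, effect_pct = x$effect_pct)
}

#' Evaluate the dose effect of a parameter value
#'
#' Piecewise-linear interpolation of the anchor (value, effect) nodes,
#' clamped to the terminal anchor effects outside the anchored value range.
#'
#' @param model An [build_effect_model()] object.
#' @param value Numeric vector of parameter values (model units).
#' @return Numeric vector of signed dose effects in percent.
#' @export
effect_at_value <- function(model, value) {
  stopifnot(inherits(model, "effect_model"))
  if (length(value) == 0 || any(!is.finite(value))) {
    abort(sprintf("parameter values for %s must be finite", model$parameter),
          class = "beamaudit_invalid")
  }
  if (length(model$node_value) == 1) {
    return(rep(model$node_effect, length(value)))
  }
  approx(model$node_value, model$node_effect, xout = value,
         method = "linear", rule = 2)$y
}

#' Evaluate the dose effect at a community percentile
#'
#' Converts the percentile to a parameter value through the distribution's
#' quantile function ([quantile_of()]), then applies [effect_at_value()].
#' With a distribution whose quantiles coincide with the anchor values this
#' reproduces the anchor effects exactly (e.g. the 90th percentile of the
#' community DLG distribution maps to the +1.2% anchor).
#'
#' @param model An `effect_model`.
#' @param dist A [fit_distribution()] survey distribution or a
#'   [community_model()] (for the latter the model's parameter is used).
#' @param percentile Numeric vector of percentiles in \[0, 100\].
#' @return Numeric vector of signed dose effects in percent.
#' @export
effect_at_percentile <- function(model, dist, percentile) {
  if (any(!is.finite(percentile) | percentile < 0 | percentile > 100)) {
    abort("percentiles must lie in [0, 100]", class = "beamaudit_invalid")
  }
  value <- if (inherits(dist, "community_model")) {
    quantile_of(dist, percentile, parameter = model$parameter)
  } else {
    quantile_of(dist, percentile)
  }
  effect_at_value(model, value)
}

#' Build effect models for a whole anchor catalog
#'
#' @param anchors Anchor catalog tibble ([load_anchors()]).
#' @return A tibble of class `effect_model_set`: one row per TPS/parameter
#'   with a `model` list-column of `effect_model` objects.
#' @export
build_effect_models <- function(anchors) {
  validate_anchors(anchors)
  out <- anchors |>
    dplyr::group_by(.data$tps, .data$parameter) |>
    dplyr::group_modify(~ tibble(units = .x$units[1], model = list(build_effect_model(
      dplyr::mutate(.x, tps = .y$tps, parameter = .y$parameter)
    )))) |>
    dplyr::ungroup()
  class(out) <- c("effect_model_set", class(out))
  out
}

lookup_model <- function(models, tps, parameter) {
  hit <- models$model[norm_field(models$tps) == norm_field(tps) &
                        norm_field(models$parameter) == norm_field(parameter)]
  if (length(hit) == 0) {
    abort(sprintf("no effect model for %s / %s", tps, parameter),
          class = "beamaudit_missing_model")
  }
  hit[[1]]
}

#' Predict per-parameter dose effects for reported values
#'
#' Data-frame-first wrapper over [effect_at_value()]: one row in, one row
#' out, with the signed dose effect appended. Reported parameters without a
#' catalog model are dropped with a warning (they cannot contribute to the
#' dose-error estimate), mirroring how uncatalogued survey responses are
#' excluded from scoring.
#'
#' @param data Tibble with columns `tps`, `parameter`, `value` (extra
#'   columns such as `institution_id` are carried through).
#' @param models An `effect_model_set` from [build_effect_models()].
#' @return `data` restricted to modeled parameters, with `effect_pct` added.
#' @export
predict_effects <- function(data, models) {
  stopifnot(inherits(models, "effect_model_set"))
  key <- paste(norm_field(data$tps), norm_field(data$parameter), sep = "|")
  mkey <- paste(norm_field(models$tps), norm_field(models$parameter), sep = "|")
  known <- key %in% mkey
  if (any(!known)) {
    warn(paste0("no effect model for: ",
                paste(unique(data$parameter[!known]), collapse = ", "),
                " - excluded from dose-error estimation"))
  }
  kept <- data[known, , drop = FALSE]
  kept$effect_pct <- purrr::map2_dbl(
    paste(kept$tps, kept$parameter, sep = "|"), kept$value,
    function(k, v) {
      parts <- strsplit(k, "|", fixed = TRUE)[[1]]
      effect_at_value(lookup_model(models, parts[1], parts[2]), v)
    }
  )
  as_tibble(kept)
}

#' Aggregate independent per-parameter dose effects
#'
#' Per-parameter dose effects are independent (a property established for
#' these TPS parameters by phantom dose recalculations), so an institution's
#' predicted systematic TPS error is the exact arithmetic sum of its
#' per-parameter effects. An empty component list aggregates to 0; duplicate
#' parameters within one institution are an error.
#'
#' @param effects Tibble with columns `parameter` and `effect_pct`, and
#'   optionally `institution_id` (aggregation is then per institution).
#' @return Tibble with `institution_id` (if present), `n_parameters`,
#'   `total_pct`.
#' @examples
#' aggregate_error(tibble::tibble(
#'   parameter = c("Dosimetric Leaf Gap", "MLC Transmission Factor"),
#'   effect_pct = c(1.2, 0.2)
#' ))  # total_pct = 1.4
#' @export
aggregate_error <- function(effects) {
  if (nrow(effects) == 0) {
    return(tibble(n_parameters = 0L, total_pct = 0))
  }
  check_finite(effects$effect_pct, "component effects")
  grouped <- if ("institution_id" %in% names(effects)) {
    dplyr::group_by(effects, .data$institution_id)
  } else {
    effects
  }
  dup <- dplyr::filter(dplyr::count(grouped, .data$parameter), .data$n > 1)
  if (nrow(dup) > 0) {
    abort(paste0("duplicate parameter in aggregation: ",
                 paste(unique(dup$parameter), collapse = ", ")),
          class = "beamaudit_invalid")
  }
  dplyr::summarise(grouped,
                   n_parameters = dplyr::n(),
                   total_pct = sum(.data$effect_pct),
                   .groups = "drop") |> as_tibble()
}

#' Plot a dose-effect model
#'
#' @param object An `effect_model`.
#' @param ... Unused.
#' @return A ggplot: dose effect vs parameter value with anchor points.
#' @method autoplot effect_model
#' @export
autoplot.effect_model <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$value, y = .data$effect_pct)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(shape = factor(.data$percentile)), size = 2) +
    ggplot2::labs(
      x = sprintf("%s [%s]", object$parameter, object$units),
      y = "Predicted dose effect (%)",
      shape = "Community percentile",
      title = sprintf("%s: %s dose response", object$tps, object$parameter)
    ) +
    ggplot2::theme_minimal()
}

#' @method autoplot effect_model_set
#' @export
autoplot.effect_model_set <- function(object, ...) {
  td <- purrr::map_dfr(object$model, tidy)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$value, y = .data$effect_pct)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~ tps + parameter, scales = "free_x") +
    ggplot2::labs(x = "Parameter value", y = "Predicted dose effect (%)") +
    ggplot2::theme_minimal()
}
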