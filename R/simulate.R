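#' Community model: anchor-implied parameter distributions
#'
#' Defines the community distribution of each beam-model parameter in one
#' equipment stratum by the weakest assumption consistent with the published
#' quantiles: the inverse CDF is piecewise linear through the (percentile,
#' value) anchors — including the configured median — and flat beyond the
#' 2.5th/97.5th percentiles. Parametric alternatives can be substituted by
#' supplying a different anchor table.
#'
#' @param anchors Anchor catalog tibble ([load_anchors()]).
#' @param tps TPS name selecting the catalog subset (e.g. `"Eclipse AAA"`).
#' @param linac_class,beam_energy,mlc_model Stratum labels attached to
#'   generated surveys (defaults describe the common base Varian
#'   configuration the anchors were characterized on).
#' @return An object of class `community_model`.
#' @export
community_model <- function(anchors, tps,
                            linac_class = "Varian Base",
                            beam_energy = "6 MV",
                            mlc_model = "Millennium120") {
  validate_anchors(anchors)
  sub <- dplyr::filter(anchors, norm_field(.data$tps) == norm_field(!!tps))
  if (nrow(sub) == 0) {
    abort(sprintf("no anchors for TPS '%s'", tps), class = "beamaudit_invalid")
  }
  params <- lapply(split(sub, sub$parameter), function(g) {
    g <- dplyr::arrange(g, .data$percentile)
    list(p = g$percentile, v = g$value, units = g$units[1])
  })
  structure(
    list(tps = sub$tps[1], linac_class = linac_class,
         beam_energy = beam_energy, mlc_model = mlc_model,
         params = params),
    class = "community_model"
  )
}

#' @export
print.community_model <- function(x, ...) {
  cat(sprintf("<community_model> %s (%s / %s / %s), %d parameters\n",
              x$tps, x$linac_class, x$beam_energy, x$mlc_model,
              length(x$params)))
  invisible(x)
}

#' @rdname quantile_of
#' @param parameter Parameter name (required for `community_model`).
#' @export
quantile_of.community_model <- function(dist, percentile, parameter, ...) {
  if (any(!is.finite(percentile) | percentile < 0 | percentile > 100)) {
    abort("percentiles must lie in [0, 100]", class = "beamaudit_invalid")
  }
  spec <- dist$params[[parameter]]
  if (is.null(spec)) {
    abort(sprintf("community model has no parameter '%s'", parameter),
          class = "beamaudit_invalid")
  }
  # flat extension beyond the 2.5th/97.5th anchors
  approx(spec$p, spec$v, xout = percentile, method = "linear", rule = 2)$y
}

check_rank_correlation <- function(R, param_names) {
  if (is.null(R)) return(NULL)
  if (!is.matrix(R) || nrow(R) != ncol(R) || any(abs(R - t(R)) > 1e-12) ||
      any(abs(diag(R) - 1) > 1e-12)) {
    abort("rank correlation matrix must be symmetric with unit diagonal",
          class = "beamaudit_invalid")
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    abort("rank correlation matrix must be positive semi-definite",
          class = "beamaudit_invalid")
  }
  if (is.null(rownames(R)) || !all(rownames(R) %in% param_names)) {
    abort("rank correlation matrix rows must be named after model parameters",
          class = "beamaudit_invalid")
  }
  R
}

#' Sample community survey responses
#'
#' Independent draws per parameter via inverse-CDF sampling of uniforms; if
#' a rank-correlation matrix is given, the named parameters share a
#' Gaussian copula on ranks (the remaining parameters stay independent),
#' mimicking observed couplings such as DLG with MLC transmission without
#' asserting a joint parametric family.
#'
#' @param community A [community_model()].
#' @param n Number of respondents (>= 1).
#' @param seed Optional integer seed for reproducibility.
#' @param rank_correlation Optional correlation matrix with dimnames drawn
#'   from the model's parameter names.
#' @return A wide tibble: `respondent` plus one column per parameter.
#' @export
sample_community <- function(community, n, seed = NULL, rank_correlation = NULL) {
  stopifnot(inherits(community, "community_model"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  pnames <- names(community$params)
  R <- check_rank_correlation(rank_correlation, pnames)
  u <- matrix(runif(n * length(pnames)), nrow = n,
              dimnames = list(NULL, pnames))
  if (!is.null(R)) {
    cn <- rownames(R)
    z <- matrix(rnorm(n * length(cn)), nrow = n) %*% chol(R + diag(1e-12, nrow(R)))
    u[, cn] <- pnorm(z)
  }
  draws <- purrr::imap(community$params, function(spec, nm) {
    approx(spec$p / 100, spec$v, xout = u[, nm], method = "linear", rule = 2)$y
  })
  dplyr::bind_cols(tibble(respondent = seq_len(n)), as_tibble(draws))
}

#' Sample institutional beam-model reports from a community
#'
#' Each institution draws one value per parameter from the community model
#' (with optional rank correlation across parameters), producing survey-
#' style long records ready for [score_report()].
#'
#' @inheritParams sample_community
#' @param n_institutions Number of institutions (0 allowed).
#' @param id_prefix Prefix for generated institution ids.
#' @return Long tibble: `institution_id`, stratum columns, `parameter`,
#'   `value`, `units`.
#' @export
sample_institutions <- function(community, n_institutions, seed = NULL,
                                rank_correlation = NULL, id_prefix = "inst") {
  if (n_institutions == 0) {
    return(tibble(institution_id = character(), tps = character(),
                  linac_class = character(), beam_energy = character(),
                  mlc_model = character(), parameter = character(),
                  value = numeric(), units = character()))
  }
  wide <- sample_community(community, n_institutions, seed = seed,
                           rank_correlation = rank_correlation)
  units <- purrr::map_chr(community$params, "units")
  wide |>
    dplyr::mutate(institution_id = sprintf("%s%04d", id_prefix, .data$respondent)) |>
    dplyr::select(-"respondent") |>
    tidyr::pivot_longer(-"institution_id", names_to = "parameter",
                        values_to = "value") |>
    dplyr::mutate(tps = community$tps, linac_class = community$linac_class,
                  beam_energy = community$beam_energy,
                  mlc_model = community$mlc_model,
                  units = unname(units[.data$parameter])) |>
    dplyr::select("institution_id", "tps", "linac_class", "beam_energy",
                  "mlc_model", "parameter", "value", "units")
}

#' Configuration of a synthetic phantom-audit cohort
#'
#' Defaults emulate the shape of the study cohort: 337 audits, a phantom
#' mix of 258 head-and-neck / 34 spine / 45 prostate, a small rate of gross
#' localization errors (11/337), nominal 2 Gy TLD doses with 1% per-TLD
#' measurement noise, and a 2% SD of residual (non-TPS) systematic error.
#'
#' @param n_institutions Number of audited institutions.
#' @param sigma_residual_pct SD (percent dose) of systematic error modes not
#'   attributable to beam modeling (beam data, calibration, delivery, ...).
#' @param tld_noise_pct Per-TLD measurement SD in percent.
#' @param n_tld_per_phantom TLDs per irradiation (>= 1).
#' @param localization_error_prob Probability of a gross setup error.
#' @param localization_offset_range_mm Offset range (mm) for gross errors;
#'   non-error audits draw offsets uniformly below the exclusion cut.
#' @param phantom_mix Named probabilities over
#'   `c("head_and_neck", "spine", "prostate")`; must sum to 1.
#' @param seed Master seed; per-institution substreams are derived from it.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_institutions = 337,
                          sigma_residual_pct = 2,
                          tld_noise_pct = 1,
                          n_tld_per_phantom = 8,
                          localization_error_prob = 11 / 337,
                          localization_offset_range_mm = c(3, 10),
                          phantom_mix = c(head_and_neck = 258, spine = 34,
                                          prostate = 45) / 337,
                          seed = 1L) {
  if (abs(sum(phantom_mix) - 1) > 1e-8 || any(phantom_mix < 0)) {
    abort("phantom_mix must be non-negative and sum to 1", class = "beamaudit_invalid")
  }
  if (sigma_residual_pct < 0 || tld_noise_pct < 0 || n_tld_per_phantom < 1 ||
      localization_error_prob < 0 || localization_error_prob > 1 ||
      diff(localization_offset_range_mm) < 0) {
    abort("invalid cohort configuration", class = "beamaudit_invalid")
  }
  structure(list(
    n_institutions = n_institutions,
    sigma_residual_pct = sigma_residual_pct,
    tld_noise_pct = tld_noise_pct,
    n_tld_per_phantom = n_tld_per_phantom,
    localization_error_prob = localization_error_prob,
    localization_offset_range_mm = localization_offset_range_mm,
    phantom_mix = phantom_mix,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Simulate phantom audits for reported beam models
#'
#' For each institution the true systematic TPS error is the additive
#' aggregate of its per-parameter dose effects (the generative model mirrors
#' the estimator: linear per-parameter response, independent effects), plus
#' a Gaussian residual representing non-TPS error modes. Each TLD reads a
#' nominal 2 Gy scaled by measurement noise, and the calculated dose is the
#' measured dose times `1 + E/100` plus per-TLD noise, so the sign
#' convention round-trips through [tld_error()]. Localization offsets are
#' drawn independently of dose error. All draws derive from per-institution
#' substreams of the master seed.
#'
#' @param reports Long institution reports ([sample_institutions()] schema).
#' @param models An `effect_model_set` covering the reported parameters.
#' @param config A [cohort_config()].
#' @return `list(audit = <one row per TLD>, truth = <one row per
#'   institution with `aggregate_pct`, `residual_pct`, `true_error_pct`>)`.
#' @export
simulate_audits <- function(reports, models, config) {
  stopifnot(inherits(config, "cohort_config"))
  effects <- predict_effects(reports, models)
  agg <- aggregate_error(effects)
  ids <- unique(reports$institution_id)
  if (!all(ids %in% agg$institution_id)) {
    abort("missing effect model for at least one institution's parameters",
          class = "beamaudit_missing_model")
  }
  stratum <- reports |>
    dplyr::distinct(.data$institution_id, .data$tps, .data$linac_class,
                    .data$beam_energy, .data$mlc_model)
  phantoms <- names(config$phantom_mix)
  per_inst <- purrr::map(seq_along(ids), function(i) {
    set.seed(derive_seed(config$seed, i))
    id <- ids[i]
    e_agg <- agg$total_pct[agg$institution_id == id]
    resid <- rnorm(1, 0, config$sigma_residual_pct)
    e_true <- e_agg + resid
    n_tld <- config$n_tld_per_phantom
    eta <- rnorm(n_tld, 0, config$tld_noise_pct / 100)
    eps <- rnorm(n_tld, 0, config$tld_noise_pct / 100)
    measured <- 2 * (1 + eta)
    calculated <- measured * (1 + e_true / 100 + eps)
    phantom <- sample(phantoms, 1, prob = config$phantom_mix)
    gross <- runif(1) < config$localization_error_prob
    lo <- config$localization_offset_range_mm[1]
    hi <- config$localization_offset_range_mm[2]
    offset <- if (gross) runif(1, lo, hi) else runif(1, 0, min(lo, 3))
    list(
      audit = tibble(
        institution_id = id, phantom = phantom,
        tld_label = sprintf("TLD%02d", seq_len(n_tld)),
        measured_dose_gy = measured, calculated_dose_gy = calculated,
        film_pass_pct = NA_real_, localization_offset_mm = offset),
      truth = tibble(institution_id = id, aggregate_pct = e_agg,
                     residual_pct = resid, true_error_pct = e_true)
    )
  })
  audit <- purrr::map_dfr(per_inst, "audit") |>
    dplyr::left_join(stratum, by = "institution_id")
  truth <- purrr::map_dfr(per_inst, "truth")
  list(audit = audit, truth = truth)
}

#' Simulate a single phantom audit
#'
#' Convenience wrapper over [simulate_audits()] for one institution report.
#'
#' @param report One institution's long parameter report.
#' @param models An `effect_model_set`.
#' @param config A [cohort_config()].
#' @return One-institution `list(audit, truth)`.
#' @export
simulate_audit <- function(report, models, config) {
  if (length(unique(report$institution_id)) != 1) {
    abort("simulate_audit() expects a single institution's report",
          class = "beamaudit_invalid")
  }
  simulate_audits(report, models, config)
}

#' Generate a complete synthetic study
#'
#' Draws a community of institutions from the anchor-implied distributions,
#' simulates one phantom audit per institution, and writes the three
#' pipeline input files: the community survey (the audited institutions'
#' own responses — audits are scored against their surveyed community, as in
#' practice), the audit TLD records, and a ground-truth file of true
#' per-institution systematic errors for recovery testing. Fully
#' reproducible from `config$seed`.
#'
#' @param community A [community_model()].
#' @param config A [cohort_config()].
#' @param dir Output directory (created if needed); `NULL` skips writing.
#' @param models Effect models (default: built from the shipped catalog).
#' @param rank_correlation Optional copula correlation for the community.
#' @return Invisibly, `list(survey, audit, truth, paths)`.
#' @export
generate_study <- function(community, config = cohort_config(), dir = NULL,
                           models = build_effect_models(load_anchors()),
                           rank_correlation = NULL) {
  survey <- sample_institutions(community, config$n_institutions,
                                seed = derive_seed(config$seed, 0),
                                rank_correlation = rank_correlation)
  sim <- simulate_audits(survey, models, config)
  paths <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- list(survey = file.path(dir, "survey.csv"),
                  audit = file.path(dir, "cohort.csv"),
                  truth = file.path(dir, "truth.csv"))
    tryCatch({
      readr::write_csv(survey, paths$survey)
      readr::write_csv(sim$audit, paths$audit)
      readr::write_csv(sim$truth, paths$truth)
    }, error = function(e) {
      abort(sprintf("failed writing study files under %s: %s", dir,
                    conditionMessage(e)), class = "beamaudit_io")
    })
  }
  invisible(list(survey = survey, audit = sim$audit, truth = sim$truth,
                 paths = paths))
}
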