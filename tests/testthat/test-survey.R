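test_that("fitting a distribution sorts, counts and guards its input", {
  d <- fit_distribution(c(0.18, 0.14, 0.20), "DLG", min_sample_size = 1)
  expect_equal(d$values, c(0.14, 0.18, 0.20))
  expect_equal(d$n, 3)
  expect_error(fit_distribution(numeric(0), "DLG"), "no survey samples")
  expect_error(fit_distribution(c(1, NA), "DLG", min_sample_size = 1), "finite")
  expect_error(fit_distribution(1:3, "DLG", tps = "Eclipse AAA"),
               "Eclipse AAA.*need at least 5")
})

test_that("percentile lookup inverts the type-7 quantile convention", {
  d5 <- fit_distribution(1:5, "p", min_sample_size = 1)
  expect_equal(percentile_of(d5, 3), 50)
  expect_equal(percentile_of(d5, 0), 0)
  expect_equal(percentile_of(d5, 99), 100)
  d101 <- fit_distribution(seq(0, 1, length.out = 101), "p", min_sample_size = 1)
  expect_equal(percentile_of(d101, 0.9), 90, tolerance = 0.5)
  # round trip through the forward quantile
  set.seed(4)
  x <- rnorm(57)
  dx <- fit_distribution(x, "p", min_sample_size = 1)
  for (p in c(2.5, 10, 33.3, 50, 90, 97.5)) {
    expect_equal(percentile_of(dx, quantile_of(dx, p)), p, tolerance = 1e-9)
  }
  expect_error(percentile_of(dx, Inf), "finite")
})

test_that("percentile lookup is monotone and close to a brute-force rank count", {
  set.seed(9)
  for (n in c(8, 40, 200)) {
    x <- runif(n)
    d <- fit_distribution(x, "p", min_sample_size = 1)
    v <- sort(runif(25, -0.1, 1.1))
    pct <- percentile_of(d, v)
    expect_true(all(diff(pct) >= 0))
    inside <- v >= min(x) & v <= max(x)
    expect_true(all(abs(pct[inside] - rank_percentile(x, v[inside])) <= 100 / n))
  }
})

test_that("ties take the midrank percentile", {
  d <- fit_distribution(c(1, 2, 2, 2, 3), "p", min_sample_size = 1)
  # tied block occupies order statistics 2..4 of 5 -> midrank position 3
  expect_equal(percentile_of(d, 2), 50)
})

test_that("atypicality cuts are strict and symmetric", {
  expect_true(classify_atypical(91))
  expect_false(classify_atypical(50))
  expect_false(classify_atypical(10))
  expect_false(classify_atypical(90))
  expect_true(classify_atypical(9.999))
  p <- c(0, 5, 10, 45, 90, 95, 100)
  expect_equal(classify_atypical(p), classify_atypical(100 - p))
  expect_error(classify_atypical(50, low_cut = 90, high_cut = 10), "cuts")
  expect_error(classify_atypical(120), "\\[0, 100\\]")
})

test_that("scoring a report flags anchor-extreme values and guards strata", {
  a <- shipped_anchors()
  cm <- community_model(a, "Eclipse AAA")
  # survey sample whose type-7 quantiles match the anchors exactly, with
  # narrow tails beyond the 2.5th/97.5th so anchor values sit at unique ranks
  dlg_grid <- approx(c(0, 2.5, 10, 50, 90, 97.5, 100),
                     c(0.095, 0.1000, 0.1388, 0.1728, 0.2000, 0.2300, 0.2350),
                     xout = seq(0, 100, by = 0.5))$y
  survey <- tibble::tibble(
    institution_id = sprintf("s%03d", 1:201),
    tps = "Eclipse AAA", linac_class = "Varian Base",
    beam_energy = "6 MV", mlc_model = "Millennium120",
    parameter = "Dosimetric Leaf Gap", value = dlg_grid, units = "cm")
  report <- survey[1, ]
  report$value <- 0.2300  # the 97.5th-percentile anchor
  sc <- score_report(report, survey, catalog = a)
  expect_equal(sc$percentile, 97.5, tolerance = 1e-9)
  expect_true(sc$atypical)
  report$value <- quantile_of(cm, 50, parameter = "Dosimetric Leaf Gap")
  sc2 <- score_report(report, survey, catalog = a)
  expect_false(sc2$atypical)
  # unknown stratum is an error naming the parameter
  off <- report
  off$mlc_model <- "HD120"
  expect_error(score_report(off, survey, catalog = a),
               "Dosimetric Leaf Gap", class = "beamaudit_missing_distribution")
  # uncatalogued parameters pass through unscored with a warning
  extra <- dplyr::bind_rows(report, dplyr::mutate(report, parameter = "Couch Model"))
  expect_warning(sc3 <- score_report(extra, survey, catalog = a), "Couch Model")
  expect_true(is.na(sc3$percentile[sc3$parameter == "Couch Model"]))
  expect_false(sc3$scored[sc3$parameter == "Couch Model"])
})

test_that("reports drawn from their own community score uniformly", {
  srv <- toy_survey(n = 400, seed = 21)
  scores <- score_report(srv, srv, catalog = toy_anchors())
  alpha <- scores$percentile[scores$parameter == "alpha"]
  ks <- suppressWarnings(stats::ks.test(alpha / 100, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_equal(mean(scores$atypical[scores$parameter == "alpha"]), 0.2,
               tolerance = 0.06)
})

test_that("cross-parameter correlation requires variance and enough pairs", {
  srv <- toy_survey(n = 50, seed = 3)
  dup <- srv |>
    dplyr::filter(parameter == "alpha") |>
    dplyr::mutate(parameter = "beta")
  perfect <- dplyr::bind_rows(dplyr::filter(srv, parameter == "alpha"), dup)
  r <- parameter_correlation(perfect, "alpha", "beta")
  expect_equal(r$estimate, 1)
  flat <- dplyr::mutate(dup, value = 7)
  expect_error(parameter_correlation(
    dplyr::bind_rows(dplyr::filter(srv, parameter == "alpha"), flat),
    "alpha", "beta"), class = "beamaudit_zero_variance")
  expect_error(parameter_correlation(srv[1:2, ], "alpha", "beta"),
               "at least 3")
})
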