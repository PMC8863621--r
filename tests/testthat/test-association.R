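test_that("contingency tables tally flags against outcomes", {
  tab <- build_table(c(TRUE, TRUE, FALSE, FALSE), c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(unname(as.vector(t(tab))), c(1, 1, 1, 1))
  all_af <- build_table(rep(TRUE, 5), rep(TRUE, 5))
  expect_equal(unname(all_af[1, 1]), 5)
  expect_equal(sum(all_af) - all_af[1, 1], 0)
  # counts equal a brute-force tally on a random assignment
  set.seed(2)
  f <- runif(200) < 0.3; o <- runif(200) < 0.1
  tab2 <- build_table(f, o)
  expect_equal(unname(tab2[2, 1]), sum(!f & o))
  expect_error(build_table(logical(0), logical(0)), "non-empty")
  expect_error(build_table(c(TRUE, NA), c(TRUE, FALSE)), "NA")
})

test_that("Fisher's exact test matches hand enumerations", {
  expect_equal(fisher_exact(matrix(c(5, 5, 5, 5), 2))$p_value, 1)
  expect_equal(fisher_exact(matrix(c(2, 0, 0, 2), 2))$p_value, 1 / 3,
               tolerance = 1e-12)
  expect_equal(fisher_exact(matrix(c(3, 1, 1, 3), 2))$p_value, 34 / 70,
               tolerance = 1e-12)
  res <- fisher_exact(matrix(c(6, 2, 3, 9), 2, byrow = TRUE))
  expect_equal(res$estimate, (6 * 9) / (2 * 3))
  zero <- fisher_exact(matrix(c(4, 0, 1, 5), 2, byrow = TRUE))
  expect_true(is.infinite(zero$estimate))
  expect_match(zero$note, "zero cell")
  expect_error(fisher_exact(matrix(0, 2, 2)), "zero grand total")
})

test_that("Fisher p-values equal the enumeration oracle on random small tables", {
  set.seed(5)
  for (i in 1:300) {
    tab <- matrix(rpois(4, 2), 2)
    if (sum(tab) == 0) next
    expect_equal(fisher_exact(tab)$p_value, fisher_oracle(tab),
                 tolerance = 1e-10)
  }
})

test_that("chi-square matches hand computation and is transpose-invariant", {
  tab <- matrix(c(30, 20, 20, 30), 2, byrow = TRUE)
  res <- chi_square(tab)
  expect_equal(res$statistic, 4)
  expect_equal(res$p_value, pchisq(4, 1, lower.tail = FALSE), tolerance = 1e-10)
  expect_equal(res$p_value, 0.0455, tolerance = 1e-3)
  expect_equal(chi_square(matrix(c(10, 10, 10, 10), 2))$statistic, 0)
  expect_equal(chi_square(matrix(c(10, 10, 10, 10), 2))$p_value, 1)
  set.seed(8)
  for (i in 1:50) {
    tab <- matrix(rpois(4, 6) + 1, 2)
    expect_equal(chi_square(tab)$statistic, chi_square(t(tab))$statistic,
                 tolerance = 1e-12)
  }
  expect_error(chi_square(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)), "expected")
})

test_that("Pearson correlation handles exact and degenerate cases", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_correlation(x, 2 * x + 1)$estimate, 1)
  expect_equal(pearson_correlation(x, rev(x))$estimate, -1)
  expect_equal(pearson_correlation(c(1, 2, 3), c(6, 4, 5))$estimate, -0.5,
               tolerance = 1e-12)
  # invariance under positive affine transforms
  set.seed(1)
  y <- rnorm(20); z <- rnorm(20)
  expect_equal(pearson_correlation(y, z)$estimate,
               pearson_correlation(3 * y + 2, 0.5 * z - 7)$estimate,
               tolerance = 1e-12)
  expect_error(pearson_correlation(c(1, 1, 1), c(1, 2, 3)),
               class = "beamaudit_zero_variance")
  expect_error(pearson_correlation(1:2, 1:2), "at least 3")
})

test_that("the association battery reports un-computable tests, not errors", {
  srv <- toy_survey(n = 1, seed = 2)
  scores <- score_report(srv, toy_survey(n = 60, seed = 4),
                         catalog = toy_anchors())
  outcomes <- tibble::tibble(institution_id = unique(srv$institution_id),
                             tps = "ToyTPS", mean_tld_error_pct = 0,
                             failing = FALSE, poor = FALSE,
                             localization_offset_mm = 0)
  rep <- run_association_analysis(scores, outcomes, anchors = toy_anchors())
  expect_true(all(!rep$computed))
  expect_true(all(is.na(rep$p_value)))
})

test_that("the battery recovers a planted flag-outcome association", {
  set.seed(77)
  srv <- toy_survey(n = 250, seed = 31)
  scores <- score_report(srv, srv, catalog = toy_anchors())
  flag <- scores |>
    dplyr::filter(parameter == "alpha") |>
    dplyr::select(institution_id, atypical)
  outcomes <- flag |>
    dplyr::mutate(tps = "ToyTPS",
                  failing = runif(dplyr::n()) < ifelse(atypical, 0.5, 0.05),
                  poor = failing,
                  mean_tld_error_pct = rnorm(dplyr::n()),
                  localization_offset_mm = 0) |>
    dplyr::select(-atypical)
  rep <- run_association_analysis(scores, outcomes, anchors = toy_anchors())
  alpha_fail <- dplyr::filter(rep, scope == "parameter", parameter == "alpha",
                              outcome == "failing")
  expect_true(alpha_fail$computed)
  expect_lt(alpha_fail$p_value, 0.01)
  expect_gt(alpha_fail$estimate, 1) # atypical enriched among failures
  # BH adjustment only fills the per-parameter family
  expect_true(all(is.na(rep$p_adjusted[rep$scope != "parameter"])))
})
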