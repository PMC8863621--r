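test_that("community sampling is reproducible and matches the anchor quantiles", {
  cm <- community_model(shipped_anchors(), "Eclipse AAA")
  one <- sample_community(cm, 1, seed = 99)
  two <- sample_community(cm, 1, seed = 99)
  expect_identical(one, two)
  big <- sample_community(cm, 10000, seed = 12)
  dlg <- big$`Dosimetric Leaf Gap`
  q <- quantile(dlg, c(0.1, 0.9), type = 7, names = FALSE)
  expect_equal(q[1], 0.1388, tolerance = 0.003 / 0.1388)
  expect_equal(q[2], 0.2000, tolerance = 0.003 / 0.2)
  # draws never leave the inverse-CDF range
  expect_true(all(dlg >= 0.1000 & dlg <= 0.2300))
  d <- fit_distribution(dlg, "Dosimetric Leaf Gap")
  expect_equal(quantile_of(d, 90), 0.2000, tolerance = 0.005 / 0.2)
})

test_that("a rank-correlation matrix induces the requested Spearman coupling", {
  cm <- community_model(shipped_anchors(), "Eclipse AAA")
  R <- matrix(c(1, 0.6, 0.6, 1), 2, dimnames = list(
    c("Dosimetric Leaf Gap", "MLC Transmission Factor"),
    c("Dosimetric Leaf Gap", "MLC Transmission Factor")))
  s <- sample_community(cm, 5000, seed = 3, rank_correlation = R)
  rho <- cor(s$`Dosimetric Leaf Gap`, s$`MLC Transmission Factor`,
             method = "spearman")
  expect_equal(rho, 0.6, tolerance = 0.05 / 0.6)
  # recovery through the survey-side correlation function
  srv <- sample_institutions(cm, 300, seed = 6, rank_correlation = R)
  r <- parameter_correlation(srv, "Dosimetric Leaf Gap", "MLC Transmission Factor")
  se <- (1 - 0.6^2) / sqrt(297)
  expect_true(abs(r$estimate - 0.6) < 2.5 * se + 0.05)
  bad <- R; bad[1, 2] <- 0.2
  expect_error(sample_community(cm, 10, seed = 1, rank_correlation = bad),
               "symmetric")
})

test_that("institution sampling produces uniform percentile scores", {
  cm <- community_model(toy_anchors(), "ToyTPS")
  expect_equal(nrow(sample_institutions(cm, 0)), 0)
  srv <- sample_institutions(cm, 500, seed = 8)
  scores <- score_report(srv, srv, catalog = toy_anchors())
  beta <- scores$percentile[scores$parameter == "beta"]
  # probability-integral transform, midranks smoothing the anchor atoms
  expect_equal(mean(beta) / 100, 0.5, tolerance = 0.05)
  expect_equal(mean(scores$atypical[scores$parameter == "beta"]), 0.2,
               tolerance = 0.25)
})

test_that("noiseless audits reproduce the aggregate effect in every TLD", {
  a <- shipped_anchors()
  models <- build_effect_models(a)
  cm <- community_model(a, "Eclipse AAA")
  cfg <- cohort_config(n_institutions = 1, sigma_residual_pct = 0,
                       tld_noise_pct = 0, seed = 5)
  # all parameters at their community medians: zero error exactly
  med <- tibble::tibble(
    institution_id = "m1", tps = "Eclipse AAA", linac_class = "Varian Base",
    beam_energy = "6 MV", mlc_model = "Millennium120",
    parameter = names(cm$params),
    value = purrr::map_dbl(names(cm$params), ~ quantile_of(cm, 50, parameter = .x)),
    units = "")
  sim <- simulate_audit(med, models, cfg)
  expect_equal(tld_error(sim$audit$measured_dose_gy, sim$audit$calculated_dose_gy),
               rep(0, cfg$n_tld_per_phantom))
  # DLG at the 90th percentile, others at medians: +1.2% in every TLD
  hot <- med
  hot$value[hot$parameter == "Dosimetric Leaf Gap"] <-
    quantile_of(cm, 90, parameter = "Dosimetric Leaf Gap")
  sim2 <- simulate_audit(hot, models, cfg)
  expect_equal(tld_error(sim2$audit$measured_dose_gy, sim2$audit$calculated_dose_gy),
               rep(1.2, cfg$n_tld_per_phantom), tolerance = 1e-12)
  expect_equal(sim2$truth$true_error_pct, 1.2, tolerance = 1e-12)
})

test_that("TLD noise enters with the configured spread", {
  a <- shipped_anchors()
  models <- build_effect_models(a)
  cm <- community_model(a, "Eclipse AAA")
  cfg <- cohort_config(n_institutions = 400, sigma_residual_pct = 0,
                       tld_noise_pct = 1, n_tld_per_phantom = 8, seed = 10)
  srv <- sample_institutions(cm, cfg$n_institutions, seed = 44)
  sim <- simulate_audits(srv, models, cfg)
  err <- tld_error(sim$audit$measured_dose_gy, sim$audit$calculated_dose_gy)
  etrue <- sim$truth$true_error_pct[match(sim$audit$institution_id,
                                          sim$truth$institution_id)]
  expect_equal(sd(err - etrue), 1, tolerance = 0.05)
})

test_that("generated studies are reproducible and internally consistent", {
  cm <- community_model(toy_anchors(), "ToyTPS")
  models <- build_effect_models(toy_anchors())
  cfg <- cohort_config(n_institutions = 25, seed = 14)
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  st1 <- generate_study(cm, cfg, dir = dir1, models = models)
  st2 <- generate_study(cm, cfg, dir = dir2, models = models)
  expect_identical(readLines(st1$paths$survey), readLines(st2$paths$survey))
  expect_identical(readLines(st1$paths$audit), readLines(st2$paths$audit))
  expect_identical(readLines(st1$paths$truth), readLines(st2$paths$truth))
  expect_setequal(unique(st1$audit$institution_id), st1$truth$institution_id)
  expect_equal(nrow(st1$audit), 25 * cfg$n_tld_per_phantom)
  # truth decomposes into aggregate + residual
  expect_equal(st1$truth$true_error_pct,
               st1$truth$aggregate_pct + st1$truth$residual_pct)
})

test_that("a null cohort fails at the rate implied by residual noise alone", {
  a <- shipped_anchors()
  models <- build_effect_models(a)
  cm <- community_model(a, "Eclipse AAA")
  sigma <- 3
  cfg <- cohort_config(n_institutions = 600, sigma_residual_pct = sigma,
                       tld_noise_pct = 0, n_tld_per_phantom = 1,
                       localization_error_prob = 0, seed = 18)
  # every institution exactly at community medians -> aggregate 0
  med_vals <- purrr::map_dbl(names(cm$params), ~ quantile_of(cm, 50, parameter = .x))
  srv <- tidyr::expand_grid(institution_id = sprintf("n%03d", 1:600),
                            parameter = names(cm$params)) |>
    dplyr::mutate(tps = "Eclipse AAA", linac_class = "Varian Base",
                  beam_energy = "6 MV", mlc_model = "Millennium120",
                  units = "")
  srv$value <- med_vals[match(srv$parameter, names(cm$params))]
  sim <- simulate_audits(srv, models, cfg)
  out <- classify_outcomes(sim$audit)
  expected_fail <- 2 * pnorm(-7 / sigma)
  expect_equal(mean(out$failing), expected_fail,
               tolerance = 3 * sqrt(expected_fail / 600) / expected_fail)
})
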