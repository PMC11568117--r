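test_that("generation is deterministic given the seed", {
  cfg <- generator_config(n_exams = 1000, seed = 7)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)
  expect_equal(nrow(a), 1000)
  c2 <- simulate_cohort(generator_config(n_exams = 1000, seed = 8))
  expect_false(identical(a, c2))
})

test_that("invalid configurations are rejected", {
  expect_error(generator_config(facility_weights = c(0.5, 0.4, 0.2)),
               class = "bagverify_config_error")
  expect_error(generator_config(score_cutpoints = c(0, 1, 1, 2)),
               class = "bagverify_config_error")
  expect_error(generator_config(missing_rate_psa = 1),
               class = "bagverify_config_error")
  expect_error(generator_config(n_exams = 0),
               class = "bagverify_config_error")
})

test_that("a null disease model yields the intercept's binomial rate", {
  cfg <- generator_config(
    n_exams = 20000, seed = 13,
    disease_coefficients = c(intercept = qlogis(0.25)),
    miss_rate = 0
  )
  cohort <- generate_cohort(cfg)
  se <- sqrt(0.25 * 0.75 / 20000)
  expect_lt(abs(mean(cohort$true_cspca) - 0.25), 3 * se)
})

test_that("the preset reproduces the cohort's marginal score structure", {
  cohort <- simulate_cohort(generator_config(n_exams = 20000, seed = 3))
  share12 <- mean(cohort$pirads <= 2)
  expect_lt(abs(share12 - 0.554), 3 * sqrt(0.554 * 0.446 / 20000) + 0.01)
  # facility shares
  fshare <- prop.table(table(cohort$facility))
  expect_equal(as.numeric(fshare[c("I", "II", "III")]),
               c(0.534, 0.213, 0.253), tolerance = 0.05)
  # monotone risk gradient across strata
  risks <- tapply(cohort$true_cspca, pirads_stratum(cohort$pirads), mean)
  expect_true(all(diff(risks) > 0))
})

test_that("verification modes behave as specified", {
  cfg_full <- generator_config(n_exams = 500, seed = 5,
                               verification_mode = "FULL")
  full <- simulate_cohort(cfg_full)
  expect_true(all(full$verified))
  expect_true(all(!is.na(full$cspca)))
  expect_identical(full$cspca, full$true_cspca)

  # MAR preset verification rate in PI-RADS 1-2 near the tuned 15.4%
  cohort <- simulate_cohort(generator_config(n_exams = 20000, seed = 5))
  low <- cohort[cohort$pirads <= 2, ]
  rate <- mean(low$verified)
  expect_lt(abs(rate - 0.154), 3 * sqrt(0.154 * 0.846 / nrow(low)))
  expect_true(all(is.na(cohort$cspca[!cohort$verified])))
  expect_identical(cohort$cspca[cohort$verified],
                   cohort$true_cspca[cohort$verified])

  # verification before generation is a precondition error
  expect_error(
    apply_verification(dplyr::mutate(generate_cohort(cfg_full),
                                     true_cspca = NA), cfg_full),
    class = "bagverify_precondition_error"
  )
})

test_that("MNAR shifts the unverified disease rate relative to matched MAR", {
  mar <- simulate_cohort(generator_config(n_exams = 20000, seed = 17),
                         keep_latent = TRUE)
  mnar <- simulate_cohort(
    generator_config(n_exams = 20000, seed = 17, verification_mode = "MNAR",
                     mnar_hidden_effect = 1.5),
    keep_latent = TRUE
  )
  r_mar <- mean(mar$true_cspca[!mar$verified])
  r_mnar <- mean(mnar$true_cspca[!mnar$verified])
  expect_gt(abs(r_mnar - r_mar), 0.02)
})

test_that("missingness injection is MCAR at the configured rates", {
  cfg0 <- generator_config(n_exams = 300, seed = 9, missing_rate_psa = 0,
                           missing_rate_vol = 0)
  cohort <- generate_cohort(cfg0) |> apply_verification(cfg0)
  expect_identical(inject_missingness(cohort, cfg0), cohort)

  cfg <- generator_config(n_exams = 12141, seed = 9, missing_rate_psa = 0.106,
                          missing_rate_vol = 0.03)
  injected <- inject_missingness(generate_cohort(cfg), cfg)
  n_miss <- sum(is.na(injected$psa))
  se <- sqrt(0.106 * 0.894 * 12141)
  expect_lt(abs(n_miss - 0.106 * 12141), 3 * se)
  # reproducible mask
  again <- inject_missingness(generate_cohort(cfg), cfg)
  expect_identical(is.na(injected$psa), is.na(again$psa))
})

test_that("under full verification observed counts equal latent truth per stratum", {
  cohort <- simulate_cohort(
    generator_config(n_exams = 3000, seed = 19, verification_mode = "FULL"),
    keep_latent = TRUE
  )
  by_stratum <- cohort |>
    dplyr::group_by(stratum = pirads_stratum(pirads)) |>
    dplyr::summarise(obs = sum(cspca), latent = sum(true_cspca))
  expect_identical(by_stratum$obs, by_stratum$latent)
})

test_that("cohort CSV and config YAML round-trip", {
  cohort <- tiny_cohort(n = 150, seed = 23)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(cohort, path)
  back <- read_cohort(path)
  expect_equal(as.data.frame(back), as.data.frame(cohort), tolerance = 1e-12)

  cfg <- generator_config(n_exams = 500, seed = 23,
                          verification_mode = "MNAR", mnar_hidden_effect = 0.7)
  cfg_path <- withr::local_tempfile(fileext = ".yaml")
  write_generator_config(cfg, cfg_path)
  cfg2 <- read_generator_config(cfg_path)
  expect_equal(unclass(cfg2), unclass(cfg), tolerance = 1e-12)
})
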