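test_that("plan fitting validates input and is deterministic", {
  cohort <- tiny_cohort(n = 300, seed = 1)
  degenerate <- dplyr::mutate(cohort, age = 65)
  expect_error(fit_preprocess_plan(degenerate), "age",
               class = "bagverify_fit_error")
  expect_error(fit_preprocess_plan(cohort[0, ]), class = "bagverify_fit_error")
  all_missing <- dplyr::mutate(cohort, psa = NA_real_)
  expect_error(fit_preprocess_plan(all_missing), "missing",
               class = "bagverify_fit_error")

  p1 <- fit_preprocess_plan(cohort, seed = 4)
  p2 <- fit_preprocess_plan(cohort, seed = 4)
  expect_identical(p1, p2)
})

test_that("log then standardize gives mean 0, sd 1 on the training set", {
  cohort <- tiny_cohort(n = 400, seed = 2)
  cohort$psa[1:3] <- c(1, exp(1), exp(2))  # known log values survive the chain
  plan <- fit_preprocess_plan(cohort, seed = 2)
  fm <- apply_preprocess_plan(plan, cohort)
  for (col in c("age", "log_psa", "log_vol", "log_psad")) {
    expect_lt(abs(mean(fm[[col]])), 1e-9)
    expect_lt(abs(sd(fm[[col]]) - 1), 1e-9)
  }
})

test_that("applying a plan to held-out data reuses training statistics", {
  train <- tiny_cohort(n = 400, seed = 3)
  held <- dplyr::mutate(tiny_cohort(n = 400, seed = 30), age = age + 5)
  plan <- fit_preprocess_plan(train, seed = 3)
  fm <- apply_preprocess_plan(plan, held)
  expect_gt(abs(mean(fm$age)), 0.1)  # not recentred
  # no leakage: plan statistics unaffected by records outside the train set
  plan2 <- fit_preprocess_plan(train, seed = 3)
  expect_identical(plan$standardize_stats, plan2$standardize_stats)
})

test_that("imputation leaves complete data untouched and is reproducible", {
  cohort <- simulate_cohort(generator_config(n_exams = 300, seed = 5,
                                             missing_rate_psa = 0,
                                             missing_rate_vol = 0))
  plan <- fit_preprocess_plan(cohort, seed = 5)
  done <- impute_chained(plan, cohort)
  expect_equal(done$log_psa, log(cohort$psa))
  expect_equal(done$log_vol, log(cohort$volume))

  one <- cohort[1, ]
  one$psa <- NA_real_
  f1 <- impute_chained(plan, one, seed = 99)
  f2 <- impute_chained(plan, one, seed = 99)
  expect_true(is.finite(f1$log_psa))
  expect_identical(f1$log_psa, f2$log_psa)
})

test_that("chained imputation recovers the complete-data mean under MCAR", {
  # Monte-Carlo oracle: on correlated (log-PSA, log-volume) data with 20%
  # MCAR missingness, the imputed-data mean of log-PSA matches the
  # complete-data mean within 3 SE over replicates.
  reps <- 40
  diffs <- withr::with_seed(8, vapply(seq_len(reps), function(r) {
    cohort <- simulate_cohort(
      generator_config(n_exams = 400, seed = 800 + r,
                       missing_rate_psa = 0, missing_rate_vol = 0)
    )
    complete_mean <- mean(log(cohort$psa))
    holed <- cohort
    holed$psa[runif(400) < 0.2] <- NA_real_
    plan <- fit_preprocess_plan(holed, seed = 800 + r)
    done <- impute_chained(plan, holed)
    mean(done$log_psa) - complete_mean
  }, numeric(1)))
  expect_lt(abs(mean(diffs)), 3 * sd(diffs) / sqrt(reps))
})

test_that("PSAD is PSA over volume before log/standardisation", {
  cohort <- tiny_cohort(n = 100, seed = 6)
  cohort$psa[1] <- 5
  cohort$volume[1] <- 50
  plan <- fit_preprocess_plan(cohort, seed = 6)
  done <- impute_chained(plan, cohort)
  psad <- exp(done$log_psa - done$log_vol)
  expect_equal(psad[1], 0.10, tolerance = 1e-12)
  expect_true(all(psad > 0))
})

test_that("plan application is idempotent and handles unseen levels", {
  cohort <- tiny_cohort(n = 250, seed = 7)
  plan <- fit_preprocess_plan(cohort, seed = 7)
  a <- apply_preprocess_plan(plan, cohort, seed = 7)
  b <- apply_preprocess_plan(plan, cohort, seed = 7)
  expect_identical(a, b)
  expect_false(anyNA(a[, attr(a, "features")]))

  odd <- cohort[1, ]
  odd$facility <- "IV"
  expect_warning(fm <- apply_preprocess_plan(plan, odd), "unseen")
  expect_equal(fm$facility_II + fm$facility_III, 0)
})

test_that("feature groups map to matrix columns and unknown groups error", {
  cohort <- tiny_cohort(n = 150, seed = 8)
  plan <- fit_preprocess_plan(cohort, seed = 8)
  fm <- apply_preprocess_plan(plan, cohort)
  cols <- bagverify:::feature_group_columns(default_features(),
                                            attr(fm, "features"))
  expect_setequal(cols, c("age", "biopsy_benign", "biopsy_unknown",
                          "facility_II", "facility_III",
                          paste0("score_", 2:5), "log_psad", "log_vol"))
  expect_error(bagverify:::feature_group_columns("nope", attr(fm, "features")),
               class = "bagverify_config_error")
})
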