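# The fully-verified 626-patient biopsy-naive reference cohort used as a
# worked example throughout: per-score totals and csPCa-positive counts
# reconstructed from its published ratios (positives 10/6/34/96 of
# 309/40/136/141 exams).
reference_full_table <- function() {
  fractional_table(
    c("1-2", "3", "4", "5"),
    n = c(309, 40, 136, 141),
    verified = c(309, 40, 136, 141),
    observed_pos = c(10, 6, 34, 96)
  )
}

test_that("fractional counts follow the defining identities", {
  tb <- fractional_table("4", n = 200, verified = 100, observed_pos = 60,
                         pi_hat = 0.15)
  expect_equal(tb$expected_pos, 100 * 0.15)
  expect_equal(tb$n_pos, 60 + 15)
  expect_equal(tb$n_neg, 40 + 85)
  expect_equal(tb$n_pos + tb$n_neg, tb$n, tolerance = 1e-12)

  # facility-I PI-RADS 5 arithmetic: V=861, n=943, O=756, pi=0.883
  tb5 <- fractional_table("5", n = 943, verified = 861, observed_pos = 756,
                          pi_hat = 0.883)
  expect_equal(tb5$n_pos, 756 + 82 * 0.883, tolerance = 1e-12)

  expect_error(fractional_table("3", n = 10, verified = 12, observed_pos = 1),
               class = "bagverify_config_error")
  expect_error(fractional_table("3", n = 10, verified = 5, observed_pos = 1),
               class = "bagverify_config_error")  # missing pi_hat
})

test_that("metric formulas reproduce the published worked-example ratios", {
  rep <- metric_report(reference_full_table())
  get <- function(metric, threshold, col = "estimated") {
    rep[[col]][rep$metric == metric & rep$threshold == threshold]
  }
  pct <- function(x) bagverify:::round_half_up(100 * x, 1)

  expect_equal(pct(get("sensitivity", ">=3")), 93.2)  # 136/146
  expect_equal(pct(get("sensitivity", ">=4")), 89.0)  # 130/146
  expect_equal(pct(get("sensitivity", "5")), 65.8)    # 96/146
  expect_equal(pct(get("specificity", ">=3")), 62.3)  # 299/480
  expect_equal(pct(get("specificity", ">=4")), 69.4)  # 333/480
  expect_equal(pct(get("specificity", "5")), 90.6)    # 435/480
  expect_equal(pct(get("ppv", ">=3")), 42.9)          # 136/317
  expect_equal(pct(get("ppv", ">=4")), 46.9)          # 130/277
  expect_equal(pct(get("ppv", "5")), 68.1)            # 96/141
  expect_equal(pct(get("npv", "1-2")), 96.8)          # 299/309
  expect_equal(pct(get("cdr", ">=3")), 21.7)          # 136/626
  expect_equal(pct(get("air", ">=3", "observed")), 50.6)  # 317/626
  expect_equal(pct(get("prevalence", "all")), 23.3)   # 146/626
})

test_that("AIR is the share of examinations at or above PI-RADS 3", {
  # 1073 of 2130 examinations scored >= 3
  tb <- fractional_table(
    c("1-2", "3", "4", "5"),
    n = c(1057, 300, 500, 273), verified = c(1057, 300, 500, 273),
    observed_pos = c(0, 10, 20, 30)
  )
  rep <- metric_report(tb)
  air <- rep$observed[rep$metric == "air"]
  expect_equal(air, 1073 / 2130, tolerance = 1e-12)
  expect_equal(bagverify:::round_half_up(100 * air, 1), 50.4)
})

test_that("confirmation rates are per-score verified shares", {
  tb <- fractional_table(
    c("1-2", "3"), n = c(3530, 889), verified = c(494, 623),
    observed_pos = c(87, 214), pi_hat = c(0.15, 0.3)
  )
  rep <- metric_report(tb)
  cr <- rep$observed[rep$metric == "confirmation_rate"]
  expect_equal(cr, c(494 / 3530, 623 / 889), tolerance = 1e-12)
  expect_equal(bagverify:::round_half_up(100 * cr[1], 1), 14.0)
})

test_that("perfect and degenerate classifiers bound the ROC", {
  perfect <- fractional_table(
    c("1-2", "5"), n = c(100, 50), verified = c(100, 50),
    observed_pos = c(0, 50)
  )
  roc <- roc_auc_fractional(perfect)
  expect_equal(roc$auc$estimated, 1.0)
  rep <- metric_report(perfect)
  expect_equal(rep$estimated[rep$metric == "sensitivity" & rep$threshold == "5"], 1)
  expect_equal(rep$estimated[rep$metric == "specificity" & rep$threshold == "5"], 1)
  expect_equal(rep$estimated[rep$metric == "cdr"],
               rep$estimated[rep$metric == "prevalence"])

  one_level <- fractional_table("4", n = 80, verified = 80, observed_pos = 30)
  expect_equal(roc_auc_fractional(one_level)$auc$estimated, 0.5)

  no_pos <- fractional_table("4", n = 80, verified = 80, observed_pos = 0)
  expect_error(roc_auc_fractional(no_pos), class = "bagverify_fit_error")
})

test_that("fractional AUC equals exhaustive pairwise concordance", {
  # pooled verified counts of the development cohort:
  # positives 165/284/1271/1366, negatives 876/649/781/278
  pos <- c(165, 284, 1271, 1366)
  neg <- c(876, 649, 781, 278)
  tb <- fractional_table(
    c("1-2", "3", "4", "5"), n = pos + neg, verified = pos + neg,
    observed_pos = pos
  )
  auc <- roc_auc_fractional(tb)$auc$estimated
  oracle <- brute_force_auc(pos, neg, scale = 1L)
  expect_equal(auc, oracle, tolerance = 1e-12)

  # random small fractional tables vs the tenfold-expanded oracle
  withr::with_seed(99, {
    for (r in 1:100) {
      k <- sample(2:4, 1)
      strata <- c("1-2", "3", "4", "5")[seq_len(k)]
      n <- sample(5:40, k, replace = TRUE)
      v <- vapply(n, function(m) sample(1:m, 1), integer(1))
      o <- vapply(v, function(m) sample(0:m, 1), integer(1))
      if (sum(o) == 0) o[1] <- min(1, v[1])
      if (sum(v - o) == 0) next
      pi_hat <- sample(0:10, k, replace = TRUE) / 10
      tb <- fractional_table(strata, n = n, verified = v, observed_pos = o,
                             pi_hat = pi_hat)
      if (sum(tb$n_pos) == 0 || sum(tb$n_neg) == 0) next
      auc <- roc_auc_fractional(tb)$auc$estimated
      expect_equal(auc, brute_force_auc(tb$n_pos, tb$n_neg), tolerance = 1e-12)
      auc_obs <- roc_auc_fractional(tb)$auc$observed
      expect_equal(auc_obs, brute_force_auc(o, v - o, scale = 1L),
                   tolerance = 1e-12)
    }
  })
})

test_that("fractional tables built from a cohort honour the accounting identity", {
  cohort <- tiny_cohort(n = 600, seed = 33)
  est <- tibble::tibble(stratum = c("1-2", "3", "4", "5"),
                        pi_hat = c(0.14, 0.3, 0.55, 0.88))
  tb <- build_fractional_table(cohort, est)
  expect_equal(sum(tb$n_pos) + sum(tb$n_neg), nrow(cohort), tolerance = 1e-9)
  expect_equal(sum(tb$n), nrow(cohort))

  expect_error(build_fractional_table(cohort, NULL),
               class = "bagverify_config_error")
})

test_that("facility tables need per-facility estimates", {
  cohort <- tiny_cohort(n = 600, seed = 34)
  est <- tidyr::crossing(group = paste0("facility:", c("I", "II", "III")),
                         stratum = c("1-2", "3", "4", "5")) |>
    dplyr::mutate(pi_hat = 0.3)
  tbf <- build_fractional_table(cohort, est, group = "facility")
  expect_equal(sum(tbf$n), nrow(cohort))
  expect_equal(length(unique(tbf$group)), 3)
})

test_that("metrics are monotone and internally consistent", {
  tb <- fractional_table(
    c("1-2", "3", "4", "5"), n = c(500, 120, 200, 150),
    verified = c(80, 85, 180, 140), observed_pos = c(12, 25, 110, 120),
    pi_hat = c(0.13, 0.28, 0.55, 0.85)
  )
  rep <- metric_report(tb)
  sens <- rep$estimated[rep$metric == "sensitivity"]
  spec <- rep$estimated[rep$metric == "specificity"]
  expect_true(all(diff(sens) <= 0))  # thresholds ordered >=3, >=4, 5
  expect_true(all(diff(spec) >= 0))
  cdr <- rep$estimated[rep$metric == "cdr"]
  expect_lte(cdr, rep$estimated[rep$metric == "prevalence"])
  expect_lte(cdr, rep$observed[rep$metric == "air"])
})

test_that("bootstrap CI propagation uses percentile order statistics", {
  base <- fractional_table(
    c("1-2", "3"), n = c(100, 60), verified = c(40, 45),
    observed_pos = c(6, 15), pi_hat = c(0.1, 0.3)
  )
  same <- replicate(25, base, simplify = FALSE)
  rep <- propagate_bootstrap_ci(same)
  expect_equal(rep$lower, rep$estimated, tolerance = 1e-12)
  expect_equal(rep$upper, rep$estimated, tolerance = 1e-12)

  # explicit order-statistic check at the 80% level
  bags <- lapply(seq(0.1, 1.0, by = 0.1) / 2, function(p) {
    fractional_table("1-2", n = 100, verified = 40, observed_pos = 6,
                     pi_hat = p)
  })
  rep80 <- suppressWarnings(propagate_bootstrap_ci(bags, level = 0.8))
  prev <- rep80[rep80$metric == "prevalence", ]
  prev_of <- function(p) (6 + 60 * p) / 100
  expect_equal(prev$lower, prev_of(0.05), tolerance = 1e-12)
  expect_equal(prev$upper, prev_of(0.45), tolerance = 1e-12)
  expect_warning(propagate_bootstrap_ci(bags[1:5]), "unstable")
})
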