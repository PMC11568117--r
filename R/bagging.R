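#' Bootstrap-aggregated estimation of the unverified csPCa proportion
#'
#' The core engine, run separately for each PI-RADS stratum. For each of
#' `n_bags` bootstrap repetitions: the stratum's verified exams are resampled
#' with replacement (bag size = number of verified exams); the full
#' preprocessing plan (imputation, standardisation, encoding) is refitted on
#' the bag alone, so no statistic leaks across repetitions; a threefold
#' cross-validated, sigmoid-calibrated logistic ensemble is fitted on the
#' bag; the ensemble then predicts every unverified exam and every
#' out-of-bag verified exam. The bag's estimate is the mean predicted
#' probability over the unverified exams, and its out-of-bag bias is
#' (mean prediction on out-of-bag verified exams) minus (their observed
#' csPCa proportion). Bags are aggregated by the mean, with percentile
#' confidence intervals over the bag distribution. Bags whose folds cannot
#' hold both outcome classes after five re-draws are skipped and logged.
#'
#' Besides the pooled estimate, per-facility and per-biopsy-history group
#' means are tracked so that facility-level and subgroup reports can be
#' built from the same bags.
#'
#' @param verified Tibble of verified exam records of one stratum (must
#'   contain both outcome classes).
#' @param unverified Tibble of unverified exam records of the same stratum
#'   (may be empty, e.g. under full verification; the estimate is then
#'   undefined and reported as `NA` with zero downstream weight).
#' @param n_bags Number of bootstrap repetitions (paper-scale default 1000;
#'   use 100-200 for experimentation).
#' @param features Character vector of clinical feature groups for the
#'   model (default [default_features()]). Columns that are constant within
#'   a bag (e.g. the score dummies inside a single stratum) are dropped
#'   automatically.
#' @param seed Integer seed; the run is deterministic given it.
#' @param ridge Ridge penalty for the logistic fits.
#' @param ci_level Confidence level of the percentile intervals.
#' @param impute_iter Chained-imputation sweeps per plan fit.
#' @return An object of class `bv_stratum_estimate`: tibble `estimates`
#'   (per reporting group: `pi_hat`, CI, out-of-bag `bias`, CI, counts),
#'   tibble `bag_results` (per bag and group), `exam_predictions`
#'   (bag-averaged prediction per unverified exam), and the skipped-bag log.
#' @export
run_bagged_estimation <- function(verified, unverified, n_bags = 1000L,
                                  features = default_features(), seed = 1L,
                                  ridge = 1e-4, ci_level = 0.95,
                                  impute_iter = 10L) {
  if (n_bags < 1) stop_config("`n_bags` must be a positive integer.")
  if (nrow(verified) == 0 || length(unique(verified$cspca)) < 2) {
    stop_fit("verified exams must contain both outcome classes.")
  }
  stratum <- as.character(pirads_stratum(verified$pirads[1]))

  n_ver <- nrow(verified)
  n_unv <- nrow(unverified)
  y_all <- as.numeric(verified$cspca)

  groups <- function(df) {
    list(pooled = rep(TRUE, nrow(df)),
         `facility:I` = df$facility == "I",
         `facility:II` = df$facility == "II",
         `facility:III` = df$facility == "III",
         `biopsy:naive` = df$prior_biopsy == "naive",
         `biopsy:benign` = df$prior_biopsy == "benign",
         `biopsy:unknown` = df$prior_biopsy == "unknown")
  }
  unv_groups <- groups(unverified)
  ver_groups <- groups(verified)
  group_names <- names(unv_groups)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  bag_seeds <- sample.int(2^31 - 2, n_bags)

  bag_rows <- vector("list", n_bags)
  pred_sum <- numeric(n_unv)
  pred_bags <- 0L
  skipped <- integer(0)

  both <- dplyr::bind_rows(unverified, verified)
  for (b in seq_len(n_bags)) {
    idx <- sample.int(n_ver, n_ver, replace = TRUE)
    oob <- setdiff(seq_len(n_ver), unique(idx))
    bag <- verified[idx, ]
    res <- tryCatch({
      plan <- fit_preprocess_plan(bag, seed = bag_seeds[b],
                                  n_iter = impute_iter)
      fm_bag <- apply_preprocess_plan(plan, bag, seed = bag_seeds[b])
      cols <- feature_group_columns(features, attr(fm_bag, "features"))
      x_bag <- as.matrix(fm_bag[, cols, drop = FALSE])
      keep_cols <- apply(x_bag, 2, function(v) stats::sd(v) > 0)
      x_bag <- x_bag[, keep_cols, drop = FALSE]
      ens <- fit_calibrated_ensemble(x_bag, y_all[idx], ridge = ridge)
      fm_new <- apply_preprocess_plan(plan, both, seed = bag_seeds[b] + 1L)
      x_new <- as.matrix(fm_new[, cols[keep_cols], drop = FALSE])
      preds <- predict(ens, x_new)
      list(unv = preds[seq_len(n_unv)],
           oob = preds[n_unv + oob])
    },
    bagverify_bag_skip = function(e) NULL,
    bagverify_fit_error = function(e) NULL)
    if (is.null(res)) {
      skipped <- c(skipped, b)
      next
    }
    if (n_unv > 0) {
      pred_sum <- pred_sum + res$unv
      pred_bags <- pred_bags + 1L
    }
    y_oob <- y_all[oob]
    bag_rows[[b]] <- tibble::tibble(
      bag = b,
      group = group_names,
      pi_hat = vapply(group_names, function(g) {
        sel <- unv_groups[[g]]
        if (any(sel)) mean(res$unv[sel]) else NA_real_
      }, numeric(1)),
      oob_bias = vapply(group_names, function(g) {
        sel <- ver_groups[[g]][oob]
        if (any(sel)) mean(res$oob[sel]) - mean(y_oob[sel]) else NA_real_
      }, numeric(1))
    )
  }
  bag_results <- dplyr::bind_rows(bag_rows)
  if (nrow(bag_results) == 0) {
    stop_fit(sprintf("all %d bags were skipped for stratum %s.", n_bags, stratum))
  }

  estimates <- bag_results |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n_bags_used = sum(!is.na(.data$pi_hat)),
      pi_lower = percentile_ci(.data$pi_hat, ci_level)[[1]],
      pi_upper = percentile_ci(.data$pi_hat, ci_level)[[2]],
      bias = mean(.data$oob_bias, na.rm = TRUE),
      bias_lower = percentile_ci(.data$oob_bias, ci_level)[[1]],
      bias_upper = percentile_ci(.data$oob_bias, ci_level)[[2]],
      pi_hat = mean(.data$pi_hat, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      stratum = stratum,
      n_unverified = vapply(.data$group, function(g) sum(unv_groups[[g]]),
                            numeric(1)),
      n_verified = vapply(.data$group, function(g) sum(ver_groups[[g]]),
                          numeric(1)),
      observed = vapply(.data$group, function(g) {
        sel <- ver_groups[[g]]
        if (any(sel)) mean(y_all[sel]) else NA_real_
      }, numeric(1))
    ) |>
    dplyr::mutate(pi_hat = ifelse(.data$n_unverified == 0, NA_real_, .data$pi_hat)) |>
    dplyr::relocate("stratum") |>
    dplyr::arrange(match(.data$group, group_names))

  structure(
    list(
      stratum = stratum,
      estimates = estimates,
      bag_results = dplyr::mutate(bag_results, stratum = stratum),
      exam_predictions = tibble::tibble(
        exam_id = unverified$exam_id,
        mean_pred = if (pred_bags > 0) pred_sum / pred_bags else rep(NA_real_, n_unv)
      ),
      skipped_bags = skipped,
      n_bags = as.integer(n_bags),
      ci_level = ci_level,
      seed = as.integer(seed)
    ),
    class = "bv_stratum_estimate"
  )
}

#' @export
print.bv_stratum_estimate <- function(x, ...) {
  cat(sprintf("<bv_stratum_estimate> stratum %s, %d bags (%d skipped)\n",
              x$stratum, x$n_bags, length(x$skipped_bags)))
  print(x$estimates)
  invisible(x)
}

#' Tidy a stratum estimate
#'
#' @param x A `bv_stratum_estimate`.
#' @param ... Unused.
#' @return The per-group estimates tibble.
#' @method tidy bv_stratum_estimate
#' @export
tidy.bv_stratum_estimate <- function(x, ...) x$estimates

#' @method glance bv_stratum_estimate
#' @export
glance.bv_stratum_estimate <- function(x, ...) {
  pooled <- dplyr::filter(x$estimates, .data$group == "pooled")
  tibble::tibble(
    stratum = x$stratum,
    n_bags = x$n_bags,
    n_skipped = length(x$skipped_bags),
    pi_hat = pooled$pi_hat,
    bias = pooled$bias,
    ci_level = x$ci_level
  )
}

#' Run the bagged estimation for every PI-RADS stratum of a cohort
#'
#' Splits a cohort into the four reporting strata (1-2, 3, 4, 5) and runs
#' [run_bagged_estimation()] on each. Strata without unverified exams (full
#' verification) yield `NA` estimates with zero downstream weight.
#'
#' @param records Cohort tibble (verified exams must carry `cspca`).
#' @inheritParams run_bagged_estimation
#' @return An object of class `bv_estimate`: a named list of
#'   `bv_stratum_estimate` objects plus the combined tidy tibble.
#' @examples
#' \donttest{
#' cohort <- simulate_cohort(generator_config(n_exams = 2000, seed = 11))
#' est <- estimate_cohort(cohort, n_bags = 25, seed = 11)
#' tidy(est)
#' }
#' @export
estimate_cohort <- function(records, n_bags = 1000L,
                            features = default_features(), seed = 1L,
                            ridge = 1e-4, ci_level = 0.95,
                            impute_iter = 10L) {
  records$stratum <- pirads_stratum(records$pirads)
  strata <- levels(records$stratum)
  fits <- lapply(seq_along(strata), function(i) {
    s <- strata[i]
    sub <- records[records$stratum == s, ]
    run_bagged_estimation(
      verified = sub[sub$verified, ],
      unverified = sub[!sub$verified, ],
      n_bags = n_bags, features = features,
      seed = seed + i, ridge = ridge, ci_level = ci_level,
      impute_iter = impute_iter
    )
  })
  names(fits) <- strata
  structure(
    list(strata = fits,
         estimates = dplyr::bind_rows(lapply(fits, tidy)),
         n_bags = as.integer(n_bags),
         ci_level = ci_level,
         seed = as.integer(seed)),
    class = "bv_estimate"
  )
}

#' @export
print.bv_estimate <- function(x, ...) {
  cat(sprintf("<bv_estimate> %d strata, %d bags each\n",
              length(x$strata), x$n_bags))
  print(dplyr::filter(x$estimates, .data$group == "pooled"))
  invisible(x)
}

#' @method tidy bv_estimate
#' @export
tidy.bv_estimate <- function(x, ...) x$estimates

#' @method glance bv_estimate
#' @export
glance.bv_estimate <- function(x, ...) {
  dplyr::bind_rows(lapply(x$strata, glance))
}

#' Per-bag results of a cohort estimate
#'
#' @param x A `bv_estimate`.
#' @return Tibble of per-bag, per-group, per-stratum results
#'   (`bag`, `group`, `stratum`, `pi_hat`, `oob_bias`).
#' @export
bag_results <- function(x) {
  stopifnot(inherits(x, "bv_estimate"))
  dplyr::bind_rows(lapply(x$strata, function(s) s$bag_results))
}

#' Bar chart of estimated vs observed csPCa proportions per stratum
#'
#' @param object A `bv_estimate`.
#' @param group Reporting group to display (default `"pooled"`).
#' @param ... Unused.
#' @method autoplot bv_estimate
#' @export
autoplot.bv_estimate <- function(object, group = "pooled", ...) {
  d <- object$estimates |>
    dplyr::filter(.data$group == !!group) |>
    tidyr::pivot_longer(c("pi_hat", "observed"), names_to = "kind",
                        values_to = "proportion") |>
    dplyr::mutate(kind = dplyr::recode(.data$kind,
                                       pi_hat = "estimated (unverified)",
                                       observed = "observed (verified)"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$stratum, y = .data$proportion,
                                  fill = .data$kind)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_errorbar(
      data = dplyr::filter(d, .data$kind == "estimated (unverified)"),
      ggplot2::aes(ymin = .data$pi_lower, ymax = .data$pi_upper),
      width = 0.2, position = ggplot2::position_nudge(x = -0.225)
    ) +
    ggplot2::labs(x = "PI-RADS stratum", y = "csPCa proportion", fill = NULL) +
    ggplot2::theme_minimal()
}
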