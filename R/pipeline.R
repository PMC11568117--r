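#' Run the full estimation pipeline
#'
#' Orchestrates simulate (or load) -> optional feature selection ->
#' per-stratum bagged estimation -> fractional tables -> metric reports with
#' bootstrap CIs -> ROC, as one seeded, reproducible run. Re-running with
#' the same inputs and seed reproduces every numeric output exactly.
#'
#' @param cohort A cohort tibble (see [read_cohort()]); mutually exclusive
#'   with `config`.
#' @param config A [generator_config()] used to simulate the cohort;
#'   mutually exclusive with `cohort`.
#' @param n_bags Bootstrap repetitions per stratum.
#' @param seed Integer seed for every stochastic stage.
#' @param ci_level Confidence level for percentile intervals.
#' @param features `"auto"` to run forward selection with the one-SE rule on
#'   a seeded half of the verified exams, or a character vector of feature
#'   groups (default [default_features()]).
#' @param groups Reporting splits to tabulate (subset of `"pooled"`,
#'   `"facility"`, `"biopsy"`).
#' @param out_dir Optional directory; when given, every table is persisted
#'   as CSV and the config snapshot as YAML.
#' @return An object of class `bv_report`: the cohort, the `bv_estimate`,
#'   fractional tables, metric reports with CIs, ROC objects, the selection
#'   path (when `features = "auto"`), a run log, and emitted file paths.
#' @examples
#' \donttest{
#' rep <- run_pipeline(config = generator_config(n_exams = 1500, seed = 5),
#'                     n_bags = 25, seed = 5)
#' rep$metrics$pooled
#' }
#' @export
run_pipeline <- function(cohort = NULL, config = NULL, n_bags = 200L,
                         seed = 1L, ci_level = 0.95,
                         features = default_features(),
                         groups = c("pooled", "facility", "biopsy"),
                         out_dir = NULL) {
  if (is.null(cohort) == is.null(config)) {
    stop_config("supply exactly one of `cohort` or `config`.")
  }
  groups <- match.arg(groups, several.ok = TRUE)
  log_lines <- character(0)
  note <- function(...) {
    line <- sprintf(...)
    log_lines <<- c(log_lines, line)
    invisible(line)
  }

  if (is.null(cohort)) {
    cohort <- simulate_cohort(config)
    note("simulated cohort: n = %d, mode = %s, seed = %d",
         nrow(cohort), config$verification_mode, config$seed)
  } else {
    note("input cohort: n = %d", nrow(cohort))
  }

  selection <- NULL
  if (identical(features, "auto")) {
    verified <- cohort[cohort$verified, ]
    old <- .Random.seed_save()
    set.seed(seed)
    sub <- verified[sample.int(nrow(verified), ceiling(nrow(verified) / 2)), ]
    .Random.seed_restore(old)
    plan <- fit_preprocess_plan(sub, seed = seed)
    fm <- apply_preprocess_plan(plan, sub)
    candidates <- c("age", "psa", "volume", "psad", "facility", "pirads",
                    "biopsy", "fam_prostate", "fam_breast", "dre_nodule",
                    "race")
    selection <- forward_select_one_se(fm, candidates, seed = seed)
    features <- selection$chosen_set
    note("forward selection on %d verified exams chose: %s",
         nrow(sub), paste(features, collapse = ", "))
  }

  estimate <- estimate_cohort(cohort, n_bags = n_bags, features = features,
                              seed = seed, ci_level = ci_level)
  n_skipped <- sum(vapply(estimate$strata,
                          function(s) length(s$skipped_bags), numeric(1)))
  note("bagged estimation: %d bags x %d strata, %d skipped",
       n_bags, length(estimate$strata), n_skipped)

  tables <- lapply(stats::setNames(groups, groups), function(g) {
    build_fractional_table(cohort, estimate, group = g)
  })
  bag_tabs <- lapply(stats::setNames(groups, groups), function(g) {
    bag_fractional_tables(cohort, estimate, group = g)
  })
  metrics <- lapply(stats::setNames(groups, groups), function(g) {
    propagate_bootstrap_ci(bag_tabs[[g]], level = ci_level)
  })
  roc <- lapply(tables, roc_auc_fractional)

  bundle <- structure(
    list(cohort = cohort, estimate = estimate, selection = selection,
         tables = tables, metrics = metrics, roc = roc,
         comparison = tryCatch(compare_groups(cohort),
                               bagverify_config_error = function(e) NULL),
         features = features, n_bags = as.integer(n_bags),
         seed = as.integer(seed), ci_level = ci_level,
         log = log_lines, files = character(0)),
    class = "bv_report"
  )
  if (!is.null(out_dir)) bundle <- write_report(bundle, out_dir, config)
  bundle
}

# One fractional table per bag, substituting that bag's per-stratum (and
# per-group) estimates; bags missing from a stratum (skipped) reuse the
# aligned bag index only where present in all strata.
bag_fractional_tables <- function(cohort, estimate, group = "pooled") {
  br <- bag_results(estimate)
  wanted <- switch(group,
    pooled = "pooled",
    facility = paste0("facility:", c("I", "II", "III")),
    biopsy = paste0("biopsy:", c("naive", "benign"))
  )
  br <- br[br$group %in% wanted, ]
  ok_bags <- br |>
    dplyr::distinct(.data$bag, .data$stratum) |>
    dplyr::count(.data$bag) |>
    dplyr::filter(.data$n == dplyr::n_distinct(br$stratum)) |>
    dplyr::pull(.data$bag)
  lapply(ok_bags, function(b) {
    est <- br[br$bag == b, c("group", "stratum", "pi_hat")]
    if (group == "pooled") est$group <- "pooled"
    build_fractional_table(cohort, est, group = group)
  })
}

#' @export
print.bv_report <- function(x, ...) {
  cat("<bv_report>\n")
  for (l in x$log) cat(" ", l, "\n")
  cat("pooled metrics:\n")
  print(format_metric_report(x$metrics$pooled), n = 15)
  invisible(x)
}

write_report <- function(bundle, out_dir, config = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  emit <- function(obj, name) {
    path <- file.path(out_dir, name)
    readr::write_csv(obj, path)
    path
  }
  files <- c(
    emit(bundle$cohort, "cohort.csv"),
    emit(tidy(bundle$estimate), "stratum_estimates.csv"),
    emit(bag_results(bundle$estimate), "bag_results.csv"),
    unlist(lapply(names(bundle$tables), function(g) {
      emit(tibble::as_tibble(bundle$tables[[g]]),
           sprintf("fractional_%s.csv", g))
    })),
    unlist(lapply(names(bundle$metrics), function(g) {
      emit(tibble::as_tibble(bundle$metrics[[g]]),
           sprintf("metrics_%s.csv", g))
    })),
    unlist(lapply(names(bundle$roc), function(g) {
      emit(bundle$roc[[g]]$points, sprintf("roc_points_%s.csv", g))
    }))
  )
  if (!is.null(bundle$comparison)) {
    files <- c(files, emit(bundle$comparison, "group_comparison.csv"))
  }
  if (!is.null(bundle$selection)) {
    files <- c(files, emit(tidy(bundle$selection), "selection_path.csv"))
  }
  if (!is.null(config)) {
    cfg_path <- file.path(out_dir, "config.yaml")
    write_generator_config(config, cfg_path)
    files <- c(files, cfg_path)
  }
  log_path <- file.path(out_dir, "run_log.txt")
  writeLines(bundle$log, log_path)
  bundle$files <- c(files, log_path)
  bundle
}

#' Descriptive comparison of verified vs unverified patients
#'
#' The secondary analysis: compares the examinations with and without
#' pathological confirmation. Age is summarised as mean +/- SD and compared
#' with the unpaired two-sample t-test; PSA, prostate volume and PSAD as
#' median (Q1, Q3) with the Wilcoxon rank-sum test; categorical variables as
#' counts (percent) with the chi-squared test (no continuity correction by
#' default). Variables that are entirely missing in a group are flagged
#' rather than crashing. When the cohort carries an optional `grade_group`
#' column, its tally among csPCa-positive verified exams is appended.
#'
#' @param records Cohort tibble with the `verified` flag filled in.
#' @param by Grouping variable (default `"verified"`).
#' @param correct Continuity correction for the chi-squared test.
#' @return A tibble: `variable`, `test`, per-group summary strings,
#'   `statistic`, `p_value`.
#' @export
compare_groups <- function(records, by = "verified", correct = FALSE) {
  g <- records[[by]]
  if (length(unique(g[!is.na(g)])) < 2) {
    stop_config("both comparison groups must be nonempty.")
  }
  records$psad <- records$psa / records$volume
  g1 <- records[g %in% c(TRUE), ]
  g2 <- records[g %in% c(FALSE), ]
  lab <- function(x) if (isTRUE(x)) "group1" else "group2"

  rows <- list()
  add <- function(variable, test, s1, s2, statistic, p_value) {
    rows[[length(rows) + 1]] <<- tibble::tibble(
      variable = variable, test = test, group1 = s1, group2 = s2,
      statistic = statistic, p_value = p_value
    )
  }
  mean_sd <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return("all missing")
    sprintf("%.1f ± %.1f", mean(x), stats::sd(x))
  }
  med_iqr <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return("all missing")
    q <- stats::quantile(x, c(0.5, 0.25, 0.75))
    sprintf("%.2f (%.2f, %.2f)", q[1], q[2], q[3])
  }

  # age: t-test
  if (all(is.na(g1$age)) || all(is.na(g2$age))) {
    add("age", "t-test", mean_sd(g1$age), mean_sd(g2$age), NA_real_, NA_real_)
  } else {
    tt <- tryCatch(stats::t.test(g1$age, g2$age), error = function(e) NULL)
    add("age", "t-test", mean_sd(g1$age), mean_sd(g2$age),
        if (is.null(tt)) NA_real_ else unname(tt$statistic),
        if (is.null(tt)) 1 else tt$p.value)
  }
  # skewed continuous: rank-sum
  for (v in c("psa", "volume", "psad")) {
    x1 <- g1[[v]]
    x2 <- g2[[v]]
    if (all(is.na(x1)) || all(is.na(x2))) {
      add(v, "rank-sum", med_iqr(x1), med_iqr(x2), NA_real_, NA_real_)
    } else {
      wt <- suppressWarnings(stats::wilcox.test(x1, x2))
      add(v, "rank-sum", med_iqr(x1), med_iqr(x2),
          unname(wt$statistic), wt$p.value)
    }
  }
  # categoricals: chi-squared
  cats <- intersect(c("prior_biopsy", "facility", "race", "fam_prostate",
                      "fam_breast", "dre_nodule"), names(records))
  for (v in cats) {
    tab <- table(factor(g %in% TRUE, levels = c(TRUE, FALSE)), records[[v]])
    if (any(dim(tab) < 2)) {
      add(v, "chi-squared", "", "", NA_real_, NA_real_)
      next
    }
    ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
    pct <- function(sub) {
      t1 <- table(sub[[v]])
      paste(sprintf("%s: %d (%.1f%%)", names(t1), as.integer(t1),
                    100 * as.integer(t1) / sum(t1)), collapse = "; ")
    }
    add(v, "chi-squared", pct(g1), pct(g2),
        unname(ct$statistic), ct$p.value)
  }
  if ("grade_group" %in% names(records)) {
    gg <- records$grade_group[records$verified %in% TRUE &
                                records$cspca %in% TRUE]
    t1 <- table(gg)
    add("grade_group (csPCa+)", "tally",
        paste(sprintf("GG%s: %d", names(t1), as.integer(t1)), collapse = "; "),
        "", NA_real_, NA_real_)
  }
  dplyr::bind_rows(rows)
}
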