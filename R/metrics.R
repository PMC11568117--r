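#' Build a fractional contingency table
#'
#' Tallies, per PI-RADS stratum (and reporting group), the observed verified
#' counts and the expected fractional csPCa counts among unverified exams:
#' with \eqn{n_s} total exams, \eqn{V_s} verified, \eqn{O_s} observed
#' csPCa-positive among the verified, \eqn{U_s = n_s - V_s} unverified and
#' \eqn{\hat\pi_s} the estimated csPCa proportion among the unverified, the
#' expected positives are \eqn{\hat E_s = U_s \hat\pi_s} and the whole-
#' population cell counts are \eqn{N^+_s = O_s + \hat E_s} and
#' \eqn{N^-_s = (V_s - O_s) + (U_s - \hat E_s)}. Every estimated metric of
#' [metric_report()] is a ratio of sums of these fractional counts,
#' equivalent to assuming a 100% pathological confirmation rate.
#'
#' @param records Cohort tibble.
#' @param estimates A `bv_estimate` from [estimate_cohort()], or a tibble
#'   with columns `stratum` and `pi_hat` (optionally `group`). May be `NULL`
#'   if no stratum has unverified exams (full verification).
#' @param group Reporting split: `"pooled"` (one table), `"facility"`, or
#'   `"biopsy"` (biopsy-history subgroups; `unknown` history is reported
#'   only in the pooled group).
#' @return A `bv_fractional` tibble with columns `group`, `stratum`, `n`,
#'   `verified`, `observed_pos`, `unverified`, `pi_hat`, `expected_pos`,
#'   `n_pos`, `n_neg`.
#' @export
build_fractional_table <- function(records, estimates = NULL,
                                   group = c("pooled", "facility", "biopsy")) {
  group <- match.arg(group)
  records$stratum <- pirads_stratum(records$pirads)
  records$.grp <- switch(
    group,
    pooled = "pooled",
    facility = paste0("facility:", records$facility),
    biopsy = paste0("biopsy:", records$prior_biopsy)
  )
  if (group == "biopsy") records <- records[records$prior_biopsy != "unknown", ]

  est <- normalize_estimates(estimates)
  counts <- records |>
    dplyr::group_by(group = .data$.grp, stratum = .data$stratum, .drop = FALSE) |>
    dplyr::summarise(
      n = dplyr::n(),
      verified = sum(.data$verified),
      observed_pos = sum(.data$verified & .data$cspca, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::filter(!is.na(.data$group)) |>
    dplyr::mutate(unverified = .data$n - .data$verified)

  if (!is.null(est)) {
    if (!"group" %in% names(est)) est$group <- "pooled"
    if (group == "pooled") est <- est[est$group == "pooled", ]
    counts <- dplyr::left_join(counts,
                               est[, c("group", "stratum", "pi_hat")],
                               by = c("group", "stratum"))
  } else {
    counts$pi_hat <- NA_real_
  }
  bad <- counts$unverified > 0 & (is.na(counts$pi_hat))
  if (any(bad)) {
    stop_config(paste0(
      "no estimate for stratum/group with unverified exams: ",
      paste(sprintf("%s (%s)", counts$stratum[bad], counts$group[bad]),
            collapse = ", ")
    ))
  }
  new_fractional(dplyr::mutate(
    counts,
    expected_pos = ifelse(.data$unverified == 0, 0,
                          .data$unverified * .data$pi_hat),
    n_pos = .data$observed_pos + .data$expected_pos,
    n_neg = (.data$verified - .data$observed_pos) +
      (.data$unverified - .data$expected_pos)
  ))
}

normalize_estimates <- function(estimates) {
  if (is.null(estimates)) return(NULL)
  if (inherits(estimates, "bv_estimate")) {
    est <- estimates$estimates[, c("group", "stratum", "pi_hat")]
  } else {
    est <- tibble::as_tibble(estimates)
  }
  est$stratum <- as.character(est$stratum)
  est
}

#' Construct a fractional contingency table from explicit counts
#'
#' Direct constructor used for worked examples on published count tables and
#' in tests; [build_fractional_table()] builds the same structure from a
#' cohort.
#'
#' @param stratum Stratum labels (subset of `"1-2"`, `"3"`, `"4"`, `"5"`).
#' @param n Total exams per stratum.
#' @param verified Verified exams per stratum.
#' @param observed_pos Observed csPCa-positive among the verified.
#' @param pi_hat Estimated csPCa proportion among the unverified (ignored
#'   where there are none).
#' @param group Optional reporting-group label.
#' @return A `bv_fractional` tibble.
#' @examples
#' # facility-I PI-RADS 5 cell: 943 exams, 861 verified of which 756 csPCa+,
#' # estimated proportion 0.883 among the 82 unverified
#' fractional_table("5", n = 943, verified = 861, observed_pos = 756,
#'                  pi_hat = 0.883)
#' @export
fractional_table <- function(stratum, n, verified, observed_pos,
                             pi_hat = NA_real_, group = "pooled") {
  tb <- tibble::tibble(
    group = group,
    stratum = factor(as.character(stratum),
                     levels = c("1-2", "3", "4", "5"), ordered = TRUE),
    n = as.numeric(n),
    verified = as.numeric(verified),
    observed_pos = as.numeric(observed_pos),
    unverified = as.numeric(n) - as.numeric(verified),
    pi_hat = as.numeric(pi_hat)
  )
  if (any(tb$observed_pos > tb$verified | tb$verified > tb$n |
            tb$observed_pos < 0)) {
    stop_config("need 0 <= observed_pos <= verified <= n per stratum.")
  }
  if (any(tb$unverified > 0 & is.na(tb$pi_hat))) {
    stop_config("`pi_hat` required for strata with unverified exams.")
  }
  new_fractional(dplyr::mutate(
    tb,
    expected_pos = ifelse(.data$unverified == 0, 0,
                          .data$unverified * .data$pi_hat),
    n_pos = .data$observed_pos + .data$expected_pos,
    n_neg = (.data$verified - .data$observed_pos) +
      (.data$unverified - .data$expected_pos)
  ))
}

new_fractional <- function(tb) {
  tb <- dplyr::arrange(tb, .data$group, .data$stratum)
  class(tb) <- c("bv_fractional", class(tb))
  tb
}

# thresholds: strata at or above PI-RADS 3 / 4 / 5
threshold_strata <- list(`>=3` = c("3", "4", "5"), `>=4` = c("4", "5"),
                         `5` = "5")

#' Diagnostic performance metrics from a fractional contingency table
#'
#' Computes, per reporting group, the estimated and (where defined) observed
#' performance statistics of the ordinal score. With fractional counts
#' \eqn{N^+_s, N^-_s} (see [build_fractional_table()]) and observed verified
#' counts \eqn{O_s, V_s}:
#' \itemize{
#' \item sensitivity(>= i) = sum of \eqn{N^+_s} over s >= i / total \eqn{N^+};
#' \item specificity(>= i) = sum of \eqn{N^-_s} over s < i / total \eqn{N^-};
#' \item estimated PPV(>= i) = sum \eqn{N^+_s} / sum \eqn{n_s} over s >= i,
#'   observed PPV(>= i) = sum \eqn{O_s} / sum \eqn{V_s} over s >= i;
#' \item estimated NPV = \eqn{N^-_{1\mbox{-}2} / n_{1\mbox{-}2}}, observed
#'   NPV = \eqn{(V_{1\mbox{-}2}-O_{1\mbox{-}2}) / V_{1\mbox{-}2}};
#' \item estimated (observed) CDR = sum over s >= 3 of \eqn{N^+_s}
#'   (\eqn{O_s}) / N;
#' \item AIR = sum over s >= 3 of \eqn{n_s} / N (no estimated variant);
#' \item pathological confirmation rate per score = \eqn{V_s / n_s};
#' \item estimated prevalence = total \eqn{N^+} / N.
#' }
#' Sensitivity and specificity have no purely-observed counterpart reported
#' (their observed analogues over verified exams only are returned for
#' completeness); AIR and confirmation rates are fully observed. Metrics of
#' an empty group are returned as `NA`, never silently as zero.
#'
#' @param table A `bv_fractional` table.
#' @return A `bv_metric_report` tibble: `group`, `metric`, `threshold`,
#'   `estimated`, `observed`.
#' @examples
#' # fully-verified study: 626 biopsy-naive patients, positives per score
#' tab <- fractional_table(
#'   c("1-2", "3", "4", "5"), n = c(309, 40, 136, 141),
#'   verified = c(309, 40, 136, 141), observed_pos = c(10, 6, 34, 96)
#' )
#' metric_report(tab)
#' @export
metric_report <- function(table) {
  stopifnot(inherits(table, "bv_fractional"))
  out <- lapply(split(table, table$group), metric_report_one)
  rep <- dplyr::bind_rows(out)
  class(rep) <- c("bv_metric_report", class(rep))
  rep
}

metric_report_one <- function(tb) {
  g <- tb$group[1]
  ratio <- function(num, den) if (!isTRUE(den > 0)) NA_real_ else num / den
  total_pos <- sum(tb$n_pos)
  total_neg <- sum(tb$n_neg)
  n_total <- sum(tb$n)
  at <- function(strata) tb$stratum %in% strata

  rows <- list()
  for (th in names(threshold_strata)) {
    s <- threshold_strata[[th]]
    rows[[length(rows) + 1]] <- tibble::tibble(
      metric = "sensitivity", threshold = th,
      estimated = ratio(sum(tb$n_pos[at(s)]), total_pos),
      observed = ratio(sum(tb$observed_pos[at(s)]), sum(tb$observed_pos))
    )
    rows[[length(rows) + 1]] <- tibble::tibble(
      metric = "specificity", threshold = th,
      estimated = ratio(sum(tb$n_neg[!at(s)]), total_neg),
      observed = ratio(sum(tb$verified[!at(s)] - tb$observed_pos[!at(s)]),
                       sum(tb$verified - tb$observed_pos))
    )
    rows[[length(rows) + 1]] <- tibble::tibble(
      metric = "ppv", threshold = th,
      estimated = ratio(sum(tb$n_pos[at(s)]), sum(tb$n[at(s)])),
      observed = ratio(sum(tb$observed_pos[at(s)]), sum(tb$verified[at(s)]))
    )
  }
  neg <- tb$stratum == "1-2"
  rows[[length(rows) + 1]] <- tibble::tibble(
    metric = "npv", threshold = "1-2",
    estimated = ratio(sum(tb$n_neg[neg]), sum(tb$n[neg])),
    observed = ratio(sum(tb$verified[neg] - tb$observed_pos[neg]),
                     sum(tb$verified[neg]))
  )
  pos3 <- at(threshold_strata[[">=3"]])
  rows[[length(rows) + 1]] <- tibble::tibble(
    metric = "cdr", threshold = ">=3",
    estimated = ratio(sum(tb$n_pos[pos3]), n_total),
    observed = ratio(sum(tb$observed_pos[pos3]), n_total)
  )
  rows[[length(rows) + 1]] <- tibble::tibble(
    metric = "air", threshold = ">=3",
    estimated = NA_real_,
    observed = ratio(sum(tb$n[pos3]), n_total)
  )
  for (s in as.character(tb$stratum)) {
    i <- tb$stratum == s
    rows[[length(rows) + 1]] <- tibble::tibble(
      metric = "confirmation_rate", threshold = s,
      estimated = NA_real_,
      observed = ratio(tb$verified[i], tb$n[i])
    )
  }
  rows[[length(rows) + 1]] <- tibble::tibble(
    metric = "prevalence", threshold = "all",
    estimated = ratio(total_pos, n_total),
    observed = ratio(sum(tb$observed_pos), sum(tb$verified))
  )
  auc <- tryCatch(roc_auc_fractional(tb), error = function(e) NULL)
  rows[[length(rows) + 1]] <- tibble::tibble(
    metric = "auc", threshold = "all",
    estimated = if (is.null(auc)) NA_real_ else auc$auc$estimated,
    observed = if (is.null(auc)) NA_real_ else auc$auc$observed
  )
  dplyr::bind_rows(rows) |>
    dplyr::mutate(group = g, .before = 1)
}

#' ROC curve and AUC from a fractional contingency table
#'
#' The estimated ROC uses the fractional whole-population counts
#' \eqn{N^+_s, N^-_s}; the observed ROC uses the verified counts only. With
#' the score order 1-2 < 3 < 4 < 5, the AUC is the tie-corrected pairwise
#' concordance
#' \deqn{AUC = \frac{\sum_{i<j} N^-_i N^+_j + \tfrac12 \sum_i N^-_i N^+_i}
#'   {\sum N^- \cdot \sum N^+},}
#' which equals the trapezoidal area under the ROC points at thresholds
#' >= 3, >= 4, 5 plus the corners (0,0) and (1,1).
#'
#' @param table A `bv_fractional` table (a single reporting group).
#' @return An object of class `bv_roc`: `auc` (tibble with `estimated`,
#'   `observed`) and `points` (tibble of ROC coordinates per variant).
#' @export
roc_auc_fractional <- function(table) {
  stopifnot(inherits(table, "bv_fractional"))
  if (length(unique(table$group)) > 1) {
    out <- lapply(split(table, table$group), roc_auc_fractional)
    auc <- dplyr::bind_rows(lapply(out, function(o) o$auc), .id = "group")
    points <- dplyr::bind_rows(lapply(out, function(o) o$points), .id = "group")
    return(structure(list(auc = auc, points = points), class = "bv_roc"))
  }
  tb <- dplyr::arrange(table, .data$stratum)

  auc_of <- function(pos, neg) {
    tp <- sum(pos)
    tn <- sum(neg)
    if (tp <= 0 || tn <= 0) {
      stop_fit("AUC undefined: no positives or no negatives.")
    }
    conc <- 0
    k <- length(pos)
    for (i in seq_len(k)) {
      if (i < k) conc <- conc + neg[i] * sum(pos[(i + 1):k])
      conc <- conc + 0.5 * neg[i] * pos[i]
    }
    conc / (tp * tn)
  }
  points_of <- function(pos, neg) {
    tp <- sum(pos)
    tn <- sum(neg)
    # cumulative from the highest score down: threshold >= s
    ord <- rev(seq_along(pos))
    tpr <- cumsum(pos[ord]) / tp
    fpr <- cumsum(neg[ord]) / tn
    tibble::tibble(
      threshold = c("none", paste0(">=", rev(as.character(tb$stratum)))),
      fpr = c(0, fpr), tpr = c(0, tpr)
    )
  }
  est_auc <- auc_of(tb$n_pos, tb$n_neg)
  obs_auc <- auc_of(tb$observed_pos, tb$verified - tb$observed_pos)
  points <- dplyr::bind_rows(
    dplyr::mutate(points_of(tb$n_pos, tb$n_neg), variant = "estimated"),
    dplyr::mutate(points_of(tb$observed_pos, tb$verified - tb$observed_pos),
                  variant = "observed")
  )
  structure(
    list(auc = tibble::tibble(estimated = est_auc, observed = obs_auc),
         points = points),
    class = "bv_roc"
  )
}

#' @export
print.bv_roc <- function(x, ...) {
  cat("<bv_roc>\n")
  print(x$auc)
  invisible(x)
}

#' @method autoplot bv_roc
#' @export
autoplot.bv_roc <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = .data$fpr, y = .data$tpr,
                               linetype = .data$variant)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey80") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  linetype = NULL) +
    ggplot2::theme_minimal()
}

#' Percentile-bootstrap confidence intervals for estimated metrics
#'
#' Recomputes every estimated metric on each bag's fractional table and
#' summarises the per-bag distribution: the point estimate is the mean over
#' bags and the CI the percentile order statistics at the requested level.
#'
#' @param bag_tables List of `bv_fractional` tables with aligned bag indices
#'   across strata (one table per bag).
#' @param level Confidence level (default 0.95). Fewer than 20 bags at the
#'   95% level triggers a warning (percentiles unstable).
#' @return A `bv_metric_report` tibble with columns `estimated` (mean over
#'   bags), `lower`, `upper`, and `observed` (from the first bag table;
#'   observed quantities do not vary across bags).
#' @export
propagate_bootstrap_ci <- function(bag_tables, level = 0.95) {
  stopifnot(length(bag_tables) >= 1)
  if (length(bag_tables) < 20 && level >= 0.95) {
    rlang::warn(sprintf(
      "only %d bags at level %.2f: percentile CIs are unstable.",
      length(bag_tables), level
    ))
  }
  reports <- lapply(bag_tables, metric_report)
  base <- reports[[1]][, c("group", "metric", "threshold", "observed")]
  est <- vapply(reports, function(r) r$estimated,
                numeric(nrow(reports[[1]])))
  if (is.null(dim(est))) est <- matrix(est, nrow = 1)
  cis <- t(apply(est, 1, percentile_ci, level = level))
  out <- dplyr::mutate(
    base,
    estimated = rowMeans(est),
    lower = cis[, 1],
    upper = cis[, 2],
    .before = "observed"
  )
  class(out) <- c("bv_metric_report", class(out))
  out
}

#' Format a metric report the way the clinical tables print
#'
#' Percentages with one decimal (half away from zero), AUC with two.
#'
#' @param report A `bv_metric_report`.
#' @return A tibble with formatted character columns.
#' @export
format_metric_report <- function(report) {
  fmt <- function(metric, value) {
    dplyr::case_when(
      is.na(value) ~ "",
      metric == "auc" ~ sprintf("%.2f", round_half_up(value, 2)),
      TRUE ~ sprintf("%.1f%%", round_half_up(100 * value, 1))
    )
  }
  out <- dplyr::mutate(
    report,
    dplyr::across(dplyr::any_of(c("estimated", "observed", "lower", "upper")),
                  ~ fmt(.data$metric, .x))
  )
  tibble::as_tibble(out)
}
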