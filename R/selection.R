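#' Forward feature selection with the one-standard-error rule
#'
#' Greedy forward selection over candidate clinical variables using
#' cross-validated AUC of a logistic model on the verified exams. At each
#' step the candidate whose addition maximises the mean stratified-CV AUC is
#' added (ties broken by candidate order); the path continues until every
#' candidate has been added. The chosen set is then the shortest prefix of
#' the path whose mean AUC is at least `best_auc - SE(best)`, with
#' `SE = sd(fold AUCs) / sqrt(n_folds)` — the usual one-standard-error
#' convention favouring the most parsimonious model with near-best error.
#'
#' Candidates are named clinical variables (see [default_features()] for the
#' naming); a multi-level variable such as `facility` enters or leaves the
#' model as a block of one-hot columns.
#'
#' @param matrix A `bv_feature_matrix` from [apply_preprocess_plan()]; only
#'   rows with a non-missing outcome are used.
#' @param candidates Character vector of candidate feature-group names, or a
#'   named list mapping candidate names to feature-matrix column names.
#' @param n_folds Number of stratified CV folds (default 5).
#' @param seed Integer seed for the fold assignment.
#' @param ridge Ridge penalty for the logistic fits.
#' @return An object of class `bv_selection_path` with the step-by-step path
#'   and the chosen set; see [tidy.bv_selection_path()].
#' @examples
#' cohort <- simulate_cohort(generator_config(n_exams = 800, seed = 3))
#' plan <- fit_preprocess_plan(cohort, seed = 3)
#' fm <- apply_preprocess_plan(plan, cohort)
#' sel <- forward_select_one_se(fm, c("age", "psad", "pirads"), seed = 3)
#' sel$chosen_set
#' @export
forward_select_one_se <- function(matrix, candidates, n_folds = 5L,
                                  seed = 1L, ridge = 1e-4) {
  if (length(candidates) == 0) stop_config("`candidates` must be nonempty.")
  if (n_folds < 2) stop_config("`n_folds` must be at least 2.")
  if (is.list(candidates)) {
    group_cols <- candidates
    candidates <- names(candidates)
    if (is.null(candidates) || any(candidates == "")) {
      stop_config("a list of candidates must be fully named.")
    }
  } else {
    group_cols <- NULL
  }
  keep <- !is.na(matrix$outcome)
  y <- as.numeric(matrix$outcome[keep])
  if (length(unique(y)) < 2) {
    stop_fit("outcome has a single class; selection is impossible.")
  }
  features <- attr(matrix, "features") %||%
    setdiff(names(matrix), c("exam_id", "outcome"))
  x_all <- as.matrix(matrix[keep, features, drop = FALSE])
  cols_of <- function(cand) {
    if (is.null(group_cols)) {
      feature_group_columns(cand, features)
    } else {
      intersect(group_cols[[cand]], features)
    }
  }

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  folds <- stratified_folds(y, n_folds)
  if (any(tapply(y, folds, function(v) length(unique(v))) < 2)) {
    stop_fit("a fold lacks both outcome classes; use fewer folds or more data.")
  }

  cv_auc <- function(cols) {
    aucs <- vapply(seq_len(n_folds), function(k) {
      tr <- folds != k
      if (length(cols) == 0) {
        scores <- rep(mean(y[tr]), sum(!tr))
      } else {
        fit <- fit_logistic(x_all[tr, cols, drop = FALSE], y[tr], ridge = ridge)
        scores <- predict(fit, x_all[!tr, cols, drop = FALSE])
      }
      rank_auc(scores, y[!tr])
    }, numeric(1))
    c(mean = mean(aucs), se = stats::sd(aucs) / sqrt(n_folds))
  }

  remaining <- candidates
  current_cols <- character(0)
  path <- list()
  step <- 0L
  while (length(remaining) > 0) {
    step <- step + 1L
    scores <- vapply(remaining, function(cand) {
      cols <- union(current_cols, cols_of(cand))
      cv_auc(cols)[["mean"]]
    }, numeric(1))
    best <- remaining[which.max(scores)]  # which.max: first on ties
    current_cols <- union(current_cols, cols_of(best))
    stat <- cv_auc(current_cols)
    path[[step]] <- tibble::tibble(
      step = step, feature = best,
      mean_auc = stat[["mean"]], se = stat[["se"]]
    )
    remaining <- setdiff(remaining, best)
  }
  path <- dplyr::bind_rows(path)
  best_step <- which.max(path$mean_auc)
  threshold <- path$mean_auc[best_step] - path$se[best_step]
  chosen_n <- min(which(path$mean_auc >= threshold))
  structure(
    list(
      path = path,
      chosen_set = path$feature[seq_len(chosen_n)],
      best_auc = path$mean_auc[best_step],
      one_se_threshold = threshold,
      n_folds = as.integer(n_folds),
      seed = as.integer(seed)
    ),
    class = "bv_selection_path"
  )
}

#' @export
print.bv_selection_path <- function(x, ...) {
  cat("<bv_selection_path>\n")
  print(x$path, n = Inf)
  cat(sprintf("best CV AUC %.4f; one-SE threshold %.4f\n",
              x$best_auc, x$one_se_threshold))
  cat("chosen set:", paste(x$chosen_set, collapse = ", "), "\n")
  invisible(x)
}

#' Tidy a selection path
#'
#' @param x A `bv_selection_path`.
#' @param ... Unused.
#' @return A tibble with one row per forward step: `step`, `feature`,
#'   `mean_auc`, `se`, and `chosen` flagging the one-SE-rule prefix.
#' @method tidy bv_selection_path
#' @export
tidy.bv_selection_path <- function(x, ...) {
  dplyr::mutate(x$path, chosen = .data$feature %in% x$chosen_set)
}

#' @method glance bv_selection_path
#' @export
glance.bv_selection_path <- function(x, ...) {
  tibble::tibble(
    n_candidates = nrow(x$path),
    n_chosen = length(x$chosen_set),
    best_auc = x$best_auc,
    one_se_threshold = x$one_se_threshold,
    chosen_auc = x$path$mean_auc[length(x$chosen_set)]
  )
}

#' @method autoplot bv_selection_path
#' @export
autoplot.bv_selection_path <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$step, y = .data$mean_auc)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$mean_auc - .data$se,
                   ymax = .data$mean_auc + .data$se),
      fill = "grey85"
    ) +
    ggplot2::geom_hline(yintercept = object$one_se_threshold,
                        linetype = "dashed", colour = "grey40") +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(colour = .data$chosen), size = 2) +
    ggplot2::scale_x_continuous(breaks = d$step, labels = d$feature) +
    ggplot2::labs(x = NULL, y = "cross-validated AUC", colour = "chosen") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 35, hjust = 1))
}
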