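#' Fit a preprocessing plan on training records
#'
#' Estimates, from the training records only, everything needed to turn raw
#' examination records into a complete numeric feature matrix: log
#' transforms of PSA and prostate volume, chained-equation imputation models
#' for the two log targets, PSAD derivation, standardisation statistics
#' (mean/SD) for the continuous features, and fixed one-hot level lists for
#' the categorical features. Applying the plan never refits any statistic,
#' so it can be fitted on a bootstrap bag and applied leak-free to held-out,
#' out-of-bag and unverified exams.
#'
#' The chained imputation uses normal-linear conditional models: each log
#' target is regressed on age, PI-RADS score, facility, biopsy history and
#' the other log target; missing values are initialised at the training mean
#' and the two conditionals are refitted and redrawn for `n_iter` sweeps.
#' Imputed values are stochastic draws from the conditional (prediction plus
#' a residual-SD normal draw), so repeated application across bootstrap bags
#' propagates imputation uncertainty.
#'
#' @param train Tibble of examination records (see [simulate_cohort()]).
#' @param seed Integer seed controlling the stochastic imputation draws.
#' @param n_iter Number of chained-equation sweeps (default 10).
#' @return An object of class `bv_preprocess_plan`.
#' @export
fit_preprocess_plan <- function(train, seed = 1L, n_iter = 10L) {
  if (nrow(train) == 0) stop_fit("training set is empty.")
  df <- train
  df$log_psa <- log(df$psa)
  df$log_vol <- log(df$volume)

  for (f in c("age", "log_psa", "log_vol")) {
    v <- df[[f]][!is.na(df[[f]])]
    if (length(v) == 0) {
      stop_fit(sprintf("imputation target `%s` is missing for all training rows.", f))
    }
    if (length(unique(v)) < 2) {
      stop_fit(sprintf("continuous feature `%s` has zero variance on the training set.", f))
    }
  }

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  init_means <- c(log_psa = mean(df$log_psa, na.rm = TRUE),
                  log_vol = mean(df$log_vol, na.rm = TRUE))
  fit <- chained_fit(df, init_means, n_iter)

  # Standardisation statistics are computed on the training set completed by
  # the *stored* models with the plan seed, so that applying the plan to its
  # own training set reproduces the identical imputed values (and hence
  # exactly mean 0 / sd 1 columns).
  partial <- structure(
    list(imputation_models = fit$models, init_means = init_means,
         n_iter = as.integer(n_iter), seed = as.integer(seed)),
    class = "bv_preprocess_plan"
  )
  completed <- impute_chained(partial, train, seed = seed)
  completed$log_psad <- completed$log_psa - completed$log_vol
  stats <- lapply(c("age", "log_psa", "log_vol", "log_psad"), function(f) {
    m <- mean(completed[[f]])
    s <- stats::sd(completed[[f]])
    if (!is.finite(s) || s <= 0) {
      stop_fit(sprintf("continuous feature `%s` has zero variance on the training set.", f))
    }
    c(mean = m, sd = s)
  })
  names(stats) <- c("age", "log_psa", "log_vol", "log_psad")

  structure(
    list(
      log_targets = c("psa", "volume"),
      standardize_stats = stats,
      onehot_levels = list(
        facility = c("I", "II", "III"),
        prior_biopsy = c("naive", "benign", "unknown"),
        race = c("caucasian", "african_american", "asian", "other_unknown")
      ),
      imputation_models = fit$models,
      init_means = init_means,
      n_iter = as.integer(n_iter),
      seed = as.integer(seed)
    ),
    class = "bv_preprocess_plan"
  )
}

# Imputation design matrix: the modelled covariates other than the target.
impute_design <- function(df, other_target_values) {
  cbind(
    1,
    age = df$age,
    pirads = as.numeric(df$pirads),
    fac_II = as.numeric(df$facility == "II"),
    fac_III = as.numeric(df$facility == "III"),
    benign = as.numeric(df$prior_biopsy == "benign"),
    unknown = as.numeric(df$prior_biopsy == "unknown"),
    other = other_target_values
  )
}

# Chained-equation sweeps on the training data; returns final per-target
# normal-linear models (coefficients + residual sd) and the completed data.
chained_fit <- function(df, init_means, n_iter) {
  cur <- df
  miss <- list(log_psa = is.na(cur$log_psa), log_vol = is.na(cur$log_vol))
  cur$log_psa[miss$log_psa] <- init_means["log_psa"]
  cur$log_vol[miss$log_vol] <- init_means["log_vol"]
  models <- list()
  targets <- c("log_psa", "log_vol")
  any_missing <- vapply(miss, any, logical(1))
  iters <- if (any(any_missing)) n_iter else 1L
  for (it in seq_len(iters)) {
    for (t in targets) {
      other <- setdiff(targets, t)
      z <- impute_design(cur, cur[[other]])
      obs <- !miss[[t]]
      qr_fit <- stats::lm.fit(z[obs, , drop = FALSE], cur[[t]][obs])
      beta <- ifelse(is.na(qr_fit$coefficients), 0, qr_fit$coefficients)
      sigma <- sqrt(sum(qr_fit$residuals^2) /
                      max(sum(obs) - qr_fit$rank, 1))
      models[[t]] <- list(coef = beta, sigma = sigma)
      if (any(miss[[t]])) {
        pred <- drop(z[miss[[t]], , drop = FALSE] %*% beta)
        cur[[t]][miss[[t]]] <- pred + stats::rnorm(sum(miss[[t]]), 0, sigma)
      }
    }
  }
  list(models = models, completed = cur)
}

#' @export
print.bv_preprocess_plan <- function(x, ...) {
  cat("<bv_preprocess_plan>\n")
  for (f in names(x$standardize_stats)) {
    s <- x$standardize_stats[[f]]
    cat(sprintf("  %-9s mean = %8.4f  sd = %.4f\n", f, s["mean"], s["sd"]))
  }
  cat(sprintf("  chained imputation: %d sweeps, targets log(psa), log(volume)\n",
              x$n_iter))
  invisible(x)
}

#' Impute missing log-PSA / log-volume with a fitted plan
#'
#' Applies the plan's chained normal-linear imputation models to new
#' records: missing log targets are initialised at the training means, then
#' the stored conditionals are iterated with stochastic residual draws for
#' the plan's number of sweeps. Non-missing values are never altered.
#'
#' @param plan A [fit_preprocess_plan()] result.
#' @param records Tibble of examination records.
#' @param seed Seed for the imputation draws (defaults to the plan seed).
#' @return `records` with columns `log_psa`, `log_vol` added and complete.
#' @export
impute_chained <- function(plan, records, seed = plan$seed) {
  stopifnot(inherits(plan, "bv_preprocess_plan"))
  df <- records
  df$log_psa <- log(df$psa)
  df$log_vol <- log(df$volume)
  miss <- list(log_psa = is.na(df$log_psa), log_vol = is.na(df$log_vol))
  if (!any(unlist(miss))) return(df)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  df$log_psa[miss$log_psa] <- plan$init_means["log_psa"]
  df$log_vol[miss$log_vol] <- plan$init_means["log_vol"]
  targets <- c("log_psa", "log_vol")
  for (it in seq_len(plan$n_iter)) {
    for (t in targets) {
      if (!any(miss[[t]])) next
      other <- setdiff(targets, t)
      m <- plan$imputation_models[[t]]
      z <- impute_design(df, df[[other]])
      pred <- drop(z[miss[[t]], , drop = FALSE] %*% m$coef)
      df[[t]][miss[[t]]] <- pred + stats::rnorm(sum(miss[[t]]), 0, m$sigma)
    }
  }
  df
}

#' Apply a preprocessing plan to records
#'
#' Fixed order of operations: log-transform PSA and volume, impute missing
#' log values with the plan's chained models, derive PSAD = PSA / volume on
#' the natural scale and log-transform it, standardise the continuous
#' features with the training statistics, one-hot encode facility / biopsy
#' history / race (first level is the reference) and the PI-RADS score
#' (score 1 reference), and binary-encode the flags. The result has no
#' missing feature values. An unseen categorical level maps to an all-zero
#' one-hot row with a warning.
#'
#' @inheritParams impute_chained
#' @return A tibble (`bv_feature_matrix`): `exam_id`, `outcome` (the csPCa
#'   flag, `NA` for unverified exams) and numeric feature columns; the
#'   feature column names are recorded in attribute `features`.
#' @export
apply_preprocess_plan <- function(plan, records, seed = plan$seed) {
  stopifnot(inherits(plan, "bv_preprocess_plan"))
  df <- impute_chained(plan, records, seed = seed)
  df$log_psad <- df$log_psa - df$log_vol

  std <- function(f) {
    s <- plan$standardize_stats[[f]]
    (df[[f]] - s["mean"]) / s["sd"]
  }
  onehot <- function(var, prefix) {
    levels <- plan$onehot_levels[[var]]
    vals <- as.character(df[[var]])
    unseen <- stats::na.omit(setdiff(unique(vals), levels))
    if (length(unseen)) {
      rlang::warn(sprintf("unseen level(s) in `%s` mapped to all-zero one-hot: %s",
                          var, paste(unseen, collapse = ", ")))
    }
    out <- lapply(levels[-1], function(l) as.numeric(vals == l))
    names(out) <- paste0(prefix, "_", levels[-1])
    out
  }

  feats <- c(
    list(
      age = std("age"),
      log_psa = std("log_psa"),
      log_vol = std("log_vol"),
      log_psad = std("log_psad")
    ),
    onehot("facility", "facility"),
    stats::setNames(lapply(2:5, function(s) as.numeric(df$pirads == s)),
                    paste0("score_", 2:5)),
    onehot("prior_biopsy", "biopsy"),
    list(
      fam_prostate = as.numeric(df$fam_prostate),
      fam_breast = as.numeric(df$fam_breast),
      dre_nodule = as.numeric(df$dre_nodule)
    ),
    onehot("race", "race")
  )
  out <- tibble::tibble(
    exam_id = df$exam_id,
    outcome = ifelse(is.na(df$verified) | !df$verified, NA, as.numeric(df$cspca)),
    !!!feats
  )
  structure(out, features = setdiff(names(out), c("exam_id", "outcome")),
            class = c("bv_feature_matrix", class(out)))
}

# Candidate feature groups: maps a clinical variable name to the feature
# matrix columns that encode it.
feature_group_columns <- function(groups, available) {
  map <- list(
    age = "age",
    psa = "log_psa",
    volume = "log_vol",
    psad = "log_psad",
    facility = c("facility_II", "facility_III"),
    pirads = paste0("score_", 2:5),
    biopsy = c("biopsy_benign", "biopsy_unknown"),
    fam_prostate = "fam_prostate",
    fam_breast = "fam_breast",
    dre_nodule = "dre_nodule",
    race = c("race_african_american", "race_asian", "race_other_unknown")
  )
  unknown <- setdiff(groups, names(map))
  if (length(unknown)) {
    stop_config(paste0("unknown feature group(s): ", paste(unknown, collapse = ", ")))
  }
  cols <- unlist(map[groups], use.names = FALSE)
  intersect(cols, available)
}

#' The default model feature set
#'
#' The six clinical variables retained by forward selection with the
#' one-standard-error rule: age, previous benign-biopsy history, facility,
#' PI-RADS score, PSAD and prostate volume.
#'
#' @return Character vector of feature-group names.
#' @export
default_features <- function() {
  c("age", "biopsy", "facility", "pirads", "psad", "volume")
}
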