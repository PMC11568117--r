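#' Configuration for the synthetic multi-facility cohort generator
#'
#' Builds (and validates) the configuration of the synthetic prostate-MRI
#' cohort generator. The defaults are a preset tuned once, by moment matching,
#' to the marginal structure of a large three-facility clinical cohort:
#' skewed PSA and prostate volume (log-normal), about 55% of exams scored
#' PI-RADS 1-2, score-dependent pathological-confirmation (verification)
#' rates falling from ~91% at PI-RADS 5 to ~15% at PI-RADS 1-2, and a
#' monotone score-to-risk gradient (csPCa proportion rising from ~0.15 at
#' PI-RADS 1-2 to ~0.85 at PI-RADS 5). The exact joint distribution of such
#' cohorts is not identifiable from published marginals, so the preset is
#' illustrative rather than canonical.
#'
#' Disease and verification are logistic models over named features. Allowed
#' feature names for both coefficient maps: `intercept`, `age_std`,
#' `log_psa_std`, `log_vol_std`, `log_psad_std`, `benign_biopsy`,
#' `fam_prostate`, `fam_breast`, `dre_nodule`; the verification map may
#' additionally contain per-score offsets `pirads2`..`pirads5`. Standardised
#' features use the configured population moments, so coefficients are on a
#' per-SD scale.
#'
#' @param n_exams Number of MRI examinations to generate.
#' @param facility_weights Probabilities of facilities I, II, III (sum to 1).
#' @param age_mean,age_sd Age distribution (years), truncated below at 35.
#' @param log_psa_mean,log_psa_sd Mean/SD of log PSA (log ng/mL).
#' @param log_vol_mean,log_vol_sd Mean/SD of log prostate volume (log mL).
#' @param psa_vol_corr Correlation of log PSA and log volume (larger glands
#'   secrete more PSA; the true joint structure is unpublished, this single
#'   knob is the only dependence modelled).
#' @param disease_coefficients Named vector: logistic linear predictor of
#'   latent clinically significant cancer (csPCa).
#' @param reading_sd SD of the Gaussian reading noise added to the disease
#'   linear predictor before discretising into PI-RADS scores. One knob
#'   controlling how sharply the score tracks risk.
#' @param miss_rate Probability that a lesion is radiologically occult (e.g.
#'   anterior or transition-zone location, degraded image quality): the
#'   latent reading is shifted down by `miss_shift`, so the exam is scored
#'   PI-RADS 1-2 regardless of true risk. This asymmetric second noise
#'   component is what reproduces a non-trivial csPCa proportion in the
#'   PI-RADS 1-2 stratum alongside a sharp risk gradient at 4-5.
#' @param miss_shift Downward shift of the latent reading for occult lesions.
#' @param score_cutpoints Four strictly increasing thresholds mapping the
#'   noisy latent risk to PI-RADS 1-5.
#' @param verification_mode `"MAR"` (verification depends only on modelled
#'   covariates and the score), `"MNAR"` (adds an unmodelled confounder that
#'   raises disease risk and lowers verification probability), or `"FULL"`
#'   (everyone verified).
#' @param verification_coefficients Named vector for the verification
#'   (biopsy-selection) logistic model.
#' @param mnar_hidden_effect Effect size of the hidden confounder on both the
#'   disease (+) and verification (-) linear predictors; only used under
#'   `"MNAR"` and forced to 0 under `"MAR"`.
#' @param missing_rate_psa,missing_rate_vol MCAR missingness proportions in
#'   `[0, 1)` for PSA and volume.
#' @param seed Integer seed; all generation is deterministic given the seed.
#' @return A validated `bv_generator_config` list.
#' @seealso [generate_cohort()], [simulate_cohort()]
#' @export
generator_config <- function(
    n_exams = 12191L,
    facility_weights = c(I = 0.534, II = 0.213, III = 0.253),
    age_mean = 65.7, age_sd = 8.4,
    log_psa_mean = 1.82, log_psa_sd = 0.55,
    log_vol_mean = 3.97, log_vol_sd = 0.55,
    psa_vol_corr = 0.30,
    disease_coefficients = c(
      intercept = -0.7011, age_std = 0.5470, log_psad_std = 1.9535,
      log_vol_std = -0.5470, benign_biopsy = -1.2502,
      fam_prostate = 0.3907, dre_nodule = 0.7032
    ),
    reading_sd = 0.44,
    miss_rate = 0.156,
    miss_shift = 9.55,
    # Constants below frozen from a one-off moment-matching run (1e6 draws):
    # cutpoints are quantiles of the latent reading at cumulative score
    # shares 0.250 / 0.554 / 0.665 / 0.852, giving per-stratum mean latent
    # risks 0.155 / 0.301 / 0.565 / 0.887 and overall prevalence 0.356.
    score_cutpoints = c(-4.1505, -1.2947, -0.4584, 1.2345),
    verification_mode = c("MAR", "MNAR", "FULL"),
    # Per-score verification intercepts tuned to pooled confirmation rates
    # 0.154 / 0.692 / 0.899 / 0.914.
    verification_coefficients = c(
      intercept = -1.1697, pirads3 = 2.2156, pirads4 = 3.3371,
      pirads5 = 3.0351, age_std = 0.15, log_psad_std = 0.50,
      benign_biopsy = -0.60
    ),
    mnar_hidden_effect = 0,
    missing_rate_psa = 0.106,
    missing_rate_vol = 0.030,
    seed = 1L) {
  verification_mode <- match.arg(verification_mode)
  cfg <- list(
    n_exams = as.integer(n_exams),
    facility_weights = facility_weights,
    age_mean = age_mean, age_sd = age_sd,
    log_psa_mean = log_psa_mean, log_psa_sd = log_psa_sd,
    log_vol_mean = log_vol_mean, log_vol_sd = log_vol_sd,
    psa_vol_corr = psa_vol_corr,
    disease_coefficients = disease_coefficients,
    reading_sd = reading_sd,
    miss_rate = miss_rate,
    miss_shift = miss_shift,
    score_cutpoints = score_cutpoints,
    verification_mode = verification_mode,
    verification_coefficients = verification_coefficients,
    mnar_hidden_effect = if (verification_mode == "MNAR") mnar_hidden_effect else 0,
    missing_rate_psa = missing_rate_psa,
    missing_rate_vol = missing_rate_vol,
    seed = as.integer(seed)
  )
  validate_generator_config(cfg)
  structure(cfg, class = "bv_generator_config")
}

validate_generator_config <- function(cfg) {
  if (!is.numeric(cfg$n_exams) || cfg$n_exams < 1) {
    stop_config("`n_exams` must be a positive integer.")
  }
  w <- cfg$facility_weights
  if (length(w) != 3 || any(w < 0) || abs(sum(w) - 1) > 1e-9) {
    stop_config("`facility_weights` must be 3 nonnegative values summing to 1 (tolerance 1e-9).")
  }
  cp <- cfg$score_cutpoints
  if (length(cp) != 4 || any(diff(cp) <= 0)) {
    stop_config("`score_cutpoints` must be 4 strictly increasing values.")
  }
  for (r in c("missing_rate_psa", "missing_rate_vol")) {
    if (cfg[[r]] < 0 || cfg[[r]] >= 1) {
      stop_config(sprintf("`%s` must lie in [0, 1).", r))
    }
  }
  if (cfg$age_sd <= 0 || cfg$log_psa_sd <= 0 || cfg$log_vol_sd <= 0 || cfg$reading_sd < 0) {
    stop_config("scale parameters must be positive.")
  }
  if (abs(cfg$psa_vol_corr) >= 1) stop_config("`psa_vol_corr` must lie in (-1, 1).")
  if (cfg$miss_rate < 0 || cfg$miss_rate >= 1 || cfg$miss_shift < 0) {
    stop_config("`miss_rate` must lie in [0, 1) and `miss_shift` must be nonnegative.")
  }
  invisible(cfg)
}

#' @export
print.bv_generator_config <- function(x, ...) {
  cat("<bv_generator_config>\n")
  cat(sprintf("  n_exams: %d   mode: %s   seed: %d\n",
              x$n_exams, x$verification_mode, x$seed))
  cat(sprintf("  facilities: %s\n",
              paste(sprintf("%s=%.3f", names(x$facility_weights), x$facility_weights),
                    collapse = " ")))
  cat(sprintf("  missing rates: psa=%.3f vol=%.3f   mnar effect: %.2f\n",
              x$missing_rate_psa, x$missing_rate_vol, x$mnar_hidden_effect))
  invisible(x)
}

# Design matrix of named generator features; `benign_biopsy` uses the latent
# (pre-masking) biopsy history because "unknown" is only a label mask.
generator_features <- function(df, cfg) {
  psad_mean <- cfg$log_psa_mean - cfg$log_vol_mean
  psad_sd <- sqrt(cfg$log_psa_sd^2 + cfg$log_vol_sd^2 -
                    2 * cfg$psa_vol_corr * cfg$log_psa_sd * cfg$log_vol_sd)
  cbind(
    intercept = 1,
    age_std = (df$age - cfg$age_mean) / cfg$age_sd,
    log_psa_std = (df$.log_psa - cfg$log_psa_mean) / cfg$log_psa_sd,
    log_vol_std = (df$.log_vol - cfg$log_vol_mean) / cfg$log_vol_sd,
    log_psad_std = (df$.log_psa - df$.log_vol - psad_mean) / psad_sd,
    benign_biopsy = as.numeric(df$.benign_latent),
    fam_prostate = as.numeric(df$fam_prostate),
    fam_breast = as.numeric(df$fam_breast),
    dre_nodule = as.numeric(df$dre_nodule)
  )
}

linear_predictor <- function(features, coefs) {
  unknown <- setdiff(names(coefs), c(colnames(features), paste0("pirads", 2:5)))
  if (length(unknown)) {
    stop_config(paste0("unknown coefficient name(s): ", paste(unknown, collapse = ", ")))
  }
  use <- intersect(names(coefs), colnames(features))
  drop(features[, use, drop = FALSE] %*% coefs[use])
}

#' Generate a synthetic cohort of prostate-MRI examinations
#'
#' Draws `n_exams` examination records: facility, age, PSA and prostate
#' volume (correlated log-normal), prior-biopsy history with an "unknown"
#' label mask, family histories, DRE nodule flag, race; a latent csPCa status
#' from the configured disease logistic model; and a PI-RADS 1-5 score
#' obtained by adding Gaussian reading noise to the disease linear predictor
#' and thresholding at the configured cutpoints. Verification and missingness
#' are applied by [apply_verification()] and [inject_missingness()].
#'
#' @param config A [generator_config()].
#' @return A tibble with one row per examination: `exam_id`, `facility`,
#'   `age`, `psa`, `volume`, `pirads` (1-5), `prior_biopsy`, `fam_prostate`,
#'   `fam_breast`, `dre_nodule`, `race`, `verified` (all `NA` until
#'   [apply_verification()]), `cspca` (`NA` until verification),
#'   `true_cspca` (latent truth), plus hidden simulation columns (prefixed
#'   `.`) consumed by [apply_verification()].
#' @export
generate_cohort <- function(config) {
  validate_generator_config(config)
  cfg <- config
  n <- cfg$n_exams
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cfg$seed)

  facility <- sample(c("I", "II", "III"), n, replace = TRUE,
                     prob = cfg$facility_weights)
  age <- pmax(stats::rnorm(n, cfg$age_mean, cfg$age_sd), 35)
  z1 <- stats::rnorm(n)
  z2 <- stats::rnorm(n)
  rho <- cfg$psa_vol_corr
  log_psa <- cfg$log_psa_mean + cfg$log_psa_sd * z1
  log_vol <- cfg$log_vol_mean + cfg$log_vol_sd * (rho * z1 + sqrt(1 - rho^2) * z2)

  benign_latent <- stats::runif(n) < 0.47
  unknown_mask <- stats::runif(n) < 0.36
  prior_biopsy <- ifelse(unknown_mask, "unknown",
                         ifelse(benign_latent, "benign", "naive"))
  fam_prostate <- stats::runif(n) < 0.28
  fam_breast <- stats::runif(n) < 0.105
  dre_nodule <- stats::runif(n) < 0.08
  race <- sample(c("caucasian", "african_american", "asian", "other_unknown"),
                 n, replace = TRUE, prob = c(0.912, 0.037, 0.020, 0.031))
  hidden <- stats::rnorm(n)

  df <- tibble::tibble(
    exam_id = sprintf("E%06d", seq_len(n)),
    facility, age,
    psa = exp(log_psa), volume = exp(log_vol),
    pirads = NA_integer_,
    prior_biopsy, fam_prostate, fam_breast, dre_nodule, race,
    verified = NA, cspca = NA,
    true_cspca = NA,
    .log_psa = log_psa, .log_vol = log_vol,
    .benign_latent = benign_latent, .hidden = hidden
  )
  feats <- generator_features(df, cfg)
  eta <- linear_predictor(feats, cfg$disease_coefficients) +
    cfg$mnar_hidden_effect * hidden
  df$true_cspca <- stats::runif(n) < stats::plogis(eta)
  latent_score <- eta + stats::rnorm(n, 0, cfg$reading_sd) -
    cfg$miss_shift * (stats::runif(n) < cfg$miss_rate)
  df$pirads <- 1L + findInterval(latent_score, cfg$score_cutpoints)
  df$.disease_lp <- eta
  df
}

#' Apply the verification (biopsy-selection) mechanism
#'
#' Draws the `verified` flag from the configured verification logistic model
#' and reveals `cspca = true_cspca` for verified exams only (pathology is
#' treated as error-free); `cspca` is `NA` for unverified exams. Under
#' `"MAR"` the model uses only covariates available to the estimator plus the
#' PI-RADS score; under `"MNAR"` the hidden confounder lowers verification
#' probability for exactly the patients whose disease risk it raised; under
#' `"FULL"` everyone is verified.
#'
#' @param records A cohort from [generate_cohort()] (must carry `true_cspca`
#'   and `pirads`).
#' @param config The same [generator_config()].
#' @return The cohort with `verified` and `cspca` filled in.
#' @export
apply_verification <- function(records, config) {
  validate_generator_config(config)
  if (any(is.na(records$true_cspca)) || any(is.na(records$pirads))) {
    rlang::abort("records must carry `true_cspca` and `pirads`; run generate_cohort() first.",
                 class = "bagverify_precondition_error")
  }
  cfg <- config
  n <- nrow(records)
  if (cfg$verification_mode == "FULL") {
    records$verified <- TRUE
    records$cspca <- records$true_cspca
    return(records)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cfg$seed + 1L)

  feats <- generator_features(records, cfg)
  vc <- cfg$verification_coefficients
  eta <- linear_predictor(feats, vc)
  for (sc in 2:5) {
    key <- paste0("pirads", sc)
    if (key %in% names(vc)) eta <- eta + vc[[key]] * (records$pirads == sc)
  }
  if (cfg$verification_mode == "MNAR") {
    eta <- eta - cfg$mnar_hidden_effect * records$.hidden
  }
  records$verified <- stats::runif(n) < stats::plogis(eta)
  records$cspca <- ifelse(records$verified, records$true_cspca, NA)
  records
}

#' Inject missing-completely-at-random PSA/volume values
#'
#' Each PSA (volume) value is independently set to missing with probability
#' `missing_rate_psa` (`missing_rate_vol`); all other fields are untouched.
#'
#' @inheritParams apply_verification
#' @return The cohort with `NA`s injected into `psa` / `volume`.
#' @export
inject_missingness <- function(records, config) {
  validate_generator_config(config)
  cfg <- config
  if (cfg$missing_rate_psa == 0 && cfg$missing_rate_vol == 0) return(records)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cfg$seed + 2L)
  n <- nrow(records)
  records$psa[stats::runif(n) < cfg$missing_rate_psa] <- NA_real_
  records$volume[stats::runif(n) < cfg$missing_rate_vol] <- NA_real_
  records
}

#' Simulate a complete cohort (generation, verification, missingness)
#'
#' Convenience wrapper chaining [generate_cohort()], [apply_verification()]
#' and [inject_missingness()], then dropping the hidden simulation columns.
#'
#' @inheritParams generate_cohort
#' @param keep_latent Keep the internal latent columns (prefixed `.`)?
#' @return A tibble of examination records ready for the estimation pipeline.
#' @examples
#' cohort <- simulate_cohort(generator_config(n_exams = 500, seed = 42))
#' dplyr::count(cohort, pirads, verified)
#' @export
simulate_cohort <- function(config = generator_config(), keep_latent = FALSE) {
  out <- generate_cohort(config) |>
    apply_verification(config) |>
    inject_missingness(config)
  if (!keep_latent) out <- dplyr::select(out, -dplyr::starts_with("."))
  out
}

# Save/restore the global RNG state so seeded generator calls do not disturb
# the caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Read / write cohort CSV files
#'
#' The on-disk cohort format has one header row and one row per examination
#' with columns `exam_id, facility, age, psa, volume, pirads, prior_biopsy,
#' fam_prostate, fam_breast, dre_nodule, race, verified, cspca, true_cspca`;
#' empty fields encode missing values (`cspca` is empty for unverified exams,
#' `true_cspca` for real cohorts).
#'
#' @param path File path.
#' @param records Cohort tibble.
#' @return `read_cohort()` returns the cohort tibble; `write_cohort()`
#'   returns `path` invisibly.
#' @export
read_cohort <- function(path) {
  readr::read_csv(
    path,
    col_types = readr::cols(
      exam_id = readr::col_character(),
      facility = readr::col_character(),
      age = readr::col_double(),
      psa = readr::col_double(),
      volume = readr::col_double(),
      pirads = readr::col_integer(),
      prior_biopsy = readr::col_character(),
      fam_prostate = readr::col_logical(),
      fam_breast = readr::col_logical(),
      dre_nodule = readr::col_logical(),
      race = readr::col_character(),
      verified = readr::col_logical(),
      cspca = readr::col_logical(),
      true_cspca = readr::col_logical()
    )
  )
}

#' @rdname read_cohort
#' @export
write_cohort <- function(records, path) {
  cols <- c("exam_id", "facility", "age", "psa", "volume", "pirads",
            "prior_biopsy", "fam_prostate", "fam_breast", "dre_nodule",
            "race", "verified", "cspca", "true_cspca")
  out <- records[, intersect(cols, names(records))]
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Read / write generator configuration as flat YAML
#'
#' Round-trippable flat keyed text representation of a
#' [generator_config()]; named coefficient vectors are stored as nested maps.
#'
#' @param config A `bv_generator_config`.
#' @param path File path.
#' @return `read_generator_config()` returns a validated
#'   `bv_generator_config`.
#' @export
write_generator_config <- function(config, path) {
  x <- unclass(config)
  x$facility_weights <- as.list(x$facility_weights)
  x$disease_coefficients <- as.list(x$disease_coefficients)
  x$verification_coefficients <- as.list(x$verification_coefficients)
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname write_generator_config
#' @export
read_generator_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(generator_config, list(
    n_exams = x$n_exams,
    facility_weights = unlist(x$facility_weights),
    age_mean = x$age_mean, age_sd = x$age_sd,
    log_psa_mean = x$log_psa_mean, log_psa_sd = x$log_psa_sd,
    log_vol_mean = x$log_vol_mean, log_vol_sd = x$log_vol_sd,
    psa_vol_corr = x$psa_vol_corr,
    disease_coefficients = unlist(x$disease_coefficients),
    reading_sd = x$reading_sd,
    miss_rate = x$miss_rate,
    miss_shift = x$miss_shift,
    score_cutpoints = unlist(x$score_cutpoints),
    verification_mode = x$verification_mode,
    verification_coefficients = unlist(x$verification_coefficients),
    mnar_hidden_effect = x$mnar_hidden_effect,
    missing_rate_psa = x$missing_rate_psa,
    missing_rate_vol = x$missing_rate_vol,
    seed = x$seed
  ))
}

#' Collapse PI-RADS scores into the reporting strata
#'
#' Scores 1 and 2 are generated separately but always reported as a single
#' stratum `"1-2"`; 3, 4, 5 map to themselves.
#'
#' @param pirads Integer vector of scores 1-5.
#' @return A factor with levels `"1-2" < "3" < "4" < "5"`.
#' @export
pirads_stratum <- function(pirads) {
  factor(ifelse(pirads <= 2, "1-2", as.character(pirads)),
         levels = c("1-2", "3", "4", "5"), ordered = TRUE)
}
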