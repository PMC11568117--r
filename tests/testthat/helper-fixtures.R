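# Shared fixtures and independent oracles.

# Well-specified MAR world: disease depends only on covariates that are in
# the default model feature set, so the estimation model is correctly
# specified and verification is ignorable given the model covariates.
# Intercept shifted (+0.146) to absorb the dropped family-history/DRE terms
# of the realistic preset, keeping the stratum risk gradient.
wellspec_config <- function(seed, n = 10000, ...) {
  generator_config(
    n_exams = n, seed = seed,
    disease_coefficients = c(
      intercept = -0.555, age_std = 0.5470, log_psad_std = 1.9535,
      log_vol_std = -0.5470, benign_biopsy = -1.2502
    ),
    missing_rate_psa = 0, missing_rate_vol = 0,
    ...
  )
}

# Per-stratum expected csPCa proportion among unverified exams: the mean
# true risk of those patients (the estimand of the bagging engine).
stratum_truth <- function(cohort) {
  cohort |>
    dplyr::filter(!verified) |>
    dplyr::group_by(stratum = as.character(pirads_stratum(pirads))) |>
    dplyr::summarise(truth = mean(stats::plogis(.disease_lp)),
                     .groups = "drop")
}

# Brute-force AUC oracle: enumerates every positive-negative pair
# (vectorised over negatives, looped over positives), counting concordant
# pairs and half-counting ties. Fractional counts are expanded tenfold to
# integers first. Independent of the concordance-sum formula under test.
brute_force_auc <- function(pos_counts, neg_counts, scale = 10L) {
  pos_i <- round(pos_counts * scale)
  neg_i <- round(neg_counts * scale)
  stopifnot(max(abs(pos_i - pos_counts * scale)) < 1e-6,
            max(abs(neg_i - neg_counts * scale)) < 1e-6)
  scores <- seq_along(pos_i)
  pos_scores <- rep(scores, pos_i)
  neg_scores <- rep(scores, neg_i)
  conc <- 0
  for (p in pos_scores) {
    conc <- conc + sum(neg_scores < p) + 0.5 * sum(neg_scores == p)
  }
  conc / (length(pos_scores) * length(neg_scores))
}

# Grid-search oracle for the Platt objective: shrinking-window search over
# (A, B) minimising the same smoothed cross-entropy.
platt_grid_oracle <- function(scores, labels) {
  y <- as.numeric(labels)
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  t <- ifelse(y == 1, (n1 + 1) / (n1 + 2), 1 / (n0 + 2))
  obj <- function(a, b) {
    f <- a * scores + b
    sum(ifelse(f >= 0, t * f + log1p(exp(-f)), (t - 1) * f + log1p(exp(f))))
  }
  a0 <- 0
  b0 <- 0
  half <- 25
  for (stage in 1:6) {
    as <- seq(a0 - half, a0 + half, length.out = 41)
    bs <- seq(b0 - half, b0 + half, length.out = 41)
    vals <- outer(as, bs, Vectorize(obj))
    ix <- arrayInd(which.min(vals), dim(vals))
    a0 <- as[ix[1]]
    b0 <- bs[ix[2]]
    half <- half / 8
  }
  c(A = a0, B = b0)
}

# Deterministic tiny cohort for I/O and metric plumbing tests.
tiny_cohort <- function(n = 200, seed = 42, mode = "MAR") {
  simulate_cohort(generator_config(n_exams = n, seed = seed,
                                   verification_mode = mode))
}
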