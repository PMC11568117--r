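# Internal helpers shared across modules.

# Percentile interval as pure order statistics (inverse-ECDF quantiles).
percentile_ci <- function(x, level = 0.95) {
  x <- x[is.finite(x)]
  if (length(x) == 0) return(c(lower = NA_real_, upper = NA_real_))
  a <- (1 - level) / 2
  q <- stats::quantile(x, probs = c(a, 1 - a), type = 1, names = FALSE)
  c(lower = q[1], upper = q[2])
}

# Round half away from zero (the convention used for percent display);
# base round() rounds half to even.
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Tie-corrected AUC (Mann-Whitney with midranks) for continuous scores.
rank_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- as.numeric(sum(labels == 1L))
  n0 <- as.numeric(sum(labels == 0L))
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Stratified fold assignment: within each class, folds are dealt in shuffled
# round-robin order so every fold keeps the class balance.
stratified_folds <- function(labels, n_folds) {
  folds <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    folds[idx[sample.int(length(idx))]] <-
      rep_len(seq_len(n_folds), length(idx))
  }
  folds
}

logit <- function(p) log(p / (1 - p))

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(msg) {
  rlang::abort(msg, class = "bagverify_config_error")
}

stop_fit <- function(msg) {
  rlang::abort(msg, class = "bagverify_fit_error")
}
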