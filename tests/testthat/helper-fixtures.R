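# Shared fixtures. Heavy objects (the tiny phantom cohort, trained tiny
# models) are memoised so several test files can reuse them.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- force(expr)
  .fixture_env[[key]]
}

# 12-patient noise-free tiny cohort: the desk-scale study conditions used by
# the learning and explanation checks.
tiny_cohort_config <- function() {
  phantom_config(n_normal = 4, n_benign = 4, n_malignant = 4,
                 preset = "tiny", noise_sigma = 0, seed = 11)
}

tiny_cohort <- function() {
  memo("tiny_cohort", generate_cohort(tiny_cohort_config()))
}

tiny_train_config <- function() {
  train_config(preset = "tiny", seed = 5L)
}

# One tiny full-variant model trained on the whole tiny cohort (used by the
# Grad-CAM localization check).
tiny_trained_model <- function() {
  memo("tiny_trained_model",
       train_model(tiny_cohort(), model_config("full", preset = "tiny"),
                   tiny_train_config()))
}

rand_volume <- function(dims) array(stats::rnorm(prod(dims)), dims)

# Independent tally / macro-F1 oracles written as straight-line loops.
tally_oracle <- function(true, pred) {
  m <- matrix(0L, 3, 3)
  for (i in seq_along(true)) m[true[i] + 1L, pred[i] + 1L] <-
      m[true[i] + 1L, pred[i] + 1L] + 1L
  m
}

macro_f1_oracle <- function(true, pred) {
  cm <- tally_oracle(true, pred)
  f1 <- c()
  for (k in 1:3) {
    tp <- cm[k, k]; fn <- sum(cm[k, ]) - tp; fp <- sum(cm[, k]) - tp
    if (tp + fn == 0) next  # class absent from truth
    f1 <- c(f1, if (2 * tp + fp + fn == 0) 0 else
      200 * tp / (2 * tp + fp + fn))
  }
  mean(f1)
}

# Straight-line scalar transcription of the ARA gating equations:
# Gamma = sigmoid(relu(f Phi1 + b1) Phi2 + b2), split into T2/DWI halves,
# alpha_m = Gamma_m * f_m + f_m, computed token by token with explicit
# loops. Independent oracle for the vectorized implementation.
ara_scalar_oracle <- function(fT2, fDWI, p) {
  P <- nrow(fT2); C <- ncol(fT2)
  aT2 <- matrix(0, P, C); aDWI <- matrix(0, P, C)
  for (t in seq_len(P)) {
    f <- c(fT2[t, ], fDWI[t, ])
    h <- numeric(C / 2)
    for (j in seq_len(C / 2)) {
      acc <- p$b1[j]
      for (i in seq_len(2 * C)) acc <- acc + f[i] * p$phi1[i, j]
      h[j] <- max(acc, 0)
    }
    g <- numeric(2 * C)
    for (j in seq_len(2 * C)) {
      acc <- p$b2[j]
      for (i in seq_len(C / 2)) acc <- acc + h[i] * p$phi2[i, j]
      g[j] <- 1 / (1 + exp(-acc))
    }
    for (k in seq_len(C)) {
      aT2[t, k] <- g[k] * fT2[t, k] + fT2[t, k]
      aDWI[t, k] <- g[C + k] * fDWI[t, k] + fDWI[t, k]
    }
  }
  list(t2 = aT2, dwi = aDWI)
}
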