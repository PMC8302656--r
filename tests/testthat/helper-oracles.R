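# Independent brute-force oracles and shared fixtures. The oracles evaluate
# the defining moment sums with explicit loops and never share code with the
# package's estimators.

# Biased lagged moment (1/N) sum z[m] prod_j z[m + eps_j], looped directly.
brute_moment <- function(z, eps) {
  n <- length(z)
  total <- 0
  for (m in seq_len(n)) {
    idx <- m + eps
    if (all(idx >= 1) && all(idx <= n)) {
      total <- total + z[m] * prod(z[idx])
    }
  }
  total / n
}

brute_cumulant2 <- function(x, max_lag) {
  z <- x - mean(x)
  sapply(-max_lag:max_lag, function(e) brute_moment(z, e))
}

brute_cumulant3 <- function(x, max_lag) {
  z <- x - mean(x)
  sapply(-max_lag:max_lag, function(e) brute_moment(z, c(e, e)))
}

brute_cumulant4 <- function(x, max_lag) {
  z <- x - mean(x)
  sapply(-max_lag:max_lag, function(e) {
    brute_moment(z, c(e, e, e)) -
      3 * brute_moment(z, abs(e)) * brute_moment(z, 0)
  })
}

# Dense KELM evaluation with explicit kernel loops and an explicit inverse.
brute_kelm_predict <- function(Xtr, labels, Xte, c_r, p_k) {
  rbf <- function(a, b) exp(-p_k * sum((a - b)^2))
  W <- nrow(Xtr)
  classes <- sort(unique(labels))
  K <- matrix(0, W, W)
  for (j in seq_len(W)) for (k in seq_len(W)) K[j, k] <- rbf(Xtr[j, ], Xtr[k, ])
  G <- matrix(0, W, length(classes))
  for (w in seq_len(W)) G[w, which(classes == labels[w])] <- 1
  M <- solve(diag(W) / c_r + K) %*% G
  preds <- integer(nrow(Xte))
  for (i in seq_len(nrow(Xte))) {
    kv <- sapply(seq_len(W), function(w) rbf(Xte[i, ], Xtr[w, ]))
    preds[i] <- classes[which.max(kv %*% M)]
  }
  preds
}

# Per-class counts printed for the three clinical databases.
MLII_COUNTS <- c(283, 66, 20, 135, 13, 21, 133, 55, 13, 10, 10, 10, 11,
                 103, 62, 10, 45)
UCI_COUNTS <- c(245, 44, 15, 15, 13, 25, 3, 2, 9, 50, 4, 5, 22)
PTBDB_COUNTS <- c(4046, 10506)

# A dataset with given per-class counts; attributes carry the row index so
# membership and provenance are checkable after resampling.
counts_dataset <- function(counts, n_attr = 2L) {
  n <- sum(counts)
  labels <- rep(seq_along(counts) - 1L, counts)
  samples <- matrix(seq_len(n), nrow = n, ncol = n_attr)
  as_ecg_dataset(samples, labels)
}

# Two well-separated synthetic beat classes for end-to-end checks.
easy_two_class <- function(n_per_class = 30, white_sd = 0.05, seed = 11,
                           duration = 2, sampling_rate = 100) {
  tpl1 <- beat_template(duration = duration, sampling_rate = sampling_rate)
  tpl2 <- beat_template(
    wave_amplitudes = c(0.3, -0.05, 0.6, -0.5, 0.6),
    beat_rate = 1.8, duration = duration, sampling_rate = sampling_rate
  )
  synth_dataset(list(tpl1, tpl2), c(n_per_class, n_per_class),
                noise_spec(baseline_amplitude = 0.2, powerline_amplitude = 0.05,
                           white_sd = white_sd, seed = seed))
}
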