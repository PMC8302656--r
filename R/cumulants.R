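# Higher-order cumulant slices.
#
# Features are diagonal slices of the 2nd-, 3rd- and 4th-order cumulants of a
# centred signal, evaluated over the symmetric lag range -m_l..m_l. All
# moment estimates are biased (divide by N) and use only valid overlapping
# indices (no zero padding); centring first makes every entry exactly
# invariant to mean shifts and exactly scale-equivariant (order-k entries
# scale as a^k).

check_lag <- function(signal, max_lag) {
  check_signal(signal, min_len = 2L)
  if (!is.numeric(max_lag) || length(max_lag) != 1L || max_lag < 0 ||
      max_lag != round(max_lag)) {
    stop_invalid("`max_lag` must be a single non-negative integer")
  }
  if (max_lag >= length(signal)) {
    stop_invalid("`max_lag` (%d) must be smaller than the signal length (%d)",
                 max_lag, length(signal))
  }
  as.integer(max_lag)
}

# Biased lagged product-moment (1/N) * sum z[m] * z[m + eps]^p over valid m.
lagged_moment <- function(z, eps, p) {
  n <- length(z)
  if (eps >= 0) {
    m <- seq_len(n - eps)
    sum(z[m] * z[m + eps]^p) / n
  } else {
    m <- seq((1 - eps), n)
    sum(z[m] * z[m + eps]^p) / n
  }
}

#' Second-order cumulant slice (lagged autocovariance)
#'
#' Entry for lag `eps` in `-max_lag..max_lag` is the biased sample
#' autocovariance at that lag; lag 0 equals the biased sample variance.
#'
#' @param signal Numeric vector, length >= 2.
#' @param max_lag Maximum lag `m_l`; must be smaller than the signal length.
#' @return Numeric vector of length `2 * max_lag + 1`; index 1 corresponds to
#'   lag `-max_lag`.
#' @export
cumulant2 <- function(signal, max_lag) {
  max_lag <- check_lag(signal, max_lag)
  z <- signal - mean(signal)
  pos <- vapply(0:max_lag, function(eps) lagged_moment(z, eps, 1L), numeric(1))
  c(rev(pos[-1L]), pos) # autocovariance is even in the lag
}

#' Third-order cumulant diagonal slice (lagged skewness structure)
#'
#' Entry for lag `eps` is the biased estimate of `K3(eps, eps)` of the
#' centred signal, i.e. the mean of `z[m] * z[m + eps]^2` over valid indices.
#' Lag 0 equals the third central sample moment; a signal symmetric about its
#' mean gives zeros.
#'
#' @inheritParams cumulant2
#' @return Numeric vector of length `2 * max_lag + 1`, lag `-max_lag` first.
#' @export
cumulant3_diag <- function(signal, max_lag) {
  max_lag <- check_lag(signal, max_lag)
  z <- signal - mean(signal)
  vapply(-max_lag:max_lag, function(eps) lagged_moment(z, eps, 2L), numeric(1))
}

#' Fourth-order cumulant diagonal slice (lagged kurtosis structure)
#'
#' Entry for lag `eps` is the biased estimate of `K4(eps, eps, eps)` of the
#' centred signal: `n4(eps) - 3 * n2(eps) * n2(0)` with `n4`, `n2` the biased
#' lagged sample moments. Lag 0 equals the fourth central moment minus three
#' times the squared biased variance; Gaussian signals give values near zero.
#'
#' @inheritParams cumulant2
#' @return Numeric vector of length `2 * max_lag + 1`, lag `-max_lag` first.
#' @export
cumulant4_diag <- function(signal, max_lag) {
  max_lag <- check_lag(signal, max_lag)
  z <- signal - mean(signal)
  n2_0 <- sum(z^2) / length(z)
  vapply(-max_lag:max_lag, function(eps) {
    n4 <- lagged_moment(z, eps, 3L)
    n2 <- lagged_moment(z, abs(eps), 1L)
    n4 - 3 * n2 * n2_0
  }, numeric(1))
}

#' Concatenated multi-cumulant feature vector
#'
#' Concatenates the 2nd-, 3rd- and 4th-order diagonal cumulant slices of a
#' signal, giving `3 * (2 * max_lag + 1)` features. A `max_lag` too large for
#' the signal is clamped to `floor((n - 1) / 2)` with a warning, so
#' optimiser-proposed lags never exceed the data.
#'
#' @inheritParams cumulant2
#' @return Numeric vector of length `3 * (2 * max_lag + 1)` (after any
#'   clamping), with attribute `max_lag` recording the lag actually used.
#' @examples
#' length(multicumulant_features(sin(seq_len(120) / 5), 25)) # 153
#' @export
multicumulant_features <- function(signal, max_lag) {
  check_signal(signal, min_len = 2L)
  limit <- (length(signal) - 1L) %/% 2L
  if (max_lag > limit) {
    warn(sprintf("max_lag %d clamped to %d for signal length %d",
                 as.integer(max_lag), limit, length(signal)))
    max_lag <- limit
  }
  out <- c(cumulant2(signal, max_lag),
           cumulant3_diag(signal, max_lag),
           cumulant4_diag(signal, max_lag))
  attr(out, "max_lag") <- as.integer(max_lag)
  out
}

#' Extract multi-cumulant features for every row of a dataset
#'
#' @param data Labelled dataset tibble whose attribute columns are samples of
#'   a time series.
#' @param max_lag Maximum cumulant lag `m_l`.
#' @return A labelled dataset tibble of `3 * (2 * max_lag + 1)` feature
#'   columns plus `label`.
#' @export
extract_features <- function(data, max_lag) {
  check_dataset(data)
  mat <- dataset_matrix(data)
  feats <- t(apply(mat, 1L, function(x) {
    as.numeric(suppressWarnings(multicumulant_features(x, max_lag)))
  }))
  as_ecg_dataset(feats, data$label)
}
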