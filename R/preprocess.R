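# Signal conditioning ahead of feature extraction: wavelet denoising,
# moving-average baseline correction, powerline notch, amplitude
# normalisation, and per-class imputation of missing attribute values.

#' Wavelet denoising by band removal
#'
#' Decomposes the signal (db6, level 10 by default), zeroes the listed detail
#' bands (high-frequency noise) and optionally the final approximation (the
#' lowest band, which carries slow drift), then reconstructs. For signals too
#' short to support the requested depth, the level is reduced to the deepest
#' feasible one and the "final approximation" dropped is the approximation at
#' that effective level.
#'
#' @param signal Numeric vector, length >= 2.
#' @param wavelet Wavelet name (default `"db6"`).
#' @param level Requested decomposition depth (default 10).
#' @param drop_details Integer detail-band indices to zero (default `c(1, 2)`,
#'   the two finest bands). Indices beyond the effective level are ignored.
#' @param drop_approximation Zero the final approximation band? Default TRUE.
#' @param soft_threshold Additionally soft-threshold the retained detail
#'   bands at the universal threshold `sigma * sqrt(2 log n)`, with `sigma`
#'   estimated from the finest band by the MAD rule. Off by default: plain
#'   hard removal of the listed bands.
#' @return Denoised numeric vector, same length as the input.
#' @export
dwt_denoise <- function(signal, wavelet = "db6", level = 10L,
                        drop_details = c(1L, 2L),
                        drop_approximation = TRUE,
                        soft_threshold = FALSE) {
  dec <- dwt_decompose(signal, wavelet = wavelet, level = level)
  if (soft_threshold) {
    sigma <- stats::mad(dec$details[[1L]], center = 0)
    thr <- sigma * sqrt(2 * log(length(signal)))
    dec$details <- lapply(dec$details, function(d) sign(d) * pmax(abs(d) - thr, 0))
  }
  for (j in intersect(as.integer(drop_details), seq_len(dec$level))) {
    dec$details[[j]] <- numeric(length(dec$details[[j]]))
  }
  if (isTRUE(drop_approximation)) {
    dec$approximation <- numeric(length(dec$approximation))
  }
  dwt_reconstruct(dec)
}

#' Remove baseline wander with a centred moving average
#'
#' Subtracts a centred moving average from the signal; at the boundaries the
#' window shrinks to the available samples. The default window of 0.75 s
#' covers one period of the slowest respiration-band wander (0.15--0.8 Hz) at
#' typical ECG sampling rates.
#'
#' @param signal Numeric vector.
#' @param window_samples Window width in samples, between 1 and the signal
#'   length. Even widths are used as given (the window is then asymmetric by
#'   one sample).
#' @return Detrended numeric vector of the same length.
#' @export
remove_baseline <- function(signal, window_samples) {
  check_signal(signal)
  n <- length(signal)
  if (!is.numeric(window_samples) || window_samples < 1 || window_samples > n) {
    stop_invalid("`window_samples` must lie in [1, %d]", n)
  }
  w <- as.integer(window_samples)
  half_lo <- (w - 1L) %/% 2L
  half_hi <- w - 1L - half_lo
  cs <- c(0, cumsum(signal))
  lo <- pmax(seq_len(n) - half_lo, 1L)
  hi <- pmin(seq_len(n) + half_hi, n)
  baseline <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  signal - baseline
}

#' Notch out powerline interference
#'
#' Applies a zero-phase second-order Butterworth band-stop around the
#' powerline frequency. The filter is skipped (with a warning) when the
#' sampling rate is too low for the notch to sit below Nyquist.
#'
#' @param signal Numeric vector.
#' @param sampling_rate Sampling frequency in Hz.
#' @param frequency Powerline frequency in Hz (default 60).
#' @param bandwidth Stop-band full width in Hz (default 4).
#' @return Filtered numeric vector of the same length.
#' @export
notch_powerline <- function(signal, sampling_rate, frequency = 60, bandwidth = 4) {
  check_signal(signal, min_len = 8L)
  if (sampling_rate <= 2 * frequency) {
    warn(sprintf("sampling rate %.4g Hz too low for a %.4g Hz notch; signal unchanged",
                 sampling_rate, frequency))
    return(signal)
  }
  nyq <- sampling_rate / 2
  band <- c(frequency - bandwidth / 2, frequency + bandwidth / 2) / nyq
  flt <- signal::butter(2, band, type = "stop")
  as.numeric(signal::filtfilt(flt, signal))
}

#' Normalise a signal to zero mean and unit variance
#'
#' Removes the DC offset and scales to unit standard deviation (population
#' convention). A constant signal maps to all zeros.
#'
#' @param signal Numeric vector.
#' @return Normalised numeric vector.
#' @export
normalize_signal <- function(signal) {
  check_signal(signal)
  centred <- signal - mean(signal)
  s <- sqrt(mean(centred^2))
  if (s > 0) centred / s else centred
}

#' Impute missing attributes by the pooled class standard deviation
#'
#' Every missing cell in a row of class `c` is replaced by the standard
#' deviation (population convention, divide by N) of all non-missing
#' attribute values pooled across all rows of class `c`. Non-missing cells
#' are untouched.
#'
#' @param data Labelled dataset tibble; missing cells are `NA` (use
#'   [read_dataset()]'s `missing_marker` to map markers such as `"?"`).
#' @return The dataset with all `NA` attribute cells filled.
#' @export
impute_missing <- function(data) {
  check_dataset(data)
  attr_cols <- setdiff(names(data), "label")
  for (cl in unique(data$label)) {
    rows <- which(data$label == cl)
    block <- as.matrix(data[rows, attr_cols, drop = FALSE])
    vals <- block[!is.na(block)]
    if (anyNA(block)) {
      if (length(vals) == 0L) {
        abort(sprintf("imputation failed: class %s has no non-missing values", cl),
              class = "ecgkelm_imputation_failure")
      }
      fill <- sqrt(mean((vals - mean(vals))^2))
      block[is.na(block)] <- fill
      data[rows, attr_cols] <- as_tibble(as.data.frame(block))
    }
  }
  data
}

#' Denoise every row of a signal dataset
#'
#' Convenience wrapper applying [dwt_denoise()], [notch_powerline()] (only
#' when the sampling rate supports it), [remove_baseline()] and
#' [normalize_signal()] row-wise, in that order.
#'
#' @param data Labelled dataset tibble whose attribute columns are samples of
#'   a time series.
#' @param sampling_rate Sampling frequency in Hz.
#' @param wavelet,level,drop_details,drop_approximation Passed to
#'   [dwt_denoise()].
#' @param baseline_window_sec Moving-average window in seconds (default
#'   0.75 s); set to `NULL` to skip baseline correction.
#' @param notch_frequency Powerline frequency in Hz; `NULL` skips the notch.
#' @return The dataset with every row replaced by its conditioned version.
#' @export
preprocess_dataset <- function(data, sampling_rate = 360,
                               wavelet = "db6", level = 10L,
                               drop_details = c(1L, 2L),
                               drop_approximation = TRUE,
                               baseline_window_sec = 0.75,
                               notch_frequency = 60) {
  check_dataset(data)
  attr_cols <- setdiff(names(data), "label")
  mat <- as.matrix(data[attr_cols])
  win <- if (!is.null(baseline_window_sec)) {
    max(1L, min(ncol(mat), round(baseline_window_sec * sampling_rate)))
  }
  out <- t(apply(mat, 1L, function(x) {
    y <- suppressWarnings(dwt_denoise(x, wavelet = wavelet, level = level,
                                      drop_details = drop_details,
                                      drop_approximation = drop_approximation))
    if (!is.null(notch_frequency) && sampling_rate > 2 * notch_frequency) {
      y <- notch_powerline(y, sampling_rate, frequency = notch_frequency)
    }
    if (!is.null(win)) y <- remove_baseline(y, win)
    normalize_signal(y)
  }))
  as_ecg_dataset(out, data$label)
}
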