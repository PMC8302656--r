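# Orthonormal discrete wavelet transform with circular (periodic) extension.
#
# The analysis operator at each level is the downsampled circulant matrix of
# the Daubechies scaling/wavelet quadrature-mirror pair; because the filters
# are orthonormal the operator is orthogonal and synthesis is its transpose,
# giving exact perfect reconstruction. Odd-length inputs are padded by one
# repeated end sample before a level and truncated back after synthesis, so
# the round trip is exact at every length.

# Daubechies scaling filters (natural order); the wavelet filter follows by
# the quadrature-mirror relation h[l] = (-1)^l g[L-1-l].
DAUBECHIES_SCALING <- list(
  haar = c(7.0710678118654746e-01, 7.0710678118654746e-01),
  db2 = c(4.8296291314453416e-01, 8.3651630373780794e-01,
          2.2414386804201339e-01, -1.2940952255126037e-01),
  db4 = c(2.3037781330889651e-01, 7.1484657055291567e-01,
          6.3088076792985892e-01, -2.7983769416859854e-02,
          -1.8703481171909309e-01, 3.0841381835560764e-02,
          3.2883011666885197e-02, -1.0597401785069032e-02),
  db6 = c(1.1154074335010947e-01, 4.9462389039845306e-01,
          7.5113390802109536e-01, 3.1525035170919763e-01,
          -2.2626469396543983e-01, -1.2976686756726194e-01,
          9.7501605587323043e-02, 2.7522865530305727e-02,
          -3.1582039317486030e-02, 5.5384220116149613e-04,
          4.7772575109455108e-03, -1.0773010853084796e-03),
  db8 = c(5.4415842243104008e-02, 3.1287159091429995e-01,
          6.7563073629728976e-01, 5.8535468365420673e-01,
          -1.5829105256349306e-02, -2.8401554296154691e-01,
          4.7248457391328279e-04, 1.2874742662047847e-01,
          -1.7369301001807547e-02, -4.4088253930794755e-02,
          1.3981027917398282e-02, 8.7460940474057766e-03,
          -4.8703529934515741e-03, -3.9174037337694705e-04,
          6.7544940645056933e-04, -1.1747678412476953e-04)
)

dwt_filters <- function(wavelet) {
  g <- DAUBECHIES_SCALING[[wavelet]]
  if (is.null(g)) {
    stop_invalid("unknown wavelet '%s' (available: %s)", wavelet,
                 paste(names(DAUBECHIES_SCALING), collapse = ", "))
  }
  L <- length(g)
  h <- rev(g) * (-1)^(seq_len(L) - 1L)
  list(g = g, h = h, length = L)
}

#' Deepest feasible decomposition level for a signal length
#'
#' @param n Signal length.
#' @param wavelet Wavelet name (e.g. `"db6"`).
#' @return `floor(log2(n / (filter_length - 1)))`, floored at zero.
#' @export
dwt_max_level <- function(n, wavelet = "db6") {
  L <- dwt_filters(wavelet)$length
  if (n < L) return(0L)
  max(0L, as.integer(floor(log2(n / (L - 1)))))
}

dwt_step <- function(x, flt) {
  n <- length(x)
  half <- n %/% 2L
  base <- 2L * (seq_len(half) - 1L)
  a <- numeric(half)
  d <- numeric(half)
  for (l in seq_len(flt$length)) {
    idx <- (base + (l - 1L)) %% n + 1L
    a <- a + flt$g[l] * x[idx]
    d <- d + flt$h[l] * x[idx]
  }
  list(a = a, d = d)
}

idwt_step <- function(a, d, flt) {
  half <- length(a)
  n <- 2L * half
  base <- 2L * (seq_len(half) - 1L)
  x <- numeric(n)
  for (l in seq_len(flt$length)) {
    idx <- (base + (l - 1L)) %% n + 1L
    x[idx] <- x[idx] + flt$g[l] * a + flt$h[l] * d
  }
  x
}

#' Multi-level discrete wavelet decomposition
#'
#' Splits a signal into detail bands `D1..DL` (finest first) and the final
#' approximation `A_L`. The requested level is reduced to the deepest level
#' feasible for the signal length ([dwt_max_level()]); a warning reports the
#' reduction.
#'
#' @param signal Numeric vector, length >= 2.
#' @param wavelet Wavelet name; `"db6"` by default.
#' @param level Requested decomposition depth.
#' @return An object of class `wavelet_decomposition` with elements
#'   `approximation`, `details` (list, `D1` first), `wavelet`, `level`.
#' @export
dwt_decompose <- function(signal, wavelet = "db6", level = 10L) {
  check_signal(signal, min_len = 2L)
  flt <- dwt_filters(wavelet)
  if (level < 1L) stop_invalid("`level` must be >= 1")
  feasible <- dwt_max_level(length(signal), wavelet)
  if (feasible < 1L) {
    stop_invalid("signal of length %d is too short for wavelet '%s'",
                 length(signal), wavelet)
  }
  eff <- min(as.integer(level), feasible)
  if (eff < level) {
    warn(sprintf("decomposition level reduced from %d to %d for length %d",
                 level, eff, length(signal)))
  }
  cur <- signal
  details <- vector("list", eff)
  lens <- integer(eff)
  for (j in seq_len(eff)) {
    lens[j] <- length(cur)
    if (length(cur) %% 2L == 1L) cur <- c(cur, cur[length(cur)])
    step <- dwt_step(cur, flt)
    details[[j]] <- step$d
    cur <- step$a
  }
  structure(
    list(approximation = cur, details = details, wavelet = wavelet,
         level = eff, input_lengths = lens),
    class = "wavelet_decomposition"
  )
}

#' Reconstruct a signal from a wavelet decomposition
#'
#' Exact inverse of [dwt_decompose()] when the coefficients are unmodified.
#'
#' @param decomposition A `wavelet_decomposition` object.
#' @return Numeric vector with the original signal length.
#' @export
dwt_reconstruct <- function(decomposition) {
  if (!inherits(decomposition, "wavelet_decomposition")) {
    stop_invalid("`decomposition` must come from dwt_decompose()")
  }
  flt <- dwt_filters(decomposition$wavelet)
  cur <- decomposition$approximation
  for (j in rev(seq_len(decomposition$level))) {
    cur <- idwt_step(cur, decomposition$details[[j]], flt)
    cur <- cur[seq_len(decomposition$input_lengths[j])]
  }
  cur
}
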