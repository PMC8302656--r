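# Synthetic ECG-like signal generation.
#
# A beat is modelled as five Gaussian bumps (P, Q, R, S, T) placed at fixed
# phase fractions of the cardiac cycle and repeated periodically at the beat
# rate. The model is deliberately simple: it reproduces the P-QRS-T morphology
# that distinguishes beat classes without attempting physiological realism.

#' Describe a synthetic beat morphology
#'
#' A beat template places five Gaussian bumps -- the P, Q, R, S and T waves --
#' inside one cardiac cycle. The generated signal repeats the beat
#' periodically at `beat_rate` for `duration` seconds.
#'
#' @param wave_amplitudes Numeric length-5 vector of P, Q, R, S, T amplitudes
#'   (arbitrary units; Q and S are conventionally negative).
#' @param wave_centers Numeric length-5 vector of wave centres as fractions of
#'   the beat period, strictly increasing, each in `[0, 1)`.
#' @param wave_widths Numeric length-5 vector of Gaussian standard deviations,
#'   as fractions of the beat period; all positive.
#' @param beat_rate Beats per second (1.2 corresponds to 72 bpm).
#' @param duration Signal duration in seconds.
#' @param sampling_rate Sampling frequency in Hz.
#'
#' @return An object of class `beat_template`.
#' @examples
#' tpl <- beat_template()
#' sig <- synth_beat(tpl)
#' length(sig) # duration * sampling_rate
#' @export
beat_template <- function(wave_amplitudes = c(0.15, -0.15, 1, -0.25, 0.35),
                          wave_centers = c(0.15, 0.27, 0.30, 0.33, 0.55),
                          wave_widths = c(0.040, 0.010, 0.012, 0.010, 0.060),
                          beat_rate = 1.2,
                          duration = 10,
                          sampling_rate = 360) {
  if (length(wave_amplitudes) != 5L || length(wave_centers) != 5L ||
      length(wave_widths) != 5L) {
    stop_invalid("wave_amplitudes, wave_centers and wave_widths must each have length 5")
  }
  if (any(wave_widths <= 0)) stop_invalid("wave_widths must all be positive")
  if (any(wave_centers < 0) || any(wave_centers >= 1) ||
      any(diff(wave_centers) <= 0)) {
    stop_invalid("wave_centers must be strictly increasing within [0, 1)")
  }
  if (!is.numeric(beat_rate) || beat_rate <= 0) stop_invalid("beat_rate must be positive")
  if (!is.numeric(duration) || duration <= 0) stop_invalid("duration must be positive")
  if (!is.numeric(sampling_rate) || sampling_rate <= 0) {
    stop_invalid("sampling_rate must be positive")
  }
  structure(
    list(
      wave_amplitudes = as.numeric(wave_amplitudes),
      wave_centers = as.numeric(wave_centers),
      wave_widths = as.numeric(wave_widths),
      beat_rate = beat_rate,
      duration = duration,
      sampling_rate = sampling_rate
    ),
    class = "beat_template"
  )
}

#' Render a noiseless periodic beat train from a template
#'
#' Deterministically evaluates the sum of the template's five Gaussian bumps
#' at every sample, with the phase wrapped so the distance to each wave centre
#' is measured around the cycle.
#'
#' @param template A [beat_template()].
#' @return Numeric vector of length `round(duration * sampling_rate)`.
#' @export
synth_beat <- function(template) {
  if (!inherits(template, "beat_template")) {
    stop_invalid("`template` must be created by beat_template()")
  }
  n <- round(template$duration * template$sampling_rate)
  if (n < 1L) stop_invalid("duration x sampling_rate must give at least one sample")
  t_sec <- (seq_len(n) - 1L) / template$sampling_rate
  phase <- (t_sec * template$beat_rate) %% 1
  out <- numeric(n)
  for (w in 1:5) {
    d <- abs(phase - template$wave_centers[w])
    d <- pmin(d, 1 - d) # wrap-around distance within the cycle
    out <- out + template$wave_amplitudes[w] *
      exp(-d^2 / (2 * template$wave_widths[w]^2))
  }
  out
}

#' Specify additive ECG noise
#'
#' Bundles the three disturbance sources applied to synthetic beats: baseline
#' wander (a low-frequency sinusoid in the 0.15--0.8 Hz respiration band),
#' powerline interference (a 60 Hz sinusoid), and wideband Gaussian noise.
#'
#' @param baseline_amplitude Amplitude of the baseline-wander sinusoid (>= 0).
#' @param baseline_frequency Baseline-wander frequency in Hz; must lie in
#'   `[0.15, 0.8]`.
#' @param powerline_amplitude Amplitude of the powerline sinusoid (>= 0).
#' @param powerline_frequency Powerline frequency in Hz (60 by default).
#' @param white_sd Standard deviation of the additive Gaussian noise (>= 0).
#' @param seed Integer seed controlling the Gaussian draw.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(baseline_amplitude = 0,
                       baseline_frequency = 0.3,
                       powerline_amplitude = 0,
                       powerline_frequency = 60,
                       white_sd = 0,
                       seed = 1L) {
  amps <- c(baseline_amplitude, powerline_amplitude, white_sd)
  if (!all(is.finite(amps)) || any(amps < 0)) {
    stop_invalid("noise amplitudes must be finite and non-negative")
  }
  if (baseline_frequency < 0.15 || baseline_frequency > 0.8) {
    stop_invalid("baseline_frequency must lie in [0.15, 0.8] Hz")
  }
  structure(
    list(
      baseline_amplitude = baseline_amplitude,
      baseline_frequency = baseline_frequency,
      powerline_amplitude = powerline_amplitude,
      powerline_frequency = powerline_frequency,
      white_sd = white_sd,
      seed = as.integer(seed)
    ),
    class = "noise_spec"
  )
}

#' Add baseline wander, powerline interference and white noise to a signal
#'
#' @param signal Numeric input signal.
#' @param spec A [noise_spec()].
#' @param sampling_rate Sampling frequency in Hz, used to phase the sinusoids.
#' @return Numeric vector of the same length as `signal`.
#' @export
add_noise <- function(signal, spec, sampling_rate = 360) {
  check_signal(signal)
  if (!inherits(spec, "noise_spec")) stop_invalid("`spec` must be a noise_spec()")
  n <- length(signal)
  t_sec <- (seq_len(n) - 1L) / sampling_rate
  out <- signal +
    spec$baseline_amplitude * sin(2 * pi * spec$baseline_frequency * t_sec) +
    spec$powerline_amplitude * sin(2 * pi * spec$powerline_frequency * t_sec)
  if (spec$white_sd > 0) {
    out <- out + withr_seed_rnorm(spec$seed, n, spec$white_sd)
  }
  out
}

# Draw n Gaussian values under a local seed without clobbering the caller's
# RNG stream.
withr_seed_rnorm <- function(seed, n, sd) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  rnorm(n, mean = 0, sd = sd)
}

#' Generate a labelled multi-class synthetic ECG dataset
#'
#' Each class is rendered from its own beat template; every row receives an
#' independent noise realisation. Row seeds are derived from `spec$seed` by a
#' fixed counter scheme (`seed + row_index`), so any subset of rows is
#' reproducible independently of generation order.
#'
#' @param class_templates List of [beat_template()] objects, one per class.
#' @param class_counts Integer vector of per-class row counts (same length).
#' @param spec A [noise_spec()] applied to every row.
#' @return A tibble with one amplitude column per sample point plus an integer
#'   `label` column (class indices start at 0), grouped by class in order.
#' @examples
#' tpl <- list(beat_template(), beat_template(wave_amplitudes = c(0.1, -0.1, 0.6, -0.4, 0.5)))
#' ds <- synth_dataset(tpl, c(8, 3), noise_spec(white_sd = 0.02, seed = 7))
#' table(ds$label)
#' @export
synth_dataset <- function(class_templates, class_counts, spec = noise_spec()) {
  if (!is.list(class_templates) || length(class_templates) < 1L) {
    stop_invalid("`class_templates` must be a non-empty list of beat templates")
  }
  if (length(class_counts) != length(class_templates)) {
    stop_invalid("`class_templates` and `class_counts` must have equal length")
  }
  if (any(class_counts < 1)) stop_invalid("class_counts must all be positive")
  if (!inherits(spec, "noise_spec")) stop_invalid("`spec` must be a noise_spec()")

  clean <- lapply(class_templates, synth_beat)
  n_attr <- unique(lengths(clean))
  if (length(n_attr) != 1L) {
    stop_invalid("all class templates must produce signals of equal length")
  }
  fs <- class_templates[[1L]]$sampling_rate

  total <- sum(class_counts)
  samples <- matrix(0, nrow = total, ncol = n_attr)
  labels <- integer(total)
  row_counter <- 0L
  for (cl in seq_along(class_templates)) {
    for (i in seq_len(class_counts[cl])) {
      row_counter <- row_counter + 1L
      row_spec <- spec
      row_spec$seed <- spec$seed + row_counter
      samples[row_counter, ] <- add_noise(clean[[cl]], row_spec, sampling_rate = fs)
      labels[row_counter] <- cl - 1L
    }
  }
  as_ecg_dataset(samples, labels)
}
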