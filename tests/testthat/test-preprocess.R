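test_that("wavelet decomposition reconstructs perfectly at any length", {
  set.seed(31)
  for (n in c(64, 187, 188, 501, 3600)) {
    x <- rnorm(n)
    dec <- suppressWarnings(dwt_decompose(x, "db6", 10))
    expect_lt(max(abs(dwt_reconstruct(dec) - x)), 1e-8 * max(1, max(abs(x))))
    expect_equal(length(dec$details), dec$level)
  }
  expect_error(dwt_decompose(rnorm(64), "nosuch"),
               class = "ecgkelm_invalid_argument")
  expect_error(dwt_decompose(1), class = "ecgkelm_invalid_argument")
})

test_that("level is capped by signal length and filter support", {
  expect_equal(dwt_max_level(3600, "db6"), 8L)
  expect_equal(dwt_max_level(188, "db6"), 4L)
  expect_warning(dwt_decompose(rnorm(188), "db6", 10), "reduced")
})

test_that("denoising drops the targeted bands", {
  # dropping nothing is the identity
  set.seed(5)
  x <- rnorm(256)
  expect_equal(dwt_denoise(x, level = 4, drop_details = integer(0),
                           drop_approximation = FALSE), x, tolerance = 1e-8)

  # a constant lives entirely in the final approximation
  out <- dwt_denoise(rep(2.5, 256), level = 4)
  expect_lt(max(abs(out)), 1e-10)

  # D1 removal kills Nyquist-band energy: 0.3 Hz sinusoid at 360 Hz plus
  # alternating +-1, attenuation at Nyquist >= 20 dB (Fourier magnitude)
  n <- 1024
  fs <- 360
  t <- (0:(n - 1)) / fs
  sig <- sin(2 * pi * 0.3 * t) + rep(c(1, -1), n / 2)
  den <- dwt_denoise(sig, level = 4, drop_details = 1L,
                     drop_approximation = FALSE)
  nyq_bin <- n / 2 + 1
  atten_db <- 20 * log10(Mod(fft(sig))[nyq_bin] / Mod(fft(den))[nyq_bin])
  expect_gt(atten_db, 20)
})

test_that("denoising is idempotent once the dropped bands are zero", {
  set.seed(8)
  x <- rnorm(512)
  once <- dwt_denoise(x, level = 5)
  twice <- dwt_denoise(once, level = 5)
  expect_lt(max(abs(twice - once)), 1e-6 * max(abs(once)))
})

test_that("moving-average baseline removal behaves on closed forms", {
  expect_equal(remove_baseline(rep(7, 50), 9), rep(0, 50))
  expect_equal(remove_baseline(rnorm(20), 1), rep(0, 20))

  # interior of a linear ramp: centred mean equals the midpoint value
  ramp <- seq(0, 1, length.out = 101)
  out <- remove_baseline(ramp, 11)
  expect_lt(max(abs(out[6:95])), 1e-12)

  # commutes with additive constants
  set.seed(9)
  x <- rnorm(80)
  expect_equal(remove_baseline(x + 3, 15), remove_baseline(x, 15))

  expect_error(remove_baseline(rnorm(10), 0), class = "ecgkelm_invalid_argument")
  expect_error(remove_baseline(rnorm(10), 11), class = "ecgkelm_invalid_argument")
})

test_that("normalize_signal gives zero mean, unit sd, affine invariance", {
  set.seed(10)
  x <- rnorm(200, mean = 4, sd = 3)
  z <- normalize_signal(x)
  expect_lt(abs(mean(z)), 1e-10)
  expect_equal(sqrt(mean((z - mean(z))^2)), 1, tolerance = 1e-10)
  expect_equal(normalize_signal(2.5 * x + 7), z, tolerance = 1e-10)
  expect_equal(normalize_signal(rep(3, 10)), rep(0, 10))
})

test_that("notch filter suppresses 60 Hz and skips low sampling rates", {
  fs <- 360
  t <- (0:2047) / fs
  sig <- sin(2 * pi * 1.2 * t) + 0.5 * sin(2 * pi * 60 * t)
  out <- notch_powerline(sig, fs)
  spec_in <- Mod(fft(sig))
  spec_out <- Mod(fft(out))
  bin60 <- round(60 * length(t) / fs) + 1
  expect_lt(spec_out[bin60] / spec_in[bin60], 0.1)
  expect_warning(low <- notch_powerline(sig, 100), "too low")
  expect_identical(low, sig)
})

test_that("imputation pools the class standard deviation", {
  # hand-computed oracle: class values {1, 3, 5}, population sd = sqrt(8/3)
  ds <- as_ecg_dataset(rbind(c(1, NA), c(3, 5)), c(0, 0))
  out <- impute_missing(ds)
  expect_equal(out$V2[1], sqrt(8 / 3), tolerance = 1e-12)

  # no missing values: identity
  full <- as_ecg_dataset(matrix(rnorm(12), 4), rep(0:1, 2))
  expect_identical(impute_missing(full), full)

  # constant class imputes zero spread
  const <- as_ecg_dataset(rbind(c(2, NA), c(2, 2)), c(1, 1))
  expect_equal(impute_missing(const)$V2[1], 0)

  # only missing cells change
  ds2 <- as_ecg_dataset(rbind(c(1, NA, 4), c(3, 5, 6)), c(0, 0))
  out2 <- impute_missing(ds2)
  expect_identical(out2$V1, ds2$V1)
  expect_identical(out2$V3, ds2$V3)

  allna <- as_ecg_dataset(rbind(c(NA, NA)), 0)
  expect_error(impute_missing(allna), class = "ecgkelm_imputation_failure")
})

test_that("preprocess_dataset conditions every row", {
  ds <- easy_two_class(n_per_class = 4, seed = 21)
  out <- preprocess_dataset(ds, sampling_rate = 100)
  expect_equal(dim(out), dim(ds))
  expect_identical(out$label, ds$label)
  mats <- as.matrix(out[setdiff(names(out), "label")])
  expect_true(all(abs(rowMeans(mats)) < 1e-8))
})
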