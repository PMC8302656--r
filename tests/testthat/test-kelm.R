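test_that("kernel matrices match their defining formulas", {
  # polynomial degree 1 by hand: (1*3 + 2*4 + 1)^1 = 12
  expect_equal(
    kernel_matrix(matrix(c(1, 2), 1), matrix(c(3, 4), 1),
                  kernel_spec("polynomial", degree = 1))[1, 1],
    12
  )

  set.seed(30)
  X <- matrix(rnorm(20), 5)
  for (nm in c("rbf", "polynomial", "laplacian", "sigmoid", "wavelet")) {
    K <- kernel_matrix(X, X, kernel_spec(nm))
    expect_equal(K, t(K), tolerance = 1e-12)
  }
  Krbf <- kernel_matrix(X, X, kernel_spec("rbf", p_k = 0.7))
  expect_true(all(diag(Krbf) == 1))
  expect_true(all(Krbf > 0 & Krbf <= 1))
  Klap <- kernel_matrix(X, X, kernel_spec("laplacian", sigma = 2))
  expect_true(all(Klap > 0 & Klap <= 1))

  expect_error(kernel_matrix(X, matrix(0, 2, 5), kernel_spec("rbf")),
               class = "ecgkelm_invalid_argument")
  expect_error(kernel_spec("rbf", p_k = -1), class = "ecgkelm_invalid_argument")
})

test_that("rbf kernel agrees with an independent kernel library", {
  skip_if_not_installed("kernlab")
  set.seed(31)
  X <- matrix(rnorm(40), 8)
  p_k <- 0.35
  ours <- kernel_matrix(X, X, kernel_spec("rbf", p_k = p_k))
  theirs <- kernlab::kernelMatrix(kernlab::rbfdot(sigma = p_k), X)
  expect_equal(ours, matrix(theirs, 8, 8), tolerance = 1e-10)
})

test_that("kelm_fit solves its defining linear system", {
  set.seed(32)
  ds <- as_ecg_dataset(matrix(rnorm(60), 12), rep(0:2, 4))
  spec <- kernel_spec("rbf", p_k = 0.5)
  fit <- kelm_fit(ds, c_r = 10, spec)
  K <- kernel_matrix(fit$train_inputs, fit$train_inputs, spec)
  G <- matrix(0, 12, 3)
  G[cbind(1:12, ds$label + 1)] <- 1
  resid <- (diag(12) / 10 + K) %*% fit$output_weights - G
  expect_lt(norm(resid, "F") / norm(G, "F"), 1e-6)

  expect_error(kelm_fit(ds, c_r = 0), class = "ecgkelm_invalid_argument")
})

test_that("tiny fit/predict path matches the brute-force dense oracle", {
  set.seed(33)
  for (trial in 1:3) {
    Xtr <- matrix(rnorm(10), 5, 2)
    labels <- c(0, 0, 1, 1, 2)
    Xte <- matrix(rnorm(8), 4, 2)
    fit <- kelm_fit(as_ecg_dataset(Xtr, labels), c_r = 50,
                    kernel_spec("rbf", p_k = 0.8))
    expect_equal(predict(fit, Xte),
                 brute_kelm_predict(Xtr, labels, Xte, 50, 0.8))
  }

  # 1 training point per class, near-interpolating c_r: self-prediction
  X1 <- rbind(c(0, 0), c(5, 5))
  fit1 <- kelm_fit(as_ecg_dataset(X1, c(0, 1)), c_r = 1e6,
                   kernel_spec("rbf", p_k = 1))
  expect_equal(predict(fit1, X1), c(0, 1))
})

test_that("well-separated blobs are learned to zero training error", {
  set.seed(34)
  X <- rbind(matrix(rnorm(100), 50), matrix(rnorm(100, mean = 10), 50))
  ds <- as_ecg_dataset(X, rep(0:1, each = 50))
  fit <- kelm_fit(ds, c_r = 100, kernel_spec("rbf", p_k = 1))
  expect_equal(error_rate(ds$label, predict(fit, ds)), 0)
  expect_equal(glance(fit)$train_error, 0)
})

test_that("prediction contracts: determinism, zero-padding, permutation", {
  set.seed(35)
  Xtr <- matrix(rnorm(30), 10, 3)
  ds <- as_ecg_dataset(Xtr, rep(0:1, 5))
  fit <- kelm_fit(ds, c_r = 20, kernel_spec("rbf", p_k = 0.4))
  Xte <- matrix(rnorm(15), 5, 3)

  # duplicated test row predicts identically
  p <- predict(fit, rbind(Xte, Xte[1, , drop = FALSE]))
  expect_equal(p[6], p[1])

  # rbf scores invariant to an appended all-zero attribute
  fit0 <- kelm_fit(as_ecg_dataset(cbind(Xtr, 0), ds$label), c_r = 20,
                   kernel_spec("rbf", p_k = 0.4))
  expect_equal(predict(fit0, cbind(Xte, 0), type = "score"),
               predict(fit, Xte, type = "score"), tolerance = 1e-10)

  # permutation equivariance over test rows
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(predict(fit, Xte[perm, ]), predict(fit, Xte)[perm])

  expect_error(predict(fit, matrix(0, 2, 7)), class = "ecgkelm_invalid_argument")
})

test_that("training error is non-increasing in the regularisation constant", {
  set.seed(36)
  X <- rbind(matrix(rnorm(60, sd = 2), 30), matrix(rnorm(60, 2, sd = 2), 30))
  ds <- as_ecg_dataset(X, rep(0:1, each = 30))
  errs <- sapply(c(0.01, 1, 100, 1e4), function(cr) {
    fit <- kelm_fit(ds, c_r = cr, kernel_spec("rbf", p_k = 0.5))
    error_rate(ds$label, predict(fit, ds))
  })
  expect_true(all(diff(errs) <= 0))
})

test_that("error_rate implements the confusion-matrix formula", {
  # TP = 9, FN = 1, FP = 0, TN = 10 -> (0 + 1) / 20
  truth <- rep(c(1, 0), c(10, 10))
  pred <- c(rep(1, 9), 0, rep(0, 10))
  expect_equal(error_rate(truth, pred), 0.05)
  expect_equal(error_rate(1:5, 1:5), 0)
  expect_equal(error_rate(rep(0, 4), rep(1, 4)), 1)
  expect_error(error_rate(1:3, 1:4), class = "ecgkelm_invalid_argument")
})
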