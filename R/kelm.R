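# Kernel extreme learning machine.
#
# Training is a single regularised linear solve: with kernel matrix K over
# the W training rows and one-hot target matrix G (1 for the true class, 0
# elsewhere), the output weights solve (I / C_R + K) M = G. Prediction of a
# new row y evaluates the kernel vector [psi(y, y_1) ... psi(y, y_W)] and
# takes the class of the maximum score.

#' Specify a kernel function
#'
#' Five kernels are available:
#' \describe{
#'   \item{rbf}{`exp(-p_k * ||x - y||^2)` with width parameter `p_k > 0`.}
#'   \item{polynomial}{`(x'y + 1)^degree`, `degree >= 1`.}
#'   \item{laplacian}{`exp(-||x - y|| / sigma)`, `sigma > 0`.}
#'   \item{sigmoid}{`tanh(beta * x'y + c)`.}
#'   \item{wavelet}{product over coordinates of
#'     `cos(1.75 u) * exp(-u^2 / 2)` with `u = (x_i - y_i) / nu`, `nu > 0`.}
#' }
#'
#' @param name Kernel name.
#' @param p_k RBF width parameter.
#' @param degree Polynomial degree.
#' @param sigma Laplacian scale.
#' @param beta,c Sigmoid slope and offset.
#' @param nu Wavelet dilation.
#' @return An object of class `kernel_spec`.
#' @export
kernel_spec <- function(name = c("rbf", "polynomial", "laplacian", "sigmoid", "wavelet"),
                        p_k = 1, degree = 2, sigma = 1, beta = 1, c = 0, nu = 1) {
  name <- match.arg(name)
  pars <- switch(name,
    rbf = {
      if (p_k <= 0) stop_invalid("rbf kernel needs p_k > 0")
      list(p_k = p_k)
    },
    polynomial = {
      if (degree < 1) stop_invalid("polynomial kernel needs degree >= 1")
      list(degree = degree)
    },
    laplacian = {
      if (sigma <= 0) stop_invalid("laplacian kernel needs sigma > 0")
      list(sigma = sigma)
    },
    sigmoid = list(beta = beta, c = c),
    wavelet = {
      if (nu <= 0) stop_invalid("wavelet kernel needs nu > 0")
      list(nu = nu)
    }
  )
  structure(list(name = name, parameters = pars), class = "kernel_spec")
}

cross_sqdist <- function(X, Y) {
  # ||x||^2 + ||y||^2 - 2 x'y, clipped at 0 against rounding
  d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * tcrossprod(X, Y)
  pmax(d2, 0)
}

#' Evaluate a kernel matrix between two sample sets
#'
#' @param X,Y Numeric matrices with equal column (attribute) counts; rows are
#'   samples.
#' @param spec A [kernel_spec()].
#' @return The `nrow(X) x nrow(Y)` matrix of pairwise kernel values.
#' @export
kernel_matrix <- function(X, Y, spec = kernel_spec("rbf")) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (ncol(X) != ncol(Y)) {
    stop_invalid("X and Y must share the attribute dimension (%d vs %d)",
                 ncol(X), ncol(Y))
  }
  if (!inherits(spec, "kernel_spec")) stop_invalid("`spec` must be a kernel_spec()")
  p <- spec$parameters
  switch(spec$name,
    rbf = exp(-p$p_k * cross_sqdist(X, Y)),
    polynomial = (tcrossprod(X, Y) + 1)^p$degree,
    laplacian = exp(-sqrt(cross_sqdist(X, Y)) / p$sigma),
    sigmoid = tanh(p$beta * tcrossprod(X, Y) + p$c),
    wavelet = {
      K <- matrix(1, nrow(X), nrow(Y))
      for (j in seq_len(ncol(X))) {
        u <- outer(X[, j], Y[, j], "-") / p$nu
        K <- K * cos(1.75 * u) * exp(-u^2 / 2)
      }
      K
    }
  )
}

#' Fit a kernel extreme learning machine
#'
#' Solves `(I / c_r + K) M = G` for the output-weight matrix `M`, where `K`
#' is the training kernel matrix and `G` the one-hot (1/0) class indicator
#' matrix. The solve is a factorised linear solve, not an explicit inverse.
#'
#' @param data Labelled dataset tibble (attribute columns plus `label`).
#' @param c_r Regularisation coefficient; any non-zero real. Negative values
#'   are accepted but can make the system singular, in which case a
#'   solver-failure error names the offending `c_r`.
#' @param spec A [kernel_spec()]; RBF by default.
#' @return An object of class `kelm` holding the training inputs, kernel
#'   spec, `c_r`, class levels, and solved output weights.
#' @examples
#' ds <- synth_dataset(list(beat_template(duration = 1, sampling_rate = 60),
#'                          beat_template(wave_amplitudes = c(0, 0, 0.4, 0, 0.6),
#'                                        duration = 1, sampling_rate = 60)),
#'                     c(5, 5), noise_spec(white_sd = 0.01, seed = 2))
#' fit <- kelm_fit(ds, c_r = 100, kernel_spec("rbf", p_k = 0.5))
#' mean(predict(fit, ds) != ds$label)
#' @export
kelm_fit <- function(data, c_r, spec = kernel_spec("rbf")) {
  check_dataset(data)
  if (!is.numeric(c_r) || length(c_r) != 1L || c_r == 0 || !is.finite(c_r)) {
    stop_invalid("`c_r` must be a single non-zero finite number")
  }
  X <- dataset_matrix(data)
  classes <- sort(unique(data$label))
  if (length(classes) < 1L) stop_invalid("at least one class required")
  G <- matrix(0, nrow(X), length(classes))
  G[cbind(seq_len(nrow(X)), match(data$label, classes))] <- 1
  K <- kernel_matrix(X, X, spec)
  A <- K
  diag(A) <- diag(A) + 1 / c_r
  M <- tryCatch(
    solve(A, G),
    error = function(e) {
      abort(sprintf("KELM solve failed for c_r = %g: %s", c_r, conditionMessage(e)),
            class = "ecgkelm_solver_failure")
    }
  )
  structure(
    list(train_inputs = X, output_weights = M, kernel = spec,
         c_r = c_r, classes = classes, train_labels = data$label),
    class = "kelm"
  )
}

#' Predict classes with a fitted KELM
#'
#' @param object A fitted `kelm` model.
#' @param newdata Labelled dataset tibble or bare numeric matrix with the
#'   training attribute dimension.
#' @param type `"class"` (default) for predicted labels, `"score"` for the
#'   raw score matrix (one column per class).
#' @param ... Unused.
#' @return Integer label vector, or score matrix for `type = "score"`. Ties
#'   are broken towards the lowest class index.
#' @export
predict.kelm <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  Xnew <- if (is.data.frame(newdata)) dataset_matrix(newdata) else as.matrix(newdata)
  if (ncol(Xnew) != ncol(object$train_inputs)) {
    stop_invalid("newdata has %d attributes; model was trained with %d",
                 ncol(Xnew), ncol(object$train_inputs))
  }
  scores <- kernel_matrix(Xnew, object$train_inputs, object$kernel) %*%
    object$output_weights
  colnames(scores) <- object$classes
  if (type == "score") return(scores)
  object$classes[max.col(scores, ties.method = "first")]
}

#' @export
print.kelm <- function(x, ...) {
  cat(sprintf("KELM model: %d training samples, %d attributes, %d classes\n",
              nrow(x$train_inputs), ncol(x$train_inputs), length(x$classes)))
  cat(sprintf("kernel: %s (%s); c_r = %g\n", x$kernel$name,
              paste(names(x$kernel$parameters), unlist(x$kernel$parameters),
                    sep = " = ", collapse = ", "), x$c_r))
  invisible(x)
}

#' @rdname tidy.kelm
#' @export
glance.kelm <- function(x, ...) {
  train_pred <- predict(x, x$train_inputs)
  tibble(
    n_train = nrow(x$train_inputs),
    n_classes = length(x$classes),
    kernel = x$kernel$name,
    c_r = x$c_r,
    train_error = error_rate(x$train_labels, train_pred)
  )
}

#' Broom-style summaries of a fitted KELM
#'
#' `tidy()` returns one row per training sample with its predicted label and
#' scores; `glance()` returns a one-row model summary.
#'
#' @param x A fitted `kelm` model.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.kelm <- function(x, ...) {
  scores <- predict(x, x$train_inputs, type = "score")
  tibble(
    row = seq_len(nrow(scores)),
    predicted = x$classes[max.col(scores, ties.method = "first")],
    max_score = apply(scores, 1L, max)
  )
}

#' Classification error rate
#'
#' Fraction of positions where prediction and truth disagree; in the binary
#' case this equals `(FP + FN) / (TP + FN + FP + TN)` with the standard
#' confusion-matrix cells.
#'
#' @param truth,estimate Equal-length label vectors.
#' @return A single number in `[0, 1]`.
#' @export
error_rate <- function(truth, estimate) {
  if (length(truth) != length(estimate) || length(truth) < 1L) {
    stop_invalid("`truth` and `estimate` must have equal positive length")
  }
  mean(truth != estimate)
}
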