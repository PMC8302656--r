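# End-to-end orchestration: balance -> preprocess -> cumulant features ->
# stratified split -> GA-tuned KELM -> report.

#' Stratified train/test split
#'
#' The test size is `round(n_rows * (1 - train_fraction))` (round-to-nearest
#' on the whole dataset); in stratified mode the test rows are apportioned
#' across classes by largest remainder, so per-class allocations sum exactly
#' to the global test count.
#'
#' @param data Labelled dataset tibble.
#' @param train_fraction Fraction of rows used for training, in `(0, 1)`.
#' @param stratified Allocate test rows per class? Default TRUE.
#' @param seed Integer seed for the random row assignment.
#' @return A list with tibbles `train` and `test`; together they cover the
#'   input with no overlap.
#' @export
split_dataset <- function(data, train_fraction, stratified = TRUE, seed = 1L) {
  check_dataset(data)
  if (!is.numeric(train_fraction) || train_fraction <= 0 || train_fraction >= 1) {
    stop_invalid("`train_fraction` must lie strictly between 0 and 1")
  }
  set.seed(seed)
  n <- nrow(data)
  n_test <- round(n * (1 - train_fraction))
  if (!stratified) {
    test_idx <- sample(n, n_test)
  } else {
    labels <- data$label
    classes <- sort(unique(labels))
    counts <- vapply(classes, function(cl) sum(labels == cl), integer(1))
    exact <- counts * n_test / n
    alloc <- floor(exact)
    short <- n_test - sum(alloc)
    if (short > 0L) {
      # largest-remainder apportionment; remainder ties broken by class order
      order_rem <- order(exact - alloc, decreasing = TRUE)
      alloc[order_rem[seq_len(short)]] <- alloc[order_rem[seq_len(short)]] + 1L
    }
    alloc <- pmin(alloc, counts)
    test_idx <- unlist(lapply(seq_along(classes), function(k) {
      rows <- which(labels == classes[k])
      if (alloc[k] > 0L) sample(rows, alloc[k]) else integer(0)
    }), use.names = FALSE)
  }
  list(train = data[-test_idx, , drop = FALSE],
       test = data[test_idx, , drop = FALSE])
}

#' Run the full evolutionary hybrid classification pipeline
#'
#' Applies class balancing, signal conditioning, and a stratified split, then
#' lets a genetic algorithm tune `(m_l, c_r, p_k)`: for each candidate the
#' cumulant features are (re)computed at the candidate's `m_l` (cached per
#' lag), a KELM is trained on the training fold, and the fitness is the
#' classification error rate on either an inner validation fold carved from
#' the training rows (`leakage_mode = "validation"`, default) or the test
#' fold itself (`leakage_mode = "paper"`, flagged in the report). The best
#' chromosome is finally refit on the full training fold and evaluated on the
#' untouched test fold.
#'
#' @param data Labelled dataset tibble of raw signals.
#' @param balancing One of `"none"`, `"rost"`, `"irst"`, `"rust"`. Balancing
#'   happens before the split; duplicated oversampled rows can then appear in
#'   both folds, which `leakage_mode = "validation"` does not repair -- use
#'   `balance_after_split = TRUE` for a leakage-free protocol.
#' @param train_fraction Training fraction for [split_dataset()].
#' @param ga A [ga_config()]; its `m_l` bounds are clamped to the data.
#' @param kernel_name Kernel family for the KELM (default `"rbf"`; the tuned
#'   `p_k` parameterises it).
#' @param preprocess Apply [preprocess_dataset()] first? Default TRUE (set
#'   FALSE for parametric attribute vectors, which are not time series).
#' @param sampling_rate Sampling frequency in Hz (used by preprocessing).
#' @param leakage_mode `"validation"` or `"paper"` (see above).
#' @param validation_fraction Fraction of training rows held out as the inner
#'   validation fold (validation mode only).
#' @param balance_after_split Balance the training fold only, after
#'   splitting.
#' @param seed Integer seed driving balancing, splitting and the GA.
#' @return An object of class `ecg_run_report`.
#' @export
run_pipeline <- function(data,
                         balancing = c("none", "rost", "irst", "rust"),
                         train_fraction = 0.7,
                         ga = ga_config(),
                         kernel_name = "rbf",
                         preprocess = TRUE,
                         sampling_rate = 360,
                         leakage_mode = c("validation", "paper"),
                         validation_fraction = 0.25,
                         balance_after_split = FALSE,
                         seed = 1L) {
  t0 <- Sys.time()
  check_dataset(data)
  balancing <- match.arg(balancing)
  leakage_mode <- match.arg(leakage_mode)

  balance <- function(d, why) {
    tryCatch(
      switch(balancing,
             none = d,
             rost = resample_rost(d, seed = seed),
             irst = resample_irst(d, seed = seed),
             rust = resample_rust(d, seed = seed)),
      error = function(e) abort(sprintf("balancing stage (%s): %s", why,
                                        conditionMessage(e)))
    )
  }
  if (!balance_after_split) data <- balance(data, "before split")

  if (preprocess) {
    data <- tryCatch(
      preprocess_dataset(data, sampling_rate = sampling_rate),
      error = function(e) abort(sprintf("preprocessing stage: %s",
                                        conditionMessage(e)))
    )
  }

  folds <- split_dataset(data, train_fraction, stratified = TRUE, seed = seed)
  train <- folds$train
  test <- folds$test
  if (balance_after_split) train <- balance(train, "training fold")

  if (leakage_mode == "validation") {
    inner <- split_dataset(train, 1 - validation_fraction, stratified = TRUE,
                           seed = seed + 1L)
    fit_fold <- inner$train
    eval_fold <- inner$test
  } else {
    fit_fold <- train
    eval_fold <- test
  }

  n_attr <- ncol(data) - 1L
  lag_cap <- (n_attr - 1L) %/% 2L
  ga$bounds$m_l <- c(max(1, ga$bounds$m_l[1L]), min(lag_cap, ga$bounds$m_l[2L]))
  ga$seed <- seed

  feature_cache <- new.env(parent = emptyenv())
  features_at <- function(d, m_l, tag) {
    key <- paste0(tag, "@", m_l)
    if (is.null(feature_cache[[key]])) {
      feature_cache[[key]] <- extract_features(d, m_l)
    }
    feature_cache[[key]]
  }

  fitness <- function(genes) {
    m_l <- as.integer(genes[["m_l"]])
    spec <- kernel_spec(kernel_name, p_k = genes[["p_k"]])
    fit <- kelm_fit(features_at(fit_fold, m_l, "fit"), c_r = genes[["c_r"]],
                    spec = spec)
    pred <- predict(fit, features_at(eval_fold, m_l, "eval"))
    error_rate(eval_fold$label, pred)
  }

  ga_result <- ga_optimize(fitness, ga)
  best <- ga_result$best
  spec <- kernel_spec(kernel_name, p_k = best[["p_k"]])

  final_train_feats <- features_at(train, as.integer(best[["m_l"]]), "final_train")
  model <- kelm_fit(final_train_feats, c_r = best[["c_r"]], spec = spec)
  train_pred <- predict(model, final_train_feats)
  test_feats <- features_at(test, as.integer(best[["m_l"]]), "final_test")
  test_pred <- predict(model, test_feats)

  classes <- sort(unique(data$label))
  confusion <- table(
    truth = factor(test$label, levels = classes),
    predicted = factor(test_pred, levels = classes)
  )

  structure(
    list(
      chosen = list(m_l = as.integer(best[["m_l"]]), c_r = best[["c_r"]],
                    p_k = best[["p_k"]]),
      train_error = error_rate(train$label, train_pred),
      test_error = error_rate(test$label, test_pred),
      confusion = confusion,
      test_predictions = tibble(truth = test$label, predicted = test_pred),
      split_sizes = c(train = nrow(train), test = nrow(test)),
      balancing = balancing,
      leakage_mode = leakage_mode,
      fitness_fold = if (leakage_mode == "validation") "inner validation" else "test",
      balance_after_split = balance_after_split,
      ga_history = ga_result$history,
      model = model,
      seed = seed,
      elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs"))
    ),
    class = "ecg_run_report"
  )
}

#' @export
print.ecg_run_report <- function(x, ...) {
  cat("Evolutionary hybrid classifier run\n")
  cat(sprintf("  balancing: %s%s | GA fitness fold: %s\n", x$balancing,
              if (x$balance_after_split) " (after split)" else "",
              x$fitness_fold))
  cat(sprintf("  split: %d train / %d test rows\n",
              x$split_sizes[["train"]], x$split_sizes[["test"]]))
  cat(sprintf("  chosen m_l = %d, c_r = %.4g, p_k = %.4g\n",
              x$chosen$m_l, x$chosen$c_r, x$chosen$p_k))
  cat(sprintf("  train error %.2f%% | test error %.2f%%\n",
              100 * x$train_error, 100 * x$test_error))
  invisible(x)
}

#' Broom-style summaries of a pipeline run
#'
#' `tidy()` flattens the confusion matrix to one row per truth/prediction
#' pair; `glance()` gives the one-row run summary.
#'
#' @param x An `ecg_run_report`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.ecg_run_report <- function(x, ...) {
  as_tibble(as.data.frame(x$confusion)) |>
    dplyr::rename(count = "Freq")
}

#' @rdname tidy.ecg_run_report
#' @export
glance.ecg_run_report <- function(x, ...) {
  tibble(
    m_l = x$chosen$m_l, c_r = x$chosen$c_r, p_k = x$chosen$p_k,
    train_error = x$train_error, test_error = x$test_error,
    n_train = x$split_sizes[["train"]], n_test = x$split_sizes[["test"]],
    balancing = x$balancing, leakage_mode = x$leakage_mode, seed = x$seed
  )
}
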