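# Class-imbalance correction.
#
# Three strategies equalise per-class counts: random oversampling (ROST)
# raises every class to the majority count by copying rows with replacement;
# random undersampling (RUST) cuts every class to the minority count; and
# importance resampling (IRST) moves every class to ceil(mean class size),
# oversampling minority classes by weighted draw and undersampling majority
# classes by dropping the lowest-weight rows first. Output keeps original
# rows first in input order, then duplicates, so provenance stays auditable.

class_counts_of <- function(labels) {
  table(factor(labels, levels = sort(unique(labels))))
}

#' Largest and smallest per-class counts
#'
#' @param data Labelled dataset tibble (or an integer label vector).
#' @return A named list with `max_count` and `min_count`.
#' @examples
#' imbalance_ratio(as_ecg_dataset(matrix(0, 8, 1), c(rep(0, 5), rep(1, 3))))
#' @export
imbalance_ratio <- function(data) {
  labels <- if (is.data.frame(data)) check_dataset(data)$label else data
  if (length(labels) < 1L) stop_invalid("labels must be non-empty")
  counts <- as.integer(class_counts_of(labels))
  list(max_count = max(counts), min_count = min(counts))
}

resample_core <- function(data, seed, target_fun, sampler) {
  check_dataset(data)
  set.seed(seed)
  labels <- data$label
  classes <- sort(unique(labels))
  counts <- as.integer(class_counts_of(labels))
  target <- target_fun(counts, length(labels))
  keep_idx <- unlist(lapply(seq_along(classes), function(k) {
    rows <- which(labels == classes[k])
    sampler(rows, target, k)
  }), use.names = FALSE)
  data[keep_idx, , drop = FALSE]
}

#' Random oversampling (ROST)
#'
#' Every class is raised to the majority-class count: all original rows are
#' retained and minority classes are topped up with copies drawn uniformly
#' with replacement.
#'
#' @param data Labelled dataset tibble.
#' @param seed Integer seed for the random draws.
#' @return A tibble with `n_classes * max_count` rows.
#' @export
resample_rost <- function(data, seed = 1L) {
  resample_core(
    data, seed,
    target_fun = function(counts, n) max(counts),
    sampler = function(rows, target, k) {
      extra <- target - length(rows)
      c(rows, if (extra > 0L) sample(rows, extra, replace = TRUE))
    }
  )
}

#' Random undersampling (RUST)
#'
#' Every class is cut to the minority-class count by keeping a uniformly
#' random subset of its rows (in input order).
#'
#' @inheritParams resample_rost
#' @return A tibble with `n_classes * min_count` rows.
#' @export
resample_rust <- function(data, seed = 1L) {
  resample_core(
    data, seed,
    target_fun = function(counts, n) min(counts),
    sampler = function(rows, target, k) {
      if (length(rows) > target) sort(sample(rows, target)) else rows
    }
  )
}

#' Importance resampling (IRST)
#'
#' Every class is moved to `ceiling(n_rows / n_classes)` rows. Classes below
#' the target are topped up by a weighted draw with replacement; classes above
#' it are trimmed by dropping their lowest-weight rows first. With the default
#' uniform weights both directions reduce to random resampling.
#'
#' @inheritParams resample_rost
#' @param weights Optional non-negative per-row importance weights.
#' @return A tibble with `n_classes * ceiling(n_rows / n_classes)` rows.
#' @export
resample_irst <- function(data, seed = 1L, weights = NULL) {
  check_dataset(data)
  if (!is.null(weights)) {
    if (length(weights) != nrow(data)) {
      stop_invalid("`weights` must have one entry per row")
    }
    if (any(!is.finite(weights)) || any(weights < 0)) {
      stop_invalid("`weights` must be finite and non-negative")
    }
  } else {
    weights <- rep(1, nrow(data))
  }
  resample_core(
    data, seed,
    target_fun = function(counts, n) as.integer(ceiling(n / length(counts))),
    sampler = function(rows, target, k) {
      w <- weights[rows]
      if (length(rows) < target) {
        extra <- target - length(rows)
        probs <- if (sum(w) > 0) w else rep(1, length(rows))
        c(rows, sample(rows, extra, replace = TRUE, prob = probs))
      } else if (length(rows) > target) {
        # drop lowest-weight rows first; ties (e.g. uniform weights) broken
        # at random
        ord <- order(w, runif(length(rows)), decreasing = TRUE)
        sort(rows[ord[seq_len(target)]])
      } else {
        rows
      }
    }
  )
}
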