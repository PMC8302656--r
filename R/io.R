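# Dataset container and CSV round-trip.
#
# The on-disk layout is one sample per row: numeric attribute columns followed
# by a final integer class-label column. Missing attribute values are written
# with a configurable marker ("?" by default, the UCI convention) and read
# back as NA.

#' Assemble a labelled dataset tibble
#'
#' @param samples Numeric matrix or data frame, one sample per row.
#' @param labels Integer-like class labels, one per row.
#' @return A tibble with attribute columns `V1..Vp` and a final `label`
#'   column.
#' @export
as_ecg_dataset <- function(samples, labels) {
  samples <- as.matrix(samples)
  if (nrow(samples) != length(labels)) {
    stop_invalid("`samples` rows (%d) and `labels` length (%d) differ",
                 nrow(samples), length(labels))
  }
  colnames(samples) <- paste0("V", seq_len(ncol(samples)))
  out <- as_tibble(samples)
  out$label <- as.integer(labels)
  out
}

#' Read a labelled dataset from delimited text
#'
#' Expects the package's CSV layout: numeric attribute columns with the class
#' label in the final column. Cells equal to `missing_marker` become `NA`.
#'
#' @param path File path.
#' @param header Does the first line carry column names?
#' @param missing_marker String marking a missing attribute value.
#' @return A labelled dataset tibble (see [as_ecg_dataset()]).
#' @export
read_dataset <- function(path, header = TRUE, missing_marker = "?") {
  if (!file.exists(path)) stop_invalid("file not found: %s", path)
  raw <- suppressWarnings(readr::read_csv(
    path,
    col_names = header,
    na = c(missing_marker, "NA", ""),
    col_types = readr::cols(.default = readr::col_double()),
    progress = FALSE,
    show_col_types = FALSE
  )) # parse issues surface below as structured errors, not vroom warnings
  probs <- readr::problems(raw)
  if (nrow(probs) > 0L) {
    stop_invalid("malformed row at line %d of %s: %s",
                 probs$row[1L], path, probs$expected[1L])
  }
  if (ncol(raw) < 2L) stop_invalid("dataset needs at least one attribute column plus a label")
  n_missing <- sum(is.na(raw[, -ncol(raw)]))
  if (n_missing > 0L) {
    message(sprintf("read_dataset: %d missing attribute value(s) marked NA", n_missing))
  }
  labels <- raw[[ncol(raw)]]
  if (any(is.na(labels)) || any(labels != round(labels))) {
    stop_invalid("final column of %s must hold integer class labels", path)
  }
  as_ecg_dataset(raw[, -ncol(raw), drop = FALSE], as.integer(labels))
}

#' Write a labelled dataset as delimited text
#'
#' Inverse of [read_dataset()]: attribute columns first, `label` last, `NA`
#' cells rendered with `missing_marker`.
#'
#' @param data Labelled dataset tibble.
#' @param path Output file path.
#' @param missing_marker String used for missing attribute values.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path, missing_marker = "?") {
  check_dataset(data)
  out <- data[c(setdiff(names(data), "label"), "label")]
  readr::write_csv(out, path, na = missing_marker, progress = FALSE)
  invisible(path)
}
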