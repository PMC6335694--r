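#' Read an annotated RR-interval table
#'
#' Reads a delimited text file of beat times and RR intervals into a tidy
#' RR-series tibble. The file must have columns `time_ms` (cumulative beat
#' time, milliseconds), `rr_ms` (interval ending at that beat) and optionally
#' `label` (per-beat annotation, `"N"` for normal sinus beats; anything else
#' is treated as non-normal). A header row is optional and auto-detected;
#' the delimiter is a comma for `.csv` files and a tab otherwise.
#'
#' @param path Path to a delimited text file.
#' @param subject_id Opaque subject identifier stored in the `subject` column.
#' @param condition Recording condition, `"rest"` or `"stress"`.
#' @return A tibble with columns `subject`, `condition`, `time_ms`, `rr_ms`,
#'   `label`, one row per beat, validated so that beat times are strictly
#'   increasing, intervals are positive and `diff(time_ms) == rr_ms[-1]`.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("time_ms,rr_ms,label", "800,800,N", "1600,800,N"), f)
#' read_rr_table(f, subject_id = "s01", condition = "rest")
#' @export
read_rr_table <- function(path, subject_id = "unknown", condition = c("rest", "stress")) {
  condition <- match.arg(condition)
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) abort(sprintf("Empty RR file: %s", path))
  first_fields <- strsplit(first, delim, fixed = TRUE)[[1L]]
  has_header <- is.na(suppressWarnings(as.numeric(first_fields[1L])))
  raw <- read_delim(
    path,
    delim = delim,
    col_names = has_header,
    show_col_types = FALSE,
    progress = FALSE
  )
  if (ncol(raw) < 2L) abort(sprintf("RR file needs at least 2 columns (time_ms, rr_ms): %s", path))
  if (!has_header) {
    names(raw)[1:2] <- c("time_ms", "rr_ms")
    if (ncol(raw) >= 3L) names(raw)[3L] <- "label"
  }
  assert_cols(raw, c("time_ms", "rr_ms"), "RR file")
  if (!"label" %in% names(raw)) raw$label <- "N"
  header_offset <- if (has_header) 1L else 0L
  time_ms <- suppressWarnings(as.numeric(raw$time_ms))
  rr_ms <- suppressWarnings(as.numeric(raw$rr_ms))
  bad <- which(!is.finite(time_ms) | !is.finite(rr_ms))
  if (length(bad) > 0L) {
    abort(sprintf("Malformed RR row at line %d of %s.", bad[1L] + header_offset, path))
  }
  new_rr_series(
    time_ms = time_ms, rr_ms = rr_ms, label = as.character(raw$label),
    subject_id = subject_id, condition = condition,
    line_offset = header_offset, source = path
  )
}

# Construct and validate a tidy RR series. `line_offset` is used to report
# file line numbers from read_rr_table(); for programmatic construction the
# offset is 0 and "line" means row.
new_rr_series <- function(time_ms, rr_ms, label = "N",
                          subject_id = "unknown", condition = "rest",
                          line_offset = 0L, source = "input") {
  n <- length(time_ms)
  if (n == 0L) abort("RR series is empty.")
  label <- rep_len(as.character(label), n)
  bad_rr <- which(rr_ms <= 0)
  if (length(bad_rr) > 0L) {
    abort(sprintf(
      "Non-positive RR interval at line %d of %s.",
      bad_rr[1L] + line_offset, source
    ))
  }
  if (n > 1L) {
    dt <- diff(time_ms)
    bad_t <- which(dt <= 0)
    if (length(bad_t) > 0L) {
      abort(sprintf(
        "Beat times not strictly increasing at line %d of %s.",
        bad_t[1L] + 1L + line_offset, source
      ))
    }
    # Interval i must end at beat i: allow half-millisecond rounding slack.
    bad_c <- which(abs(dt - rr_ms[-1L]) > 0.5)
    if (length(bad_c) > 0L) {
      abort(sprintf(
        "rr_ms does not match diff(time_ms) at line %d of %s.",
        bad_c[1L] + 1L + line_offset, source
      ))
    }
  }
  tibble(
    subject = as.character(subject_id),
    condition = as.character(condition),
    time_ms = as.numeric(time_ms),
    rr_ms = as.numeric(rr_ms),
    label = label
  )
}

#' Write an RR series back to delimited text
#'
#' Inverse of [read_rr_table()]: writes `time_ms`, `rr_ms`, `label` with a
#' header row, as CSV for `.csv` paths and TSV otherwise, so that a
#' read/write cycle round-trips.
#'
#' @param series RR-series tibble (from [read_rr_table()] or
#'   [generate_rr_series()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_rr_table <- function(series, path) {
  assert_cols(series, c("time_ms", "rr_ms", "label"), "series")
  out <- series[, c("time_ms", "rr_ms", "label")]
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    write_csv(out, path, progress = FALSE)
  } else {
    write_tsv(out, path, progress = FALSE)
  }
  invisible(path)
}

# An interval is NN iff both of its delimiting beats are labelled N. The
# beat opening the first interval precedes the record and is assumed normal.
nn_flags <- function(label) {
  is_n <- label == "N"
  n <- length(is_n)
  if (n == 1L) return(is_n)
  is_n & c(TRUE, is_n[-n])
}

#' NN/RR signal-quality ratio
#'
#' Fraction of RR intervals that are normal-to-normal (NN), i.e. delimited by
#' two beats labelled `"N"`. Used as a movement-artifact quality index: series
#' whose ratio falls below a threshold (90% by default) are excluded rather
#' than corrected.
#'
#' @param series RR-series tibble with columns `rr_ms` and `label`.
#' @return A fraction in `[0, 1]`.
#' @examples
#' s <- generate_rr_series(seed = 1)
#' nn_ratio(s)
#' @export
nn_ratio <- function(series) {
  assert_cols(series, c("rr_ms", "label"), "series")
  if (nrow(series) == 0L) abort("Cannot compute NN/RR ratio of an empty series.")
  mean(nn_flags(series$label))
}

#' Signal-quality gate on the NN/RR ratio
#'
#' @param series RR-series tibble.
#' @param threshold Minimum NN/RR ratio; the boundary is inclusive (a ratio
#'   exactly equal to the threshold passes). Must lie in `(0, 1]`.
#' @return `TRUE` if the series passes, `FALSE` otherwise.
#' @export
quality_gate <- function(series, threshold = 0.90) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 1) {
    abort("`threshold` must be a single value in (0, 1].")
  }
  nn_ratio(series) >= threshold
}

#' Derive the NN-interval excerpt from an annotated RR series
#'
#' Keeps only intervals whose two delimiting beats are labelled normal;
#' removed intervals are dropped outright, with no interpolation or ectopic
#' correction (quality is handled by the gate, not by editing). The series
#' must pass [quality_gate()] first; otherwise the call fails, reporting the
#' offending ratio.
#'
#' @param series RR-series tibble (or an already-derived NN tibble, in which
#'   case it is returned unchanged: the operation is idempotent).
#' @param threshold Quality-gate threshold passed to [quality_gate()].
#' @return A tibble with columns `subject`, `condition`, `time_ms` (ending
#'   beat time of each interval) and `nn_ms`.
#' @export
derive_nn <- function(series, threshold = 0.90) {
  if ("nn_ms" %in% names(series)) {
    return(series)
  }
  assert_cols(series, c("time_ms", "rr_ms", "label"), "series")
  ratio <- nn_ratio(series)
  if (ratio < threshold) {
    abort(sprintf(
      "Series fails the NN/RR quality gate: ratio %.3f < threshold %.2f.",
      ratio, threshold
    ))
  }
  keep <- nn_flags(series$label)
  out <- series[keep, , drop = FALSE]
  cols <- intersect(c("subject", "condition"), names(out))
  out <- out[, c(cols, "time_ms", "rr_ms")]
  names(out)[names(out) == "rr_ms"] <- "nn_ms"
  as_tibble(out)
}
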