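#' Construct a frame-level feature sequence
#'
#' A `feature_sequence` is the package's container for time-ordered
#' frame-level features: a numeric matrix with one row per analysis frame
#' (default frame step 10 ms) plus timing metadata. It is the common
#' currency between the feature readers, the speaker segmentation and the
#' autoencoder fits.
#'
#' @param values Numeric matrix, `n_frames x n_dims`. All values must be
#'   finite.
#' @param frame_step Seconds between consecutive frames (default 0.010).
#' @param start_time Time in seconds of frame 1's left edge (default 0).
#' @param feature_set Label for the feature set, e.g. `"compare_llds"` or
#'   `"deep_spectrum"`. Deep Spectrum sequences are never standardized by
#'   the pipeline (see [standardize_per_recording()]).
#' @param times Optional explicit per-frame start times in seconds; used for
#'   subsequences that are no longer evenly spaced (after speaker
#'   segmentation). Must be strictly increasing and match `nrow(values)`.
#'
#' @return An object of class `feature_sequence`: the matrix with
#'   `frame_step`, `start_time`, `feature_set` (and possibly `times`)
#'   attributes.
#' @seealso [read_feature_table()], [frame_times()], [append_deltas()]
#' @export
#' @examples
#' fs <- feature_sequence(matrix(rnorm(20), 10, 2))
#' frame_times(fs)
feature_sequence <- function(values, frame_step = 0.010, start_time = 0,
                             feature_set = "unknown", times = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) {
    stop("feature values must be numeric", call. = FALSE)
  }
  if (nrow(values) < 1L || ncol(values) < 1L) {
    stop("empty input: a feature_sequence needs at least one frame and one dimension",
         call. = FALSE)
  }
  if (!all(is.finite(values))) {
    stop("all feature values must be finite", call. = FALSE)
  }
  if (!is.numeric(frame_step) || length(frame_step) != 1L || frame_step <= 0) {
    stop("frame_step must be a single positive number (seconds)", call. = FALSE)
  }
  if (!is.null(times)) {
    times <- as.numeric(times)
    if (length(times) != nrow(values)) {
      stop("times must have one entry per frame", call. = FALSE)
    }
    if (nrow(values) > 1L && any(diff(times) <= 0)) {
      stop("times must be strictly increasing", call. = FALSE)
    }
  }
  structure(values,
            frame_step = frame_step,
            start_time = start_time,
            feature_set = feature_set,
            times = times,
            class = c("feature_sequence", "matrix", "array"))
}

#' @export
print.feature_sequence <- function(x, ...) {
  cat(sprintf("<feature_sequence> %d frames x %d dims (%s)\n",
              nrow(x), ncol(x), attr(x, "feature_set")))
  tm <- frame_times(x)
  cat(sprintf("  frame step %.4g s, time span [%.3f, %.3f] s\n",
              attr(x, "frame_step"), tm[1L], tm[length(tm)]))
  invisible(x)
}

#' Frame start times of a feature sequence
#'
#' Frame `i` (1-based) covers the half-open interval
#' `[start_time + (i-1) * frame_step, start_time + i * frame_step)`; this
#' returns its left edge. Subsequences created by speaker segmentation carry
#' explicit (no longer evenly spaced) times, which are returned unchanged.
#'
#' @param x A `feature_sequence`.
#' @return Numeric vector of per-frame start times in seconds.
#' @export
frame_times <- function(x) {
  stopifnot(inherits(x, "feature_sequence"))
  tm <- attr(x, "times")
  if (!is.null(tm)) return(tm)
  attr(x, "start_time") + (seq_len(nrow(x)) - 1) * attr(x, "frame_step")
}

# strip class/attrs -> plain matrix (internal)
as_matrix <- function(x) {
  y <- unclass(x)
  attributes(y) <- list(dim = dim(y), dimnames = dimnames(y))
  y
}

#' Read a delimited frame-level feature table
#'
#' Reads a comma- or tab-delimited numeric table with one row per frame into
#' a [feature_sequence()]. An optional single header row supplies dimension
#' names. ARFF-style openSMILE exports are also accepted: `@attribute`
#' declarations become dimension names and rows are read from the `@data`
#' section (a leading `name` string column and trailing class column, if
#' present, are dropped when non-numeric).
#'
#' @param path Path to the feature table.
#' @param frame_step Seconds per frame (default 0.010, the usual LLD step).
#' @param start_time Time of the first frame in seconds.
#' @param feature_set Feature-set label stored on the result.
#' @param sep Field separator; `NULL` (default) sniffs comma vs whitespace.
#' @return A `feature_sequence` with rows in file order.
#' @export
read_feature_table <- function(path, frame_step = 0.010, start_time = 0,
                               feature_set = "compare_llds", sep = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    stop("empty input: ", path, call. = FALSE)
  }
  col_names <- NULL
  if (any(grepl("^\\s*@", lines))) {
    # ARFF: names from @attribute lines, rows after @data
    attr_lines <- grep("^\\s*@attribute", lines, ignore.case = TRUE, value = TRUE)
    col_names <- vapply(strsplit(trimws(attr_lines), "\\s+"), `[`, "", 2L)
    data_at <- grep("^\\s*@data", lines, ignore.case = TRUE)
    if (length(data_at) != 1L) stop("malformed ARFF: missing @data section", call. = FALSE)
    lines <- lines[seq.int(data_at + 1L, length(lines))]
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L) stop("empty input: no rows after @data", call. = FALSE)
    sep <- ","
  }
  if (is.null(sep)) sep <- if (grepl(",", lines[1L])) "," else "[\t ]+"
  fields <- strsplit(trimws(lines), sep)
  first <- suppressWarnings(as.numeric(fields[[1L]]))
  if (is.null(col_names) && anyNA(first)) {
    # header row of names
    col_names <- fields[[1L]]
    fields <- fields[-1L]
    if (length(fields) == 0L) stop("empty input: header but no data rows", call. = FALSE)
  }
  widths <- lengths(fields)
  if (length(unique(widths)) != 1L) {
    bad <- which(widths != widths[1L])[1L]
    stop(sprintf("format error: ragged rows (row %d has %d fields, expected %d)",
                 bad, widths[bad], widths[1L]), call. = FALSE)
  }
  keep_numeric <- function(row) suppressWarnings(as.numeric(row))
  num <- lapply(fields, keep_numeric)
  drop_cols <- integer(0)
  col_na <- vapply(seq_len(widths[1L]),
                   function(j) sum(is.na(vapply(num, `[`, 0, j))), 0L)
  # tolerate openSMILE's name/class bookends: fully non-numeric edge columns
  drop_cols <- which(col_na == length(num) & seq_len(widths[1L]) %in% c(1L, widths[1L]))
  partial <- setdiff(which(col_na > 0L), drop_cols)
  if (length(partial)) {
    bad_row <- which(is.na(vapply(num, `[`, 0, partial[1L])))[1L]
    stop(sprintf("parse error: non-numeric value at row %d, column %d",
                 bad_row, partial[1L]), call. = FALSE)
  }
  mat <- do.call(rbind, num)
  if (length(drop_cols)) {
    mat <- mat[, -drop_cols, drop = FALSE]
    if (!is.null(col_names)) col_names <- col_names[-drop_cols]
  }
  if (!is.null(col_names) && length(col_names) == ncol(mat)) {
    colnames(mat) <- col_names
  }
  feature_sequence(mat, frame_step = frame_step, start_time = start_time,
                   feature_set = feature_set)
}

#' Standardize a feature sequence per recording
#'
#' Rescales every dimension to zero mean and unit standard deviation over
#' the frames of the recording, the within-recording normalization applied
#' to frame-level acoustic descriptors before autoencoder training to
#' remove recording-environment variance. The population (1/N) standard
#' deviation is used; dimensions whose standard deviation falls below `eps`
#' are mapped to all zeros rather than divided by a vanishing scale.
#'
#' Deep Spectrum sequences (`feature_set == "deep_spectrum"`) are
#' deliberately left untouched by the pipeline: normalizing those
#' embeddings degrades autoencoder reconstruction, so calling this on one
#' is an error unless `force = TRUE`.
#'
#' @param seq A [feature_sequence()] with at least 2 frames.
#' @param eps Degenerate-variance tolerance (default `1e-8`).
#' @param force Standardize even if the feature set is `"deep_spectrum"`.
#' @return A standardized `feature_sequence` with the same shape and timing.
#' @export
standardize_per_recording <- function(seq, eps = 1e-8, force = FALSE) {
  stopifnot(inherits(seq, "feature_sequence"))
  if (identical(attr(seq, "feature_set"), "deep_spectrum") && !force) {
    stop("deep_spectrum features are used raw (not standardized); ",
         "pass force = TRUE to override", call. = FALSE)
  }
  if (nrow(seq) < 2L) {
    stop("insufficient data: standardization needs at least 2 frames", call. = FALSE)
  }
  x <- as_matrix(seq)
  n <- nrow(x)
  mu <- colMeans(x)
  centered <- sweep(x, 2L, mu)
  sd_pop <- sqrt(colSums(centered^2) / n)
  out <- sweep(centered, 2L, pmax(sd_pop, eps), "/")
  out[, sd_pop < eps] <- 0
  feature_sequence(out,
                   frame_step = attr(seq, "frame_step"),
                   start_time = attr(seq, "start_time"),
                   feature_set = attr(seq, "feature_set"),
                   times = attr(seq, "times"))
}

#' Append first-order delta features
#'
#' Doubles the dimensionality of a frame-level sequence by appending the
#' first-order differences `d[i] = x[i] - x[i-1]` (with `d[1] = 0`) of every
#' dimension, turning e.g. a 65-LLD acoustic table into the 130-dimensional
#' representation used for autoencoder training. Tables whose deltas were
#' already computed upstream (openSMILE-style 130-dim exports) should skip
#' this step; note openSMILE's own deltas come from a regression window, not
#' a simple difference, so the two are close but not identical.
#'
#' @param seq A [feature_sequence()].
#' @return A `feature_sequence` with `2 * n_dims` columns: the originals
#'   followed by their deltas (named `delta_<name>` when names exist).
#' @export
append_deltas <- function(seq) {
  stopifnot(inherits(seq, "feature_sequence"))
  x <- as_matrix(seq)
  d <- rbind(0, diff(x))
  if (!is.null(colnames(x))) colnames(d) <- paste0("delta_", colnames(x))
  feature_sequence(cbind(x, d),
                   frame_step = attr(seq, "frame_step"),
                   start_time = attr(seq, "start_time"),
                   feature_set = attr(seq, "feature_set"),
                   times = attr(seq, "times"))
}

#' Write a feature sequence as a delimited table
#'
#' Inverse of [read_feature_table()] at the written precision; used by the
#' synthetic corpus generator.
#'
#' @param seq A [feature_sequence()].
#' @param path Output path.
#' @param digits Significant digits to write (default 8).
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(seq, path, digits = 8) {
  stopifnot(inherits(seq, "feature_sequence"))
  x <- as_matrix(seq)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(colnames(x))) {
    writeLines(paste(colnames(x), collapse = ","), con)
  }
  writeLines(apply(x, 1L, function(r)
    paste(formatC(r, digits = digits, format = "g"), collapse = ",")), con)
  invisible(path)
}
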