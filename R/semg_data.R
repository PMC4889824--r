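#' @title SEMG recording data model, file I/O and segmentation
#' @name semg_data
#' @keywords internal
NULL

#' Gesture label vocabulary
#'
#' The six basic hand gestures the toolkit classifies: hand closing (HC),
#' hand opening (HO), wrist flexion (WF), wrist extension (WE), index finger
#' straightening (IF) and thumb straightening (T). Samples outside any
#' annotated gesture interval are labelled REST.
#'
#' @return Character vector of gesture labels (without REST).
#' @export
gesture_labels <- function() c("HC", "HO", "WF", "WE", "IF", "T")

#' @rdname gesture_labels
#' @return `default_label_set()` returns the gesture labels plus `"REST"`.
#' @export
default_label_set <- function() c(gesture_labels(), "REST")

#' Construct an SEMG recording
#'
#' A recording is a multi-channel numeric envelope time series with a
#' sampling rate and a set of labelled, non-overlapping gesture intervals.
#' Indices are 0-based and intervals are half-open `[start, end)`, so an
#' annotation covers samples `start + 1, ..., end` in R's 1-based terms.
#'
#' @param samples Numeric matrix, one column per channel, one row per sample.
#'   Column names are the channel names (defaults are supplied if missing).
#' @param sampling_rate_hz Positive sampling rate in Hz.
#' @param annotations `data.frame` with columns `start`, `end` (0-based,
#'   half-open) and `label`, or `NULL` for no annotations.
#' @param label_set Allowed gesture labels; defaults to the six gestures
#'   plus REST.
#' @return An object of class `semg_recording`.
#' @examples
#' x <- cbind(flexor = abs(sin(1:64)), extensor = abs(cos(1:64)))
#' rec <- semg_recording(x, 16, data.frame(start = 8, end = 40, label = "HC"))
#' rec
#' @export
semg_recording <- function(samples, sampling_rate_hz, annotations = NULL,
                           label_set = default_label_set()) {
  if (is.data.frame(samples)) samples <- as.matrix(samples)
  if (!is.matrix(samples) || !is.numeric(samples)) {
    stop("`samples` must be a numeric matrix (rows = samples, cols = channels)")
  }
  if (is.null(colnames(samples))) {
    colnames(samples) <- paste0("ch", seq_len(ncol(samples)))
  }
  if (anyDuplicated(colnames(samples))) stop("channel names must be unique")
  if (!is.numeric(sampling_rate_hz) || length(sampling_rate_hz) != 1L ||
      !is.finite(sampling_rate_hz) || sampling_rate_hz <= 0) {
    stop("`sampling_rate_hz` must be a single positive number")
  }
  annotations <- validate_annotations(annotations, nrow(samples), label_set)
  structure(
    list(
      channels = colnames(samples),
      samples = samples,
      sampling_rate_hz = as.numeric(sampling_rate_hz),
      annotations = annotations,
      label_set = label_set
    ),
    class = "semg_recording"
  )
}

validate_annotations <- function(annotations, n_total, label_set) {
  if (is.null(annotations) || (is.data.frame(annotations) && nrow(annotations) == 0L)) {
    return(data.frame(start = integer(0), end = integer(0),
                      label = character(0), stringsAsFactors = FALSE))
  }
  if (!is.data.frame(annotations) ||
      !all(c("start", "end", "label") %in% names(annotations))) {
    stop("`annotations` must be a data.frame with columns start, end, label")
  }
  ann <- data.frame(start = as.integer(annotations$start),
                    end = as.integer(annotations$end),
                    label = as.character(annotations$label),
                    stringsAsFactors = FALSE)
  if (any(ann$start < 0L) || any(ann$end > n_total) || any(ann$start >= ann$end)) {
    stop("annotation intervals must satisfy 0 <= start < end <= number of samples")
  }
  unknown <- setdiff(unique(ann$label), label_set)
  if (length(unknown) > 0L) {
    stop("unknown gesture label(s): ", paste(unknown, collapse = ", "))
  }
  ann <- ann[order(ann$start, ann$end), , drop = FALSE]
  rownames(ann) <- NULL
  if (nrow(ann) > 1L && any(ann$end[-nrow(ann)] > ann$start[-1L])) {
    stop("annotation intervals overlap")
  }
  ann
}

#' @export
print.semg_recording <- function(x, ...) {
  cat(sprintf(
    "semg_recording: %d channels (%s), %d samples @ %g Hz (%.3f s), %d annotations\n",
    length(x$channels), paste(x$channels, collapse = ", "),
    nrow(x$samples), x$sampling_rate_hz,
    nrow(x$samples) / x$sampling_rate_hz, nrow(x$annotations)
  ))
  invisible(x)
}

#' Read an SEMG recording from a signal file and a JSON sidecar
#'
#' The signal file is a delimited text table (CSV or TSV) with a header row
#' naming the channels and one row per sample; a leading time column named
#' `time`, `t` or `timestamp` (any case) is ignored. The sidecar is JSON with
#' keys `sampling_rate_hz`, `channel_names` and `labels` (an array of
#' `{start, end, label}` objects, 0-based half-open intervals).
#'
#' @param signal_path Path to the tabular signal file.
#' @param meta_path Path to the JSON metadata sidecar.
#' @param label_set Allowed labels (see [semg_recording()]).
#' @return A [semg_recording()] object. Column order of the signal file is
#'   preserved.
#' @seealso [write_recording()]
#' @export
read_recording <- function(signal_path, meta_path, label_set = default_label_set()) {
  if (!file.exists(signal_path)) stop("signal file not found: ", signal_path)
  if (!file.exists(meta_path)) stop("metadata file not found: ", meta_path)
  sep <- if (grepl("\\.tsv$", signal_path, ignore.case = TRUE)) "\t" else ","
  nf <- utils::count.fields(signal_path, sep = sep, blank.lines.skip = TRUE)
  if (length(unique(nf)) > 1L) {
    stop("malformed signal file: rows have differing column counts")
  }
  tab <- utils::read.table(signal_path, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) >= 1L && tolower(names(tab)[1L]) %in% c("time", "t", "timestamp")) {
    tab <- tab[, -1L, drop = FALSE]
  }
  if (ncol(tab) == 0L) stop("malformed signal file: no channel columns")
  if (!all(vapply(tab, is.numeric, logical(1)))) {
    stop("malformed signal file: non-numeric sample values")
  }
  if (anyNA(tab)) stop("malformed signal file: missing sample values")
  meta <- jsonlite::fromJSON(meta_path, simplifyVector = TRUE)
  if (is.null(meta$sampling_rate_hz)) {
    stop("metadata must declare sampling_rate_hz")
  }
  ann <- NULL
  if (!is.null(meta$labels) && length(meta$labels) > 0L) {
    ann <- as.data.frame(meta$labels, stringsAsFactors = FALSE)
  }
  if (!is.null(meta$channel_names) &&
      !identical(as.character(meta$channel_names), names(tab))) {
    stop("channel_names in metadata do not match signal file header")
  }
  semg_recording(as.matrix(tab), meta$sampling_rate_hz, ann, label_set = label_set)
}

#' Write an SEMG recording to a signal file and a JSON sidecar
#'
#' Numeric values are written with 15 significant digits, so a write/read
#' round trip reproduces the recording to at least 12 significant digits.
#'
#' @param rec A [semg_recording()].
#' @param signal_path Output path for the CSV signal table.
#' @param meta_path Output path for the JSON sidecar.
#' @return Invisibly, `rec`.
#' @export
write_recording <- function(rec, signal_path, meta_path) {
  stopifnot(inherits(rec, "semg_recording"))
  if (!all(is.finite(rec$samples))) {
    stop("recording contains non-finite sample values; refusing to write")
  }
  df <- as.data.frame(rec$samples)
  df[] <- lapply(df, function(col) format(col, digits = 15, trim = TRUE, scientific = FALSE))
  utils::write.csv(df, signal_path, row.names = FALSE, quote = FALSE)
  labels <- if (nrow(rec$annotations) > 0L) {
    lapply(seq_len(nrow(rec$annotations)), function(i) {
      list(start = rec$annotations$start[i],
           end = rec$annotations$end[i],
           label = rec$annotations$label[i])
    })
  } else {
    list()
  }
  meta <- list(
    sampling_rate_hz = rec$sampling_rate_hz,
    channel_names = rec$channels,
    labels = labels
  )
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(rec)
}

#' Sliding (non-overlapping) segmentation of a recording
#'
#' Splits a recording into consecutive fixed-length windows covering it left
#' to right; a trailing remainder shorter than one window is discarded. The
#' window length in samples is `N = round(window_ms / 1000 * sampling_rate_hz)`;
#' at 16 Hz the 187.5 ms default gives exactly 3 samples. Each window is
#' labelled from the annotations it overlaps according to `label_policy`:
#'
#' * `"majority"`: the label covering the most samples in the window wins;
#'   samples outside every annotation count toward REST, gesture labels beat
#'   REST on ties, and ties between gestures go to the earlier-starting
#'   annotation.
#' * `"strict"`: windows lying entirely inside one annotation take its label,
#'   windows entirely outside all annotations are REST, mixed windows are
#'   dropped.
#'
#' @param rec A [semg_recording()].
#' @param window_ms Window length in milliseconds (default 187.5).
#' @param label_policy `"majority"` (default) or `"strict"`.
#' @return List of `semg_segment` objects, each a list with elements
#'   `window` (N x channels matrix), `label`, `start` and `end` (0-based,
#'   half-open sample span). An empty list if the recording is shorter than
#'   one window.
#' @examples
#' x <- cbind(ch1 = rep(1, 10), ch2 = rep(2, 10))
#' rec <- semg_recording(x, 16, data.frame(start = 0, end = 10, label = "HC"))
#' length(sliding_segments(rec, 187.5))  # floor(10 / 3) = 3
#' @export
sliding_segments <- function(rec, window_ms = 187.5,
                             label_policy = c("majority", "strict")) {
  stopifnot(inherits(rec, "semg_recording"))
  label_policy <- match.arg(label_policy)
  n <- as.integer(round(window_ms / 1000 * rec$sampling_rate_hz))
  if (n < 3L) {
    stop("window of ", window_ms, " ms yields ", n,
         " samples; at least 3 are required (slope sign change needs interior points)")
  }
  n_total <- nrow(rec$samples)
  n_seg <- n_total %/% n
  if (n_seg == 0L) return(list())
  ann <- rec$annotations
  segments <- vector("list", n_seg)
  keep <- logical(n_seg)
  for (k in seq_len(n_seg)) {
    s0 <- (k - 1L) * n          # 0-based window start
    e0 <- s0 + n                # 0-based window end (exclusive)
    lab <- window_label(s0, e0, ann, label_policy)
    if (is.na(lab)) next        # strict policy drops mixed windows
    keep[k] <- TRUE
    segments[[k]] <- structure(
      list(window = rec$samples[(s0 + 1L):e0, , drop = FALSE],
           label = lab, start = s0, end = e0),
      class = "semg_segment"
    )
  }
  segments[keep]
}

# Label one half-open window [s0, e0) from sorted non-overlapping annotations.
# Returns NA_character_ when the strict policy must drop a mixed window.
window_label <- function(s0, e0, ann, policy) {
  if (nrow(ann) == 0L) return("REST")
  ov_start <- pmax(s0, ann$start)
  ov_end <- pmin(e0, ann$end)
  cover <- pmax(0L, ov_end - ov_start)
  hit <- which(cover > 0L)
  if (policy == "strict") {
    full <- which(ann$start <= s0 & ann$end >= e0)
    if (length(full) == 1L) return(ann$label[full])
    if (length(hit) == 0L) return("REST")
    return(NA_character_)
  }
  rest_cover <- (e0 - s0) - sum(cover)
  if (length(hit) == 0L) return("REST")
  best <- max(cover[hit])
  if (rest_cover > best) return("REST")
  # gesture labels beat REST on ties; earlier-starting annotation wins ties
  winners <- hit[cover[hit] == best]
  ann$label[winners[1L]]
}

#' @export
print.semg_segment <- function(x, ...) {
  cat(sprintf("semg_segment: [%d, %d) label=%s, %d samples x %d channels\n",
              x$start, x$end, x$label, nrow(x$window), ncol(x$window)))
  invisible(x)
}
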