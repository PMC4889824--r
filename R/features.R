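#' Mean absolute value
#'
#' `MAV = (1/N) * sum(|x_i|)` — the average rectified amplitude of a signal
#' window, the workhorse time-domain SEMG feature.
#'
#' @param x Numeric vector with at least one finite entry.
#' @return Nonnegative scalar.
#' @examples
#' mav(c(1, -2, 3))  # 2
#' @export
mav <- function(x) {
  check_signal(x, min_len = 1L, "mav")
  mean(abs(x))
}

#' Waveform length
#'
#' `WL = sum(|x_{i+1} - x_i|)` — the cumulative absolute sample-to-sample
#' variation over a window; measures combined amplitude and frequency content.
#'
#' @param x Numeric vector of length at least 2.
#' @return Nonnegative scalar.
#' @examples
#' wl(c(1, 3, 2))  # |3-1| + |2-3| = 3
#' @export
wl <- function(x) {
  check_signal(x, min_len = 2L, "wl")
  sum(abs(diff(x)))
}

#' Willison amplitude
#'
#' Counts the successive-sample differences whose magnitude reaches a
#' threshold: `WAMP = #{ i : |x_i - x_{i+1}| >= threshold }`. The indicator
#' convention is "greater than or equal", so a zero threshold counts every
#' pair.
#'
#' @param x Numeric vector of length at least 2.
#' @param threshold Nonnegative scalar in signal units.
#' @return Integer count in `0 .. length(x) - 1`.
#' @examples
#' wamp(c(0, 1, 0), threshold = 0.5)  # 2
#' @export
wamp <- function(x, threshold) {
  check_signal(x, min_len = 2L, "wamp")
  check_threshold(threshold)
  sum(abs(diff(x)) >= threshold)
}

#' Slope sign change
#'
#' Counts interior points where the slope reverses with sufficient magnitude:
#' `SSC = #{ i in 2..N-1 : (x_i - x_{i-1}) * (x_i - x_{i+1}) >= threshold }`.
#' The threshold is in squared signal units; the package default is a machine
#' epsilon (`1e-12`) so that exact-zero products from repeated samples are not
#' counted as slope reversals.
#'
#' @param x Numeric vector of length at least 3.
#' @param threshold Nonnegative scalar in squared signal units.
#' @return Integer count in `0 .. length(x) - 2`.
#' @examples
#' ssc(c(1, 2, 1, 2), threshold = 1e-12)  # 2
#' @export
ssc <- function(x, threshold) {
  check_signal(x, min_len = 3L, "ssc")
  check_threshold(threshold)
  n <- length(x)
  mid <- x[2:(n - 1L)]
  sum((mid - x[1:(n - 2L)]) * (mid - x[3:n]) >= threshold)
}

check_signal <- function(x, min_len, what) {
  if (!is.numeric(x) || length(x) < min_len) {
    stop(what, " requires a numeric vector of length >= ", min_len)
  }
  if (!all(is.finite(x))) stop(what, ": non-finite sample values")
  invisible(TRUE)
}

check_threshold <- function(threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      !is.finite(threshold) || threshold < 0) {
    stop("`threshold` must be a single nonnegative number")
  }
  invisible(TRUE)
}

#' Feature extraction configuration
#'
#' Selects which time-domain features to compute and fixes the two indicator
#' thresholds. `wamp_threshold = NULL` requests the scale-adaptive default,
#' 0.05 times the median MAV over the segment set the configuration is
#' resolved against (see [resolve_feature_config()]); the device's amplitude
#' units are arbitrary, so an absolute default would be meaningless.
#'
#' @param features Ordered subset of `c("MAV", "WL", "WAMP", "SSC")`.
#' @param wamp_threshold Nonnegative scalar (signal units) or `NULL` for the
#'   adaptive default.
#' @param ssc_threshold Nonnegative scalar (squared signal units); default
#'   `1e-12`, an epsilon that excludes exact-zero products.
#' @param normalize `"none"` (default) or `"zscore"`; z-scoring is available
#'   because radial-basis kernels are scale sensitive, but is off by default.
#' @return An object of class `feature_config`.
#' @export
feature_config <- function(features = c("MAV", "WL", "WAMP", "SSC"),
                           wamp_threshold = NULL,
                           ssc_threshold = 1e-12,
                           normalize = c("none", "zscore")) {
  known <- c("MAV", "WL", "WAMP", "SSC")
  features <- as.character(features)
  if (length(features) == 0L || !all(features %in% known) || anyDuplicated(features)) {
    stop("`features` must be a non-empty, duplicate-free subset of ",
         paste(known, collapse = ", "))
  }
  if (!is.null(wamp_threshold)) check_threshold(wamp_threshold)
  check_threshold(ssc_threshold)
  structure(
    list(features = features,
         wamp_threshold = wamp_threshold,
         ssc_threshold = ssc_threshold,
         normalize = match.arg(normalize)),
    class = "feature_config"
  )
}

#' Resolve adaptive thresholds against a segment set
#'
#' Replaces a `NULL` `wamp_threshold` with 0.05 times the median per-channel
#' MAV over `segments`. Call this on the training material before extraction
#' so that the threshold is a fixed preprocessing constant.
#'
#' @param cfg A [feature_config()].
#' @param segments List of segments from [sliding_segments()].
#' @return The configuration with all thresholds numeric.
#' @export
resolve_feature_config <- function(cfg, segments) {
  stopifnot(inherits(cfg, "feature_config"))
  if (!is.null(cfg$wamp_threshold)) return(cfg)
  if (length(segments) == 0L) stop("cannot resolve adaptive threshold: no segments")
  mavs <- unlist(lapply(segments, function(s) apply(s$window, 2, mav)))
  cfg$wamp_threshold <- 0.05 * stats::median(mavs)
  cfg
}

# Minimum window length demanded by the selected features.
min_segment_length <- function(cfg) {
  if ("SSC" %in% cfg$features) 3L
  else if (any(c("WL", "WAMP") %in% cfg$features)) 2L
  else 1L
}

#' Extract a feature vector from one segment
#'
#' Dimensions are laid out channel-major: for each channel (in recording
#' order), the selected features in configuration order. Names have the form
#' `<channel>_<feature>`, e.g. `ch1_MAV`.
#'
#' @param seg An `semg_segment` (see [sliding_segments()]).
#' @param cfg A [feature_config()] with numeric thresholds (resolve adaptive
#'   thresholds first if WAMP is selected).
#' @return Named numeric vector with attribute `"label"`.
#' @export
extract_features <- function(seg, cfg) {
  stopifnot(inherits(seg, "semg_segment"), inherits(cfg, "feature_config"))
  if ("WAMP" %in% cfg$features && is.null(cfg$wamp_threshold)) {
    stop("WAMP selected but wamp_threshold is unresolved; ",
         "call resolve_feature_config() first")
  }
  n <- nrow(seg$window)
  need <- min_segment_length(cfg)
  if (n < need) {
    offender <- if (need == 3L) "SSC" else "WL/WAMP"
    stop("segment of length ", n, " is too short for feature ", offender,
         " (needs >= ", need, " samples)")
  }
  vals <- unlist(lapply(seq_len(ncol(seg$window)), function(ci) {
    x <- seg$window[, ci]
    vapply(cfg$features, function(f) {
      switch(f,
             MAV = mav(x),
             WL = wl(x),
             WAMP = as.numeric(wamp(x, cfg$wamp_threshold)),
             SSC = as.numeric(ssc(x, cfg$ssc_threshold)))
    }, numeric(1))
  }))
  names(vals) <- as.vector(t(outer(colnames(seg$window), cfg$features, paste, sep = "_")))
  attr(vals, "label") <- seg$label
  vals
}

#' Extract a labelled feature data frame from a segment list
#'
#' @param segments List of segments from [sliding_segments()].
#' @param cfg A [feature_config()]; an adaptive WAMP threshold is resolved
#'   against `segments`.
#' @param drop_rest Drop REST-labelled segments (default `TRUE`; the
#'   classifier is trained on the six gestures only).
#' @return `data.frame` with one numeric column per feature dimension and a
#'   factor column `label`. The resolved configuration is attached as
#'   attribute `"feature_config"`.
#' @export
extract_dataset <- function(segments, cfg, drop_rest = TRUE) {
  stopifnot(inherits(cfg, "feature_config"))
  if (drop_rest) {
    segments <- segments[vapply(segments, function(s) s$label != "REST", logical(1))]
  }
  if (length(segments) == 0L) stop("no segments to extract features from")
  cfg <- resolve_feature_config(cfg, segments)
  rows <- lapply(segments, extract_features, cfg = cfg)
  mat <- do.call(rbind, rows)
  labels <- vapply(segments, function(s) s$label, character(1))
  df <- as.data.frame(mat)
  df$label <- factor(labels, levels = intersect(default_label_set(), unique(labels)))
  attr(df, "feature_config") <- cfg
  df
}

#' Fit / apply a per-dimension z-score normalizer
#'
#' Fit on the training split only, then apply to both splits. Dimensions with
#' zero variance pass through unchanged.
#'
#' @param x Numeric matrix or feature data frame (a `label` column is
#'   ignored) with at least two rows.
#' @return `fit_normalizer()` returns an object of class
#'   `feature_normalizer`; `apply_normalizer()` returns the transformed
#'   matrix/data frame with the same shape as its input.
#' @export
fit_normalizer <- function(x) {
  x <- feature_matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 vectors to fit a normalizer")
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  scale <- ifelse(sd > 0, sd, 1)   # sd = 0 dimensions pass through
  structure(list(mean = mu, scale = scale, center_zero = sd == 0),
            class = "feature_normalizer")
}

#' @rdname fit_normalizer
#' @param norm A fitted `feature_normalizer`.
#' @export
apply_normalizer <- function(norm, x) {
  stopifnot(inherits(norm, "feature_normalizer"))
  is_df <- is.data.frame(x)
  label <- if (is_df && "label" %in% names(x)) x$label else NULL
  m <- feature_matrix(x)
  if (ncol(m) != length(norm$mean)) {
    stop("dimension mismatch: normalizer has ", length(norm$mean),
         " dimensions, input has ", ncol(m))
  }
  center <- ifelse(norm$center_zero, 0, norm$mean)
  out <- sweep(sweep(m, 2, center, "-"), 2, norm$scale, "/")
  if (is_df) {
    out <- as.data.frame(out)
    if (!is.null(label)) out$label <- label
  }
  out
}

# Strip a label column and coerce to a numeric matrix.
feature_matrix <- function(x) {
  if (is.data.frame(x)) {
    x <- x[, setdiff(names(x), "label"), drop = FALSE]
    x <- as.matrix(x)
  }
  if (!is.matrix(x) || !is.numeric(x)) stop("expected a numeric feature matrix")
  x
}
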