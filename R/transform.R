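#' Arcsine-square-root transform of two-channel signals
#'
#' Converts two fluorescence signal strengths (channel a and channel b of a
#' biallelic SNP assay) to the variance-stabilized response
#' y = arcsin(sqrt(s_b / (s_a + s_b))), mapping the signal ratio in \[0, 1\]
#' onto \[0, pi/2\].  Missing where either signal is missing or the total
#' signal is zero.
#'
#' @param signal_a,signal_b Nonnegative numeric vectors (recycled to common
#'   length); `NA` allowed.
#' @return Numeric vector of transformed values in \[0, pi/2\] with `NA` where
#'   undefined.
#' @examples
#' transform_ratio(1, 1)  # pi/4
#' @export
transform_ratio <- function(signal_a, signal_b) {
  n <- max(length(signal_a), length(signal_b))
  signal_a <- rep_len(signal_a, n)
  signal_b <- rep_len(signal_b, n)
  bad <- which(signal_a < 0 | signal_b < 0)
  if (length(bad)) {
    stop("negative signal value(s) at position(s) ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  tot <- signal_a + signal_b
  ratio <- ifelse(is.na(tot) | tot == 0, NA_real_, signal_b / tot)
  asin(sqrt(ratio))
}

#' Transform a ratio in \[0,1\] to the arcsine-square-root scale
#'
#' @param ratio Numeric vector in \[0, 1\]; `NA` allowed.
#' @return Numeric vector in \[0, pi/2\].
#' @export
transform_from_ratio <- function(ratio) {
  bad <- which(ratio < 0 | ratio > 1)
  if (length(bad)) {
    stop("ratio value(s) outside [0, 1] at position(s) ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  asin(sqrt(ratio))
}

#' Per-marker signal container
#'
#' Bundles the per-sample two-channel intensities and derived transformed
#' ratio for a single marker.  Either both raw signals or a precomputed
#' `ratio` must be given; `y` is always derived, never supplied.
#'
#' @param marker_id Marker name (length-1 character).
#' @param sample_ids Character vector of sample names (unique).
#' @param signal_a,signal_b Nonnegative per-sample intensities (optional if
#'   `ratio` given).
#' @param ratio Optional precomputed per-sample signal ratio s_b/(s_a+s_b).
#' @return An object of class `marker_signals`: list with `marker_id`,
#'   `sample_ids`, `signal_a`, `signal_b`, `ratio`, `y`.
#' @export
marker_signals <- function(marker_id, sample_ids, signal_a = NULL,
                           signal_b = NULL, ratio = NULL) {
  n <- length(sample_ids)
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ids for marker ", marker_id, call. = FALSE)
  }
  if (is.null(ratio)) {
    if (is.null(signal_a) || is.null(signal_b)) {
      stop("either ratio or both signals must be supplied", call. = FALSE)
    }
    if (length(signal_a) != n || length(signal_b) != n) {
      stop("signal vectors must match sample_ids in length for marker ",
           marker_id, call. = FALSE)
    }
    if (any(signal_a < 0, na.rm = TRUE) || any(signal_b < 0, na.rm = TRUE)) {
      bad <- sample_ids[which(signal_a < 0 | signal_b < 0)][1L]
      stop("negative signal for sample ", bad, " at marker ", marker_id,
           call. = FALSE)
    }
    tot <- signal_a + signal_b
    ratio <- ifelse(is.na(tot) | tot == 0, NA_real_, signal_b / tot)
  } else {
    if (length(ratio) != n) {
      stop("ratio must match sample_ids in length for marker ", marker_id,
           call. = FALSE)
    }
    if (any(ratio < 0 | ratio > 1, na.rm = TRUE)) {
      stop("ratio outside [0, 1] at marker ", marker_id, call. = FALSE)
    }
    if (is.null(signal_a)) signal_a <- rep(NA_real_, n)
    if (is.null(signal_b)) signal_b <- rep(NA_real_, n)
  }
  structure(
    list(marker_id = as.character(marker_id),
         sample_ids = as.character(sample_ids),
         signal_a = as.numeric(signal_a),
         signal_b = as.numeric(signal_b),
         ratio = as.numeric(ratio),
         y = asin(sqrt(as.numeric(ratio)))),
    class = "marker_signals")
}

#' @export
print.marker_signals <- function(x, ...) {
  cat(sprintf("marker_signals '%s': %d samples (%d with observed ratio)\n",
              x$marker_id, length(x$sample_ids), sum(!is.na(x$y))))
  invisible(x)
}
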