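#' Time-series segment
#'
#' Wraps one channel's windowed signal together with its sampling rate. Nodes
#' of every visibility graph are the samples of such a segment; node times are
#' the consecutive integer indices 1..N (unit spacing), so the sampling rate
#' is carried as metadata only and never enters the visibility or weight
#' computations.
#'
#' @param values numeric vector of amplitudes (microvolts or arbitrary
#'   units), length at least 2, all finite.
#' @param sampling_rate samples per second (metadata only).
#' @return an object of class `ts_segment`.
#' @examples
#' seg <- ts_segment(c(7, 4, 8, 6.5, 7.6, 9))
#' length(seg$values)
#' @export
ts_segment <- function(values, sampling_rate = 1) {
  values <- as.numeric(values)
  if (length(values) < 2L)
    stop("a segment needs at least 2 samples, got ", length(values))
  if (!all(is.finite(values)))
    stop("segment values must all be finite")
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      !is.finite(sampling_rate) || sampling_rate <= 0)
    stop("sampling_rate must be a single positive number")
  structure(list(values = values, sampling_rate = sampling_rate),
            class = "ts_segment")
}

#' @export
print.ts_segment <- function(x, ...) {
  cat(sprintf("<ts_segment> %d samples @ %g Hz\n",
              length(x$values), x$sampling_rate))
  invisible(x)
}

#' @export
length.ts_segment <- function(x) length(x$values)

#' The six-point demonstration series
#'
#' The short series x = \{7.0, 4.0, 8.0, 6.5, 7.6, 9.0\} used throughout the
#' documentation to illustrate visibility-graph construction and the
#' angle-based edge weights; its forward and backward weight matrices are
#' worked through cell by cell in the methods vignette.
#'
#' @return a [ts_segment] of length 6 with unit time steps.
#' @examples
#' toy_series()$values
#' @export
toy_series <- function() {
  ts_segment(c(7.0, 4.0, 8.0, 6.5, 7.6, 9.0), sampling_rate = 1)
}

as_segment <- function(x) {
  if (inherits(x, "ts_segment")) x else ts_segment(x)
}
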