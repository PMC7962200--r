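time_feature_names <- c("mean", "std", "first_diff", "second_diff",
                        "norm_first_diff", "norm_second_diff")

#' Six time-domain amplitude features
#'
#' Computes, on one segment of N samples:
#' the mean; the population standard deviation (divisor N);
#' the first difference, the mean absolute difference of consecutive
#' samples; the second difference, the mean absolute difference of samples
#' two apart; and the first and second differences of the standardized
#' series X(t) = (x(t) - mean) / std, which equal the raw differences
#' divided by the standard deviation and are therefore invariant to
#' positive affine transforms of the signal.
#'
#' A constant segment has zero standard deviation; its normalized
#' differences are reported as 0 with a warning.
#'
#' @param segment a [ts_segment] or numeric vector with at least 3 samples.
#' @return named numeric vector: `mean`, `std`, `first_diff`,
#'   `second_diff`, `norm_first_diff`, `norm_second_diff`.
#' @examples
#' time_domain_features(toy_series())
#' @export
time_domain_features <- function(segment) {
  x <- as_segment(segment)$values
  n <- length(x)
  if (n < 3L) stop("time-domain features need at least 3 samples, got ", n)
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  d1 <- mean(abs(diff(x)))
  d2 <- mean(abs(diff(x, lag = 2)))
  if (s > 0) {
    nd1 <- d1 / s
    nd2 <- d2 / s
  } else {
    warning("constant segment: normalized differences reported as 0")
    nd1 <- nd2 <- 0
  }
  c(mean = m, std = s, first_diff = d1, second_diff = d2,
    norm_first_diff = nd1, norm_second_diff = nd2)
}
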