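#' Multichannel EEG recording
#'
#' One trial's multichannel signal plus the self-reported valence and
#' arousal ratings on the 1-9 scale (either may be omitted for unlabelled
#' data).
#'
#' @param signal channels x samples numeric matrix.
#' @param sampling_rate samples per second.
#' @param channel_names optional character vector, one per channel.
#' @param trial_id identifier carried through to the design matrix.
#' @param valence,arousal ratings in [1, 9], or `NA`.
#' @return an object of class `eeg_recording`.
#' @export
eeg_recording <- function(signal, sampling_rate,
                          channel_names = NULL, trial_id = 1L,
                          valence = NA_real_, arousal = NA_real_) {
  signal <- as.matrix(signal)
  if (nrow(signal) < 1L) stop("recording needs at least one channel")
  if (!all(is.finite(signal))) stop("signal values must all be finite")
  if (is.null(channel_names))
    channel_names <- paste0("Ch", seq_len(nrow(signal)))
  if (length(channel_names) != nrow(signal))
    stop("channel_names length must equal the number of channels")
  for (r in c(valence = valence, arousal = arousal))
    if (!is.na(r) && (r < 1 || r > 9))
      stop("ratings must lie in [1, 9], got ", r)
  rownames(signal) <- channel_names
  structure(list(signal = signal, sampling_rate = sampling_rate,
                 channel_names = channel_names, trial_id = trial_id,
                 valence = valence, arousal = arousal),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> trial %s: %d channels x %d samples @ %g Hz (valence %s, arousal %s)\n",
    format(x$trial_id), nrow(x$signal), ncol(x$signal), x$sampling_rate,
    format(x$valence), format(x$arousal)))
  invisible(x)
}

#' Sliding-window segmentation
#'
#' Cuts every channel of a recording into windows of `window_seconds`
#' starting every `window_seconds * (1 - overlap_fraction)` seconds. Only
#' full windows are kept — no padding of trailing partials. A one-minute
#' signal at 128 Hz with a 10-s window and 50% overlap yields 11 segments
#' of 1280 samples per channel.
#'
#' @param recording an [eeg_recording].
#' @param window_seconds window length in seconds.
#' @param overlap_fraction fraction of a window shared with its successor,
#'   in [0, 1).
#' @param skip_seconds leading seconds to discard before windowing
#'   (default 0).
#' @return list over channels; each element a list of [ts_segment]s.
#' @export
segment_signal <- function(recording, window_seconds = 10,
                           overlap_fraction = 0.5, skip_seconds = 0) {
  stopifnot(inherits(recording, "eeg_recording"))
  if (overlap_fraction < 0 || overlap_fraction >= 1)
    stop("overlap_fraction must lie in [0, 1)")
  sr <- recording$sampling_rate
  skip <- round(skip_seconds * sr)
  spw <- round(window_seconds * sr)
  nsamp <- ncol(recording$signal) - skip
  if (spw > nsamp)
    stop("window of ", window_seconds, " s does not fit in the ",
         nsamp / sr, " s of signal after the skip")
  step <- round(spw * (1 - overlap_fraction))
  starts <- seq.int(skip + 1L, skip + nsamp - spw + 1L, by = step)
  lapply(seq_len(nrow(recording$signal)), function(ch) {
    lapply(starts, function(s)
      ts_segment(recording$signal[ch, s:(s + spw - 1L)], sr))
  })
}

#' Number of full windows in a signal
#'
#' `floor((duration - window) / (window * (1 - overlap))) + 1`.
#'
#' @inheritParams segment_signal
#' @param duration_seconds signal length in seconds (after any skip).
#' @return integer segment count.
#' @export
segment_count <- function(duration_seconds, window_seconds = 10,
                          overlap_fraction = 0.5) {
  as.integer(floor((duration_seconds - window_seconds) /
                     (window_seconds * (1 - overlap_fraction))) + 1)
}

#' Binarize a 1-9 affective rating
#'
#' Ratings below 5 are the low class; 5 and above are high. High is the
#' positive class throughout the evaluation metrics.
#'
#' @param rating numeric rating(s) in [1, 9].
#' @return factor with levels `low`, `high`.
#' @export
binarize_rating <- function(rating) {
  if (any(is.na(rating))) stop("cannot binarize a missing rating")
  factor(ifelse(rating < 5, "low", "high"), levels = c("low", "high"))
}

#' Fuse forward and backward feature vectors
#'
#' Elementwise sum of the feature vector extracted from the forward graph
#' and the one from the backward graph.
#'
#' @param forward,backward numeric vectors of equal length.
#' @return their elementwise sum.
#' @export
fuse <- function(forward, backward) {
  if (length(forward) != length(backward))
    stop("fused vectors must have equal length")
  forward + backward
}

#' Min-max normalization to [0, 1]
#'
#' `(g - min(g)) / (max(g) - min(g))`. A constant vector carries no range
#' information and maps to all zeros, with a warning.
#'
#' @param g numeric vector (nonempty).
#' @return vector of the same length with values in [0, 1].
#' @export
minmax_normalize <- function(g) {
  if (length(g) == 0L) stop("cannot normalize an empty vector")
  rng <- range(g)
  if (rng[1] == rng[2]) {
    warning("constant feature vector normalized to all zeros")
    return(rep(0, length(g)))
  }
  (g - rng[1]) / (rng[2] - rng[1])
}

#' Classifier-ready design matrix from labelled recordings
#'
#' Segments every recording, extracts per-segment features on every channel,
#' and assembles one row per (trial, segment) with columns ordered
#' channels-major, features-minor. Feature sets: `"network"` gives the four
#' weighted-network statistics per channel (4 x channels columns, 128 for a
#' 32-channel montage), `"time"` the six time-domain features (192), and
#' `"combined"` stacks network over time features (10 per channel, 320).
#' Network features are extracted from the forward and backward weighted
#' graphs and fused by [fuse()] unless a single `direction` is requested.
#'
#' Each column — one feature on one channel, across all of the subject's
#' segments — is min-max normalized to [0, 1] via [minmax_normalize()]
#' when `normalize = "per_subject"` (the recordings passed in are treated
#' as one subject); `"none"` leaves raw values.
#'
#' @param recordings list of [eeg_recording]s for one subject.
#' @param feature_set `"network"`, `"time"`, or `"combined"`.
#' @param label `"valence"` or `"arousal"`; binarized at 5.
#' @param direction `"fused"` (default), `"forward"`, or `"backward"`
#'   weighted-graph features.
#' @param base_kind visibility criterion for the weighted graphs,
#'   `"hvg"` (default) or `"vg"`.
#' @param normalize `"per_subject"` (default) or `"none"`.
#' @inheritParams segment_signal
#' @inheritParams extract_network_features
#' @return list with `x` (rows x columns numeric matrix), `y` (factor
#'   low/high), `trial` and `segment` row annotations.
#' @export
build_design_matrix <- function(recordings,
                                feature_set = c("network", "time", "combined"),
                                label = c("valence", "arousal"),
                                window_seconds = 10, overlap_fraction = 0.5,
                                skip_seconds = 0,
                                direction = c("fused", "forward", "backward"),
                                base_kind = c("hvg", "vg"),
                                shift_min = TRUE,
                                normalize = c("per_subject", "none")) {
  feature_set <- match.arg(feature_set)
  label <- match.arg(label)
  direction <- match.arg(direction)
  base_kind <- match.arg(base_kind)
  normalize <- match.arg(normalize)
  if (!length(recordings)) stop("no recordings supplied")

  seg_features <- function(seg) {
    net <- if (feature_set != "time") {
      if (direction == "fused") {
        extract_network_features(seg, fuse = TRUE, base_kind = base_kind,
                                 shift_min = shift_min)
      } else {
        extract_network_features(seg, fuse = FALSE, base_kind = base_kind,
                                 shift_min = shift_min)[[direction]]
      }
    }
    tim <- if (feature_set != "network") time_domain_features(seg)
    c(net, tim)
  }

  rows <- list(); trial <- c(); segidx <- c(); ratings <- c()
  for (rec in recordings) {
    stopifnot(inherits(rec, "eeg_recording"))
    segs <- segment_signal(rec, window_seconds, overlap_fraction,
                           skip_seconds)
    m <- length(segs[[1]])
    per_channel <- lapply(segs, function(chsegs)
      vapply(chsegs, seg_features, numeric(length(seg_features(chsegs[[1]])))))
    # per_channel[[ch]] is features x segments; flatten channels-major
    block <- do.call(rbind, lapply(seq_len(m), function(s)
      unlist(lapply(per_channel, function(fm) fm[, s]))))
    rows[[length(rows) + 1L]] <- block
    trial <- c(trial, rep(rec$trial_id, m))
    segidx <- c(segidx, seq_len(m))
    ratings <- c(ratings, rep(rec[[label]], m))
  }
  x <- do.call(rbind, rows)
  feat_names <- switch(feature_set,
                       network = network_feature_names,
                       time = time_feature_names,
                       combined = c(network_feature_names,
                                    time_feature_names))
  chn <- recordings[[1]]$channel_names
  colnames(x) <- as.vector(t(outer(chn, feat_names, paste, sep = ".")))
  if (normalize == "per_subject")
    x <- apply(x, 2, minmax_normalize)
  list(x = x, y = binarize_rating(ratings), trial = trial, segment = segidx)
}
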