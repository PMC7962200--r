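#' The 32 EEG channel names of the Geneva electrode order
#'
#' Standard 10-20 montage labels in the order used by the preprocessed
#' 32-channel emotion-database layout that [read_deap_preprocessed()] reads.
#'
#' @export
deap_channel_names <- c(
  "Fp1", "AF3", "F3", "F7", "FC5", "FC1", "C3", "T7", "CP5", "CP1", "P3",
  "P7", "PO3", "O1", "Oz", "Pz", "Fp2", "AF4", "Fz", "F4", "F8", "FC6",
  "FC2", "Cz", "C4", "T8", "CP6", "CP2", "P4", "P8", "PO4", "O2")

#' Configuration of the surrogate EEG generator
#'
#' Describes a cohort of labelled two-class multichannel recordings. Each
#' channel is band-limited (4-45 Hz) coloured noise whose spectral exponent
#' and amplitude-modulation depth depend on the class, so the two classes
#' differ in waveform roughness — the property visibility-graph degree
#' statistics respond to — rather than in mean level, which segment
#' min-shifting would erase anyway. The defaults emulate the study
#' conditions: 40 one-minute trials (20 per class) of 32 channels at
#' 128 Hz, with a clearly separable roughness contrast.
#'
#' @param n_subjects number of subjects.
#' @param n_trials_per_class trials per class per subject.
#' @param n_channels channels per recording.
#' @param duration_s trial length in seconds.
#' @param sampling_rate samples per second.
#' @param spectral_slope named vector `c(low = , high = )`: 1/f^alpha
#'   exponent per class (larger = smoother signal).
#' @param am_depth named vector `c(low = , high = )`: depth of a slow
#'   (0.1-0.5 Hz) amplitude modulation per class, in [0, 1).
#' @param noise_sd white measurement noise, as a fraction of the signal's
#'   standard deviation.
#' @param seed integer seed fixing the full stream.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_subjects = 1, n_trials_per_class = 20,
                             n_channels = 32, duration_s = 60,
                             sampling_rate = 128,
                             spectral_slope = c(low = 0.5, high = 1.5),
                             am_depth = c(low = 0.0, high = 0.4),
                             noise_sd = 0.1, seed = 1L) {
  stopifnot(n_subjects >= 1, n_trials_per_class >= 1, n_channels >= 1,
            duration_s > 0, sampling_rate > 0, noise_sd >= 0,
            all(c("low", "high") %in% names(spectral_slope)),
            all(c("low", "high") %in% names(am_depth)),
            all(am_depth >= 0 & am_depth < 1))
  structure(list(n_subjects = n_subjects,
                 n_trials_per_class = n_trials_per_class,
                 n_channels = n_channels, duration_s = duration_s,
                 sampling_rate = sampling_rate,
                 spectral_slope = spectral_slope, am_depth = am_depth,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synthetic_config")
}

# Band-limited 1/f^alpha noise by frequency-domain synthesis: amplitudes
# f^(-alpha/2) inside [f_lo, f_hi], random phases, inverse FFT; unit sd.
colored_band_noise <- function(n, sr, alpha, f_lo = 4, f_hi = 45) {
  nyq <- n %/% 2
  f <- (1:nyq) * sr / n
  amp <- ifelse(f >= f_lo & f <= min(f_hi, sr / 2), f^(-alpha / 2), 0)
  phases <- stats::runif(nyq, 0, 2 * pi)
  spec <- complex(modulus = amp, argument = phases)
  full <- complex(real = numeric(n))
  full[2:(nyq + 1)] <- spec
  if (n %% 2 == 0) {
    full[nyq + 1] <- complex(real = amp[nyq])  # Nyquist bin must be real
    if (nyq >= 2) full[n:(n - nyq + 2)] <- Conj(full[2:nyq])
  } else {
    full[n:(n - nyq + 1)] <- Conj(full[2:(nyq + 1)])
  }
  x <- Re(stats::fft(full, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s > 0) x / s else x
}

#' Generate labelled surrogate EEG recordings
#'
#' Draws `n_trials_per_class` recordings per class per subject under the
#' class-conditional signal model of [synthetic_config()]. Trials are
#' interleaved low/high, ratings are drawn uniformly from [1, 4.9] (low)
#' or [5.1, 9] (high) and attached to both valence and arousal, and the
#' whole stream is fixed by `config$seed` — the same configuration always
#' yields the identical cohort.
#'
#' @param config a [synthetic_config()].
#' @return flat list of [eeg_recording]s (subjects concatenated), each with
#'   a `sNN_tNN` trial id.
#' @export
generate_recordings <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- round(config$duration_s * config$sampling_rate)
  chn <- if (config$n_channels <= 32)
    deap_channel_names[seq_len(config$n_channels)]
  else paste0("Ch", seq_len(config$n_channels))
  tt <- seq_len(n) / config$sampling_rate
  out <- list()
  for (s in seq_len(config$n_subjects)) {
    classes <- rep(c("low", "high"), config$n_trials_per_class)
    for (tr in seq_along(classes)) {
      cl <- classes[tr]
      sig <- matrix(0, config$n_channels, n)
      for (ch in seq_len(config$n_channels)) {
        x <- colored_band_noise(n, config$sampling_rate,
                                config$spectral_slope[[cl]])
        fm <- stats::runif(1, 0.1, 0.5)
        env <- 1 + config$am_depth[[cl]] *
          sin(2 * pi * fm * tt + stats::runif(1, 0, 2 * pi))
        x <- x * env
        sig[ch, ] <- 10 * x + 10 * config$noise_sd * stats::rnorm(n)
      }
      rating <- if (cl == "low") stats::runif(1, 1, 4.9)
                else stats::runif(1, 5.1, 9)
      out[[length(out) + 1L]] <- eeg_recording(
        sig, config$sampling_rate, channel_names = chn,
        trial_id = sprintf("s%02d_t%02d", s, tr),
        valence = rating, arousal = rating)
    }
  }
  out
}

#' Read a preprocessed 40-trial recording file
#'
#' Reads one subject of the preprocessed emotion-database layout: a
#' serialized R list with a `data` array of 40 trials x 40 channels x
#' (63 s x sampling rate) samples and a `labels` matrix of 40 x 4 ratings
#' (valence, arousal, dominance, liking). The first 32 channels are kept
#' as EEG, the leading 3-s pre-trial baseline is dropped so 60 s remain,
#' and the valence/arousal ratings are attached. Files are written with
#' [write_deap_fixture()]; the database's own MATLAB/pickle containers can
#' be converted to this layout with any array tool.
#'
#' @param path path to an `.rds` file with elements `data` and `labels`.
#' @param sampling_rate samples per second of the stored data (128).
#' @param baseline_s leading baseline seconds to drop (3).
#' @return list of 40 [eeg_recording]s of 32 channels.
#' @export
read_deap_preprocessed <- function(path, sampling_rate = 128,
                                   baseline_s = 3) {
  obj <- readRDS(path)
  if (!is.list(obj) || is.null(obj$data) || is.null(obj$labels))
    stop("file must hold a list with elements 'data' and 'labels'")
  d <- obj$data
  if (length(dim(d)) != 3L)
    stop("'data' must be a 3-d array (trials x channels x samples), got ",
         paste(dim(d), collapse = " x "))
  lb <- as.matrix(obj$labels)
  if (nrow(lb) != dim(d)[1] || ncol(lb) < 2L)
    stop("'labels' must be ", dim(d)[1], " x 4 (valence, arousal, ",
         "dominance, liking), got ", paste(dim(lb), collapse = " x "))
  n_eeg <- min(32L, dim(d)[2])
  drop <- round(baseline_s * sampling_rate)
  if (dim(d)[3] <= drop)
    stop("'data' has only ", dim(d)[3], " samples, fewer than the ",
         drop, "-sample baseline")
  keep <- (drop + 1L):dim(d)[3]
  lapply(seq_len(dim(d)[1]), function(tr)
    eeg_recording(d[tr, seq_len(n_eeg), keep, drop = TRUE],
                  sampling_rate,
                  channel_names = deap_channel_names[seq_len(n_eeg)],
                  trial_id = tr,
                  valence = lb[tr, 1], arousal = lb[tr, 2]))
}

#' @rdname read_deap_preprocessed
#' @param data 40 x 40 x samples array.
#' @param labels 40 x 4 ratings matrix.
#' @export
write_deap_fixture <- function(data, labels, path) {
  saveRDS(list(data = data, labels = labels), path)
  invisible(path)
}
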