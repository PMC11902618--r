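#' Augmentation specification
#'
#' Parameters for the three acoustic augmentations applied to both speech and
#' eating-sound clips: speed modulation, time-domain dropout (zeroed
#' intervals) and frequency-domain dropout (masked bands). All augmentations
#' are deterministic given `(input, rng_seed)`.
#'
#' @param speed_factors positive speed factors (default `c(0.9, 1.0, 1.1)`)
#' @param time_dropout_max_s maximum total zeroed duration in seconds
#' @param freq_dropout_bands number of masked frequency bands (each up to
#'   1 kHz wide, drawn uniformly)
#' @param rng_seed integer seed
#' @return an `augment_spec` object
#' @export
augment_spec <- function(speed_factors = c(0.9, 1.0, 1.1),
                         time_dropout_max_s = 0.2,
                         freq_dropout_bands = 1L,
                         rng_seed = 1L) {
  stopifnot(all(speed_factors > 0), time_dropout_max_s >= 0,
            freq_dropout_bands >= 0)
  structure(list(speed_factors = speed_factors,
                 time_dropout_max_s = time_dropout_max_s,
                 freq_dropout_bands = as.integer(freq_dropout_bands),
                 rng_seed = as.integer(rng_seed)),
            class = "augment_spec")
}

#' Speed perturbation
#'
#' Alters playback speed by the sampling-rate trick: the waveform is resampled
#' onto a time axis scaled by `1/factor` while the nominal rate is kept, so
#' duration becomes `duration/factor` and all frequencies scale by `factor`.
#' Strong-label times in a perturbed clip scale by `1/factor` (see
#' `scale_track`).
#'
#' @param clip an [audio_clip]
#' @param factor positive speed factor (>1 = faster/shorter)
#' @return the perturbed [audio_clip] at the original nominal rate
#' @export
speed_perturb <- function(clip, factor) {
  stopifnot(inherits(clip, "audio_clip"))
  if (!is.numeric(factor) || factor <= 0)
    stop_mealvoice("speed factor must be positive", "mealvoice_param_error")
  if (factor == 1) return(clip)
  n <- n_samples(clip)
  n_out <- max(1L, as.integer(round(n / factor)))
  xs <- seq(1, n, length.out = n_out)
  out <- t(apply(clip$samples, 1L, function(x)
    stats::approx(seq_len(n), x, xout = xs)$y))
  if (n_channels(clip) == 1L) out <- matrix(out, nrow = 1L)
  audio_clip(out, clip$sample_rate, clip$source_id)
}

#' Time-domain dropout
#'
#' Replaces one random time interval (length uniform in
#' `[0, time_dropout_max_s]`) with zeros; all other samples are untouched and
#' the clip length is preserved.
#'
#' @param clip an [audio_clip]
#' @param spec an [augment_spec]
#' @return the augmented [audio_clip]
#' @export
time_dropout <- function(clip, spec) {
  stopifnot(inherits(clip, "audio_clip"), inherits(spec, "augment_spec"))
  max_n <- floor(spec$time_dropout_max_s * clip$sample_rate)
  if (max_n <= 0) return(clip)
  if (max_n >= n_samples(clip))
    stop_mealvoice("time dropout longer than the clip", "mealvoice_param_error")
  with_seed(spec$rng_seed, {
    len <- sample.int(max_n + 1L, 1L) - 1L  # uniform in {0, ..., max_n}
    out <- clip$samples
    if (len > 0L) {
      start <- sample.int(n_samples(clip) - len + 1L, 1L)
      out[, start:(start + len - 1L)] <- 0
    }
    audio_clip(out, clip$sample_rate, clip$source_id)
  })
}

#' Frequency-domain dropout
#'
#' Masks `freq_dropout_bands` random frequency bands (width uniform up to
#' 1 kHz, capped at a quarter of the bandwidth) by zeroing the corresponding
#' DFT bins; out-of-band content is preserved exactly and length is unchanged.
#'
#' @inheritParams time_dropout
#' @return the augmented [audio_clip]
#' @export
freq_dropout <- function(clip, spec) {
  stopifnot(inherits(clip, "audio_clip"), inherits(spec, "augment_spec"))
  if (spec$freq_dropout_bands == 0L) return(clip)
  nyq <- clip$sample_rate / 2
  bands <- with_seed(spec$rng_seed, {
    w <- stats::runif(spec$freq_dropout_bands, 0, min(1000, nyq / 4))
    lo <- stats::runif(spec$freq_dropout_bands, 0, nyq - w)
    cbind(lo, lo + w)
  })
  drop_freq_bands(clip, bands)
}

## Zero the DFT bins inside each [lo, hi) band (both spectrum halves).
drop_freq_bands <- function(clip, bands) {
  n <- n_samples(clip)
  freqs <- (seq_len(n) - 1L) / n * clip$sample_rate
  folded <- pmin(freqs, clip$sample_rate - freqs)  # mirror frequencies
  mask <- rep(FALSE, n)
  for (i in seq_len(nrow(bands)))
    mask <- mask | (folded >= bands[i, 1] & folded < bands[i, 2])
  out <- t(apply(clip$samples, 1L, function(x) {
    X <- stats::fft(x)
    X[mask] <- 0
    Re(stats::fft(X, inverse = TRUE)) / n
  }))
  if (n_channels(clip) == 1L) out <- matrix(out, nrow = 1L)
  audio_clip(out, clip$sample_rate, clip$source_id)
}

#' Label-initiated segmentation (LISA)
#'
#' Expands a long eating recording into one training segment per label entry:
#' segment *i* starts at entry *i*'s onset and extends up to `max_dur_s` (or
#' to the end of the clip). Each segment keeps exactly the labels lying fully
#' inside its window, re-based to segment-local time.
#'
#' @param clip an [audio_clip]
#' @param track a nonempty [strong_track] whose entries lie within the clip
#' @param max_dur_s maximum segment duration in seconds (default 10)
#' @return a list of `list(clip =, track =)` pairs, one per label entry
#' @export
lisa_split <- function(clip, track, max_dur_s = 10) {
  stopifnot(inherits(clip, "audio_clip"), inherits(track, "strong_track"))
  if (!nrow(track))
    stop_mealvoice("lisa_split needs a nonempty track", "mealvoice_param_error")
  if (any(track$end_s > clip_duration(clip) + 1e-9))
    stop_mealvoice("track entries extend past the clip", "mealvoice_value_error")
  rate <- clip$sample_rate
  lapply(seq_len(nrow(track)), function(i) {
    t0 <- track$start_s[i]
    t1 <- min(t0 + max_dur_s, clip_duration(clip))
    i0 <- floor(t0 * rate) + 1L
    i1 <- min(floor(t1 * rate), n_samples(clip))
    seg <- audio_clip(clip$samples[, i0:i1, drop = FALSE], rate,
                      sprintf("%s/lisa%03d", clip$source_id, i))
    t0s <- (i0 - 1L) / rate
    t1s <- i1 / rate
    keep <- track$start_s >= t0s - 1e-9 & track$end_s <= t1s + 1e-9
    sub <- track[keep, , drop = FALSE]
    list(clip = seg,
         track = strong_track(sub$start_s - t0s, sub$end_s - t0s, sub$symbol,
                              clip_id = seg$source_id))
  })
}
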