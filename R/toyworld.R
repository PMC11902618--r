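#' Toy-audio world specification
#'
#' Parameters of the synthetic stand-in for the two study corpora: speech
#' clips are variable-length sequences of fixed-vocabulary tone bursts with
#' exact transcripts (emulating a read-speech corpus), and eating clips
#' contain quasi-periodic broadband chew clicks and longer low-band swallow
#' bursts with strong labels (emulating contact-microphone meal recordings).
#' All carriers sit above 200 Hz so clips survive the 100 Hz high-pass.
#'
#' @param sample_rate working rate in Hz (default 16000; 4000 supported for
#'   fast runs)
#' @param vocab speech token symbols (default 8 letters)
#' @param tone_map named numeric vector token -> carrier Hz; autogenerated
#'   between 300 Hz and 0.85 x Nyquist when `NULL`
#' @param tone_ms speech tone-burst length in ms (default 120)
#' @param tokens_per_s average speech token rate (default 4)
#' @param tone_jitter per-token fractional carrier jitter (default 0.08),
#'   emulating speaker variability; adjacent carriers overlap under jitter,
#'   giving the toy speech task an irreducible confusion floor
#' @param chew_rate_hz chew rate within a chew train (default 1.5)
#' @param chew_click_ms chew click length (default 30)
#' @param swallow_burst_ms swallow burst length (default 400)
#' @param snr_db tone/click level above the noise floor (default 30;
#'   `Inf` = noise-free)
#' @param n_speech,n_eating pool sizes (defaults 40 and 24)
#' @param seed master seed
#' @return a `toy_spec`
#' @export
toy_spec <- function(sample_rate = 16000L, vocab = letters[1:8],
                     tone_map = NULL, tone_ms = 120, tokens_per_s = 4,
                     tone_jitter = 0.08, chew_rate_hz = 1.5,
                     chew_click_ms = 30, swallow_burst_ms = 400,
                     snr_db = 30, n_speech = 40L, n_eating = 24L,
                     seed = 1L) {
  sample_rate <- as.integer(sample_rate)
  if (is.null(tone_map)) {
    tone_map <- stats::setNames(
      seq(300, 0.85 * sample_rate / 2, length.out = length(vocab)), vocab)
  }
  stopifnot(length(tone_map) == length(vocab),
            all(tone_map > 200), all(tone_map < sample_rate / 2),
            !anyDuplicated(tone_map),
            tone_ms > 0, tokens_per_s > 0, tone_ms / 1000 <= 1 / tokens_per_s,
            tone_jitter >= 0, tone_jitter < 0.5,
            chew_rate_hz > 0, chew_click_ms > 0, swallow_burst_ms > 0)
  structure(list(sample_rate = sample_rate, vocab = vocab,
                 tone_map = tone_map, tone_ms = tone_ms,
                 tokens_per_s = tokens_per_s, tone_jitter = tone_jitter,
                 chew_rate_hz = chew_rate_hz,
                 chew_click_ms = chew_click_ms,
                 swallow_burst_ms = swallow_burst_ms, snr_db = snr_db,
                 n_speech = as.integer(n_speech),
                 n_eating = as.integer(n_eating), seed = as.integer(seed)),
            class = "toy_spec")
}

toy_noise_floor <- function(spec, n) {
  if (!is.finite(spec$snr_db)) return(numeric(n))
  stats::rnorm(n, sd = 0.5 * 10^(-spec$snr_db / 20))
}

## Raised-cosine amplitude envelope for a burst of n samples.
burst_env <- function(n) 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / max(1, n - 1))

#' Generate one toy speech clip
#'
#' Each transcript token is rendered as a `tone_ms` tone burst at its mapped
#' carrier, separated by jittered silences; the weak label sequence is the
#' transcript itself. Deterministic given `(spec, transcript, dur_s, seed)`.
#'
#' @param spec a [toy_spec]
#' @param transcript character vector of tokens from `spec$vocab`
#' @param dur_s clip duration in seconds (< 10)
#' @param seed integer seed
#' @param id clip identifier
#' @return list with `clip` (an [audio_clip]) and `weak` (a [weak_seq])
#' @export
gen_speech_clip <- function(spec, transcript, dur_s, seed = 1L,
                            id = "toy-speech") {
  stopifnot(inherits(spec, "toy_spec"), dur_s > 0, dur_s < 10)
  bad <- setdiff(transcript, spec$vocab)
  if (length(bad))
    stop_mealvoice(sprintf("transcript token(s) outside the toy vocabulary: %s",
                           paste(bad, collapse = " ")),
                   "mealvoice_value_error")
  rate <- spec$sample_rate
  n <- as.integer(round(dur_s * rate))
  tone_n <- as.integer(round(spec$tone_ms / 1000 * rate))
  k <- length(transcript)
  if (k * tone_n > n)
    stop_mealvoice("transcript does not fit in the requested duration",
                   "mealvoice_param_error")
  with_seed(seed, {
    x <- toy_noise_floor(spec, n)
    if (k) {
      slack <- n - k * tone_n
      w <- stats::runif(k + 1L, 0.5, 1.5)
      gaps <- floor(slack * w / sum(w))
      gaps[k + 1L] <- slack - sum(gaps[seq_len(k)])
      pos <- 0L
      for (i in seq_len(k)) {
        pos <- pos + gaps[i]
        f <- spec$tone_map[[transcript[i]]] *
          (1 + stats::runif(1, -spec$tone_jitter, spec$tone_jitter))
        tt <- (seq_len(tone_n) - 1L) / rate
        x[(pos + 1L):(pos + tone_n)] <- x[(pos + 1L):(pos + tone_n)] +
          0.5 * burst_env(tone_n) * sin(2 * pi * f * tt)
        pos <- pos + tone_n
      }
    }
    list(clip = audio_clip(peak_normalize(x), rate, id),
         weak = weak_seq(transcript, id))
  })
}

#' Generate one toy eating clip
#'
#' Chew clicks (short broadband noise bursts) are laid out quasi-periodically
#' at `chew_rate_hz` with +-15% onset jitter; each requested swallow is a
#' longer low-band burst placed after the chew train. The strong track marks
#' every event with its true onset/offset.
#'
#' @param spec a [toy_spec]
#' @param n_chews,n_swallows event counts
#' @param dur_s clip duration in seconds
#' @param seed integer seed
#' @param id clip identifier
#' @return list with `clip` (an [audio_clip]) and `strong` (a [strong_track])
#' @export
gen_eating_clip <- function(spec, n_chews, n_swallows, dur_s, seed = 1L,
                            id = "toy-eating") {
  stopifnot(inherits(spec, "toy_spec"), dur_s > 0)
  rate <- spec$sample_rate
  n <- as.integer(round(dur_s * rate))
  click_n <- as.integer(round(spec$chew_click_ms / 1000 * rate))
  burst_n <- as.integer(round(spec$swallow_burst_ms / 1000 * rate))
  period <- 1 / spec$chew_rate_hz
  need <- n_chews * period + n_swallows * (spec$swallow_burst_ms / 1000 + 0.3)
  if (need > dur_s)
    stop_mealvoice("events do not fit in the requested duration at this chew rate",
                   "mealvoice_param_error")
  ## chews are laid out in n_swallows runs (or one run when no swallow),
  ## each run closed by a swallow burst — the meal's chew-then-swallow cycle
  run_sizes <- if (n_swallows > 0)
    diff(round(seq(0, n_chews, length.out = n_swallows + 1L)))
  else n_chews
  with_seed(seed, {
    x <- toy_noise_floor(spec, n)
    onsets <- numeric(0); offsets <- numeric(0); syms <- character(0)
    t_cursor <- stats::runif(1, 0.05, 0.2)
    nyq <- rate / 2
    bf_hi <- signal::butter(4, min(0.95, 600 / nyq), type = "high")
    bf_lo <- signal::butter(4, min(0.95, 450 / nyq), type = "low")
    place_chew <- function(t0) {
      i0 <- as.integer(round(t0 * rate)) + 1L
      i1 <- min(i0 + click_n - 1L, n)
      seg_n <- i1 - i0 + 1L
      ## crunch click: high-band noise burst with a sharp envelope
      click <- signal::filtfilt(bf_hi, stats::rnorm(seg_n + 40L))[21:(seg_n + 20L)]
      x[i0:i1] <<- x[i0:i1] + 0.9 * burst_env(seg_n) * click
      onsets <<- c(onsets, (i0 - 1L) / rate)
      offsets <<- c(offsets, i1 / rate)
      syms <<- c(syms, CHEW_SYMBOL)
    }
    place_swallow <- function(t0) {
      i0 <- as.integer(round(t0 * rate)) + 1L
      i1 <- min(i0 + burst_n - 1L, n)
      seg_n <- i1 - i0 + 1L
      ## gulp: low-band noise transient decaying fast; the annotated interval
      ## covers the full deglutition act, most of which is near-silent
      tt <- (seq_len(seg_n) - 1L) / rate
      gulp <- signal::filtfilt(bf_lo, stats::rnorm(seg_n + 40L))[21:(seg_n + 20L)]
      x[i0:i1] <<- x[i0:i1] + 0.9 * exp(-tt / 0.04) * gulp
      onsets <<- c(onsets, (i0 - 1L) / rate)
      offsets <<- c(offsets, i1 / rate)
      syms <<- c(syms, SWALLOW_SYMBOL)
    }
    for (r in seq_along(run_sizes)) {
      if (run_sizes[r] > 0) for (i in seq_len(run_sizes[r])) {
        jit <- stats::runif(1, -0.15, 0.15) * period
        t0 <- t_cursor + if (i > 1L) jit else 0
        place_chew(t0)
        t_cursor <- t0 + period
      }
      if (n_swallows > 0) {
        t0 <- t_cursor + stats::runif(1, 0.1, 0.25)
        place_swallow(t0)
        t_cursor <- t0 + spec$swallow_burst_ms / 1000 + 0.05
      }
    }
    list(clip = audio_clip(peak_normalize(x), rate, id),
         strong = strong_track(onsets, offsets, syms, clip_id = id))
  })
}

#' Generate the full toy dataset
#'
#' Builds disjoint speech and eating pools plus a held-out test split whose
#' clips come from a disjoint seed group (emulating held-out test subjects).
#' Durations are stratified so both synthesis branches are exercised: part of
#' each pool falls in \[7, 10) s (the pad path) and part below 7 s (the
#' concatenation path).
#'
#' @param spec a [toy_spec]
#' @param n_test_speech,n_test_eating held-out clip counts (defaults 10 and 8)
#' @return list with `speech` and `eating` pools (lists of [source_item]s)
#'   and `test = list(speech =, eating =)` example lists
#' @export
gen_toy_dataset <- function(spec, n_test_speech = 10L, n_test_eating = 8L) {
  stopifnot(inherits(spec, "toy_spec"), spec$n_speech >= 4L,
            spec$n_eating >= 4L)
  seeds <- derive_seeds(spec$seed, 4L)
  make_speech <- function(n, seed_base, tag) {
    ss <- derive_seeds(seed_base, 2L * n)
    lapply(seq_len(n), function(i) {
      long <- i %% 3L == 0L  # every third clip takes the pad path
      dur <- with_seed(ss[2L * i - 1L],
                       if (long) stats::runif(1, 7.2, 9.5)
                       else stats::runif(1, 1.5, 5.5))
      k <- max(1L, as.integer(floor(dur * spec$tokens_per_s)))
      tr <- with_seed(ss[2L * i - 1L] + 1L,
                      sample(spec$vocab, k, replace = TRUE))
      g <- gen_speech_clip(spec, tr, dur, seed = ss[2L * i],
                           id = sprintf("%s-speech-%03d", tag, i))
      source_item(g$clip, g$weak, "speech")
    })
  }
  make_eating <- function(n, seed_base, tag) {
    ss <- derive_seeds(seed_base, 2L * n)
    lapply(seq_len(n), function(i) {
      long <- i %% 3L == 0L
      dur <- with_seed(ss[2L * i - 1L],
                       if (long) stats::runif(1, 7.2, 9.5)
                       else stats::runif(1, 2.5, 6.5))
      ## each clip alternates chew runs and swallows (the meal cycle);
      ## roughly one swallow every 3 s of material
      period <- 1 / spec$chew_rate_hz
      n_swal <- max(1L, as.integer(round(dur / 3)))
      budget <- dur - n_swal * (spec$swallow_burst_ms / 1000 + 0.55) - 0.35
      n_chews <- max(1L, as.integer(floor(budget / period)))
      g <- gen_eating_clip(spec, n_chews, n_swal, dur,
                           seed = ss[2L * i],
                           id = sprintf("%s-eating-%03d", tag, i))
      source_item(g$clip, weak_from_strong(g$strong), "eating",
                  strong = g$strong)
    })
  }
  list(
    speech = make_speech(spec$n_speech, seeds[1], "train"),
    eating = make_eating(spec$n_eating, seeds[2], "train"),
    test = list(
      speech = lapply(make_speech(n_test_speech, seeds[3], "test"),
                      function(it) list(clip = it$clip, weak = it$weak)),
      eating = lapply(make_eating(n_test_eating, seeds[4], "test"),
                      function(it) list(clip = it$clip, weak = it$weak,
                                        strong = it$strong))
    )
  )
}

#' Hand-coded reference event detector for toy audio
#'
#' A detector built directly from the toy generator's signal model: per-frame
#' band energies separate broadband chew clicks (flat, short) from low-band
#' swallow bursts (narrowband, long). On noise-free toy clips it recovers the
#' labels essentially perfectly, establishing that the toy task is learnable
#' and the strong labels are correct.
#'
#' @param clip a mono toy eating [audio_clip]
#' @param spec the [toy_spec] used to generate it
#' @return data.frame of detected events (`class`, `onset_s`, `offset_s`)
#' @export
reference_event_detector <- function(clip, spec) {
  stopifnot(inherits(clip, "audio_clip"), inherits(spec, "toy_spec"))
  rate <- clip$sample_rate
  hop <- as.integer(round(0.01 * rate))
  x <- clip$samples[1L, ]
  T_ <- length(x) %/% hop
  X <- matrix(x[seq_len(T_ * hop)], hop, T_)
  sp <- Mod(stats::mvfft(X))^2
  freqs <- seq(0, rate / 2, length.out = hop %/% 2L + 1L)
  half <- sp[seq_len(hop %/% 2L + 1L), , drop = FALSE]
  low <- colSums(half[freqs >= 150 & freqs <= 400, , drop = FALSE])
  high <- colSums(half[freqs > 500, , drop = FALSE])
  thr <- 0.05 * max(low + high)
  runs <- function(active) {
    r <- rle(active)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    cbind(starts[r$values], ends[r$values])
  }
  out <- data.frame(class = character(), onset_s = numeric(),
                    offset_s = numeric(), stringsAsFactors = FALSE)
  act <- (low + high) > thr
  seg <- runs(act)
  for (i in seq_len(nrow(seg))) {
    idx <- seg[i, 1]:seg[i, 2]
    ## chew clicks are broadband (high band dominates); the swallow gulp is
    ## low-band dominant
    is_swallow <- sum(low[idx]) > sum(high[idx])
    out <- rbind(out, data.frame(
      class = if (is_swallow) SWALLOW_SYMBOL else CHEW_SYMBOL,
      onset_s = (seg[i, 1] - 1L) * hop / rate,
      offset_s = seg[i, 2] * hop / rate, stringsAsFactors = FALSE))
  }
  out
}
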