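#' Source item for corpus synthesis
#'
#' One preprocessed mono clip with its labels, tagged by acoustic domain.
#' Speech items carry their transcript as a weak sequence only; eating items
#' additionally carry a strong (timed) track. Items longer than 10 s are
#' excluded upstream.
#'
#' @param clip a mono [audio_clip] at the working rate
#' @param weak a [weak_seq] (transcript or event order)
#' @param domain `"speech"` or `"eating"`
#' @param strong optional [strong_track] (eating items)
#' @param id source identifier; defaults to the clip's
#' @return a `source_item`
#' @export
source_item <- function(clip, weak, domain, strong = NULL, id = clip$source_id) {
  stopifnot(inherits(clip, "audio_clip"), inherits(weak, "weak_seq"),
            domain %in% c("speech", "eating"))
  if (n_channels(clip) != 1L)
    stop_mealvoice("source items must be mono", "mealvoice_param_error")
  if (!is.null(strong)) stopifnot(inherits(strong, "strong_track"))
  structure(list(clip = clip, weak = weak, strong = strong, domain = domain,
                 id = as.character(id), duration_s = clip_duration(clip)),
            class = "source_item")
}

clip_rms <- function(clip) sqrt(mean(clip$samples^2))

## Gaussian white padding noise, `noise_snr_db` below a reference RMS.
noise_sd <- function(ref_rms, noise_snr_db) ref_rms * 10^(-noise_snr_db / 20)

make_synthetic_example <- function(samples, rate, weak, strong, segments, seed,
                                   id) {
  structure(list(
    clip = audio_clip(samples, rate, id),
    weak = weak, strong = strong,
    segments = segments, rng_seed = as.integer(seed)
  ), class = "synthetic_example")
}

#' @export
print.synthetic_example <- function(x, ...) {
  cat(sprintf("<synthetic_example '%s': %.1f s, %d segment(s), weak [%s]>\n",
              x$clip$source_id, clip_duration(x$clip), nrow(x$segments),
              paste(x$weak$tokens, collapse = " ")))
  invisible(x)
}

#' Pad a source item to a fixed duration with white noise
#'
#' Used for clips between 7 and 10 s: white noise is appended to both ends
#' (random left/right split, seeded) so the output lasts exactly
#' `target_dur_s`. The source samples are embedded contiguously and bit-exact;
#' weak labels are unchanged and strong labels shift by the placement offset.
#'
#' @param item a [source_item] no longer than `target_dur_s`
#' @param target_dur_s output duration in seconds (default 10)
#' @param noise_snr_db padding-noise level in dB below `ref_rms` (default 30)
#' @param seed integer seed for the left/right split and the noise
#' @param ref_rms reference RMS for the noise level; defaults to the item's own
#' @return a `synthetic_example`
#' @export
pad_to_fixed <- function(item, target_dur_s = 10, noise_snr_db = 30, seed = 1L,
                         ref_rms = clip_rms(item$clip)) {
  stopifnot(inherits(item, "source_item"))
  rate <- item$clip$sample_rate
  n_target <- as.integer(round(target_dur_s * rate))
  n_item <- n_samples(item$clip)
  if (n_item > n_target)
    stop_mealvoice("item longer than the synthesis target duration",
                   "mealvoice_param_error")
  with_seed(seed, {
    n_pad <- n_target - n_item
    n_left <- if (n_pad > 0L) sample.int(n_pad + 1L, 1L) - 1L else 0L
    sd <- noise_sd(ref_rms, noise_snr_db)
    out <- stats::rnorm(n_target, sd = sd)
    if (n_pad == 0L) out <- numeric(n_target)
    out[(n_left + 1L):(n_left + n_item)] <- item$clip$samples[1L, ]
    offset_s <- n_left / rate
    strong <- if (!is.null(item$strong)) shift_track(item$strong, offset_s)
              else strong_track(clip_id = item$id)
    make_synthetic_example(
      out, rate, weak_seq(item$weak$tokens, item$id), strong,
      data.frame(source_id = item$id, domain = item$domain,
                 placed_offset_s = offset_s, source_dur_s = item$duration_s,
                 stringsAsFactors = FALSE),
      seed, sprintf("synth-pad-%s", item$id))
  })
}

#' Assemble several source items into one fixed-length mixture
#'
#' Items are placed in the given order with white-noise gaps before, between
#' and after them (random seeded gap split, integer samples) so the output is
#' exactly `target_dur_s`. The weak sequence is the concatenation of the item
#' sequences, with a space token between two adjacent speech items; the strong
#' track is the union of the shifted eating-event tracks.
#'
#' @param items ordered nonempty list of [source_item]s whose durations sum to
#'   at most `target_dur_s`
#' @inheritParams pad_to_fixed
#' @param ref_rms reference RMS for the noise level; defaults to the items'
#'   median
#' @return a `synthetic_example`
#' @export
assemble_mixture <- function(items, target_dur_s = 10, noise_snr_db = 30,
                             seed = 1L,
                             ref_rms = stats::median(vapply(items, function(i)
                               clip_rms(i$clip), 0))) {
  if (!length(items))
    stop_mealvoice("assemble_mixture needs at least one item",
                   "mealvoice_param_error")
  stopifnot(all(vapply(items, inherits, TRUE, "source_item")))
  rate <- items[[1]]$clip$sample_rate
  stopifnot(all(vapply(items, function(i) i$clip$sample_rate, 0L) == rate))
  n_target <- as.integer(round(target_dur_s * rate))
  n_items <- vapply(items, function(i) n_samples(i$clip), 0L)
  n_slack <- n_target - sum(n_items)
  if (n_slack < 0L)
    stop_mealvoice("item durations exceed the synthesis target",
                   "mealvoice_param_error")
  k <- length(items)
  with_seed(seed, {
    ## split the slack over k+1 gaps in whole samples
    w <- stats::runif(k + 1L)
    gaps <- floor(n_slack * w / sum(w))
    rem <- n_slack - sum(gaps)
    if (rem > 0L) gaps[seq_len(rem)] <- gaps[seq_len(rem)] + 1L
    sd <- noise_sd(ref_rms, noise_snr_db)
    out <- stats::rnorm(n_target, sd = sd)
    pos <- 0L
    offs <- numeric(k)
    for (i in seq_len(k)) {
      pos <- pos + gaps[i]
      out[(pos + 1L):(pos + n_items[i])] <- items[[i]]$clip$samples[1L, ]
      offs[i] <- pos / rate
      pos <- pos + n_items[i]
    }
    tokens <- character()
    for (i in seq_len(k)) {
      if (i > 1L && items[[i - 1L]]$domain == "speech" &&
          items[[i]]$domain == "speech")
        tokens <- c(tokens, SPACE_SYMBOL)
      tokens <- c(tokens, items[[i]]$weak$tokens)
    }
    st <- list(start = numeric(), end = numeric(), sym = character())
    for (i in seq_len(k)) {
      if (!is.null(items[[i]]$strong) && nrow(items[[i]]$strong)) {
        sh <- shift_track(items[[i]]$strong, offs[i])
        st$start <- c(st$start, sh$start_s)
        st$end <- c(st$end, sh$end_s)
        st$sym <- c(st$sym, sh$symbol)
      }
    }
    ids <- vapply(items, function(i) i$id, "")
    make_synthetic_example(
      out, rate, weak_seq(tokens, paste(ids, collapse = "+")),
      strong_track(st$start, st$end, st$sym,
                   clip_id = paste(ids, collapse = "+")),
      data.frame(source_id = ids,
                 domain = vapply(items, function(i) i$domain, ""),
                 placed_offset_s = offs,
                 source_dur_s = vapply(items, function(i) i$duration_s, 0),
                 stringsAsFactors = FALSE),
      seed, sprintf("synth-mix-%s", paste(ids, collapse = "+")))
  })
}

#' Generate the synthetic mixed speech/eating corpus
#'
#' The central data-augmentation procedure: clips lasting at least 7 s are
#' noise-padded to the fixed length; shorter clips are concatenated with a
#' partner whose domain is chosen to balance cumulative speech and eating
#' material (measured in seconds), remaining room is filled with further
#' randomly selected clips while they fit, and white noise fills the gaps.
#' Every source item is consumed at least once, and the result is split 9:1
#' into training and validation examples.
#'
#' @param speech_items,eating_items nonempty lists of [source_item]s
#' @param target_dur_s fixed example duration in seconds (default 10)
#' @param seed integer seed; the whole corpus is deterministic given it
#' @param noise_snr_db padding-noise level in dB below the pool median RMS
#' @param pad_threshold_s clips at least this long take the pad path
#'   (default 7)
#' @param reuse logical: may clips be reused when filling remaining room
#' @param split_ratio training fraction of the 9:1 split (default 0.9)
#' @param target_ratio desired speech:eating duration ratio (default 1)
#' @return a list with `examples`, index vectors `train` and `val`, and
#'   `balance` (cumulative speech/eating seconds)
#' @export
build_corpus <- function(speech_items, eating_items, target_dur_s = 10,
                         seed = 1L, noise_snr_db = 30, pad_threshold_s = 7,
                         reuse = TRUE, split_ratio = 0.9, target_ratio = 1.0) {
  if (!length(speech_items) || !length(eating_items))
    stop_mealvoice("both source pools must be nonempty",
                   "mealvoice_config_error")
  pool <- c(speech_items, eating_items)
  durs <- vapply(pool, function(i) i$duration_s, 0)
  doms <- vapply(pool, function(i) i$domain, "")
  if (any(durs > target_dur_s))
    stop_mealvoice("source items longer than target_dur_s must be excluded upstream",
                   "mealvoice_param_error")
  ref_rms <- stats::median(vapply(pool, function(i) clip_rms(i$clip), 0))
  sub_seeds <- derive_seeds(seed, 4L * length(pool) + 1000L)
  seed_i <- 0L
  next_seed <- function() {
    seed_i <<- seed_i + 1L
    sub_seeds[seed_i]
  }
  bal <- c(speech = 0, eating = 0)
  examples <- list()

  add_example <- function(ex) {
    examples[[length(examples) + 1L]] <<- ex
    for (r in seq_len(nrow(ex$segments)))
      bal[[ex$segments$domain[r]]] <<- bal[[ex$segments$domain[r]]] +
        ex$segments$source_dur_s[r]
  }

  long_idx <- which(durs >= pad_threshold_s)
  short_idx <- which(durs < pad_threshold_s)
  for (i in long_idx)
    add_example(pad_to_fixed(pool[[i]], target_dur_s, noise_snr_db,
                             next_seed(), ref_rms))

  pick <- function(cand) cand[sample.int(length(cand), 1L)]

  consumed <- rep(FALSE, length(pool))
  consumed[long_idx] <- TRUE
  order_short <- with_seed(next_seed(), sample(short_idx))
  for (i in order_short) {
    if (consumed[i]) next
    with_seed(next_seed(), {
      consumed[i] <- TRUE
      parts <- list(pool[[i]])
      remaining <- target_dur_s - durs[i]
      repeat {
        want <- needy_domain_after(bal, parts, target_ratio)
        cand <- short_idx[doms[short_idx] == want & durs[short_idx] <= remaining &
                            !consumed[short_idx]]
        if (!length(cand) && reuse)
          cand <- short_idx[doms[short_idx] == want & durs[short_idx] <= remaining]
        if (!length(cand)) {
          other <- setdiff(c("speech", "eating"), want)
          cand <- short_idx[doms[short_idx] == other & durs[short_idx] <= remaining &
                              !consumed[short_idx]]
          if (!length(cand) && reuse)
            cand <- short_idx[doms[short_idx] == other & durs[short_idx] <= remaining]
        }
        if (!length(cand)) break
        j <- pick(cand)
        consumed[j] <- TRUE
        parts[[length(parts) + 1L]] <- pool[[j]]
        remaining <- remaining - durs[j]
      }
      add_example(assemble_mixture(parts, target_dur_s, noise_snr_db,
                                   next_seed(), ref_rms))
    })
  }

  n <- length(examples)
  n_train <- as.integer(round(split_ratio * n))
  perm <- with_seed(next_seed(), sample.int(n))
  list(examples = examples,
       train = sort(perm[seq_len(n_train)]),
       val = sort(perm[-seq_len(n_train)]),
       balance = bal)
}

## Balance including segments staged for the current example.
needy_domain_after <- function(bal, parts, target_ratio) {
  for (p in parts) bal[[p$domain]] <- bal[[p$domain]] + p$duration_s
  share <- target_ratio / (1 + target_ratio)
  tot <- sum(bal)
  if (tot == 0 || bal[["speech"]] / tot < share) "speech" else "eating"
}
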