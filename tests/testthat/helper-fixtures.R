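# Shared fixture builders. Everything is generated in code at test time.

# A random, properly row-normalized posteriorgram over `vocab`.
random_post <- function(T_, vocab, seed = 1L, concentration = 1) {
  set.seed(seed)
  p <- matrix(stats::rgamma(T_ * length(vocab), shape = concentration),
              T_, length(vocab))
  p <- p / rowSums(p)
  posteriorgram(log(p), vocab, 0.02)
}

# Exhaustive CTC oracle: enumerate all V^T alignment paths, collapse each,
# and sum the probabilities of those collapsing to `target`.
brute_ctc_prob <- function(post, target) {
  p <- exp(post$logp)
  T_ <- nrow(p); V <- ncol(p)
  paths <- as.matrix(expand.grid(rep(list(seq_len(V)), T_)))
  collapse <- function(path) {
    keep <- path[c(TRUE, diff(path) != 0)]
    post$vocab[keep[keep != 1L]]
  }
  total <- 0
  for (r in seq_len(nrow(paths))) {
    path <- paths[r, ]
    if (identical(unname(collapse(path)), unname(target)))
      total <- total + prod(p[cbind(seq_len(T_), path)])
  }
  total
}

# Brute-force maximum total-probability labeling (argmax over labelings of
# the summed alignment probability), computed from raw path enumeration.
brute_best_labeling <- function(post) {
  p <- exp(post$logp)
  T_ <- nrow(p); V <- ncol(p)
  paths <- as.matrix(expand.grid(rep(list(seq_len(V)), T_)))
  scores <- new.env(parent = emptyenv())
  for (r in seq_len(nrow(paths))) {
    path <- paths[r, ]
    keep <- path[c(TRUE, diff(path) != 0)]
    lab <- paste(post$vocab[keep[keep != 1L]], collapse = "\x1f")
    key <- if (nzchar(lab)) lab else "<empty>"
    scores[[key]] <- (if (is.null(scores[[key]])) 0 else scores[[key]]) +
      prod(p[cbind(seq_len(T_), path)])
  }
  keys <- ls(scores)
  vals <- vapply(keys, function(k) scores[[k]], 0)
  best <- keys[which.max(vals)]
  list(tokens = if (best == "<empty>") character() else
         strsplit(best, "\x1f", fixed = TRUE)[[1]],
       prob = max(vals))
}

# Small deterministic strong track.
demo_track <- function() {
  strong_track(c(0.1, 0.5, 1.0), c(0.3, 0.6, 1.4), c("#", "#", "$"),
               clip_id = "demo")
}

# FFT peak frequency of a mono clip.
fft_peak_hz <- function(clip) {
  x <- clip$samples[1L, ]
  n <- length(x)
  sp <- Mod(stats::fft(x))[seq_len(n %/% 2L)]
  (which.max(sp) - 1L) * clip$sample_rate / n
}

# Amplitude of the `freq` component of a mono clip, by FFT magnitude.
fft_amp_at <- function(clip, freq) {
  x <- clip$samples[1L, ]
  n <- length(x)
  sp <- Mod(stats::fft(x)) * 2 / n
  bin <- round(freq * n / clip$sample_rate) + 1L
  max(sp[max(1L, bin - 1L):min(n, bin + 1L)])
}

tiny_toy_spec <- function(seed = 1L, rate = 4000L, ...) {
  toy_spec(sample_rate = rate, n_speech = 8L, n_eating = 6L, seed = seed, ...)
}
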