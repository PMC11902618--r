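#' Per-frame token posteriorgram
#'
#' The acoustic model's output: a `T x V` matrix of log-probabilities over the
#' token vocabulary (blank first) at a 20 ms frame stride. Each row
#' log-sum-exps to 0.
#'
#' @param logp `T x V` matrix of log-probabilities; columns named by token
#' @param vocab character vector of tokens, blank (`"_"`) first
#' @param frame_stride_s frame stride in seconds (default 0.02)
#' @param clip_id identifier of the scored clip
#' @return a `posteriorgram`
#' @export
posteriorgram <- function(logp, vocab, frame_stride_s = 0.02, clip_id = "") {
  stopifnot(is.matrix(logp), ncol(logp) == length(vocab),
            vocab[1] == BLANK_SYMBOL)
  colnames(logp) <- vocab
  structure(list(logp = logp, vocab = vocab,
                 frame_stride_s = frame_stride_s,
                 clip_id = as.character(clip_id)),
            class = "posteriorgram")
}

#' @export
print.posteriorgram <- function(x, ...) {
  cat(sprintf("<posteriorgram '%s': %d frames x %d tokens @ %.0f ms>\n",
              x$clip_id, nrow(x$logp), ncol(x$logp), x$frame_stride_s * 1000))
  invisible(x)
}

## Map target token symbols to vocabulary indices (1-based; index 1 = blank).
target_indices <- function(post, target) {
  toks <- if (inherits(target, "weak_seq")) target$tokens else as.character(target)
  idx <- match(toks, post$vocab)
  if (anyNA(idx))
    stop_mealvoice(sprintf("target token(s) outside the vocabulary: %s",
                           paste(unique(toks[is.na(idx)]), collapse = " ")),
                   "mealvoice_value_error")
  if (any(idx == 1L))
    stop_mealvoice("CTC targets must not contain the blank",
                   "mealvoice_value_error")
  idx
}

## Extended state sequence: blank, l1, blank, l2, ..., blank.
ctc_extended <- function(lab) {
  S <- 2L * length(lab) + 1L
  z <- integer(S)
  z[seq(1L, S, by = 2L)] <- 1L
  if (length(lab)) z[seq(2L, S - 1L, by = 2L)] <- lab
  z
}

## Scaled (linear-space, per-step renormalized) forward pass over the
## blank-extended state lattice. Exact up to machine precision; avoids the
## per-step log-sum-exp of a log-space recursion. Returns the negative
## log-likelihood plus, if `need_alpha`, the scaled alpha matrix for the
## backward pass.
ctc_forward <- function(logp, lab, need_alpha = FALSE) {
  T_ <- nrow(logp)
  p <- exp(logp)
  z <- ctc_extended(lab)
  S <- length(z)
  allow2 <- rep(FALSE, S)
  if (S >= 3L)
    allow2[3:S] <- z[3:S] != 1L & z[3:S] != z[1:(S - 2L)]
  ah <- if (need_alpha) matrix(0, T_, S)
  a <- numeric(S)
  a[1L] <- p[1L, 1L]
  if (S >= 2L) a[2L] <- p[1L, z[2L]]
  c1 <- sum(a)
  if (c1 == 0) return(list(nll = Inf, z = z, allow2 = allow2))
  a <- a / c1
  loglik <- log(c1)
  if (need_alpha) ah[1L, ] <- a
  if (T_ >= 2L) for (t in 2:T_) {
    tot <- a
    if (S >= 2L) tot[2:S] <- tot[2:S] + a[1:(S - 1L)]
    if (S >= 3L) tot[3:S] <- tot[3:S] + a[1:(S - 2L)] * allow2[3:S]
    a <- tot * p[t, z]
    ct <- sum(a)
    if (ct == 0) return(list(nll = Inf, z = z, allow2 = allow2))
    a <- a / ct
    loglik <- loglik + log(ct)
    if (need_alpha) ah[t, ] <- a
  }
  tail_states <- if (S >= 2L) c(S - 1L, S) else S
  tail_mass <- sum(a[tail_states])
  if (tail_mass == 0) return(list(nll = Inf, z = z, allow2 = allow2))
  list(nll = -(loglik + log(tail_mass)), alpha = ah, z = z, allow2 = allow2,
       p = p)
}

#' CTC negative log-likelihood
#'
#' The forward-algorithm sum over all monotonic blank-augmented alignments of
#' `target` to the `T` frames of `post`; `-log` of the total path probability.
#' Targets that cannot be aligned in `T` frames yield `+Inf` (a clean
#' infinite-loss signal, not a numeric overflow).
#'
#' @param post a [posteriorgram]
#' @param target a [weak_seq] or character vector of non-blank tokens
#' @return nonnegative scalar (possibly `Inf`)
#' @export
ctc_nll <- function(post, target) {
  stopifnot(inherits(post, "posteriorgram"))
  ctc_forward(post$logp, target_indices(post, target))$nll
}

## Scaled backward pass (emissions t+1..T, excluding t), renormalized per
## step; combined with the scaled alpha it yields the state posterior.
ctc_backward_scaled <- function(p, z, allow2, T_) {
  S <- length(z)
  bh <- matrix(0, T_, S)
  b <- numeric(S)
  tail_states <- if (S >= 2L) c(S - 1L, S) else S
  b[tail_states] <- 1
  bh[T_, ] <- b / sum(b)
  b <- bh[T_, ]
  if (T_ >= 2L) for (t in (T_ - 1L):1L) {
    e <- b * p[t + 1L, z]
    nb <- e
    if (S >= 2L) nb[1:(S - 1L)] <- nb[1:(S - 1L)] + e[2:S]
    if (S >= 3L) nb[1:(S - 2L)] <- nb[1:(S - 2L)] + e[3:S] * allow2[3:S]
    sb <- sum(nb)
    if (sb == 0) sb <- 1
    b <- nb / sb
    bh[t, ] <- b
  }
  bh
}

#' CTC loss and gradient with respect to the logits
#'
#' Runs the forward-backward recursions and returns both the negative
#' log-likelihood and its gradient with respect to unnormalized logits `z`
#' (where `logp = z - logsumexp(z)` rowwise): `d nll / d z = softmax(z) - G`,
#' with `G` the per-frame posterior token occupancy.
#'
#' @inheritParams ctc_nll
#' @return list with `nll` and `grad` (`T x V` matrix)
#' @export
ctc_nll_grad <- function(post, target) {
  stopifnot(inherits(post, "posteriorgram"))
  logp <- post$logp
  lab <- target_indices(post, target)
  T_ <- nrow(logp)
  fw <- ctc_forward(logp, lab, need_alpha = TRUE)
  if (!is.finite(fw$nll))
    return(list(nll = fw$nll, grad = matrix(0, nrow(logp), ncol(logp))))
  z <- fw$z; S <- length(z)
  bh <- ctc_backward_scaled(fw$p, z, fw$allow2, T_)
  ## state posterior: alpha (emissions 1..t) x beta (emissions t+1..T);
  ## the per-step scale factors cancel in the row normalization
  g <- fw$alpha * bh
  rs <- rowSums(g)
  rs[rs == 0] <- 1
  g <- g / rs
  G <- matrix(0, T_, ncol(logp))
  for (s in seq_len(S)) G[, z[s]] <- G[, z[s]] + g[, s]
  list(nll = fw$nll, grad = fw$p - G)
}

#' Decoded token sequence
#'
#' @param tokens character vector of non-blank tokens
#' @param frames integer vector of emitting frame indices (0-based),
#'   strictly increasing
#' @param score log-probability of the decode
#' @param frame_stride_s frame stride in seconds
#' @return a `decoded_seq` with `frame_times` in seconds
#' @export
decoded_seq <- function(tokens, frames, score, frame_stride_s = 0.02) {
  stopifnot(length(tokens) == length(frames))
  if (length(frames) >= 2L && any(diff(frames) <= 0))
    stop_mealvoice("emitting frames must be strictly increasing",
                   "mealvoice_value_error")
  structure(list(tokens = as.character(tokens), frames = as.integer(frames),
                 frame_times = as.numeric(frames) * frame_stride_s,
                 score = score, frame_stride_s = frame_stride_s),
            class = "decoded_seq")
}

#' Best-path (greedy) CTC decoding
#'
#' Takes the per-frame argmax (ties broken toward the lowest token index,
#' blank first), collapses repeats, and removes blanks. Each emitted token is
#' stamped with the first frame of its run.
#'
#' @param post a [posteriorgram]
#' @return a [decoded_seq]
#' @export
best_path_decode <- function(post) {
  stopifnot(inherits(post, "posteriorgram"))
  idx <- max.col(post$logp, ties.method = "first")
  score <- sum(post$logp[cbind(seq_along(idx), idx)])
  keep <- idx != 1L & (seq_along(idx) == 1L | idx != c(0L, idx[-length(idx)]))
  frames <- which(keep) - 1L
  decoded_seq(post$vocab[idx[keep]], frames, score, post$frame_stride_s)
}

#' Beam-search configuration
#'
#' Defaults follow the decoding setup used for recognition: beam width 100,
#' beam log-probability pruning threshold -12.0, minimum per-frame token
#' log-probability -1.2, history pruning on, no language model.
#'
#' @param beam_width maximum beams kept per frame
#' @param logp_prune drop beams trailing the best by more than `|logp_prune|`
#'   (`-Inf` disables)
#' @param token_logp_min expand only tokens whose frame log-probability is at
#'   least this (`-Inf` disables)
#' @param history_prune merge beams sharing a collapsed prefix by
#'   log-sum-exp (otherwise keep the max-scoring contributor)
#' @param use_lm must be `FALSE` (no language-model fusion)
#' @return a `beam_config`
#' @export
beam_config <- function(beam_width = 100L, logp_prune = -12.0,
                        token_logp_min = -1.2, history_prune = TRUE,
                        use_lm = FALSE) {
  stopifnot(beam_width >= 1L, logp_prune <= 0, isFALSE(use_lm))
  structure(list(beam_width = as.integer(beam_width),
                 logp_prune = logp_prune, token_logp_min = token_logp_min,
                 history_prune = isTRUE(history_prune), use_lm = FALSE),
            class = "beam_config")
}

#' CTC prefix beam search
#'
#' Searches over collapsed label prefixes, tracking blank- and
#' non-blank-ending path mass per prefix. With a saturating beam and pruning
#' disabled this returns the maximum total-probability labeling (the sum over
#' all alignments of each labeling). Token pruning skips non-blank tokens
#' below `token_logp_min`; beam pruning drops prefixes trailing the leader by
#' more than `|logp_prune|`; history pruning merges equal prefixes by
#' log-sum-exp.
#'
#' @param post a [posteriorgram]
#' @param cfg a [beam_config]
#' @return a [decoded_seq] for the best prefix
#' @export
prefix_beam_search <- function(post, cfg = beam_config()) {
  stopifnot(inherits(post, "posteriorgram"), inherits(cfg, "beam_config"))
  logp <- post$logp
  T_ <- nrow(logp); V <- ncol(logp)
  ## beam record: key, tokens (int idx), frames, pb (ends in blank), pnb
  beams <- list(list(key = "@", tokens = integer(), frames = integer(),
                     pb = 0, pnb = -Inf))
  merge_in <- function(tbl, key, rec, field, val) {
    cur <- tbl[[key]]
    if (is.null(cur)) {
      rec[[field]] <- val
      tbl[[key]] <- rec
    } else {
      old <- cur[[field]]
      new <- if (cfg$history_prune) logsumexp(c(old, val)) else max(old, val)
      ## keep the alignment of the stronger contributor
      if (val > old) {
        cur$tokens <- rec$tokens
        cur$frames <- rec$frames
      }
      cur[[field]] <- new
      tbl[[key]] <- cur
    }
    tbl
  }
  for (t in seq_len(T_)) {
    tbl <- list()
    cand <- which(logp[t, ] >= cfg$token_logp_min)
    cand <- cand[cand != 1L]
    for (b in beams) {
      tot <- logsumexp(c(b$pb, b$pnb))
      ## stay on the same prefix via blank
      tbl <- merge_in(tbl, b$key, list(key = b$key, tokens = b$tokens,
                                       frames = b$frames, pb = -Inf, pnb = -Inf),
                      "pb", tot + logp[t, 1L])
      last <- if (length(b$tokens)) b$tokens[length(b$tokens)] else 0L
      if (last != 0L && is.finite(b$pnb)) {
        ## repeat the last token without a separating blank: same prefix
        tbl <- merge_in(tbl, b$key, list(key = b$key, tokens = b$tokens,
                                         frames = b$frames, pb = -Inf, pnb = -Inf),
                        "pnb", b$pnb + logp[t, last])
      }
      for (k in cand) {
        ext_key <- paste0(b$key, ",", k)
        ext <- list(key = ext_key, tokens = c(b$tokens, k),
                    frames = c(b$frames, t - 1L), pb = -Inf, pnb = -Inf)
        val <- if (k == last) b$pb + logp[t, k] else tot + logp[t, k]
        if (is.finite(val)) tbl <- merge_in(tbl, ext_key, ext, "pnb", val)
      }
    }
    scores <- vapply(tbl, function(x) logsumexp(c(x$pb, x$pnb)), 0)
    keep <- order(scores, decreasing = TRUE)
    if (is.finite(cfg$logp_prune))
      keep <- keep[scores[keep] >= scores[keep[1]] + cfg$logp_prune]
    keep <- keep[seq_len(min(length(keep), cfg$beam_width))]
    beams <- unname(tbl[keep])
    if (!length(beams)) {
      beams <- list(list(key = "@", tokens = integer(), frames = integer(),
                         pb = -Inf, pnb = -Inf))
      break
    }
  }
  scores <- vapply(beams, function(x) logsumexp(c(x$pb, x$pnb)), 0)
  best <- beams[[which.max(scores)]]
  decoded_seq(post$vocab[best$tokens], best$frames, max(scores),
              post$frame_stride_s)
}

#' Convert decoded event peaks to timed event intervals
#'
#' CTC emits each event as an isolated peak of 1-4 frames; each decoded chew
#' or swallow token becomes a single-frame interval
#' `[onset, onset + frame_stride)` for overlap-based scoring. Character and
#' space tokens are ignored.
#'
#' @param dec a [decoded_seq]
#' @param classes event symbols to keep (default chew `"#"` and swallow `"$"`)
#' @return data.frame with columns `class`, `onset_s`, `offset_s`
#' @export
peaks_to_events <- function(dec, classes = c(CHEW_SYMBOL, SWALLOW_SYMBOL)) {
  stopifnot(inherits(dec, "decoded_seq"))
  keep <- dec$tokens %in% classes
  data.frame(class = dec$tokens[keep],
             onset_s = dec$frame_times[keep],
             offset_s = dec$frame_times[keep] + dec$frame_stride_s,
             stringsAsFactors = FALSE)
}
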