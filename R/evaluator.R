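#' Temporal allowance configuration for event scoring
#'
#' Each ground-truth interval is expanded by a per-class collar before
#' matching: 0.05 s for chewing (frequency estimation tolerates looser
#' timing) and a strict 0.01 s for swallowing (whose timing matters for
#' aspiration-risk assessment).
#'
#' @param chew_allowance_s collar for chew events (default 0.05)
#' @param swallow_allowance_s collar for swallow events (default 0.01)
#' @param frame_s decoder frame length in seconds (default 0.02)
#' @return an `allowance_config`
#' @export
allowance_config <- function(chew_allowance_s = 0.05,
                             swallow_allowance_s = 0.01, frame_s = 0.02) {
  stopifnot(chew_allowance_s >= 0, swallow_allowance_s >= 0)
  structure(list(chew_allowance_s = chew_allowance_s,
                 swallow_allowance_s = swallow_allowance_s,
                 frame_s = frame_s),
            class = "allowance_config")
}

#' Character / token error rate
#'
#' Minimum edit distance (substitutions + deletions + insertions) between the
#' hypothesis and reference, divided by the reference length. Event tokens
#' (`#`, `$`), blanks and whitespace are stripped before comparison, so the
#' rate scores the transcript only. Inputs may be single strings (compared
#' per character) or token vectors (compared per token).
#'
#' @param ref reference transcript; must be nonempty after stripping
#' @param hyp hypothesis transcript
#' @return nonnegative error rate (can exceed 1 with many insertions)
#' @export
character_error_rate <- function(ref, hyp) {
  strip <- function(x) {
    toks <- if (length(x) == 1L && !inherits(x, "AsIs"))
      strsplit(x, "")[[1]] else as.character(x)
    toks[!toks %in% c(CHEW_SYMBOL, SWALLOW_SYMBOL, BLANK_SYMBOL) &
           !grepl("^\\s*$", toks)]
  }
  r <- strip(ref)
  h <- strip(hyp)
  if (!length(r))
    stop_mealvoice("character_error_rate is undefined for an empty reference",
                   "mealvoice_value_error")
  edit_distance(r, h) / length(r)
}

## Levenshtein distance between two token vectors (unit costs).
edit_distance <- function(a, b) {
  n <- length(a); m <- length(b)
  if (!n) return(m)
  if (!m) return(n)
  prev <- 0:m
  for (i in seq_len(n)) {
    cur <- numeric(m + 1L)
    cur[1L] <- i
    for (j in seq_len(m)) {
      cur[j + 1L] <- min(prev[j + 1L] + 1L, cur[j] + 1L,
                         prev[j] + (a[i] != b[j]))
    }
    prev <- cur
  }
  prev[m + 1L]
}

#' Match predicted events to ground-truth intervals
#'
#' Each ground-truth entry is expanded by its class allowance, then
#' predictions are processed in time order: a prediction is a true positive
#' if its (half-open) interval overlaps the earliest not-yet-matched expanded
#' entry of the same class, which it consumes; otherwise it is a false
#' positive. Unconsumed entries are false negatives. This chronological
#' greedy one-to-one matching is deterministic and conservative for rapid
#' chew trains.
#'
#' @param preds data.frame with `class`, `onset_s`, `offset_s` (as from
#'   [peaks_to_events()]), sorted by onset
#' @param truth a [strong_track] restricted to event entries
#' @param cfg an [allowance_config]
#' @return an `event_match` list: per-class `tp`, `fp`, `fn` counts and the
#'   matched prediction/entry index pairs
#' @export
match_events <- function(preds, truth, cfg = allowance_config()) {
  stopifnot(is.data.frame(preds), inherits(truth, "strong_track"))
  classes <- c(CHEW_SYMBOL, SWALLOW_SYMBOL)
  if (nrow(preds) && !all(preds$class %in% classes))
    stop_mealvoice(sprintf("unknown event class in predictions: %s",
                           paste(setdiff(preds$class, classes), collapse = " ")),
                   "mealvoice_value_error")
  if (nrow(preds) && is.unsorted(preds$onset_s))
    preds <- preds[order(preds$onset_s), , drop = FALSE]
  truth <- truth[truth$symbol %in% classes, , drop = FALSE]
  collar <- ifelse(truth$symbol == CHEW_SYMBOL, cfg$chew_allowance_s,
                   cfg$swallow_allowance_s)
  lo <- truth$start_s - collar
  hi <- truth$end_s + collar
  consumed <- rep(FALSE, nrow(truth))
  counts <- list()
  for (cl in classes) counts[[cl]] <- c(tp = 0L, fp = 0L, fn = 0L)
  pairs <- data.frame(pred = integer(), entry = integer())
  for (i in seq_len(nrow(preds))) {
    cl <- preds$class[i]
    ## half-open interval overlap with the expanded entry
    hit <- which(!consumed & truth$symbol == cl &
                   preds$onset_s[i] < hi & preds$offset_s[i] > lo)
    if (length(hit)) {
      j <- hit[which.min(truth$start_s[hit])]
      consumed[j] <- TRUE
      counts[[cl]]["tp"] <- counts[[cl]]["tp"] + 1L
      pairs <- rbind(pairs, data.frame(pred = i, entry = j))
    } else {
      counts[[cl]]["fp"] <- counts[[cl]]["fp"] + 1L
    }
  }
  for (cl in classes)
    counts[[cl]]["fn"] <- sum(!consumed & truth$symbol == cl)
  structure(list(counts = counts, pairs = pairs,
                 n_truth = table(factor(truth$symbol, levels = classes)),
                 n_pred = table(factor(preds$class, levels = classes))),
            class = "event_match")
}

## Accumulate two event_match results (summing counts).
combine_matches <- function(a, b) {
  for (cl in names(a$counts)) a$counts[[cl]] <- a$counts[[cl]] + b$counts[[cl]]
  a$n_truth <- a$n_truth + b$n_truth
  a$n_pred <- a$n_pred + b$n_pred
  a
}

#' Per-class precision, recall and F1
#'
#' `F1 = 2PR/(P+R)`, defined as 0 whenever `P + R = 0` (and precision/recall
#' as 0 when their denominators vanish).
#'
#' @param r an `event_match` from [match_events()]
#' @return data.frame with one row per class: `tp`, `fp`, `fn`, `precision`,
#'   `recall`, `f1`
#' @export
f1_scores <- function(r) {
  stopifnot(inherits(r, "event_match"))
  rows <- lapply(names(r$counts), function(cl) {
    x <- r$counts[[cl]]
    p <- if (x["tp"] + x["fp"] > 0) x["tp"] / (x["tp"] + x["fp"]) else 0
    rc <- if (x["tp"] + x["fn"] > 0) x["tp"] / (x["tp"] + x["fn"]) else 0
    f1 <- if (p + rc > 0) 2 * p * rc / (p + rc) else 0
    data.frame(class = cl, tp = x[["tp"]], fp = x[["fp"]], fn = x[["fn"]],
               precision = unname(p), recall = unname(rc), f1 = unname(f1),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Evaluate a trained model on held-out test sets
#'
#' Computes the character/token error rate on the speech set (beam-search
#' transcripts) and per-class event F1 on the eating set (best-path peak
#' timing; chew allowance 0.05 s, swallow 0.01 s), the standard report
#' columns.
#'
#' @param model a `ctc_model`
#' @param speech_test list of examples with `clip` and reference `weak`
#'   transcript (may be `NULL` to skip)
#' @param eating_test list of examples with `clip` and ground-truth `strong`
#'   track (may be `NULL` to skip)
#' @param cfg an [allowance_config]
#' @param beam a [beam_config] for transcript decoding
#' @return an `eval_report` list: `cer`, `chew_f1`, `swallow_f1`, plus the
#'   underlying `match` counts and per-clip transcripts
#' @export
evaluate_run <- function(model, speech_test = NULL, eating_test = NULL,
                         cfg = allowance_config(), beam = beam_config()) {
  stopifnot(inherits(model, "ctc_model"))
  cer <- NA_real_
  transcripts <- NULL
  if (!is.null(speech_test) && length(speech_test)) {
    if (any(!vapply(speech_test, function(e) inherits(e$weak, "weak_seq"), TRUE)))
      stop_mealvoice("speech test examples must carry reference transcripts",
                     "mealvoice_config_error")
    tot_edit <- 0; tot_ref <- 0L
    transcripts <- list()
    for (e in speech_test) {
      post <- forward_logprobs(model, e$clip)
      dec <- prefix_beam_search(post, beam)
      strip <- function(x) x[!x %in% c(CHEW_SYMBOL, SWALLOW_SYMBOL,
                                       BLANK_SYMBOL, SPACE_SYMBOL)]
      r <- strip(e$weak$tokens)
      h <- strip(dec$tokens)
      tot_edit <- tot_edit + edit_distance(r, h)
      tot_ref <- tot_ref + length(r)
      transcripts[[length(transcripts) + 1L]] <-
        list(clip_id = e$clip$source_id, ref = r, hyp = h)
    }
    if (tot_ref == 0L)
      stop_mealvoice("speech test references are empty", "mealvoice_config_error")
    cer <- tot_edit / tot_ref
  }
  match <- NULL
  chew_f1 <- NA_real_
  swallow_f1 <- NA_real_
  if (!is.null(eating_test) && length(eating_test)) {
    if (any(!vapply(eating_test, function(e) inherits(e$strong, "strong_track"),
                    TRUE)))
      stop_mealvoice("eating test examples must carry strong label tracks",
                     "mealvoice_config_error")
    for (e in eating_test) {
      post <- forward_logprobs(model, e$clip)
      preds <- peaks_to_events(best_path_decode(post))
      m <- match_events(preds, e$strong, cfg)
      match <- if (is.null(match)) m else combine_matches(match, m)
    }
    f1 <- f1_scores(match)
    chew_f1 <- f1$f1[f1$class == CHEW_SYMBOL]
    swallow_f1 <- f1$f1[f1$class == SWALLOW_SYMBOL]
  }
  structure(list(cer = cer, chew_f1 = chew_f1, swallow_f1 = swallow_f1,
                 match = match, transcripts = transcripts,
                 allowance = cfg),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report: CER %s | chew F1@%.2fs %s | swallow F1@%.2fs %s>\n",
    ifelse(is.na(x$cer), "-", sprintf("%.3f", x$cer)),
    x$allowance$chew_allowance_s,
    ifelse(is.na(x$chew_f1), "-", sprintf("%.3f", x$chew_f1)),
    x$allowance$swallow_allowance_s,
    ifelse(is.na(x$swallow_f1), "-", sprintf("%.3f", x$swallow_f1))))
  invisible(x)
}

#' Serialize an evaluation report
#'
#' @param report an `eval_report`
#' @param path destination `.json` path
#' @return `path`, invisibly
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "eval_report"))
  obj <- list(cer = report$cer, chew_f1 = report$chew_f1,
              swallow_f1 = report$swallow_f1,
              chew_allowance_s = report$allowance$chew_allowance_s,
              swallow_allowance_s = report$allowance$swallow_allowance_s)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
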