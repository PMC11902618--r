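#' Classify a token symbol
#'
#' Reserved symbols: `"_"` is the CTC blank, `"#"` a chewing event, `"$"` a
#' swallowing event, `" "` the utterance delimiter; everything else is an
#' ordinary character token.
#'
#' @param symbol character vector of token symbols
#' @return character vector of kinds among `character`, `chew`, `swallow`,
#'   `blank`, `space`
#' @export
token_kind <- function(symbol) {
  out <- rep("character", length(symbol))
  out[symbol == BLANK_SYMBOL] <- "blank"
  out[symbol == CHEW_SYMBOL] <- "chew"
  out[symbol == SWALLOW_SYMBOL] <- "swallow"
  out[symbol == SPACE_SYMBOL] <- "space"
  out
}

#' Strong (timed) label track
#'
#' An ordered set of `(start_s, end_s, symbol)` event/character intervals, the
#' ground truth used for temporal evaluation. Entries are sorted by start time;
#' every entry must satisfy `0 <= start_s < end_s` and must not carry the
#' reserved blank symbol.
#'
#' @param start_s,end_s numeric vectors of interval bounds in seconds
#' @param symbol character vector of token symbols
#' @param clip_id identifier of the clip the track annotates
#' @return a `strong_track`: a data.frame with columns `start_s`, `end_s`,
#'   `symbol` and attribute `clip_id`
#' @export
strong_track <- function(start_s = numeric(), end_s = numeric(),
                         symbol = character(), clip_id = "") {
  stopifnot(length(start_s) == length(end_s),
            length(start_s) == length(symbol))
  if (length(start_s)) {
    if (any(start_s < 0) || any(end_s <= start_s))
      stop_mealvoice("strong_track requires 0 <= start_s < end_s",
                     "mealvoice_value_error")
    if (any(symbol == BLANK_SYMBOL))
      stop_mealvoice("strong_track entries must not carry the blank symbol",
                     "mealvoice_value_error")
    o <- order(start_s, end_s)
    start_s <- start_s[o]; end_s <- end_s[o]; symbol <- symbol[o]
  }
  structure(
    data.frame(start_s = as.numeric(start_s), end_s = as.numeric(end_s),
               symbol = as.character(symbol), stringsAsFactors = FALSE),
    clip_id = as.character(clip_id),
    class = c("strong_track", "data.frame")
  )
}

#' Weak (order-only) label sequence
#'
#' The ordered token sequence with times removed — the CTC training target.
#' May be empty (a pure-noise clip); never contains blanks.
#'
#' @param tokens character vector of token symbols
#' @param clip_id identifier of the annotated clip
#' @return a `weak_seq` object
#' @export
weak_seq <- function(tokens = character(), clip_id = "") {
  tokens <- as.character(tokens)
  if (any(tokens == BLANK_SYMBOL))
    stop_mealvoice("weak_seq must not contain the blank symbol",
                   "mealvoice_value_error")
  structure(list(tokens = tokens, clip_id = as.character(clip_id)),
            class = "weak_seq")
}

#' @export
print.weak_seq <- function(x, ...) {
  cat(sprintf("<weak_seq '%s': [%s]>\n", x$clip_id,
              paste(x$tokens, collapse = " ")))
  invisible(x)
}

#' Project a strong track to its weak label sequence
#'
#' Drops the time stamps, keeping the event/character order — the supervision
#' signal used for CTC training.
#'
#' @param track a [strong_track]
#' @return a [weak_seq] with one token per track entry, in start-time order
#' @export
weak_from_strong <- function(track) {
  stopifnot(inherits(track, "strong_track"))
  weak_seq(track$symbol, clip_id = attr(track, "clip_id"))
}

#' Shift all track times by a constant offset
#'
#' @param track a [strong_track]
#' @param offset_s nonnegative shift in seconds
#' @return the shifted track
#' @export
shift_track <- function(track, offset_s) {
  stopifnot(inherits(track, "strong_track"), offset_s >= 0)
  strong_track(track$start_s + offset_s, track$end_s + offset_s,
               track$symbol, clip_id = attr(track, "clip_id"))
}

## Scale all times by 1/factor (used when a clip is speed-perturbed).
scale_track <- function(track, factor) {
  stopifnot(inherits(track, "strong_track"), factor > 0)
  strong_track(track$start_s / factor, track$end_s / factor,
               track$symbol, clip_id = attr(track, "clip_id"))
}

#' Read / write a strong label track
#'
#' The on-disk format is the Audacity label-track TSV: one
#' `start<TAB>end<TAB>symbol` line per entry, times in seconds with canonical
#' 6-decimal formatting. Write-then-read reproduces entries to 1e-6 s, and a
#' canonically formatted file round-trips byte-identically.
#'
#' @param path path to a TSV label file
#' @param clip_id identifier to attach to the track
#' @return `read_track` returns a [strong_track]; `write_track` returns `path`
#'   invisibly
#' @export
read_track <- function(path, clip_id = basename(path)) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(strong_track(clip_id = clip_id))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) != 3L)
  if (length(bad))
    stop_mealvoice(sprintf("malformed label line %d in '%s'", bad[1], path),
                   "mealvoice_parse_error")
  start_s <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 1L)))
  end_s <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  if (anyNA(start_s) || anyNA(end_s)) {
    bad <- which(is.na(start_s) | is.na(end_s))[1]
    stop_mealvoice(sprintf("non-numeric time on label line %d in '%s'", bad, path),
                   "mealvoice_parse_error")
  }
  if (any(end_s <= start_s))
    stop_mealvoice(sprintf("end <= start on label line %d in '%s'",
                           which(end_s <= start_s)[1], path),
                   "mealvoice_value_error")
  strong_track(start_s, end_s, vapply(parts, `[[`, "", 3L), clip_id = clip_id)
}

#' @rdname read_track
#' @param track a [strong_track]
#' @export
write_track <- function(track, path) {
  stopifnot(inherits(track, "strong_track"))
  lines <- sprintf("%.6f\t%.6f\t%s", track$start_s, track$end_s, track$symbol)
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a token vocabulary
#'
#' One token per line; the first line must be the blank symbol `"_"`.
#'
#' @param path path to a vocabulary file
#' @return `read_vocab` returns a character vector with the blank first
#' @export
read_vocab <- function(path) {
  v <- readLines(path)
  if (!length(v) || v[1] != BLANK_SYMBOL)
    stop_mealvoice("vocabulary file must start with the blank symbol '_'",
                   "mealvoice_format_error")
  v
}

#' @rdname read_vocab
#' @param vocab character vector of tokens, blank first
#' @export
write_vocab <- function(vocab, path) {
  stopifnot(vocab[1] == BLANK_SYMBOL)
  writeLines(vocab, path)
  invisible(path)
}
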