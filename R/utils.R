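#' @keywords internal
"_PACKAGE"

## Reserved token symbols. "_" is the CTC blank and never appears in labels;
## "#" marks one chewing event, "$" one swallowing event, " " delimits
## concatenated utterances inside a synthetic mixture.
BLANK_SYMBOL <- "_"
CHEW_SYMBOL <- "#"
SWALLOW_SYMBOL <- "$"
SPACE_SYMBOL <- " "

#' Numerically stable log(sum(exp(x)))
#' @param x numeric vector
#' @return scalar
#' @keywords internal
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Evaluate code with a temporary RNG seed
#'
#' Saves and restores the global RNG state so that seeded package internals do
#' not disturb the caller's random stream.
#'
#' @param seed integer seed
#' @param code expression to evaluate
#' @return the value of `code`
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## Derive n child seeds from a master seed, all < 2^31.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_mealvoice <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "mealvoice_error")))
}
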