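#' Split a corpus into training and validation sets
#'
#' Deterministic 9:1 split by example count: `|train| = round(ratio * N)`.
#'
#' @param corpus a list of examples (any type)
#' @param ratio training fraction (default 0.9)
#' @param seed integer seed
#' @return list with `train` and `val` sub-lists
#' @export
split_train_val <- function(corpus, ratio = 0.9, seed = 1L) {
  n <- length(corpus)
  if (n < 2L)
    stop_mealvoice("need at least 2 examples to split", "mealvoice_param_error")
  n_train <- as.integer(round(ratio * n))
  perm <- with_seed(seed, sample.int(n))
  list(train = corpus[sort(perm[seq_len(n_train)])],
       val = corpus[sort(perm[-seq_len(n_train)])])
}

#' The seven comparative training protocols
#'
#' `A1`/`A2` are single-task baselines (speech-only / eating-only, one stage);
#' `B1`/`B2` are single-stage runs on the pooled independent data or the
#' synthetic corpus; `C1`--`C3` are two-stage runs that first adapt to speech
#' and then fine-tune on eating-only, pooled, or synthetic data respectively.
#'
#' @param id one of `"A1","A2","B1","B2","C1","C2","C3"`
#' @return a `protocol` with `stage1_data` and `stage2_data` corpus selectors
#' @export
protocol <- function(id) {
  defs <- list(
    A1 = list(stage1 = "speech", stage2 = NULL),
    A2 = list(stage1 = "eating", stage2 = NULL),
    B1 = list(stage1 = "both", stage2 = NULL),
    B2 = list(stage1 = "synthetic", stage2 = NULL),
    C1 = list(stage1 = "speech", stage2 = "eating"),
    C2 = list(stage1 = "speech", stage2 = "both"),
    C3 = list(stage1 = "speech", stage2 = "synthetic")
  )
  if (!id %in% names(defs))
    stop_mealvoice(sprintf("unknown protocol '%s'", id),
                   "mealvoice_config_error")
  structure(list(id = id, stage1_data = defs[[id]]$stage1,
                 stage2_data = defs[[id]]$stage2),
            class = "protocol")
}

## A training example: list(clip = mono audio_clip, weak = weak_seq).
## Frontend features are precomputed once per clip; the frontend stays fixed
## throughout a stage.
prep_examples <- function(model, examples) {
  lapply(examples, function(ex) {
    list(X = frontend_features(model, ex$clip),
         target = ex$weak$tokens)
  })
}

batch_loss_grads <- function(model, prepped, idx, train, dropout_seed) {
  Xs <- lapply(prepped[idx], `[[`, "X")
  rows <- vapply(Xs, nrow, 0L)
  X <- do.call(rbind, Xs)
  fw <- model_forward(model, X, train = train, dropout_seed = dropout_seed)
  dlogits <- matrix(0, nrow(X), ncol(fw$logp))
  total_nll <- 0
  total_tok <- 0L
  off <- 0L
  for (j in seq_along(idx)) {
    sl <- off + seq_len(rows[j])
    post <- posteriorgram(fw$logp[sl, , drop = FALSE], model$vocab,
                          model$enc$frame_stride_s)
    tgt <- prepped[[idx[j]]]$target
    res <- if (train) ctc_nll_grad(post, tgt)
           else list(nll = ctc_nll(post, tgt))
    if (is.nan(res$nll))
      stop_mealvoice(sprintf("NaN CTC loss in batch element %d (clip %d)",
                             j, idx[j]), "mealvoice_numeric_error")
    if (is.finite(res$nll)) {
      total_nll <- total_nll + res$nll
      total_tok <- total_tok + max(1L, length(tgt))
      if (train) dlogits[sl, ] <- res$grad
    }
    off <- off + rows[j]
  }
  list(fw = fw, dlogits = dlogits / length(idx), nll = total_nll,
       n_tok = total_tok)
}

## Momentum update of batch-norm running statistics from a training forward.
update_running_stats <- function(model, cache, momentum = 0.9) {
  for (l in seq_along(model$params$head)) {
    lay <- model$params$head[[l]]
    model$params$head[[l]]$run_mean <-
      momentum * lay$run_mean + (1 - momentum) * cache$bn[[l]]$mu
    model$params$head[[l]]$run_var <-
      momentum * lay$run_var + (1 - momentum) * cache$bn[[l]]$v
  }
  model
}

#' Train one fine-tuning stage
#'
#' Minibatch CTC training with the two-group optimizer recipe (AdaDelta head,
#' Adam encoder body; the frozen frontend receives no updates and no optimizer
#' state). After every epoch the validation loss is computed in evaluation
#' mode; learning rates anneal by their group factors whenever the relative
#' improvement over the previous epoch is below the configured threshold, and
#' the returned model is the checkpoint with the minimum validation loss.
#'
#' @param model a `ctc_model` whose vocabulary covers all target tokens
#' @param train,val lists of examples, each `list(clip =, weak =)`
#' @param optim an [optim_group_config]
#' @param epochs number of epochs (default 30)
#' @param batch_size minibatch size (default 8)
#' @param seed integer seed driving shuffling and dropout
#' @param verbose print per-epoch losses
#' @return list with `model` (best checkpoint), `history` (per-epoch
#'   data.frame) and `best_epoch`
#' @export
train_stage <- function(model, train, val, optim = optim_group_config(),
                        epochs = 30L, batch_size = 8L, seed = 1L,
                        verbose = FALSE) {
  stopifnot(inherits(model, "ctc_model"), length(train) >= 1L,
            length(val) >= 1L)
  for (ex in c(train, val)) {
    bad <- setdiff(ex$weak$tokens, model$vocab)
    if (length(bad))
      stop_mealvoice(sprintf("model vocabulary is missing target token(s): %s",
                             paste(unique(bad), collapse = " ")),
                     "mealvoice_config_error")
  }
  prepped_tr <- prep_examples(model, train)
  prepped_va <- prep_examples(model, val)
  flat_head <- flatten_params(model$params[c("head", "out")])
  flat_enc <- flatten_params(model$params["encoder"])
  ## The frontend is trained frozen here (its features are precomputed once);
  ## no optimizer state exists for it. The partition API still reports it
  ## trainable when frozen_frontend = FALSE, but stage training keeps it fixed.
  st_head <- adadelta_state(flat_head)
  st_enc <- adam_state(flat_enc)
  lr_head <- optim$head_lr
  lr_enc <- optim$encoder_lr
  seeds <- derive_seeds(seed, epochs * 2L)
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_loss = numeric(), lr_head = numeric(),
                     lr_encoder = numeric(), annealed = logical())
  best <- list(loss = Inf, params = model$params, epoch = 0L)
  prev_val <- NA_real_
  stalled <- 0L
  for (ep in seq_len(epochs)) {
    ord <- with_seed(seeds[2L * ep - 1L], sample(seq_along(prepped_tr)))
    batches <- split(ord, ceiling(seq_along(ord) / batch_size))
    drop_seeds <- derive_seeds(seeds[2L * ep], length(batches))
    ep_nll <- 0; ep_tok <- 0L
    for (bi in seq_along(batches)) {
      res <- batch_loss_grads(model, prepped_tr, batches[[bi]], TRUE,
                              drop_seeds[bi])
      ep_nll <- ep_nll + res$nll; ep_tok <- ep_tok + res$n_tok
      grads <- model_backward(model, res$fw$cache, res$dlogits)
      gh <- flatten_params(grads[c("head", "out")])
      ge <- flatten_params(grads["encoder"])
      up_h <- adadelta_step(flatten_params(model$params[c("head", "out")]),
                            gh, st_head, lr_head, optim$head_rho,
                            optim$head_eps)
      st_head <- up_h$state
      model$params <- unflatten_assign(model$params, up_h$params)
      up_e <- adam_step(flatten_params(model$params["encoder"]), ge, st_enc,
                        lr_enc)
      st_enc <- up_e$state
      model$params <- unflatten_assign(model$params, up_e$params)
      model <- update_running_stats(model, res$fw$cache)
    }
    val_nll <- 0; val_tok <- 0L
    for (j in seq_along(prepped_va)) {
      r <- batch_loss_grads(model, prepped_va, j, FALSE, 1L)
      val_nll <- val_nll + r$nll; val_tok <- val_tok + r$n_tok
    }
    train_loss <- ep_nll / max(1L, ep_tok)
    val_loss <- val_nll / max(1L, val_tok)
    annealed <- FALSE
    if (ep > 1L) {
      rel <- (prev_val - val_loss) / abs(prev_val)
      if (!is.finite(rel) || rel < optim$improvement_threshold) {
        stalled <- stalled + 1L
        if (stalled > optim$anneal_patience) {
          lr_head <- lr_head * optim$anneal_factor_head
          lr_enc <- lr_enc * optim$anneal_factor_encoder
          annealed <- TRUE
          stalled <- 0L
        }
      } else {
        stalled <- 0L
      }
    }
    prev_val <- val_loss
    if (val_loss < best$loss)
      best <- list(loss = val_loss, params = model$params, epoch = ep)
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = train_loss,
                                   val_loss = val_loss, lr_head = lr_head,
                                   lr_encoder = lr_enc, annealed = annealed))
    if (verbose)
      message(sprintf("epoch %d: train %.4f val %.4f lr %.3g/%.3g",
                      ep, train_loss, val_loss, lr_head, lr_enc))
  }
  model$params <- best$params
  list(model = model, history = hist, best_epoch = best$epoch)
}

#' Extend a model's vocabulary for second-stage fine-tuning
#'
#' Keeps all trained weights; output rows for the newly introduced tokens
#' (typically the chew/swallow event tokens) are initialized to small random
#' values.
#'
#' @param model a trained `ctc_model`
#' @param new_tokens character vector of tokens to add
#' @param seed integer seed for the new-row initialization
#' @return the extended `ctc_model`
#' @export
extend_vocab <- function(model, new_tokens, seed = 1L) {
  stopifnot(inherits(model, "ctc_model"))
  add <- setdiff(new_tokens, model$vocab)
  if (!length(add)) return(model)
  W <- model$params$out$W
  newW <- with_seed(seed, matrix(stats::rnorm(nrow(W) * length(add), sd = 0.01),
                                 nrow(W), length(add)))
  model$params$out$W <- cbind(W, newW)
  model$params$out$b <- c(model$params$out$b, numeric(length(add)))
  model$vocab <- c(model$vocab, add)
  model
}

#' Run one comparative protocol end to end
#'
#' Executes stage 1 (and, for C protocols, stage 2 resuming from the stage-1
#' best checkpoint with the vocabulary extended by any new event tokens), then
#' evaluates on the held-out test sets with the standard report columns
#' (character/token error rate, chew F1 at 0.05 s allowance, swallow F1 at
#' 0.01 s).
#'
#' @param p a [protocol] (or its id string)
#' @param corpora named list with `speech`, `eating`, `synthetic` training
#'   corpora (each a list of `list(clip =, weak =)` examples) and
#'   `test = list(speech =, eating =)` carrying references
#' @param seed integer seed
#' @param enc,head model configs (see [encoder_config()], [head_config()])
#' @param optim an [optim_group_config]
#' @param epochs,batch_size stage-1 training budget
#' @param epochs2 stage-2 epoch budget (default `epochs`); stage 2 adapts an
#'   already-trained model and typically needs fewer epochs
#' @param allow an [allowance_config] for event scoring
#' @param blank_bias initial blank bias passed to [build_model()]
#' @param stage1 optional pre-trained stage-1 result (from a previous
#'   `run_protocol` call with the same seed) to reuse for C protocols
#' @return list with `model`, `report`, `history` (per stage), `protocol`
#' @export
run_protocol <- function(p, corpora, seed = 1L,
                         enc = encoder_config(), head = head_config(),
                         optim = optim_group_config(), epochs = 30L,
                         batch_size = 8L, epochs2 = epochs,
                         allow = allowance_config(), blank_bias = 0,
                         stage1 = NULL) {
  if (is.character(p)) p <- protocol(p)
  stopifnot(inherits(p, "protocol"))
  pick_corpus <- function(sel) {
    out <- switch(sel,
                  speech = corpora$speech,
                  eating = corpora$eating,
                  synthetic = corpora$synthetic,
                  both = c(corpora$speech, corpora$eating))
    if (is.null(out) || !length(out))
      stop_mealvoice(sprintf("protocol %s needs the '%s' corpus", p$id, sel),
                     "mealvoice_config_error")
    out
  }
  corpus_vocab <- function(cor)
    c(BLANK_SYMBOL, sort(unique(unlist(lapply(cor, function(e) e$weak$tokens)))))
  seeds <- derive_seeds(seed, 6L)
  history <- list()
  if (is.null(stage1)) {
    cor1 <- pick_corpus(p$stage1_data)
    sp1 <- split_train_val(cor1, 0.9, seeds[1])
    m <- build_model(corpus_vocab(cor1), enc, head, seed = seeds[2],
                     blank_bias = blank_bias)
    s1 <- train_stage(m, sp1$train, sp1$val, optim, epochs, batch_size,
                      seed = seeds[3])
  } else {
    if (!is.null(p$stage2_data) && is.null(stage1$model))
      stop_mealvoice("stage-1 checkpoint required for C protocols",
                     "mealvoice_config_error")
    s1 <- stage1
  }
  history$stage1 <- s1$history
  model <- s1$model
  if (!is.null(p$stage2_data)) {
    cor2 <- pick_corpus(p$stage2_data)
    frame_rate_before <- model$enc$frame_stride_s
    vocab_before <- model$vocab
    model <- extend_vocab(model, corpus_vocab(cor2)[-1L], seed = seeds[4])
    stopifnot(identical(model$enc$frame_stride_s, frame_rate_before),
              identical(model$vocab[seq_along(vocab_before)], vocab_before))
    sp2 <- split_train_val(cor2, 0.9, seeds[5])
    s2 <- train_stage(model, sp2$train, sp2$val, optim, epochs2, batch_size,
                      seed = seeds[6])
    history$stage2 <- s2$history
    model <- s2$model
  }
  report <- evaluate_run(model, corpora$test$speech, corpora$test$eating,
                         allow)
  list(model = model, report = report, history = history, protocol = p$id)
}
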