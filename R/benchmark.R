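#' Toy configuration for desk-scale end-to-end runs
#'
#' The fixed conditions under which the comparative protocols are exercised on
#' a CPU: 4 kHz toy audio, a single 64-unit head block over a 64-dim surrogate
#' encoder, 24 spectral filters, minibatches of 4, 70 stage-1 epochs and 80
#' stage-2 epochs over augmentation-expanded corpora, with annealing patience
#' 10 (from-scratch surrogate training plateaus before CTC's symmetry
#' breaking; patience keeps the learning rate alive across the plateau). A
#' stage-1 run takes one to two minutes on one core; a stage-2 adaptation
#' under a minute. The CTC task stays nontrivial (variable-length tone
#' sequences, chew trains with repeated tokens) while remaining learnable
#' within the budget.
#'
#' @param sample_rate toy rate in Hz (default 4000)
#' @param n_speech,n_eating training pool sizes
#' @param n_test_speech,n_test_eating held-out clip counts
#' @param epochs stage-1 epochs (default 100)
#' @param epochs2 stage-2 epochs (default 40)
#' @param batch_size minibatch size (default 4)
#' @param seed master seed
#' @return a named list of configs consumed by [run_toy_benchmark()]
#' @export
toy_config <- function(sample_rate = 4000L, n_speech = 28L, n_eating = 18L,
                       n_test_speech = 8L, n_test_eating = 8L,
                       epochs = 70L, epochs2 = 80L, batch_size = 4L,
                       seed = 1L) {
  list(
    spec = toy_spec(sample_rate = sample_rate, tone_ms = 140, tokens_per_s = 5,
                    n_speech = n_speech, n_eating = n_eating, seed = seed),
    enc = encoder_config(feature_dim = 64L, n_filters = 24L, context = 2L,
                         sample_rate = sample_rate),
    head = head_config(n_layers = 1L, width = 64L, dropout_p = 0.15),
    n_test_speech = as.integer(n_test_speech),
    n_test_eating = as.integer(n_test_eating),
    epochs = as.integer(epochs), epochs2 = as.integer(epochs2),
    batch_size = as.integer(batch_size),
    blank_bias = 2.5,
    optim = optim_group_config(anneal_patience = 10L),
    seed = as.integer(seed)
  )
}

#' Build the three toy training corpora plus test sets
#'
#' Generates the toy pools, expands the direct training corpora with the
#' standard acoustic augmentations (speed 0.9/1.1, one time-dropout and one
#' frequency-dropout copy per clip — the same recipe applied to both domains
#' at full scale), and runs the synthetic-mixture generator over the original
#' pools, yielding the `speech`, `eating` and `synthetic` corpora the
#' comparative protocols select from.
#'
#' @param cfg a [toy_config()]
#' @return a `corpora` list accepted by [run_protocol()]
#' @export
build_toy_corpora <- function(cfg) {
  ds <- gen_toy_dataset(cfg$spec, cfg$n_test_speech, cfg$n_test_eating)
  augmented <- function(items, base_seed) {
    seeds <- derive_seeds(base_seed, 2L * length(items))
    out <- list()
    for (i in seq_along(items)) {
      it <- items[[i]]
      sp <- augment_spec(time_dropout_max_s = 0.2, freq_dropout_bands = 1L,
                         rng_seed = seeds[2L * i - 1L])
      sp2 <- augment_spec(time_dropout_max_s = 0.2, freq_dropout_bands = 1L,
                          rng_seed = seeds[2L * i])
      out <- c(out, list(
        list(clip = it$clip, weak = it$weak, strong = it$strong),
        list(clip = speed_perturb(it$clip, 0.9), weak = it$weak),
        list(clip = speed_perturb(it$clip, 1.1), weak = it$weak),
        list(clip = time_dropout(it$clip, sp), weak = it$weak),
        list(clip = freq_dropout(it$clip, sp2), weak = it$weak)
      ))
    }
    out
  }
  seeds <- derive_seeds(cfg$seed + 1L, 3L)
  synth <- build_corpus(ds$speech, ds$eating,
                        target_dur_s = 10, seed = seeds[1])
  list(
    speech = augmented(ds$speech, seeds[2]),
    eating = augmented(ds$eating, seeds[3]),
    synthetic = lapply(synth$examples, function(ex)
      list(clip = ex$clip, weak = ex$weak, strong = ex$strong)),
    test = ds$test,
    synth_balance = synth$balance
  )
}

#' Run the comparative-protocol toy benchmark
#'
#' Executes the qualitative replication of the comparative study at toy
#' scale: A1 (speech-only baseline), A2 (eating-only baseline), then the
#' two-stage protocols C1 (stage-2 eating only, which overwrites the
#' linguistic representations) and C3 (stage-2 synthetic mixtures, which
#' preserves them), all sharing A1's stage-1 checkpoint. Reports token error
#' rates and per-class event F1.
#'
#' @param seed master seed
#' @param cfg a [toy_config()]; its `seed` is overridden by `seed`
#' @param protocols which protocols to run (default the four used in the
#'   qualitative comparison)
#' @param verbose print stage progress
#' @return list of per-protocol results plus a `summary` data.frame with
#'   columns `protocol`, `token_error`, `chew_f1`, `swallow_f1`
#' @export
run_toy_benchmark <- function(seed = 1L, cfg = toy_config(seed = seed),
                              protocols = c("A1", "A2", "C1", "C3"),
                              verbose = FALSE) {
  cfg$seed <- as.integer(seed)
  cfg$spec$seed <- as.integer(seed)
  corpora <- build_toy_corpora(cfg)
  res <- list()
  stage1_speech <- NULL
  for (pid in protocols) {
    if (verbose) message("protocol ", pid)
    p <- protocol(pid)
    reuse <- if (!is.null(p$stage2_data) && p$stage1_data == "speech" &&
                 !is.null(stage1_speech)) stage1_speech else NULL
    r <- run_protocol(p, corpora, seed = seed, enc = cfg$enc, head = cfg$head,
                      optim = cfg$optim, epochs = cfg$epochs,
                      batch_size = cfg$batch_size, epochs2 = cfg$epochs2,
                      blank_bias = cfg$blank_bias, stage1 = reuse)
    if (pid == "A1")
      stage1_speech <- list(model = r$model, history = r$history$stage1)
    res[[pid]] <- r
  }
  summary <- do.call(rbind, lapply(names(res), function(pid) {
    rep <- res[[pid]]$report
    data.frame(protocol = pid, token_error = rep$cer, chew_f1 = rep$chew_f1,
               swallow_f1 = rep$swallow_f1, stringsAsFactors = FALSE)
  }))
  list(results = res, summary = summary, balance = corpora$synth_balance,
       seed = seed)
}
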