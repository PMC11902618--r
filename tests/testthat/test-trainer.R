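test_that("split_train_val applies the 9:1 rounding rule", {
  sp <- split_train_val(as.list(1:10), 0.9, seed = 1L)
  expect_length(sp$train, 9L)
  expect_length(sp$val, 1L)
  # corpus-scale arithmetic: 35,177 -> 31,659 / 3,518
  expect_equal(as.integer(round(0.9 * 35177)), 31659L)
  expect_equal(35177L - as.integer(round(0.9 * 35177)), 3518L)
  # deterministic and a disjoint cover
  sp2 <- split_train_val(as.list(1:10), 0.9, seed = 1L)
  expect_identical(sp, sp2)
  expect_setequal(c(unlist(sp$train), unlist(sp$val)), 1:10)
  expect_error(split_train_val(list(1)), class = "mealvoice_param_error")
})

test_that("annealing follows the 0.8/0.9 closed form at <0.25% improvement", {
  opt <- optim_group_config()
  # flat validation losses: anneal after epochs 2 and 3
  h <- anneal_schedule(c(10, 10, 10), opt)
  expect_equal(h$lr_head, c(1.0, 0.8, 0.64))
  expect_equal(h$lr_encoder, c(1e-4, 0.9e-4, 0.81e-4))
  expect_equal(h$annealed, c(FALSE, TRUE, TRUE))
  # strictly improving by >= 0.3% per epoch: never anneal
  losses <- 10 * cumprod(c(1, rep(0.997, 5)))
  h2 <- anneal_schedule(losses, opt)
  expect_false(any(h2$annealed))
  expect_equal(tail(h2$lr_head, 1), 1.0)
  # mixed script: anneal exactly where relative improvement < 0.25%
  h3 <- anneal_schedule(c(10, 9.9, 9.89, 9.0), opt)
  expect_equal(h3$annealed, c(FALSE, FALSE, TRUE, FALSE))
  expect_equal(h3$lr_head, c(1, 1, 0.8, 0.8))
})

test_that("train_stage histories follow the annealing rule and pick argmin", {
  spec <- tiny_toy_spec(seed = 3L)
  exs <- lapply(1:6, function(i) {
    g <- gen_speech_clip(spec, sample(spec$vocab, 3), 1.2, seed = 50L + i)
    list(clip = g$clip, weak = g$weak)
  })
  m <- build_model(c("_", spec$vocab),
                   encoder_config(feature_dim = 16L, n_filters = 12L,
                                  context = 1L, sample_rate = 4000L),
                   head_config(1L, 12L, 0), seed = 5L)
  s <- train_stage(m, exs[1:4], exs[5:6], epochs = 4L, batch_size = 2L,
                   seed = 7L)
  h <- s$history
  expect_equal(nrow(h), 4L)
  # lr trace reproduces the pure annealing arithmetic on the same losses
  ref <- anneal_schedule(h$val_loss, optim_group_config())
  expect_equal(h$lr_head, ref$lr_head)
  expect_equal(h$lr_encoder, ref$lr_encoder)
  expect_equal(h$annealed, ref$annealed)
  # best checkpoint is the argmin of the validation losses
  expect_equal(s$best_epoch, which.min(h$val_loss))
  # determinism: same seeds, same history
  s2 <- train_stage(m, exs[1:4], exs[5:6], epochs = 4L, batch_size = 2L,
                    seed = 7L)
  expect_equal(s$history, s2$history)
  expect_equal(s$model$params, s2$model$params)
  # vocabulary coverage is enforced
  bad <- list(clip = exs[[1]]$clip, weak = weak_seq("z"))
  expect_error(train_stage(m, c(exs[1:3], list(bad)), exs[5:6], epochs = 1L),
               class = "mealvoice_config_error")
})

test_that("protocol table defines stages as specified", {
  expect_null(protocol("A1")$stage2_data)
  expect_null(protocol("B2")$stage2_data)
  expect_equal(protocol("A1")$stage1_data, "speech")
  expect_equal(protocol("A2")$stage1_data, "eating")
  expect_equal(protocol("B2")$stage1_data, "synthetic")
  # C1: speech then eating-only; C3: speech then synthetic
  expect_equal(protocol("C1")$stage1_data, "speech")
  expect_equal(protocol("C1")$stage2_data, "eating")
  expect_equal(protocol("C3")$stage2_data, "synthetic")
  expect_equal(protocol("C2")$stage2_data, "both")
  expect_error(protocol("D9"), class = "mealvoice_config_error")
})

test_that("extend_vocab preserves weights and adds small new rows", {
  m <- build_model(c("_", "a", "b"),
                   encoder_config(feature_dim = 8L, n_filters = 8L,
                                  context = 0L, sample_rate = 4000L),
                   head_config(1L, 8L, 0), seed = 2L)
  m2 <- extend_vocab(m, c("#", "$"), seed = 3L)
  expect_equal(m2$vocab, c("_", "a", "b", "#", "$"))
  expect_equal(m2$params$out$W[, 1:3], m$params$out$W)
  expect_lt(max(abs(m2$params$out$W[, 4:5])), 0.1)
  expect_equal(m2$params$out$b[4:5], c(0, 0))
  # idempotent on known tokens
  expect_identical(extend_vocab(m2, "#"), m2)
})

test_that("run_protocol executes stages and produces the report shape", {
  spec <- tiny_toy_spec(seed = 9L)
  ds <- gen_toy_dataset(spec, n_test_speech = 2L, n_test_eating = 2L)
  as_ex <- function(items) lapply(items, function(it)
    list(clip = it$clip, weak = it$weak, strong = it$strong))
  corpora <- list(speech = as_ex(ds$speech), eating = as_ex(ds$eating),
                  synthetic = as_ex(ds$eating), test = ds$test)
  enc <- encoder_config(feature_dim = 16L, n_filters = 12L, context = 1L,
                        sample_rate = 4000L)
  hd <- head_config(1L, 12L, 0)
  rA1 <- run_protocol("A1", corpora, seed = 1L, enc = enc, head = hd,
                      epochs = 2L, batch_size = 4L)
  expect_false(is.na(rA1$report$cer))
  expect_named(rA1$history, "stage1")
  # C protocol: two stages, event tokens enter the vocabulary in stage 2
  rC1 <- run_protocol("C1", corpora, seed = 1L, enc = enc, head = hd,
                      epochs = 2L, batch_size = 4L,
                      stage1 = list(model = rA1$model,
                                    history = rA1$history$stage1))
  expect_named(rC1$history, c("stage1", "stage2"))
  expect_true(all(c("#", "$") %in% rC1$model$vocab))
  expect_false(is.na(rC1$report$chew_f1))
  # C protocols refuse a missing stage-1 checkpoint handle
  expect_error(run_protocol("C1", corpora, seed = 1L, enc = enc, head = hd,
                            epochs = 2L, stage1 = list(model = NULL)),
               class = "mealvoice_config_error")
  # single-stage pooled protocol trains on both corpora at once
  rB1 <- run_protocol("B1", corpora, seed = 1L, enc = enc, head = hd,
                      epochs = 1L, batch_size = 4L)
  expect_true(all(c("#", "$") %in% rB1$model$vocab))
  expect_named(rB1$history, "stage1")
})
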