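make_item <- function(dur_s, domain, id, rate = 4000L, seed = 1L,
                      with_events = (domain == "eating")) {
  set.seed(seed)
  clip <- audio_clip(stats::runif(round(dur_s * rate), -0.9, 0.9), rate, id)
  if (with_events) {
    n_ev <- max(1L, floor(dur_s))
    st <- seq(0.2, dur_s - 0.3, length.out = n_ev)
    tr <- strong_track(st, st + 0.05, rep("#", n_ev), clip_id = id)
    source_item(clip, weak_from_strong(tr), domain, strong = tr, id = id)
  } else {
    toks <- sample(letters[1:5], max(1L, floor(dur_s * 2)), replace = TRUE)
    source_item(clip, weak_seq(toks, id), domain, id = id)
  }
}

test_that("pad_to_fixed embeds the source bit-exactly with split noise", {
  rate <- 4000L
  # exactly 10 s: no padding at all
  full <- make_item(10, "speech", "full", rate)
  ex <- pad_to_fixed(full, 10, seed = 3L)
  expect_identical(ex$clip$samples[1, ], full$clip$samples[1, ])
  expect_equal(ex$segments$placed_offset_s, 0)

  # 8 s: exactly 2 s of noise split across the ends
  it <- make_item(8, "eating", "e8", rate)
  ex2 <- pad_to_fixed(it, 10, noise_snr_db = 30, seed = 7L)
  expect_equal(n_samples(ex2$clip), 10L * rate)
  off_n <- round(ex2$segments$placed_offset_s * rate)
  expect_identical(ex2$clip$samples[1, (off_n + 1):(off_n + 8 * rate)],
                   it$clip$samples[1, ])
  expect_equal(10L * rate - 8L * rate, 2L * rate)  # pad budget
  # strong labels shift by the placement offset
  expect_equal(ex2$strong$start_s, it$strong$start_s + ex2$segments$placed_offset_s)
  # weak labels unchanged
  expect_equal(ex2$weak$tokens, it$weak$tokens)
  # over-long items are refused
  expect_error(pad_to_fixed(make_item(11, "speech", "x", rate), 10),
               class = "mealvoice_param_error")
  # explicit shift arithmetic: entry (1.0, 1.2) placed at 0.7 -> (1.7, 1.9)
  tr <- strong_track(1.0, 1.2, "#")
  expect_equal(shift_track(tr, 0.7)$start_s, 1.7)
  expect_equal(shift_track(tr, 0.7)$end_s, 1.9)
})

test_that("assemble_mixture concatenates weak labels and fills gaps", {
  rate <- 4000L
  sp <- make_item(3, "speech", "s3", rate, seed = 2L)
  ea <- make_item(4, "eating", "e4", rate, seed = 3L)
  ex <- assemble_mixture(list(sp, ea), 10, seed = 5L)
  expect_equal(n_samples(ex$clip), 10L * rate)
  expect_equal(ex$weak$tokens, c(sp$weak$tokens, ea$weak$tokens))
  expect_equal(nrow(ex$segments), 2L)
  # both sources embedded bit-exactly at their recorded offsets
  for (i in 1:2) {
    it <- list(sp, ea)[[i]]
    o <- round(ex$segments$placed_offset_s[i] * rate)
    expect_identical(ex$clip$samples[1, (o + 1):(o + n_samples(it$clip))],
                     it$clip$samples[1, ])
  }
  # segments non-overlapping, increasing
  expect_true(ex$segments$placed_offset_s[2] >=
                ex$segments$placed_offset_s[1] + 3)
  # eating strong labels carried over, shifted
  expect_equal(nrow(ex$strong), nrow(ea$strong))
  expect_equal(ex$strong$start_s,
               ea$strong$start_s + ex$segments$placed_offset_s[2])

  # space token between two adjacent speech items
  sp2 <- make_item(2, "speech", "s2", rate, seed = 6L)
  ex2 <- assemble_mixture(list(sp, sp2), 10, seed = 8L)
  expect_equal(ex2$weak$tokens,
               c(sp$weak$tokens, " ", sp2$weak$tokens))

  # degenerate single 10 s item behaves like the no-pad case
  full <- make_item(10, "speech", "full", rate)
  exf <- assemble_mixture(list(full), 10, seed = 2L)
  expect_identical(exf$clip$samples[1, ], full$clip$samples[1, ])

  expect_error(assemble_mixture(list(), 10), class = "mealvoice_param_error")
  expect_error(assemble_mixture(list(sp, make_item(9, "eating", "e9", rate)), 10),
               class = "mealvoice_param_error")
})

test_that("build_corpus balances domains, consumes every item, splits 9:1", {
  rate <- 4000L
  speech <- lapply(1:7, function(i) make_item(5, "speech", paste0("s", i),
                                              rate, seed = 10 + i))
  eating <- lapply(1:7, function(i) make_item(5, "eating", paste0("e", i),
                                              rate, seed = 20 + i))
  corp <- build_corpus(speech, eating, target_dur_s = 10, seed = 42L)
  # every example exactly 10 s
  for (ex in corp$examples)
    expect_equal(n_samples(ex$clip), 10L * rate)
  # balance within 10% of the 1:1 target
  expect_lte(abs(corp$balance[["speech"]] - corp$balance[["eating"]]) /
               sum(corp$balance), 0.1)
  # every source item consumed at least once
  used <- unique(unlist(lapply(corp$examples, function(ex) ex$segments$source_id)))
  expect_setequal(used, c(paste0("s", 1:7), paste0("e", 1:7)))
  # split is a disjoint 9:1 cover by count
  n <- length(corp$examples)
  expect_equal(length(corp$train), round(0.9 * n))
  expect_equal(sort(c(corp$train, corp$val)), seq_len(n))
  # determinism: identical manifests for the same seed
  corp2 <- build_corpus(speech, eating, target_dur_s = 10, seed = 42L)
  expect_equal(lapply(corp$examples, `[[`, "segments"),
               lapply(corp2$examples, `[[`, "segments"))
  expect_identical(corp$examples[[3]]$clip$samples,
                   corp2$examples[[3]]$clip$samples)

  # threshold case: two 8 s items -> two single-segment padded examples
  long2 <- build_corpus(list(make_item(8, "speech", "L1", rate)),
                        list(make_item(8, "eating", "L2", rate)),
                        seed = 1L)
  expect_length(long2$examples, 2L)
  expect_true(all(vapply(long2$examples, function(e) nrow(e$segments), 0L) == 1L))

  expect_error(build_corpus(list(), eating), class = "mealvoice_config_error")
})

test_that("weak-label order equals temporal segment order in mixtures", {
  rate <- 4000L
  set.seed(31)
  for (k in 1:10) {
    items <- lapply(1:3, function(i)
      make_item(stats::runif(1, 1.5, 3), sample(c("speech", "eating"), 1),
                sprintf("m%d_%d", k, i), rate, seed = 100 * k + i))
    ex <- assemble_mixture(items, 10, seed = 7L + k)
    expect_equal(ex$weak$tokens[ex$weak$tokens != " "],
                 unlist(lapply(items, function(it) it$weak$tokens)))
    expect_false(is.unsorted(ex$segments$placed_offset_s))
    # eating strong entries appear in offset order too
    if (nrow(ex$strong)) expect_false(is.unsorted(ex$strong$start_s))
  }
})
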