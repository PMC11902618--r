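test_that("character_error_rate matches the DP edit-distance oracle", {
  expect_equal(character_error_rate("abc", "abc"), 0)
  expect_equal(character_error_rate("abc", ""), 1)
  expect_equal(character_error_rate("kitten", "sitting"), 0.5)
  expect_error(character_error_rate("", "abc"), class = "mealvoice_value_error")
  # event tokens and blanks are stripped before comparison
  expect_equal(character_error_rate(c("a", "#", "b"), c("a", "$", "b")), 0)
  expect_error(character_error_rate(c("#", "$"), "ab"),
               class = "mealvoice_value_error")
  # random pairs against utils::adist as the independent oracle
  set.seed(17)
  for (i in 1:100) {
    r <- paste(sample(letters[1:4], sample(1:9, 1), replace = TRUE),
               collapse = "")
    h <- paste(sample(letters[1:4], sample(0:9, 1), replace = TRUE),
               collapse = "")
    expect_equal(character_error_rate(r, h),
                 as.numeric(utils::adist(r, h)) / nchar(r))
  }
})

test_that("character_error_rate obeys the triangle-style bound", {
  set.seed(23)
  strs <- replicate(30, paste(sample(letters[1:3], sample(1:7, 1),
                                     replace = TRUE), collapse = ""))
  for (i in 1:30) {
    abc <- sample(strs, 3)
    a <- abc[1]; b <- abc[2]; co <- abc[3]
    lhs <- character_error_rate(a, co) * nchar(a)
    rhs <- character_error_rate(a, b) * nchar(a) + as.numeric(utils::adist(b, co))
    expect_lte(lhs, rhs + 1e-9)
  }
})

test_that("match_events applies per-class collars with greedy consumption", {
  cfg <- allowance_config()
  # direct overlap inside a chew entry
  m <- match_events(data.frame(class = "#", onset_s = 1.00, offset_s = 1.02),
                    strong_track(1.01, 1.30, "#"), cfg)
  expect_equal(unname(m$counts[["#"]]["tp"]), 1L)
  expect_equal(unname(m$counts[["#"]]["fp"]), 0L)
  expect_equal(unname(m$counts[["#"]]["fn"]), 0L)

  # swallow collar 0.01: prediction ending at 1.005 overlaps [0.99, ...)
  m2 <- match_events(data.frame(class = "$", onset_s = 0.985, offset_s = 1.005),
                     strong_track(1.00, 1.20, "$"), cfg)
  expect_equal(unname(m2$counts[["$"]]["tp"]), 1L)
  # but a swallow prediction ending before the collar misses
  m2b <- match_events(data.frame(class = "$", onset_s = 0.96, offset_s = 0.98),
                      strong_track(1.00, 1.20, "$"), cfg)
  expect_equal(unname(m2b$counts[["$"]]["tp"]), 0L)
  expect_equal(unname(m2b$counts[["$"]]["fp"]), 1L)
  expect_equal(unname(m2b$counts[["$"]]["fn"]), 1L)

  # one-to-one: two predictions inside one entry -> 1 TP + 1 FP
  m3 <- match_events(data.frame(class = c("#", "#"),
                                onset_s = c(1.05, 1.10),
                                offset_s = c(1.07, 1.12)),
                     strong_track(1.0, 1.3, "#"), cfg)
  expect_equal(unname(m3$counts[["#"]]["tp"]), 1L)
  expect_equal(unname(m3$counts[["#"]]["fp"]), 1L)

  # class mismatch is a FP plus a FN
  m4 <- match_events(data.frame(class = "$", onset_s = 1.05, offset_s = 1.07),
                     strong_track(1.0, 1.3, "#"), cfg)
  expect_equal(unname(m4$counts[["$"]]["fp"]), 1L)
  expect_equal(unname(m4$counts[["#"]]["fn"]), 1L)

  expect_error(match_events(data.frame(class = "x", onset_s = 0, offset_s = 1),
                            demo_track()), class = "mealvoice_value_error")
})

test_that("match_events count identities hold on random cases", {
  set.seed(41)
  cfg <- allowance_config()
  for (i in 1:100) {
    nt <- sample(0:6, 1)
    st <- sort(stats::runif(nt, 0, 8))
    truth <- strong_track(st, st + stats::runif(nt, 0.05, 0.4),
                          sample(c("#", "$"), nt, replace = TRUE))
    np <- sample(0:6, 1)
    on <- sort(stats::runif(np, 0, 8.5))
    preds <- data.frame(class = sample(c("#", "$"), np, replace = TRUE),
                        onset_s = on, offset_s = on + 0.02)
    m <- match_events(preds, truth, cfg)
    for (cl in c("#", "$")) {
      expect_equal(unname(m$counts[[cl]]["tp"] + m$counts[[cl]]["fn"]),
                   sum(truth$symbol == cl))
      expect_equal(unname(m$counts[[cl]]["tp"] + m$counts[[cl]]["fp"]),
                   sum(preds$class == cl))
    }
    # joint time shift leaves the result unchanged
    sh <- 2.37
    m2 <- match_events(transform(preds, onset_s = onset_s + sh,
                                 offset_s = offset_s + sh),
                       shift_track(truth, sh), cfg)
    expect_equal(m$counts, m2$counts)
  }
})

test_that("greedy TP count never exceeds the optimal bipartite matching", {
  # brute-force optimal one-to-one matcher on tiny cases
  optimal_tp <- function(preds, truth, cfg) {
    classes <- c("#", "$")
    tot <- 0L
    for (cl in classes) {
      p <- preds[preds$class == cl, , drop = FALSE]
      tr <- truth[truth$symbol == cl, , drop = FALSE]
      col <- if (cl == "#") cfg$chew_allowance_s else cfg$swallow_allowance_s
      if (!nrow(p) || !nrow(tr)) next
      ok <- outer(seq_len(nrow(p)), seq_len(nrow(tr)), function(i, j)
        p$onset_s[i] < tr$end_s[j] + col & p$offset_s[i] > tr$start_s[j] - col)
      best <- 0L
      # enumerate assignments of predictions to entries (small n)
      rec <- function(i, used) {
        if (i > nrow(p)) return(0L)
        most <- rec(i + 1L, used)  # leave unmatched
        for (j in seq_len(nrow(tr)))
          if (!used[j] && ok[i, j]) {
            u <- used; u[j] <- TRUE
            most <- max(most, 1L + rec(i + 1L, u))
          }
        most
      }
      tot <- tot + rec(1L, rep(FALSE, nrow(tr)))
    }
    tot
  }
  set.seed(53)
  cfg <- allowance_config()
  for (i in 1:40) {
    nt <- sample(1:4, 1); np <- sample(1:4, 1)
    st <- sort(stats::runif(nt, 0, 3))
    truth <- strong_track(st, st + stats::runif(nt, 0.05, 0.5),
                          sample(c("#", "$"), nt, replace = TRUE))
    on <- sort(stats::runif(np, 0, 3.5))
    preds <- data.frame(class = sample(c("#", "$"), np, replace = TRUE),
                        onset_s = on, offset_s = on + 0.02)
    m <- match_events(preds, truth, cfg)
    greedy_tp <- sum(vapply(m$counts, function(x) x[["tp"]], 0L))
    expect_lte(greedy_tp, optimal_tp(preds, truth, cfg))
  }
})

test_that("F1 formula and degenerate cases", {
  mk <- function(tp, fp, fn) {
    structure(list(counts = list("#" = c(tp = tp, fp = fp, fn = fn),
                                 "$" = c(tp = 0L, fp = 0L, fn = 0L))),
              class = "event_match")
  }
  expect_equal(f1_scores(mk(10L, 0L, 0L))$f1[1], 1.0)
  expect_equal(f1_scores(mk(0L, 3L, 2L))$f1[1], 0.0)
  r <- f1_scores(mk(8L, 2L, 4L))
  expect_equal(r$precision[1], 0.8)
  expect_equal(r$recall[1], 2 / 3)
  expect_equal(r$f1[1], 2 * 0.8 * (2 / 3) / (0.8 + 2 / 3), tolerance = 1e-12)
})

test_that("F1 is monotone in the allowance", {
  set.seed(61)
  st <- sort(stats::runif(8, 0, 8))
  truth <- strong_track(st, st + 0.1, rep("#", 8))
  on <- sort(stats::runif(10, 0, 8.4))
  preds <- data.frame(class = "#", onset_s = on, offset_s = on + 0.02)
  prev <- -1
  for (a in seq(0, 0.2, by = 0.02)) {
    m <- match_events(preds, truth,
                      allowance_config(chew_allowance_s = a))
    f1 <- f1_scores(m)$f1[1]
    expect_gte(f1, prev - 1e-12)
    prev <- f1
  }
})
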