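vocab3 <- c("_", "a", "b")
vocab4 <- c("_", "a", "b", "c")

test_that("ctc_nll matches closed forms on degenerate instances", {
  # single frame, single token
  p <- matrix(c(0.3, 0.7, 0.0), 1, 3)
  post <- posteriorgram(log(p), vocab3)
  expect_equal(ctc_nll(post, "a"), -log(0.7), tolerance = 1e-12)
  # empty target: product of blank probabilities
  set.seed(2)
  q <- matrix(stats::rgamma(12, 1), 4, 3); q <- q / rowSums(q)
  post2 <- posteriorgram(log(q), vocab3)
  expect_equal(ctc_nll(post2, character()), -sum(log(q[, 1])),
               tolerance = 1e-10)
  # unalignable target yields a clean Inf, not NaN
  expect_identical(ctc_nll(post, c("a", "b")), Inf)
  expect_identical(ctc_nll(post2, c("a", "a", "a")), Inf)
  # blanks are rejected as targets
  expect_error(ctc_nll(post, "_"), class = "mealvoice_value_error")
  expect_error(ctc_nll(post, "z"), class = "mealvoice_value_error")
})

test_that("ctc_nll equals exhaustive path enumeration on small instances", {
  # T=3, V=3, target 'ab': all 27 paths
  set.seed(7)
  post <- random_post(3, vocab3, seed = 7)
  expect_equal(ctc_nll(post, c("a", "b")),
               -log(brute_ctc_prob(post, c("a", "b"))), tolerance = 1e-8)
  # randomized sweep across shapes
  set.seed(99)
  for (i in 1:40) {
    T_ <- sample(1:5, 1)
    V <- sample(2:4, 1)
    voc <- c("_", letters[seq_len(V - 1)])
    post <- random_post(T_, voc, seed = 1000 + i)
    L <- sample(0:min(3, T_), 1)
    target <- if (L) sample(voc[-1], L, replace = TRUE) else character()
    expected <- brute_ctc_prob(post, target)
    got <- ctc_nll(post, target)
    if (expected == 0) expect_identical(got, Inf)
    else expect_equal(got, -log(expected), tolerance = 1e-8)
  }
})

test_that("ctc_nll decreases when target-consistent probabilities grow", {
  post <- random_post(4, vocab3, seed = 5)
  base <- ctc_nll(post, c("a", "b"))
  p <- exp(post$logp)
  p[2, 2] <- p[2, 2] * 1.5   # boost 'a' at frame 2
  p <- p / rowSums(p)
  expect_lt(ctc_nll(posteriorgram(log(p), vocab3), c("a", "b")), base)
})

test_that("ctc gradient matches central finite differences", {
  set.seed(13)
  for (trial in 1:5) {
    T_ <- sample(2:5, 1)
    z <- matrix(stats::rnorm(T_ * 3), T_, 3)
    logp <- z - apply(z, 1, function(r) log(sum(exp(r))))
    target <- sample(c("a", "b"), sample(1:2, 1), replace = TRUE)
    post <- posteriorgram(logp, vocab3)
    g <- ctc_nll_grad(post, target)
    if (!is.finite(g$nll)) next
    eps <- 1e-6
    nll_of <- function(zz) {
      lp <- zz - apply(zz, 1, function(r) log(sum(exp(r))))
      ctc_nll(posteriorgram(lp, vocab3), target)
    }
    for (k in sample(length(z), 4)) {
      zp <- z; zp[k] <- zp[k] + eps
      zm <- z; zm[k] <- zm[k] - eps
      fd <- (nll_of(zp) - nll_of(zm)) / (2 * eps)
      expect_equal(g$grad[k], fd, tolerance = 1e-5)
    }
  }
})

test_that("best_path_decode collapses repeats and removes blanks", {
  mk <- function(idx, V = 3) {
    lp <- matrix(log(0.1 / (V - 1)), length(idx), V)
    lp[cbind(seq_along(idx), idx)] <- log(0.9)
    posteriorgram(lp - log(rowSums(exp(lp))), vocab3[seq_len(V)])
  }
  d <- best_path_decode(mk(c(1, 2, 2, 1, 2)))  # _ a a _ a
  expect_equal(d$tokens, c("a", "a"))
  expect_equal(d$frames, c(1L, 4L))
  expect_equal(d$frame_times, c(0.02, 0.08))

  expect_length(best_path_decode(mk(c(1, 1, 1)))$tokens, 0L)

  d2 <- best_path_decode(mk(c(2, 2, 1, 2)))  # a a _ a
  expect_equal(d2$tokens, c("a", "a"))
  expect_equal(d2$frames, c(0L, 3L))

  # argmax ties break toward the lowest index (blank first)
  tie <- posteriorgram(matrix(log(1 / 3), 2, 3), vocab3)
  expect_length(best_path_decode(tie)$tokens, 0L)
})

test_that("prefix beam search matches brute force with saturating beam", {
  off <- beam_config(beam_width = 1000L, logp_prune = -Inf,
                     token_logp_min = -Inf)
  # T = 1 degenerate case
  p1 <- random_post(1, vocab3, seed = 3)
  d1 <- prefix_beam_search(p1, off)
  b1 <- brute_best_labeling(p1)
  expect_equal(d1$tokens, b1$tokens)
  expect_equal(d1$score, log(b1$prob), tolerance = 1e-9)
  # randomized sweep, T <= 4, V <= 3
  for (i in 1:30) {
    T_ <- sample(2:4, 1)
    post <- random_post(T_, vocab3, seed = 500 + i)
    dec <- prefix_beam_search(post, off)
    ref <- brute_best_labeling(post)
    expect_equal(log(ref$prob), dec$score, tolerance = 1e-9)
    expect_equal(ref$tokens, dec$tokens)
  }
})

test_that("beam search pruning behaves as configured", {
  post <- random_post(5, vocab4, seed = 77)
  # score is non-decreasing in beam width
  prev <- -Inf
  for (w in c(1L, 2L, 5L, 20L, 200L)) {
    s <- prefix_beam_search(post, beam_config(beam_width = w,
                                              logp_prune = -Inf,
                                              token_logp_min = -Inf))$score
    expect_gte(s, prev - 1e-12)
    prev <- s
  }
  # token_logp_min = 0 expands only certainty-1 tokens: empty on diffuse input
  d <- prefix_beam_search(post, beam_config(token_logp_min = 0))
  expect_length(d$tokens, 0L)
  # default paper parameters run fine
  d2 <- prefix_beam_search(post, beam_config())
  expect_true(is.finite(d2$score))
})

test_that("peaks_to_events converts decoded peaks to 20 ms intervals", {
  dec <- decoded_seq(c("a", "#", "b", "$"), c(2L, 10L, 30L, 200L), -1)
  ev <- peaks_to_events(dec)
  expect_equal(ev$class, c("#", "$"))
  expect_equal(ev$onset_s, c(0.20, 4.00))
  expect_equal(ev$offset_s, c(0.22, 4.02))

  expect_equal(nrow(peaks_to_events(decoded_seq(c("a", "b"), c(1L, 5L), -1))),
               0L)
  # adjacent chews stay distinct events
  ev2 <- peaks_to_events(decoded_seq(c("#", "#"), c(10L, 12L), -1))
  expect_equal(nrow(ev2), 2L)
})

test_that("posteriorgram rows must cover the vocabulary", {
  expect_error(posteriorgram(matrix(0, 2, 2), vocab3))
  expect_error(posteriorgram(matrix(0, 2, 3), c("a", "_", "b")))
})
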