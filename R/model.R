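#' Encoder configuration
#'
#' The frame encoder turns a mono waveform into one feature vector per 20 ms
#' frame. The `surrogate` kind is a CPU-sized stand-in with the same frame
#' rate and freeze semantics as a large pretrained self-supervised encoder: a
#' fixed-stride spectral analysis, a bank of learnable spectral filters (the
#' "frontend", frozen by default like a pretrained feature extractor), context
#' stacking, and one trainable nonlinear projection layer (the encoder body,
#' updated by the encoder optimizer group). A `pretrained-ssl-adapter` seam is
#' accepted for externally supplied waveform-to-frame functions.
#'
#' @param kind `"surrogate"` or `"pretrained-ssl-adapter"`
#' @param frame_stride_s frame stride in seconds; must be 0.02 (evaluation
#'   assumes it)
#' @param feature_dim encoder output width (default 64)
#' @param frozen_frontend freeze the spectral filterbank parameters
#' @param n_filters number of spectral filters in the frontend (default 24)
#' @param context frames of context stacked on each side (default 2)
#' @param sample_rate expected input rate in Hz (default 16000)
#' @return an `encoder_config`
#' @export
encoder_config <- function(kind = "surrogate", frame_stride_s = 0.02,
                           feature_dim = 64L, frozen_frontend = TRUE,
                           n_filters = 24L, context = 2L,
                           sample_rate = 16000L) {
  stopifnot(kind %in% c("surrogate", "pretrained-ssl-adapter"))
  if (abs(frame_stride_s - 0.02) > 1e-12)
    stop_mealvoice("frame_stride_s must be 0.02 s", "mealvoice_param_error")
  structure(list(kind = kind, frame_stride_s = frame_stride_s,
                 feature_dim = as.integer(feature_dim),
                 frozen_frontend = isTRUE(frozen_frontend),
                 n_filters = as.integer(n_filters),
                 context = as.integer(context),
                 sample_rate = as.integer(sample_rate)),
            class = "encoder_config")
}

#' Head configuration
#'
#' The classification head appended to the encoder: `n_layers` fully connected
#' blocks (LeakyReLU activation, batch normalization, dropout), each of width
#' `width`, followed by a linear projection to the vocabulary. Defaults match
#' the full-scale recipe (4 layers of 1024 units, dropout 0.15); toy runs
#' shrink them via the config.
#'
#' @param n_layers number of hidden FC blocks (default 4)
#' @param width units per block (default 1024)
#' @param dropout_p dropout probability in `[0, 1)` (default 0.15)
#' @return a `head_config`
#' @export
head_config <- function(n_layers = 4L, width = 1024L, dropout_p = 0.15) {
  stopifnot(n_layers >= 1L, width >= 1L, dropout_p >= 0, dropout_p < 1)
  structure(list(n_layers = as.integer(n_layers), width = as.integer(width),
                 dropout_p = dropout_p),
            class = "head_config")
}

## Triangular filterbank rows over FFT bins (linear spacing above 100 Hz).
init_filterbank <- function(n_filters, n_bins, sample_rate) {
  nyq <- sample_rate / 2
  edges <- seq(100, nyq, length.out = n_filters + 2L)
  bin_freq <- seq(0, nyq, length.out = n_bins)
  FB <- matrix(0, n_filters, n_bins)
  for (i in seq_len(n_filters)) {
    lo <- edges[i]; ce <- edges[i + 1L]; hi <- edges[i + 2L]
    up <- (bin_freq - lo) / (ce - lo)
    dn <- (hi - bin_freq) / (hi - ce)
    FB[i, ] <- pmax(0, pmin(up, dn))
  }
  FB
}

#' Build a recognition model
#'
#' @param vocab character vector of tokens, blank first
#' @param enc an [encoder_config]
#' @param head a [head_config]
#' @param seed integer seed for weight initialization
#' @param blank_bias initial output bias for the blank token (default 0,
#'   giving near-uniform rows). A positive value starts training from a
#'   blank-dominant prior, which steers CTC training on event-train targets
#'   away from the degenerate all-event solution; the toy benchmark uses 2.5.
#' @return a `ctc_model`
#' @export
build_model <- function(vocab, enc = encoder_config(), head = head_config(),
                        seed = 1L, blank_bias = 0) {
  stopifnot(inherits(enc, "encoder_config"), inherits(head, "head_config"),
            vocab[1] == BLANK_SYMBOL)
  stride_n <- as.integer(round(enc$frame_stride_s * enc$sample_rate))
  n_bins <- stride_n %/% 2L + 1L
  in_dim <- enc$n_filters * (2L * enc$context + 1L)
  V <- length(vocab)
  with_seed(seed, {
    params <- list(
      frontend = list(FB = init_filterbank(enc$n_filters, n_bins,
                                           enc$sample_rate)),
      encoder = list(
        W = matrix(stats::rnorm(in_dim * enc$feature_dim,
                                sd = 1 / sqrt(in_dim)),
                   in_dim, enc$feature_dim),
        b = numeric(enc$feature_dim)
      ),
      head = lapply(seq_len(head$n_layers), function(l) {
        d_in <- if (l == 1L) enc$feature_dim else head$width
        list(W = matrix(stats::rnorm(d_in * head$width, sd = sqrt(2 / d_in)),
                        d_in, head$width),
             b = numeric(head$width),
             gamma = rep(1, head$width), beta = numeric(head$width),
             run_mean = numeric(head$width), run_var = rep(1, head$width))
      }),
      ## small but not vanishing: rows stay near-uniform at init while the
      ## feature->token pathway carries enough signal to localize quickly
      out = list(W = matrix(stats::rnorm(head$width * V,
                                         sd = 0.5 / sqrt(head$width)),
                            head$width, V),
                 b = c(blank_bias, numeric(V - 1L)))
    )
    structure(list(vocab = vocab, enc = enc, head = head, params = params,
                   version = "mealvoice-ckpt-1"),
              class = "ctc_model")
  })
}

#' @export
print.ctc_model <- function(x, ...) {
  cat(sprintf(
    "<ctc_model: |vocab| = %d, %d head layer(s) x %d, encoder dim %d, %d params>\n",
    length(x$vocab), x$head$n_layers, x$head$width, x$enc$feature_dim,
    count_params(x$params)))
  invisible(x)
}

## Frame spectral features: non-overlapping stride-length windows, Hann
## weighted, power spectrum [T x n_bins]. This fixed analysis plus the
## frontend filterbank plays the role of the frozen convolutional extractor.
frame_spectra <- function(model, clip) {
  stride_n <- as.integer(round(model$enc$frame_stride_s * clip$sample_rate))
  x <- clip$samples[1L, ]
  T_ <- length(x) %/% stride_n
  if (T_ < 1L)
    stop_mealvoice("clip shorter than one frame", "mealvoice_param_error")
  X <- matrix(x[seq_len(T_ * stride_n)], stride_n, T_)
  win <- 0.5 - 0.5 * cos(2 * pi * seq(0, stride_n - 1) / stride_n)
  sp <- stats::mvfft(X * win)
  n_bins <- stride_n %/% 2L + 1L
  t(Mod(sp[seq_len(n_bins), , drop = FALSE])^2)
}

## Frontend + context stacking -> [T x in_dim] input to the encoder body.
## Log filterbank energies are mean/variance normalized per clip (CMVN) so
## the downstream tanh projection operates in its linear range.
frontend_features <- function(model, clip) {
  P <- frame_spectra(model, clip)              # T x n_bins
  E <- log(P %*% t(model$params$frontend$FB) + 1e-8)
  mu <- colMeans(E)
  sd <- sqrt(colMeans(sweep(E, 2L, mu)^2)) + 1e-3
  E <- sweep(sweep(E, 2L, mu), 2L, sd, "/")
  ctx <- model$enc$context
  T_ <- nrow(E)
  cols <- lapply(-ctx:ctx, function(d) {
    idx <- pmin(pmax(seq_len(T_) + d, 1L), T_)
    E[idx, , drop = FALSE]
  })
  do.call(cbind, cols)
}

leaky_relu <- function(x, alpha = 0.01) {
  neg <- x < 0
  x[neg] <- alpha * x[neg]
  x
}

## Full forward pass. train = TRUE uses batch statistics and dropout (seeded
## by `dropout_seed`) and returns the cache needed for backprop.
model_forward <- function(model, X, train = FALSE, dropout_seed = 1L) {
  cache <- list(X = X)
  H <- tanh(sweep(X %*% model$params$encoder$W, 2L,
                  model$params$encoder$b, "+"))
  cache$H_enc <- H
  drop_masks <- list()
  bn <- list()
  A_in <- list()
  Z_list <- list()
  p <- model$head$dropout_p
  if (train && p > 0) rng <- derive_seeds(dropout_seed, model$head$n_layers)
  for (l in seq_len(model$head$n_layers)) {
    lay <- model$params$head[[l]]
    A_in[[l]] <- H
    Z <- sweep(H %*% lay$W, 2L, lay$b, "+")
    if (train) {
      mu <- colMeans(Z)
      v <- colMeans(sweep(Z, 2L, mu)^2)
    } else {
      mu <- lay$run_mean
      v <- lay$run_var
    }
    Zhat <- sweep(sweep(Z, 2L, mu), 2L, sqrt(v + 1e-5), "/")
    Y <- sweep(sweep(Zhat, 2L, lay$gamma, "*"), 2L, lay$beta, "+")
    bn[[l]] <- list(mu = mu, v = v, Zhat = Zhat, Z = Z)
    H <- leaky_relu(Y)
    cacheY <- Y
    if (train && p > 0) {
      mask <- with_seed(rng[l],
                        matrix(stats::runif(length(H)) >= p, nrow(H), ncol(H)))
      H <- H * mask / (1 - p)
      drop_masks[[l]] <- mask
    }
    Z_list[[l]] <- cacheY
  }
  logits <- sweep(H %*% model$params$out$W, 2L, model$params$out$b, "+")
  m <- apply(logits, 1L, max)
  logp <- logits - m - log(rowSums(exp(logits - m)))
  cache$A_in <- A_in; cache$bn <- bn; cache$Y <- Z_list
  cache$drop_masks <- drop_masks; cache$H_out <- H; cache$train <- train
  list(logits = logits, logp = logp, cache = cache)
}

## Backward pass from d loss / d logits; returns gradients shaped like params.
model_backward <- function(model, cache, dlogits) {
  g <- list(out = list(), head = vector("list", model$head$n_layers),
            encoder = list(), frontend = NULL)
  g$out$W <- crossprod(cache$H_out, dlogits)
  g$out$b <- colSums(dlogits)
  dH <- dlogits %*% t(model$params$out$W)
  p <- model$head$dropout_p
  n <- nrow(dlogits)
  for (l in rev(seq_len(model$head$n_layers))) {
    lay <- model$params$head[[l]]
    if (cache$train && p > 0) dH <- dH * cache$drop_masks[[l]] / (1 - p)
    Y <- cache$Y[[l]]
    dY <- dH * (0.01 + 0.99 * (Y > 0))
    Zhat <- cache$bn[[l]]$Zhat
    g$head[[l]]$gamma <- colSums(dY * Zhat)
    g$head[[l]]$beta <- colSums(dY)
    dZhat <- sweep(dY, 2L, lay$gamma, "*")
    if (cache$train) {
      sd_inv <- 1 / sqrt(cache$bn[[l]]$v + 1e-5)
      ## batch-norm backprop through batch statistics:
      ## dZ = sd_inv * (dZhat - mean(dZhat) - Zhat * mean(dZhat * Zhat))
      centered <- sweep(dZhat, 2L, colMeans(dZhat)) -
        Zhat * matrix(colMeans(dZhat * Zhat), n, ncol(dZhat), byrow = TRUE)
      dZ <- sweep(centered, 2L, sd_inv, "*")
    } else {
      dZ <- sweep(dZhat, 2L, 1 / sqrt(lay$run_var + 1e-5), "*")
    }
    g$head[[l]]$W <- crossprod(cache$A_in[[l]], dZ)
    g$head[[l]]$b <- colSums(dZ)
    dH <- dZ %*% t(lay$W)
  }
  dHenc <- dH * (1 - cache$H_enc^2)
  g$encoder$W <- crossprod(cache$X, dHenc)
  g$encoder$b <- colSums(dHenc)
  g
}

#' Score a clip into a posteriorgram
#'
#' Runs the full model on a mono clip in evaluation mode (running batch-norm
#' statistics, no dropout); deterministic for a given model and clip.
#'
#' @param model a `ctc_model` from [build_model()]
#' @param clip a mono [audio_clip] at the model's configured rate
#' @return a [posteriorgram] with one row per 20 ms frame
#' @export
forward_logprobs <- function(model, clip) {
  stopifnot(inherits(model, "ctc_model"), inherits(clip, "audio_clip"))
  if (n_channels(clip) != 1L)
    stop_mealvoice("forward_logprobs expects a mono clip",
                   "mealvoice_contract_error")
  X <- frontend_features(model, clip)
  fw <- model_forward(model, X, train = FALSE)
  posteriorgram(fw$logp, model$vocab, model$enc$frame_stride_s,
                clip$source_id)
}

#' Partition model parameters into frontend and rest
#'
#' Mirrors the freeze semantics of fine-tuning a pretrained encoder: the
#' frontend (spectral filterbank, the analogue of the convolutional feature
#' extractor) is flagged non-trainable when `frozen_frontend` is set; every
#' parameter appears in exactly one side of the partition.
#'
#' @param model a `ctc_model`
#' @return list with `frontend` (named params + `trainable` flag) and `rest`
#' @export
trainable_parameter_partition <- function(model) {
  stopifnot(inherits(model, "ctc_model"))
  list(
    frontend = list(params = model$params["frontend"],
                    trainable = !model$enc$frozen_frontend),
    rest = list(params = model$params[c("encoder", "head", "out")],
                trainable = TRUE)
  )
}

## Total number of scalar parameters in a params-shaped list.
count_params <- function(p) {
  if (is.list(p)) sum(vapply(p, count_params, 0)) else length(p)
}

#' Save / load a model checkpoint
#'
#' Single-file JSON archive holding the version tag, both configs, the
#' vocabulary and all weights.
#'
#' @param model a `ctc_model`
#' @param path destination path
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the restored `ctc_model`
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "ctc_model"))
  obj <- list(version = model$version, vocab = model$vocab,
              enc = unclass(model$enc), head = unclass(model$head),
              params = model$params)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(obj$version))
    stop_mealvoice("checkpoint is missing its version field",
                   "mealvoice_format_error")
  enc <- do.call(encoder_config, obj$enc)
  head_cfg <- head_config(obj$head$n_layers, obj$head$width, obj$head$dropout_p)
  m <- build_model(unlist(obj$vocab), enc, head_cfg, seed = 1L)
  restore <- function(tmpl, got) {
    if (is.matrix(tmpl))
      matrix(unlist(got), nrow(tmpl), ncol(tmpl), byrow = TRUE)
    else if (is.list(tmpl)) mapply(restore, tmpl, got, SIMPLIFY = FALSE)
    else as.numeric(unlist(got))
  }
  m$params <- restore(m$params, obj$params)
  m$version <- obj$version
  m
}
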