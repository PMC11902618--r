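#' Optimizer group configuration
#'
#' The two-group optimization recipe: the head (main model) is updated with
#' AdaDelta (learning rate 1.0, rho 0.95, eps 1e-8) and the encoder body with
#' Adam (learning rate 1e-4). Whenever the relative validation-loss
#' improvement over the previous epoch falls below `improvement_threshold`
#' (0.25%), each group's learning rate is multiplied by its annealing factor
#' (0.8 for the head, 0.9 for the encoder).
#'
#' @param head_lr,head_rho,head_eps AdaDelta hyperparameters for the head
#' @param encoder_lr Adam learning rate for the encoder body
#' @param anneal_factor_head,anneal_factor_encoder per-group annealing factors
#' @param improvement_threshold relative improvement below which to anneal
#' @param anneal_patience consecutive sub-threshold epochs tolerated before a
#'   rate cut (default 0: every sub-threshold epoch anneals, the full-scale
#'   recipe; the counter resets after each cut). From-scratch surrogate runs
#'   plateau before CTC's symmetry breaking and need a nonzero patience
#' @return an `optim_group_config`
#' @export
optim_group_config <- function(head_lr = 1.0, head_rho = 0.95,
                               head_eps = 1e-8, encoder_lr = 1e-4,
                               anneal_factor_head = 0.8,
                               anneal_factor_encoder = 0.9,
                               improvement_threshold = 0.0025,
                               anneal_patience = 0L) {
  stopifnot(anneal_factor_head > 0, anneal_factor_head < 1,
            anneal_factor_encoder > 0, anneal_factor_encoder < 1,
            improvement_threshold > 0, anneal_patience >= 0)
  structure(list(head_lr = head_lr, head_rho = head_rho, head_eps = head_eps,
                 encoder_lr = encoder_lr,
                 anneal_factor_head = anneal_factor_head,
                 anneal_factor_encoder = anneal_factor_encoder,
                 improvement_threshold = improvement_threshold,
                 anneal_patience = as.integer(anneal_patience)),
            class = "optim_group_config")
}

## Flatten a params-shaped nested list into a named list of numeric leaves.
flatten_params <- function(p, prefix = "") {
  out <- list()
  for (nm in names(p)) {
    key <- if (nzchar(prefix)) paste0(prefix, ".", nm) else nm
    if (is.list(p[[nm]])) out <- c(out, flatten_params(p[[nm]], key))
    else out[[key]] <- p[[nm]]
  }
  out
}

unflatten_assign <- function(p, flat) {
  for (key in names(flat)) {
    path <- strsplit(key, ".", fixed = TRUE)[[1]]
    p[[path]] <- flat[[key]]
  }
  p
}

adadelta_state <- function(flat) {
  list(Eg2 = lapply(flat, function(x) x * 0),
       Ed2 = lapply(flat, function(x) x * 0))
}

adadelta_step <- function(flat, grads, state, lr, rho, eps) {
  for (k in names(grads)) {
    g <- grads[[k]]
    state$Eg2[[k]] <- rho * state$Eg2[[k]] + (1 - rho) * g^2
    d <- -sqrt(state$Ed2[[k]] + eps) / sqrt(state$Eg2[[k]] + eps) * g
    state$Ed2[[k]] <- rho * state$Ed2[[k]] + (1 - rho) * d^2
    flat[[k]] <- flat[[k]] + lr * d
  }
  list(params = flat, state = state)
}

adam_state <- function(flat) {
  list(m = lapply(flat, function(x) x * 0),
       v = lapply(flat, function(x) x * 0), t = 0L)
}

adam_step <- function(flat, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (k in names(grads)) {
    g <- grads[[k]]
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g^2
    mhat <- state$m[[k]] / (1 - beta1^state$t)
    vhat <- state$v[[k]] / (1 - beta2^state$t)
    flat[[k]] <- flat[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = flat, state = state)
}

#' Learning-rate annealing schedule under scripted validation losses
#'
#' Pure arithmetic of the annealing rule: starting from the configured group
#' learning rates, after every epoch whose relative validation-loss
#' improvement over the previous epoch is below the threshold, both rates are
#' multiplied by their group factors. The first epoch never anneals (there is
#' no previous loss).
#'
#' @param val_losses numeric vector of per-epoch validation losses
#' @param optim an [optim_group_config]
#' @return data.frame with per-epoch `val_loss`, `annealed`, `lr_head`,
#'   `lr_encoder` (rates in force after that epoch's decision)
#' @export
anneal_schedule <- function(val_losses, optim = optim_group_config()) {
  stopifnot(inherits(optim, "optim_group_config"))
  lr_h <- optim$head_lr
  lr_e <- optim$encoder_lr
  stalled <- 0L
  n <- length(val_losses)
  out <- data.frame(epoch = seq_len(n), val_loss = val_losses,
                    annealed = FALSE, lr_head = NA_real_,
                    lr_encoder = NA_real_)
  for (i in seq_len(n)) {
    if (i > 1L) {
      rel <- (val_losses[i - 1L] - val_losses[i]) / abs(val_losses[i - 1L])
      if (!is.finite(rel) || rel < optim$improvement_threshold) {
        stalled <- stalled + 1L
        if (stalled > optim$anneal_patience) {
          lr_h <- lr_h * optim$anneal_factor_head
          lr_e <- lr_e * optim$anneal_factor_encoder
          out$annealed[i] <- TRUE
          stalled <- 0L
        }
      } else {
        stalled <- 0L
      }
    }
    out$lr_head[i] <- lr_h
    out$lr_encoder[i] <- lr_e
  }
  out
}
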