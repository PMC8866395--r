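# Compact neural-network engine: binary classifiers trained with Adam,
# minibatches, inverted dropout, L2 weight decay and early stopping. Each
# architecture supplies init/forward/backward closures over named parameter
# lists; gradients are hand-derived and verified against numerical
# differentiation in the test suite.

sigmoid <- function(z) 1 / (1 + exp(-z))

# numerically stable mean binary cross-entropy from logits
bce_loss <- function(z, y) {
  mean(pmax(z, 0) - z * y + log1p(exp(-abs(z))))
}

leaky_relu <- function(z, slope = 0) ifelse(z > 0, z, slope * z)
leaky_relu_grad <- function(z, slope = 0) ifelse(z > 0, 1, slope)

# inverted dropout mask with keep-scaling baked in
dropout_mask <- function(dim_, p) {
  if (p <= 0) return(NULL)
  array(stats::rbinom(prod(dim_), 1, 1 - p) / (1 - p), dim_)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (k in names(params)) {
    g <- grads[[k]]
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g^2
    mhat <- state$m[[k]] / (1 - beta1^state$t)
    vhat <- state$v[[k]] / (1 - beta2^state$t)
    step <- lr * mhat / (sqrt(vhat) + eps)
    if (is.null(dim(params[[k]]))) step <- as.vector(step)
    params[[k]] <- params[[k]] - step
  }
  list(params = params, state = state)
}

# L2 penalty and its gradient restricted to the weight (not bias) entries
l2_penalty <- function(params, weight_names, l2) {
  if (l2 <= 0) return(0)
  l2 / 2 * sum(vapply(weight_names, function(k) sum(params[[k]]^2), 0))
}

add_l2_grads <- function(grads, params, weight_names, l2) {
  if (l2 <= 0) return(grads)
  for (k in weight_names) grads[[k]] <- grads[[k]] + l2 * params[[k]]
  grads
}

# Generic minibatch training with early stopping on validation loss.
# arch: list(init, forward, backward, slice, n_obs, weight_names)
#   forward(params, input, training) -> list(logit, cache)
#   backward(params, cache, dlogit)  -> grads
# Returns list(params, history, epochs_run, best_epoch).
train_network <- function(arch, input, y, l2 = 0, lr = 1e-3,
                          batch_size = 32, max_epochs = 100, patience = 10,
                          val_input = NULL, val_y = NULL, val_frac = 0.1,
                          seed = 1L, min_epochs = 0) {
  n <- arch$n_obs(input)
  stopifnot(length(y) == n)
  with_seed(substream_seed(seed, 1L, salt = 31L), {
    params <- arch$init()
    if (is.null(val_input) && val_frac > 0 && max_epochs > 0) {
      # stratified internal validation carve-out for early stopping
      pos <- which(y == 1); neg <- which(y == 0)
      vidx <- c(sample(pos, max(1, round(val_frac * length(pos)))),
                sample(neg, max(1, round(val_frac * length(neg)))))
      val_input <- arch$slice(input, vidx); val_y <- y[vidx]
      keep <- setdiff(seq_len(n), vidx)
      input <- arch$slice(input, keep); y <- y[keep]
      n <- length(keep)
    }
    state <- adam_init(params)
    best <- list(loss = Inf, params = params, epoch = 0L)
    wait <- 0L
    history <- numeric(0)
    if (max_epochs > 0) {
      for (epoch in seq_len(max_epochs)) {
        ord <- sample(n)
        starts <- seq(1, n, by = batch_size)
        for (b in starts) {
          idx <- ord[b:min(b + batch_size - 1, n)]
          xb <- arch$slice(input, idx); yb <- y[idx]
          fw <- arch$forward(params, xb, training = TRUE)
          dlogit <- (sigmoid(fw$logit) - yb) / length(yb)
          grads <- arch$backward(params, fw$cache, dlogit)
          grads <- add_l2_grads(grads, params, arch$weight_names, l2)
          upd <- adam_step(params, grads, state, lr = lr)
          params <- upd$params; state <- upd$state
        }
        vloss <- if (!is.null(val_input)) {
          fw <- arch$forward(params, val_input, training = FALSE)
          bce_loss(fw$logit, val_y)
        } else {
          fw <- arch$forward(params, input, training = FALSE)
          bce_loss(fw$logit, y)
        }
        history <- c(history, vloss)
        if (vloss < best$loss - 1e-6) {
          best <- list(loss = vloss, params = params, epoch = epoch)
          wait <- 0L
        } else {
          wait <- wait + 1L
          if (wait >= patience && epoch >= min_epochs) break
        }
      }
    }
    list(params = best$params, history = history,
         epochs_run = length(history), best_epoch = best$epoch)
  })
}

predict_network <- function(arch, params, input) {
  arch$forward(params, input, training = FALSE)$logit
}
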