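# Dense feedforward classifier (DFNN). Hidden widths start at
# `initial_width` and halve per subsequent layer (floor 8); single-logit
# decision layer. ReLU activations (optionally leaky), inverted dropout on
# hidden activations.

mlp_widths <- function(initial_width, hidden_layers) {
  vapply(seq_len(hidden_layers),
         function(l) max(8L, as.integer(round(initial_width / 2^(l - 1)))),
         integer(1))
}

mlp_arch <- function(p_in, hidden_layers, initial_width, dropout = 0,
                     slope = 0) {
  widths <- if (hidden_layers > 0) mlp_widths(initial_width, hidden_layers)
            else integer(0)
  dims <- c(p_in, widths, 1L)
  L <- length(dims) - 1L
  wn <- paste0("W", seq_len(L))

  init <- function() {
    params <- list()
    for (l in seq_len(L)) {
      params[[paste0("W", l)]] <- matrix(
        stats::rnorm(dims[l] * dims[l + 1], sd = sqrt(2 / dims[l])),
        dims[l], dims[l + 1])
      params[[paste0("b", l)]] <- numeric(dims[l + 1])
    }
    params
  }

  forward <- function(params, X, training = FALSE) {
    h <- X
    cache <- list(h = list(h), z = list(), mask = list())
    for (l in seq_len(L)) {
      z <- h %*% params[[paste0("W", l)]]
      z <- sweep(z, 2, params[[paste0("b", l)]], "+")
      cache$z[[l]] <- z
      if (l < L) {
        h <- leaky_relu(z, slope)
        if (training && dropout > 0) {
          m <- dropout_mask(dim(h), dropout)
          h <- h * m
          cache$mask[[l]] <- m
        } else cache$mask[[l]] <- NULL
      } else h <- z
      cache$h[[l + 1]] <- h
    }
    list(logit = as.vector(h), cache = cache)
  }

  backward <- function(params, cache, dlogit) {
    grads <- list()
    delta <- matrix(dlogit, ncol = 1)
    for (l in L:1) {
      h_prev <- cache$h[[l]]
      grads[[paste0("W", l)]] <- crossprod(h_prev, delta)
      grads[[paste0("b", l)]] <- colSums(delta)
      if (l > 1) {
        delta <- delta %*% t(params[[paste0("W", l)]])
        mk <- if (length(cache$mask) >= l - 1) cache$mask[[l - 1]]
        if (!is.null(mk)) delta <- delta * mk
        delta <- delta * leaky_relu_grad(cache$z[[l - 1]], slope)
      }
    }
    grads
  }

  list(init = init, forward = forward, backward = backward,
       slice = function(X, idx) X[idx, , drop = FALSE],
       n_obs = function(X) nrow(X),
       weight_names = wn)
}
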