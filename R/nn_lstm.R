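# Bidirectional LSTM classifier over a fixed feature vector. The vector is
# reshaped into `seq_len` equal-width chunks (zero-padded), read by forward
# and backward LSTM passes; the two final hidden states are concatenated
# and fed to a dense head ending in a single-logit decision layer.
# Gate order in the packed weight matrices: input, forget, output, cell.

lstm_chunk <- function(X, seq_len_ = 8L) {
  n <- nrow(X); p <- ncol(X)
  d <- as.integer(ceiling(p / seq_len_))
  pad <- seq_len_ * d - p
  if (pad > 0) X <- cbind(X, matrix(0, n, pad))
  lapply(seq_len(seq_len_), function(t)
    X[, ((t - 1) * d + 1):(t * d), drop = FALSE])
}

# one-direction LSTM forward over a list of inputs; returns final h and cache
lstm_forward_dir <- function(xs, Wx, Wh, b, H) {
  n <- nrow(xs[[1]]); S <- length(xs)
  h <- matrix(0, n, H); cc <- matrix(0, n, H)
  cache <- vector("list", S)
  for (t in seq_len(S)) {
    a <- xs[[t]] %*% Wx + h %*% Wh
    a <- sweep(a, 2, b, "+")
    i <- sigmoid(a[, 1:H, drop = FALSE])
    f <- sigmoid(a[, H + 1:H, drop = FALSE])
    o <- sigmoid(a[, 2 * H + 1:H, drop = FALSE])
    g <- tanh(a[, 3 * H + 1:H, drop = FALSE])
    c_new <- f * cc + i * g
    tc <- tanh(c_new)
    h_new <- o * tc
    cache[[t]] <- list(x = xs[[t]], h_prev = h, c_prev = cc, i = i, f = f,
                       o = o, g = g, c = c_new, tc = tc)
    h <- h_new; cc <- c_new
  }
  list(h = h, cache = cache)
}

# backprop through one direction given dL/dh_final
lstm_backward_dir <- function(dh_final, cache, Wx, Wh, H) {
  S <- length(cache)
  n <- nrow(dh_final)
  dWx <- array(0, dim(Wx)); dWh <- array(0, dim(Wh)); db <- numeric(4 * H)
  dh <- dh_final; dc <- matrix(0, n, H)
  for (t in S:1) {
    cs <- cache[[t]]
    do_ <- dh * cs$tc
    dc <- dc + dh * cs$o * (1 - cs$tc^2)
    di <- dc * cs$g
    dg <- dc * cs$i
    df <- dc * cs$c_prev
    dc_prev <- dc * cs$f
    da <- cbind(di * cs$i * (1 - cs$i),
                df * cs$f * (1 - cs$f),
                do_ * cs$o * (1 - cs$o),
                dg * (1 - cs$g^2))
    dWx <- dWx + crossprod(cs$x, da)
    dWh <- dWh + crossprod(cs$h_prev, da)
    db <- db + colSums(da)
    dh <- da %*% t(Wh)
    dc <- dc_prev
  }
  list(dWx = dWx, dWh = dWh, db = db)
}

lstm_arch <- function(p_in, hidden_layers, initial_width, dropout = 0,
                      seq_len_ = 8L) {
  H <- as.integer(initial_width)
  d <- as.integer(ceiling(p_in / seq_len_))
  head_widths <- mlp_widths(initial_width, hidden_layers)
  head_dims <- c(2L * H, head_widths, 1L)
  Lh <- length(head_dims) - 1L
  wn <- c("Wx_f", "Wh_f", "Wx_b", "Wh_b", paste0("W", seq_len(Lh)))

  init <- function() {
    gl <- function(nr, nc, sd_) matrix(stats::rnorm(nr * nc, sd = sd_), nr, nc)
    params <- list(
      Wx_f = gl(d, 4 * H, sqrt(1 / d)), Wh_f = gl(H, 4 * H, sqrt(1 / H)),
      b_f = numeric(4 * H),
      Wx_b = gl(d, 4 * H, sqrt(1 / d)), Wh_b = gl(H, 4 * H, sqrt(1 / H)),
      b_b = numeric(4 * H))
    # forget-gate bias of 1 stabilizes early training
    params$b_f[H + 1:H] <- 1
    params$b_b[H + 1:H] <- 1
    for (l in seq_len(Lh)) {
      params[[paste0("W", l)]] <- gl(head_dims[l], head_dims[l + 1],
                                     sqrt(2 / head_dims[l]))
      params[[paste0("b", l)]] <- numeric(head_dims[l + 1])
    }
    params
  }

  forward <- function(params, X, training = FALSE) {
    xs <- lstm_chunk(X, seq_len_)
    xs_rev <- rev(xs)
    fwd <- lstm_forward_dir(xs, params$Wx_f, params$Wh_f, params$b_f, H)
    bwd <- lstm_forward_dir(xs_rev, params$Wx_b, params$Wh_b, params$b_b, H)
    h <- cbind(fwd$h, bwd$h)
    cache <- list(fwd = fwd$cache, bwd = bwd$cache,
                  h = list(h), z = list(), mask = list())
    if (training && dropout > 0) {
      m0 <- dropout_mask(dim(h), dropout)
      h <- h * m0
      cache$mask0 <- m0
      cache$h[[1]] <- h
    }
    for (l in seq_len(Lh)) {
      z <- sweep(h %*% params[[paste0("W", l)]], 2,
                 params[[paste0("b", l)]], "+")
      cache$z[[l]] <- z
      if (l < Lh) {
        h <- leaky_relu(z)
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
    for (l in Lh:1) {
      grads[[paste0("W", l)]] <- crossprod(cache$h[[l]], delta)
      grads[[paste0("b", l)]] <- colSums(delta)
      delta <- delta %*% t(params[[paste0("W", l)]])
      if (l > 1) {
        mk <- if (length(cache$mask) >= l - 1) cache$mask[[l - 1]]
        if (!is.null(mk)) delta <- delta * mk
        delta <- delta * leaky_relu_grad(cache$z[[l - 1]])
      }
    }
    if (!is.null(cache$mask0)) delta <- delta * cache$mask0
    dh_f <- delta[, 1:H, drop = FALSE]
    dh_b <- delta[, H + 1:H, drop = FALSE]
    gf <- lstm_backward_dir(dh_f, cache$fwd, params$Wx_f, params$Wh_f, H)
    gb <- lstm_backward_dir(dh_b, cache$bwd, params$Wx_b, params$Wh_b, H)
    grads$Wx_f <- gf$dWx; grads$Wh_f <- gf$dWh; grads$b_f <- gf$db
    grads$Wx_b <- gb$dWx; grads$Wh_b <- gb$dWh; grads$b_b <- gb$db
    grads
  }

  list(init = init, forward = forward, backward = backward,
       slice = function(X, idx) X[idx, , drop = FALSE],
       n_obs = function(X) nrow(X),
       weight_names = wn)
}
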