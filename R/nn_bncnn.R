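# Connectome CNN (BrainNetCNN-style): edge-to-edge convolutional blocks,
# an edge-to-node layer, a node-to-graph layer, then a single-logit
# decision layer. The edge-to-edge filter for input channel c and output
# filter f combines a row component r and a column component u:
#   O_f(i,j) = sum_c [ (A_c r_cf)_i + (A_c^T u_cf)_j ] + b_f
# Input is the square connectivity representation (n x R x R); covariates
# are appended at the graph-level vector. Leaky-ReLU activations with the
# configurable negative slope; dropout on node- and graph-level features.

# expand U (n x R x F) to (n, i, j, f) constant over j
expand_rows <- function(U, n, R, F_) {
  aperm(array(U, c(n, R, F_, R)), c(1, 2, 4, 3))
}
# expand V (n x R x F) to (n, i, j, f) constant over i
expand_cols <- function(V, n, R, F_) {
  aperm(array(V, c(n, R, F_, R)), c(1, 4, 2, 3))
}

bncnn_arch <- function(R, n_cov, e2e_blocks, width, dropout = 0,
                       slope = 0.33) {
  F_ <- as.integer(width)
  # channel counts entering each E2E block
  ch_in <- if (e2e_blocks > 0) c(1L, rep(F_, e2e_blocks - 1L)) else integer(0)
  e2n_in <- if (e2e_blocks > 0) F_ else 1L
  wn <- c(if (e2e_blocks > 0)
            as.vector(vapply(seq_len(e2e_blocks),
                             function(l) paste0(c("Wr", "Wu"), l), character(2))),
          "Wn", "Wg", "Wd")

  init <- function() {
    gl <- function(nr, nc, sd_) matrix(stats::rnorm(nr * nc, sd = sd_), nr, nc)
    params <- list()
    for (l in seq_len(e2e_blocks)) {
      C <- ch_in[l]
      params[[paste0("Wr", l)]] <- gl(R * C, F_, sqrt(1 / (R * C)))
      params[[paste0("Wu", l)]] <- gl(R * C, F_, sqrt(1 / (R * C)))
      params[[paste0("be", l)]] <- numeric(F_)
    }
    params$Wn <- gl(R * e2n_in, F_, sqrt(2 / (R * e2n_in)))
    params$bn <- numeric(F_)
    params$Wg <- gl(R * F_, F_, sqrt(2 / (R * F_)))
    params$bg <- numeric(F_)
    params$Wd <- gl(F_ + n_cov, 1L, sqrt(2 / (F_ + n_cov)))
    params$bd <- 0
    params
  }

  forward <- function(params, input, training = FALSE) {
    A <- input$A           # n x R x R array
    Xc <- input$cov        # n x n_cov matrix
    n <- dim(A)[1]
    act <- array(A, c(n, R, R, 1L))
    cache <- list(e2e = vector("list", e2e_blocks))
    for (l in seq_len(e2e_blocks)) {
      C <- dim(act)[4]
      Amat <- matrix(act, n * R, R * C)                 # rows (s,i), cols (k,c)
      Apm <- matrix(aperm(act, c(1, 3, 2, 4)), n * R, R * C) # rows (s,j)
      U <- Amat %*% params[[paste0("Wr", l)]]           # (s,i) x f
      V <- Apm %*% params[[paste0("Wu", l)]]            # (s,j) x f
      Z <- expand_rows(array(U, c(n, R, F_)), n, R, F_) +
           expand_cols(array(V, c(n, R, F_)), n, R, F_)
      Z <- sweep(Z, 4, params[[paste0("be", l)]], "+")
      out <- leaky_relu(Z, slope)
      cache$e2e[[l]] <- list(act_in = act, Z = Z)
      act <- out
    }
    C <- dim(act)[4]
    Omat <- matrix(act, n * R, R * C)                   # rows (s,i), cols (j,f)
    Nz <- sweep(Omat %*% params$Wn, 2, params$bn, "+")  # (s,i) x F
    Na <- leaky_relu(Nz, slope)
    maskN <- if (training && dropout > 0) dropout_mask(dim(Na), dropout)
    if (!is.null(maskN)) Na <- Na * maskN
    Nmat <- matrix(array(Na, c(n, R, F_)), n, R * F_)   # rows s, cols (i,f)
    Gz <- sweep(Nmat %*% params$Wg, 2, params$bg, "+")
    Ga <- leaky_relu(Gz, slope)
    maskG <- if (training && dropout > 0) dropout_mask(dim(Ga), dropout)
    if (!is.null(maskG)) Ga <- Ga * maskG
    Hfull <- cbind(Ga, Xc)
    logit <- as.vector(Hfull %*% params$Wd + params$bd)
    cache <- c(cache, list(act_top = act, Nz = Nz, maskN = maskN,
                           Nmat = Nmat, Gz = Gz, maskG = maskG,
                           Hfull = Hfull, n = n))
    list(logit = logit, cache = cache)
  }

  backward <- function(params, cache, dlogit) {
    n <- cache$n
    grads <- list()
    delta <- matrix(dlogit, ncol = 1)
    grads$Wd <- crossprod(cache$Hfull, delta)
    grads$bd <- sum(delta)
    dH <- delta %*% t(params$Wd)
    dGa <- dH[, 1:F_, drop = FALSE]
    if (!is.null(cache$maskG)) dGa <- dGa * cache$maskG
    dGz <- dGa * leaky_relu_grad(cache$Gz, slope)
    grads$Wg <- crossprod(cache$Nmat, dGz)
    grads$bg <- colSums(dGz)
    dNmat <- dGz %*% t(params$Wg)                       # n x (R*F)
    dNa <- matrix(array(dNmat, c(n, R, F_)), n * R, F_) # (s,i) x f
    if (!is.null(cache$maskN)) dNa <- dNa * cache$maskN
    dNz <- dNa * leaky_relu_grad(cache$Nz, slope)
    C_top <- dim(cache$act_top)[4]
    Omat <- matrix(cache$act_top, n * R, R * C_top)
    grads$Wn <- crossprod(Omat, dNz)
    grads$bn <- colSums(dNz)
    dOmat <- dNz %*% t(params$Wn)                        # (s,i) x (j,c)
    dact <- array(dOmat, c(n, R, R, C_top))
    for (l in rev(seq_len(e2e_blocks))) {
      cs <- cache$e2e[[l]]
      dZ <- dact * leaky_relu_grad(cs$Z, slope)
      grads[[paste0("be", l)]] <- colSums(matrix(dZ, n * R * R, F_))
      # dU[s,i,f] = sum_j dZ[s,i,j,f]; dV[s,j,f] = sum_i dZ[s,i,j,f]
      dU <- array(rowSums(matrix(aperm(dZ, c(1, 2, 4, 3)), n * R * F_, R)),
                  c(n, R, F_))
      dV <- array(rowSums(matrix(aperm(dZ, c(1, 3, 4, 2)), n * R * F_, R)),
                  c(n, R, F_))
      C <- dim(cs$act_in)[4]
      Amat <- matrix(cs$act_in, n * R, R * C)
      Apm <- matrix(aperm(cs$act_in, c(1, 3, 2, 4)), n * R, R * C)
      dUm <- matrix(dU, n * R, F_)
      dVm <- matrix(dV, n * R, F_)
      grads[[paste0("Wr", l)]] <- crossprod(Amat, dUm)
      grads[[paste0("Wu", l)]] <- crossprod(Apm, dVm)
      if (l > 1) {
        dA_U <- array(dUm %*% t(params[[paste0("Wr", l)]]), c(n, R, R, C))
        dAp <- array(dVm %*% t(params[[paste0("Wu", l)]]), c(n, R, R, C))
        dact <- dA_U + aperm(dAp, c(1, 3, 2, 4))
      }
    }
    grads
  }

  list(init = init, forward = forward, backward = backward,
       slice = function(input, idx)
         list(A = input$A[idx, , , drop = FALSE],
              cov = input$cov[idx, , drop = FALSE]),
       n_obs = function(input) dim(input$A)[1],
       weight_names = wn)
}

# Rebuild the square connectivity representation from edge-feature columns.
# Diagonal set to zero (the tangent vectorization excludes it).
edges_to_matrices <- function(X, kinds) {
  fn <- colnames(X)
  is_edge <- grepl("^edge_\\d+_\\d+$", fn)
  if (!is.null(kinds)) is_edge <- is_edge & kinds == "functional"
  if (!any(is_edge))
    stop("this model requires square connectivity input, but the feature ",
         "matrix contains no functional edge features")
  en <- fn[is_edge]
  ij <- do.call(rbind, lapply(strsplit(sub("^edge_", "", en), "_"),
                              as.integer))
  R <- max(ij)
  n <- nrow(X)
  A <- array(0, c(n, R, R))
  E <- X[, is_edge, drop = FALSE]
  for (e in seq_len(nrow(ij))) {
    A[, ij[e, 1], ij[e, 2]] <- E[, e]
    A[, ij[e, 2], ij[e, 1]] <- E[, e]
  }
  cov_cols <- which(!is_edge)
  list(A = A, cov = X[, cov_cols, drop = FALSE], R = R,
       edge_names = en)
}
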