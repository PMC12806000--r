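# Neural-network primitives: forward passes with cached intermediates and
# hand-derived backward passes.  Sequence tensors are stored time-major:
# a batch of B sequences of length L with E features is an (L*B) x E
# matrix whose rows ((t-1)*B+1):(t*B) hold the batch at position t.

tm_rows <- function(t, B) ((t - 1L) * B + 1L):(t * B)

# Fast row-wise bias add (avoids sweep's aperm).
add_bias <- function(M, b) M + rep(b, each = nrow(M))

# ---- initializers ------------------------------------------------------

glorot_uniform <- function(fan_in, fan_out, dims = c(fan_in, fan_out)) {
  s <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(prod(dims), -s, s), nrow = dims[1], ncol = dims[2])
}

# ---- dense -------------------------------------------------------------

dense_forward <- function(X, W, b) {
  list(Y = add_bias(X %*% W, b), X = X)
}

dense_backward <- function(cache, W, dY) {
  list(dX = dY %*% t(W), dW = crossprod(cache$X, dY), db = colSums(dY))
}

# ---- relu / dropout ----------------------------------------------------

relu_forward <- function(X) list(Y = pmax(X, 0), mask = X > 0)
relu_backward <- function(cache, dY) dY * cache$mask

dropout_forward <- function(X, rate, training) {
  if (!training || rate <= 0) {
    return(list(Y = X, mask = NULL))
  }
  mask <- matrix(
    stats::rbinom(length(X), 1, 1 - rate) / (1 - rate),
    nrow = nrow(X)
  )
  list(Y = X * mask, mask = mask)
}

dropout_backward <- function(cache, dY) {
  if (is.null(cache$mask)) dY else dY * cache$mask
}

# ---- embedding ---------------------------------------------------------

# tokens: B x L integer matrix (0 = pad); W: (V+1) x E with row 1 = pad.
# Output is time-major (L*B) x E.
embedding_forward <- function(tokens, W) {
  B <- nrow(tokens)
  L <- ncol(tokens)
  flat <- as.integer(tokens) # column-major: position-blocks of B, i.e. time-major
  list(Y = W[flat + 1L, , drop = FALSE], flat = flat, V1 = nrow(W))
}

embedding_backward <- function(cache, dY) {
  dW <- matrix(0, nrow = cache$V1, ncol = ncol(dY))
  agg <- rowsum(dY, group = cache$flat)
  rows <- as.integer(rownames(agg)) + 1L
  dW[rows, ] <- agg
  list(dW = dW)
}

# ---- 1D convolution over time-major sequences --------------------------

# X: (L*B) x E time-major; W: (k*E) x F; output (Lout*B) x F, Lout = L-k+1.
conv1d_forward <- function(X, W, b, B, L, k) {
  Lout <- L - k + 1L
  if (Lout < 1) stop_config("conv1d kernel longer than the sequence")
  cols <- vector("list", k)
  for (j in 0:(k - 1L)) {
    cols[[j + 1L]] <- X[(j * B + 1L):((Lout + j) * B), , drop = FALSE]
  }
  Xc <- do.call(cbind, cols)
  list(
    Y = add_bias(Xc %*% W, b),
    Xc = Xc, B = B, L = L, k = k, Lout = Lout, E = ncol(X)
  )
}

conv1d_backward <- function(cache, W, dY) {
  dW <- crossprod(cache$Xc, dY)
  db <- colSums(dY)
  dXc <- dY %*% t(W)
  B <- cache$B; k <- cache$k; Lout <- cache$Lout; E <- cache$E
  dX <- matrix(0, nrow = cache$L * B, ncol = E)
  for (j in 0:(k - 1L)) {
    rows <- (j * B + 1L):((Lout + j) * B)
    dX[rows, ] <- dX[rows, ] + dXc[, (j * E + 1L):((j + 1L) * E), drop = FALSE]
  }
  list(dX = dX, dW = dW, db = db)
}

# ---- global max pooling over sequence positions ------------------------

seq_max_pool_forward <- function(X, B, L) {
  F_ <- ncol(X)
  Y <- X[tm_rows(1L, B), , drop = FALSE]
  idx <- matrix(1L, nrow = B, ncol = F_)
  if (L > 1) {
    for (t in 2:L) {
      Xt <- X[tm_rows(t, B), , drop = FALSE]
      better <- Xt > Y
      Y[better] <- Xt[better]
      idx[better] <- t
    }
  }
  list(Y = Y, idx = idx, B = B, L = L, nrow_x = nrow(X))
}

seq_max_pool_backward <- function(cache, dY) {
  dX <- matrix(0, nrow = cache$nrow_x, ncol = ncol(dY))
  B <- cache$B
  rows <- (cache$idx - 1L) * B + row(cache$idx) # time-major row of each argmax
  dX[cbind(as.vector(rows), as.vector(col(cache$idx)))] <- as.vector(dY)
  dX
}

# ---- flatten time-major -> B x (F*L) ----------------------------------

flatten_forward <- function(X, B, L) {
  blocks <- lapply(seq_len(L), function(t) X[tm_rows(t, B), , drop = FALSE])
  list(Y = do.call(cbind, blocks), B = B, L = L, F_ = ncol(X))
}

flatten_backward <- function(cache, dY) {
  B <- cache$B; L <- cache$L; F_ <- cache$F_
  dX <- matrix(0, nrow = L * B, ncol = F_)
  for (t in seq_len(L)) {
    dX[tm_rows(t, B), ] <- dY[, ((t - 1L) * F_ + 1L):(t * F_), drop = FALSE]
  }
  dX
}

# ---- LSTM --------------------------------------------------------------

lstm_init <- function(E, H) {
  list(
    Wx = glorot_uniform(E, 4L * H),
    Wh = glorot_uniform(H, 4L * H),
    # forget-gate bias starts at 1 (standard stabilization)
    b = c(rep(0, H), rep(1, H), rep(0, 2L * H))
  )
}

# X: (L*B) x E time-major. Returns all hidden states (L*B) x H plus the
# gate/cell caches needed by backward-through-time.  The recurrence runs
# in the compiled kernel (src/lstm.cpp).
lstm_forward <- function(X, Wx, Wh, b, B, L) {
  out <- lstm_forward_cpp(X, Wx, Wh, b, as.integer(B), as.integer(L))
  c(out, list(X = X, B = B, L = L, Hdim = nrow(Wh)))
}

# dY: (L*B) x H upstream gradient on every hidden state.
lstm_backward <- function(cache, Wx, Wh, dY) {
  lstm_backward_cpp(
    cache$X, Wx, Wh, cache$I, cache$F, cache$G, cache$O, cache$C,
    cache$TC, dY, as.integer(cache$B), as.integer(cache$L)
  )
}

# Gather the hidden state at each sample's last non-pad position.
# lengths: per-sample effective length (>= 1, <= L).
gather_last_forward <- function(Y, B, L, lengths) {
  rows <- (pmin(lengths, L) - 1L) * B + seq_len(B)
  list(Y = Y[rows, , drop = FALSE], rows = rows, nrow_y = nrow(Y))
}

gather_last_backward <- function(cache, dY) {
  dX <- matrix(0, cache$nrow_y, ncol(dY))
  dX[cache$rows, ] <- dY
  dX
}

# ---- graph global max pooling (batched) --------------------------------

# H: total_nodes x F; graph_index: 1..B per node.
graph_max_pool_forward <- function(H, graph_index, B) {
  F_ <- ncol(H)
  Y <- matrix(-Inf, B, F_)
  argrow <- matrix(0L, B, F_)
  for (g in seq_len(B)) {
    rows <- which(graph_index == g)
    Hg <- H[rows, , drop = FALSE]
    wm <- max.col(t(Hg), ties.method = "first")
    Y[g, ] <- Hg[cbind(wm, seq_len(F_))]
    argrow[g, ] <- rows[wm]
  }
  list(Y = Y, argrow = argrow, nrow_h = nrow(H))
}

graph_max_pool_backward <- function(cache, dY) {
  dH <- matrix(0, cache$nrow_h, ncol(dY))
  idx <- cbind(as.vector(cache$argrow), as.vector(col(cache$argrow)))
  # accumulate (several graphs cannot share a node, so plain assignment
  # per (node, feature) cell is safe)
  dH[idx] <- dH[idx] + as.vector(dY)
  dH
}

# ---- batched GCN layer -------------------------------------------------

# A_hat: sparse block-diagonal normalized adjacency over the whole batch.
gcn_layer_forward <- function(A_hat, H, W, b, activation = "relu") {
  AH <- as.matrix(A_hat %*% H)
  Z <- add_bias(AH %*% W, b)
  Y <- if (activation == "relu") pmax(Z, 0) else Z
  list(Y = Y, AH = AH, mask = if (activation == "relu") Z > 0 else NULL)
}

gcn_layer_backward <- function(cache, A_hat, W, dY) {
  dZ <- if (is.null(cache$mask)) dY else dY * cache$mask
  dW <- crossprod(cache$AH, dZ)
  db <- colSums(dZ)
  # A_hat is symmetric, so the adjoint is another multiplication by A_hat
  dH <- as.matrix(A_hat %*% (dZ %*% t(W)))
  list(dH = dH, dW = dW, db = db)
}
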