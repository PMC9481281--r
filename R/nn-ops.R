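# Low-level neural-network ops with hand-written backward passes, used by the
# TCN blocks and the three AAE subnetworks. Batched activations are stored as
# a (T*B) x C matrix with the time index fastest: row = t + (b-1)*T for beat b,
# time step t. All heavy lifting is BLAS matrix multiplication.

# Memoized im2col row indices for a causal dilated conv: for tap j (0-based
# shift s = j*d) output row r reads input row r - s, or the zero row T*B+1
# of an augmented input when the shift runs off the beat's start. The
# concatenated index (taps stacked) builds the whole im2col matrix with one
# C-level subset; the same index drives the backward fold through rowsum().
.shift_cache <- new.env(parent = emptyenv())

#' @noRd
conv_idx <- function(T_len, B, k, d) {
  key <- sprintf("%d_%d_%d_%d", T_len, B, k, d)
  val <- .shift_cache[[key]]
  if (is.null(val)) {
    t_idx <- rep(seq_len(T_len), B)
    r <- seq_len(T_len * B)
    val <- unlist(lapply(0:(k - 1L), function(j) {
      s <- j * d
      src <- r - s
      src[t_idx <= s] <- T_len * B + 1L
      src
    }))
    assign(key, val, envir = .shift_cache)
  }
  val
}

# Kernel array (k x Cin x Cout) flattened so its rows match the im2col
# column order (taps fastest within each input channel) -- the array's own
# memory order, so this is copy-free apart from the dim attribute.
#' @noRd
kernel_matrix <- function(W) {
  dm <- dim(W)
  matrix(W, dm[1] * dm[2], dm[3])
}

# Causal dilated convolution, batched, im2col style. Tap j multiplies
# x[t - (j-1)*d]; the left context is implicit zero padding ((k-1)*d
# samples), so the output has the input's length and y[t] depends only on
# inputs at times <= t. The gather, BLAS products and scatter-add run in
# compiled code (src/conv.cpp); the im2col matrix is returned for reuse in
# the backward pass when return_cols = TRUE.
#' @noRd
conv_fwd <- function(X, W, bias, d, T_len, B, return_cols = FALSE) {
  dm <- dim(W)
  k <- dm[1]
  idx <- if (k == 1L) integer(0) else conv_idx(T_len, B, k, d)
  out <- cpp_conv_fwd(X, idx, k, kernel_matrix(W),
                      if (is.null(bias)) numeric(0) else bias, return_cols)
  if (return_cols) out else out$Y
}

# Backward pass of conv_fwd given the cached im2col matrix.
#' @noRd
conv_bwd <- function(dY, Xcol, W, d, T_len, B) {
  dm <- dim(W)
  k <- dm[1]
  idx <- if (k == 1L) integer(0) else conv_idx(T_len, B, k, d)
  out <- cpp_conv_bwd(dY, Xcol, idx, k, dm[2], kernel_matrix(W))
  list(dX = out$dX, dW = array(out$dW, dm), db = as.vector(out$db))
}

# --- weight normalization -------------------------------------------------
# Conv kernels are parameterized as W[, , o] = g_o * V[, , o] / ||V[, , o]||
# (norm over taps and input channels, per output channel): the "normalization"
# stage of the residual block, batch-size independent and deterministic.

#' @noRd
wn_effective <- function(p) {
  dm <- dim(p$V)
  Vm <- matrix(p$V, dm[1] * dm[2], dm[3])
  nrm <- sqrt(colSums(Vm^2))
  nrm[nrm < 1e-12] <- 1e-12
  W <- Vm * rep(p$g / nrm, each = nrow(Vm))
  dim(W) <- dm
  list(W = W, nrm = nrm)
}

# Map gradient w.r.t. the effective kernel W back to (V, g).
#' @noRd
wn_bwd <- function(dW, p, nrm) {
  dm <- dim(p$V)
  Vm <- matrix(p$V, dm[1] * dm[2], dm[3])
  dWm <- matrix(dW, dm[1] * dm[2], dm[3])
  dots <- colSums(dWm * Vm)              # <dW, V> per output channel
  dg <- dots / nrm
  scale1 <- p$g / nrm
  scale2 <- p$g * dots / nrm^3
  dV <- sweep(dWm, 2, scale1, "*") - sweep(Vm, 2, scale2, "*")
  dim(dV) <- dm
  list(dV = dV, dg = dg)
}

# --- simple layers ---------------------------------------------------------

#' @noRd
relu_fwd <- function(X) {
  mask <- X > 0
  list(Y = X * mask, mask = mask)
}

#' @noRd
relu_bwd <- function(dY, mask) dY * mask

# Inverted dropout; identity when rate == 0 or not training.
#' @noRd
dropout_fwd <- function(X, rate, training) {
  if (!training || rate <= 0) return(list(Y = X, mask = NULL))
  mask <- matrix(runif(length(X)) >= rate, nrow(X), ncol(X)) / (1 - rate)
  list(Y = X * mask, mask = mask)
}

#' @noRd
dropout_bwd <- function(dY, mask) if (is.null(mask)) dY else dY * mask

# Max pooling over non-overlapping windows of `f` time steps per beat
# (compiled; ties keep the earliest sample).
#' @noRd
maxpool_fwd <- function(X, f, T_len, B) {
  stopifnot(T_len %% f == 0L)
  out <- cpp_maxpool_fwd(X, f, T_len, B)
  list(Y = out$Y, IDX = out$IDX, T_out = T_len %/% f)
}

#' @noRd
maxpool_bwd <- function(dY, IDX, T_len, B, C) {
  cpp_maxpool_bwd(dY, IDX, T_len, B)
}

# Nearest-neighbour (repeat) upsampling of the time axis by factor f.
#' @noRd
upsample_idx <- function(f, T_len, B) {
  rep((seq_len(B) - 1L) * T_len, each = T_len * f) +
    rep(rep(seq_len(T_len), each = f), B)
}

#' @noRd
upsample_fwd <- function(X, f, T_len, B) {
  idx <- upsample_idx(f, T_len, B)
  list(Y = X[idx, , drop = FALSE], idx = idx)
}

#' @noRd
upsample_bwd <- function(dY, idx) {
  out <- rowsum(dY, group = idx)   # groups 1..T*B each appear f times
  rownames(out) <- NULL
  out
}

# Flatten each beat's T x C activation (column-major, time fastest) into one
# row of a B x (T*C) matrix; unflatten is the exact inverse.
#' @noRd
flatten_fwd <- function(X, T_len, B) {
  C <- ncol(X)
  arr <- array(X, c(T_len, B, C))
  t(matrix(aperm(arr, c(1, 3, 2)), T_len * C, B))
}

#' @noRd
flatten_bwd <- function(dZ, T_len, B, C) {
  arr <- array(t(dZ), c(T_len, C, B))
  matrix(aperm(arr, c(1, 3, 2)), T_len * B, C)
}

#' @noRd
dense_fwd <- function(Z, W, bias) sweep(Z %*% W, 2, bias, "+")

#' @noRd
dense_bwd <- function(dY, Z, W) {
  list(dZ = dY %*% t(W), dW = crossprod(Z, dY), db = colSums(dY))
}

#' @noRd
sigmoid <- function(x) 1 / (1 + exp(-x))
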