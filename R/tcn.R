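# Temporal convolutional network primitives: the public dilated causal
# convolution, the two-layer residual block, and receptive-field accounting.

#' Dilated causal 1-D convolution
#'
#' Computes `y[t] = sum_j W[j, , ]' x[t - (j-1) d]` with implicit left zero
#' padding of `(k-1) d` samples, so the output has the input's length and
#' `y[t]` depends only on inputs at times `<= t` (strict causality).
#'
#' @param x Numeric matrix, time steps x input channels (a vector is treated
#'   as a single-channel sequence).
#' @param weights `k x Cin x Cout` numeric array (a vector of length `k` is
#'   treated as a `k x 1 x 1` kernel).
#' @param d Dilation factor (integer >= 1): spacing between kernel taps.
#' @param bias Optional length-`Cout` bias.
#' @return Numeric matrix, time steps x `Cout`.
#' @examples
#' causal_dilated_conv(c(1, 2, 3, 4), c(1, 1), d = 2)  # 1 2 4 6
#' @export
causal_dilated_conv <- function(x, weights, d = 1L, bias = NULL) {
  if (is.numeric(weights) && is.null(dim(weights)))
    weights <- array(weights, c(length(weights), 1L, 1L))
  if (length(dim(weights)) != 3L)
    stopf("`weights` must be a k x Cin x Cout array")
  k <- dim(weights)[1]
  if (k < 1L) stopf("kernel size k must be >= 1")
  if (!is.numeric(d) || length(d) != 1L || d < 1L)
    stopf("dilation d must be an integer >= 1")
  d <- as.integer(d)
  if (is.null(dim(x))) x <- matrix(x, ncol = 1L)
  if (ncol(x) != dim(weights)[2])
    stopf("input has %d channels but kernel expects %d", ncol(x),
          dim(weights)[2])
  conv_fwd(x, weights, bias, d, nrow(x), 1L)
}

#' Specification of one TCN residual block
#'
#' A block stacks two dilated causal convolutions sharing the same dilation,
#' each followed by weight normalization (folded into the kernel), ReLU and
#' dropout; the block output is `ReLU(residual(x) + F(x))` where the residual
#' is the identity when channel counts match and a kernel-size-1 convolution
#' otherwise.
#'
#' @param in_channels,out_channels Positive channel counts.
#' @param kernel_size Taps per convolution (default 9).
#' @param dilation Shared dilation factor of both convolutions.
#' @param dropout_rate Dropout probability in \[0, 1) (training only).
#' @return A list of class `tcn_block_spec`.
#' @export
tcn_block_spec <- function(in_channels, out_channels, kernel_size = 9L,
                           dilation = 1L, dropout_rate = 0.05) {
  for (v in list(in_channels, out_channels, kernel_size, dilation))
    if (!is.numeric(v) || length(v) != 1L || v < 1L || v != round(v))
      stopf("channel counts, kernel size and dilation must be integers >= 1")
  check_scalar_num(dropout_rate, "dropout_rate", 0)
  if (dropout_rate >= 1) stopf("`dropout_rate` must be < 1")
  structure(list(in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 kernel_size = as.integer(kernel_size),
                 dilation = as.integer(dilation),
                 dropout_rate = dropout_rate),
            class = "tcn_block_spec")
}

# Glorot-uniform initial parameters for one block (weight-normalized convs:
# g is set to the per-channel norm of V so the effective kernel equals V).
#' @noRd
tcn_block_init <- function(spec) {
  conv_init <- function(k, cin, cout) {
    lim <- sqrt(6 / (k * cin + k * cout))
    V <- array(runif(k * cin * cout, -lim, lim), c(k, cin, cout))
    Vm <- matrix(V, k * cin, cout)
    list(V = V, g = sqrt(colSums(Vm^2)), b = numeric(cout))
  }
  proj <- NULL
  if (spec$in_channels != spec$out_channels) {
    lim <- sqrt(6 / (spec$in_channels + spec$out_channels))
    proj <- matrix(runif(spec$in_channels * spec$out_channels, -lim, lim),
                   spec$in_channels, spec$out_channels)
  }
  list(conv1 = conv_init(spec$kernel_size, spec$in_channels,
                         spec$out_channels),
       conv2 = conv_init(spec$kernel_size, spec$out_channels,
                         spec$out_channels),
       proj = proj)
}

# Batched block forward; returns output and the cache needed for backward
# (including the im2col matrices of both convolutions).
#' @noRd
block_fwd <- function(X, spec, params, T_len, B, training = FALSE) {
  d <- spec$dilation
  w1 <- wn_effective(params$conv1)
  c1 <- conv_fwd(X, w1$W, params$conv1$b, d, T_len, B, return_cols = TRUE)
  r1 <- relu_fwd(c1$Y)
  dr1 <- dropout_fwd(r1$Y, spec$dropout_rate, training)
  w2 <- wn_effective(params$conv2)
  c2 <- conv_fwd(dr1$Y, w2$W, params$conv2$b, d, T_len, B,
                 return_cols = TRUE)
  r2 <- relu_fwd(c2$Y)
  dr2 <- dropout_fwd(r2$Y, spec$dropout_rate, training)
  res <- if (is.null(params$proj)) X else X %*% params$proj
  pre <- res + dr2$Y
  out <- relu_fwd(pre)
  list(Y = out$Y,
       cache = list(X = X, w1 = w1, w2 = w2, Xcol1 = c1$Xcol,
                    Xcol2 = c2$Xcol, r1 = r1, dr1 = dr1, r2 = r2,
                    dr2 = dr2, out_mask = out$mask, T_len = T_len, B = B,
                    spec = spec, params = params))
}

# Batched block backward: gradient w.r.t. the block input plus parameter
# gradients mirroring the parameter list structure.
#' @noRd
block_bwd <- function(dY, cache) {
  sp <- cache$spec; pm <- cache$params
  d <- sp$dilation; T_len <- cache$T_len; B <- cache$B
  dpre <- relu_bwd(dY, cache$out_mask)
  # residual branch
  dX <- if (is.null(pm$proj)) dpre else dpre %*% t(pm$proj)
  dproj <- if (is.null(pm$proj)) NULL else crossprod(cache$X, dpre)
  # F branch
  dF <- dropout_bwd(dpre, cache$dr2$mask)
  dc2 <- relu_bwd(dF, cache$r2$mask)
  g2 <- conv_bwd(dc2, cache$Xcol2, cache$w2$W, d, T_len, B)
  wn2 <- wn_bwd(g2$dW, pm$conv2, cache$w2$nrm)
  dh1 <- dropout_bwd(g2$dX, cache$dr1$mask)
  dc1 <- relu_bwd(dh1, cache$r1$mask)
  g1 <- conv_bwd(dc1, cache$Xcol1, cache$w1$W, d, T_len, B)
  wn1 <- wn_bwd(g1$dW, pm$conv1, cache$w1$nrm)
  dX <- dX + g1$dX
  grads <- list(conv1 = list(V = wn1$dV, g = wn1$dg, b = g1$db),
                conv2 = list(V = wn2$dV, g = wn2$dg, b = g2$db),
                proj = dproj)
  list(dX = dX, grads = grads)
}

#' Forward pass of one TCN residual block
#'
#' @param x Numeric matrix, time steps x `in_channels` (vector = 1 channel).
#' @param spec A [tcn_block_spec()].
#' @param params Block parameters as produced by [init_params()] (components
#'   `conv1`, `conv2` with weight-normalized kernels `V`, `g` and bias `b`,
#'   plus a `proj` matrix when channel counts differ).
#' @param training Enable dropout (default FALSE: deterministic map).
#' @return Numeric matrix, time steps x `out_channels`.
#' @export
tcn_block_forward <- function(x, spec, params, training = FALSE) {
  stopifnot(inherits(spec, "tcn_block_spec"))
  if (is.null(dim(x))) x <- matrix(x, ncol = 1L)
  if (nrow(x) < 1L) stopf("input must have at least one time step")
  if (ncol(x) != spec$in_channels)
    stopf("input has %d channels but the block expects %d; a residual \
projection is only configured for the spec'd channel counts",
          ncol(x), spec$in_channels)
  block_fwd(x, spec, params, nrow(x), 1L, training)$Y
}

#' Receptive field of a stack of TCN residual blocks
#'
#' Each block contributes two causal convolutions of kernel size `k` with its
#' dilation `d`, extending the look-back by `2 (k-1) d` samples, so a stack
#' sees `1 + sum_blocks 2 (k-1) d` past samples.
#'
#' @param k Kernel size shared by all blocks.
#' @param dilations Integer vector, one dilation per block (empty: field 1).
#' @return Integer receptive-field length in samples.
#' @examples
#' receptive_field(9, c(1, 2, 4))  # 113
#' @export
receptive_field <- function(k, dilations) {
  if (!is.numeric(k) || length(k) != 1L || k < 1L)
    stopf("kernel size k must be >= 1")
  if (length(dilations) == 0L) return(1L)
  if (any(dilations < 1L)) stopf("dilations must be >= 1")
  as.integer(1 + sum(2 * (k - 1) * dilations))
}
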