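# The adversarial autoencoder: encoder, decoder and discriminator built from
# TCN residual blocks. Layer layout (time x channels), pooling/upsampling
# factor 5 throughout:
#   encoder:       250x1 -> TCN(32) -> pool -> TCN(16) -> pool -> TCN(8)
#                  -> pool -> flatten(16) -> dense(8, ReLU)
#   decoder:       8 -> dense(16, ReLU) -> reshape 2x8 -> [up x5 -> TCN] x 3
#                  (channels 8, 16, 32) -> causal conv k9 -> 1 channel, tanh
#   discriminator: encoder stack -> dense(8, ReLU) -> dense(1, sigmoid)
# Upsampling repeats time steps only; each decoder TCN block performs the
# channel change. The final decoder activation is tanh so reconstructions can
# reach the [-1, 1] range of normalized beats (configurable back to ReLU).

#' Architecture specification of the adversarial autoencoder
#'
#' @param beat_length Input length in samples (250).
#' @param latent_dim Size of the latent code Z (8).
#' @param kernel_size Convolution taps in every TCN block (9).
#' @param dilations One dilation per block, shared by the three subnetworks
#'   (default `c(1, 2, 4)`, the standard exponential schedule).
#' @param channels Output channels of the three encoder blocks, widest first
#'   (default `c(32, 16, 8)`); the decoder mirrors them.
#' @param pool_factor Max-pooling / upsampling factor (5, forced by the
#'   250 -> 50 -> 10 -> 2 time-length ladder).
#' @param dropout_rate Dropout inside the TCN blocks during training.
#' @param output_activation `"tanh"` (default) or `"relu"` for the final
#'   decoder convolution.
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(beat_length = 250L, latent_dim = 8L, kernel_size = 9L,
                       dilations = c(1L, 2L, 4L), channels = c(32L, 16L, 8L),
                       pool_factor = 5L, dropout_rate = 0.05,
                       output_activation = c("tanh", "relu")) {
  output_activation <- match.arg(output_activation)
  if (length(dilations) != 3L || length(channels) != 3L)
    stopf("`dilations` and `channels` must each have one entry per block (3)")
  if (beat_length %% pool_factor^3 != 0L)
    stopf("`beat_length` must be divisible by pool_factor^3")
  t_deep <- beat_length / pool_factor^3          # time length after 3 pools
  structure(list(beat_length = as.integer(beat_length),
                 latent_dim = as.integer(latent_dim),
                 kernel_size = as.integer(kernel_size),
                 dilations = as.integer(dilations),
                 channels = as.integer(channels),
                 pool_factor = as.integer(pool_factor),
                 dropout_rate = dropout_rate,
                 output_activation = output_activation,
                 flat_dim = as.integer(t_deep * channels[3]),
                 t_deep = as.integer(t_deep)),
            class = "model_spec")
}

#' @noRd
enc_block_specs <- function(spec) {
  ch <- c(1L, spec$channels)
  lapply(1:3, function(i)
    tcn_block_spec(ch[i], ch[i + 1], spec$kernel_size, spec$dilations[i],
                   spec$dropout_rate))
}

#' @noRd
dec_block_specs <- function(spec) {
  ch <- c(rev(spec$channels)[1], rev(spec$channels))  # 8 -> 8, 16, 32
  lapply(1:3, function(i)
    tcn_block_spec(ch[i], ch[i + 1], spec$kernel_size, spec$dilations[i],
                   spec$dropout_rate))
}

#' Initialize all trainable parameters of the model
#'
#' Glorot-uniform weights scaled by fan-in/fan-out, zero biases; convolution
#' kernels are weight-normalized with the gain set so the initial effective
#' kernel equals the raw draw. Shapes are fully determined by the
#' [model_spec()].
#'
#' @param spec A [model_spec()].
#' @param seed Integer seed for the draw.
#' @return A list of class `aae_params` with components `encoder`, `decoder`,
#'   `discriminator` and the `spec`.
#' @export
init_params <- function(spec = model_spec(), seed = 1L) {
  stopifnot(inherits(spec, "model_spec"))
  dense_init <- function(n_in, n_out) {
    lim <- sqrt(6 / (n_in + n_out))
    list(W = matrix(runif(n_in * n_out, -lim, lim), n_in, n_out),
         b = numeric(n_out))
  }
  conv_init <- function(k, cin, cout) {
    lim <- sqrt(6 / (k * cin + k * cout))
    V <- array(runif(k * cin * cout, -lim, lim), c(k, cin, cout))
    list(V = V, g = sqrt(colSums(matrix(V, k * cin, cout)^2)),
         b = numeric(cout))
  }
  with_seed(seed, {
    encoder <- list(blocks = lapply(enc_block_specs(spec), tcn_block_init),
                    dense = dense_init(spec$flat_dim, spec$latent_dim))
    decoder <- list(dense = dense_init(spec$latent_dim, spec$flat_dim),
                    blocks = lapply(dec_block_specs(spec), tcn_block_init),
                    out = conv_init(spec$kernel_size, spec$channels[1], 1L))
    discriminator <- list(blocks = lapply(enc_block_specs(spec),
                                          tcn_block_init),
                          dense1 = dense_init(spec$flat_dim,
                                              spec$latent_dim),
                          dense2 = dense_init(spec$latent_dim, 1L))
    structure(list(encoder = encoder, decoder = decoder,
                   discriminator = discriminator, spec = spec),
              class = "aae_params")
  })
}

#' @export
print.aae_params <- function(x, ...) {
  n_par <- function(p) sum(rapply(p, length, how = "unlist"))
  cat(sprintf(paste0("<aae_params> beat_length=%d latent_dim=%d | ",
                     "encoder %d, decoder %d, discriminator %d parameters\n"),
              x$spec$beat_length, x$spec$latent_dim, n_par(x$encoder),
              n_par(x$decoder), n_par(x$discriminator)))
  invisible(x)
}

# --- shared encoder-shaped stack (used by encoder and discriminator) --------

# X: (T*B) x 1 activations. Returns the flat B x flat_dim features plus cache.
#' @noRd
enc_stack_fwd <- function(X, spec, blocks_p, B, training) {
  specs <- enc_block_specs(spec)
  T_len <- spec$beat_length
  caches <- vector("list", 3L)
  pools <- vector("list", 3L)
  shapes <- list(c(T_len, 1L))
  for (i in 1:3) {
    bf <- block_fwd(X, specs[[i]], blocks_p[[i]], T_len, B, training)
    shapes[[length(shapes) + 1L]] <- c(T_len, specs[[i]]$out_channels)
    caches[[i]] <- bf$cache
    mp <- maxpool_fwd(bf$Y, spec$pool_factor, T_len, B)
    pools[[i]] <- mp
    X <- mp$Y
    T_len <- mp$T_out
    shapes[[length(shapes) + 1L]] <- c(T_len, specs[[i]]$out_channels)
  }
  flat <- flatten_fwd(X, T_len, B)
  shapes[[length(shapes) + 1L]] <- ncol(flat)
  list(flat = flat, caches = caches, pools = pools, shapes = shapes,
       T_deep = T_len)
}

#' @noRd
enc_stack_bwd <- function(dflat, st, spec, B) {
  specs <- enc_block_specs(spec)
  C3 <- specs[[3]]$out_channels
  dX <- flatten_bwd(dflat, st$T_deep, B, C3)
  grads <- vector("list", 3L)
  T_len <- st$T_deep
  for (i in 3:1) {
    C <- specs[[i]]$out_channels
    dX <- maxpool_bwd(dX, st$pools[[i]]$IDX, T_len * spec$pool_factor, B, C)
    T_len <- T_len * spec$pool_factor
    bb <- block_bwd(dX, st$caches[[i]])
    grads[[i]] <- bb$grads
    dX <- bb$dX
  }
  list(dX = dX, blocks = grads)
}

# --- encoder ----------------------------------------------------------------

#' @noRd
encoder_fwd <- function(X, params, B, training = FALSE) {
  spec <- params$spec
  st <- enc_stack_fwd(X, spec, params$encoder$blocks, B, training)
  z_pre <- dense_fwd(st$flat, params$encoder$dense$W, params$encoder$dense$b)
  zr <- relu_fwd(z_pre)
  shapes <- c(st$shapes, list(ncol(zr$Y)))
  list(Z = zr$Y, cache = list(st = st, flat = st$flat, zmask = zr$mask,
                              shapes = shapes))
}

#' @noRd
encoder_bwd <- function(dZ, cache, params, B) {
  spec <- params$spec
  dz_pre <- relu_bwd(dZ, cache$zmask)
  dd <- dense_bwd(dz_pre, cache$flat, params$encoder$dense$W)
  sb <- enc_stack_bwd(dd$dZ, cache$st, spec, B)
  list(dX = sb$dX,
       grads = list(blocks = sb$blocks, dense = list(W = dd$dW, b = dd$db)))
}

# --- decoder ----------------------------------------------------------------

#' @noRd
decoder_fwd <- function(Z, params, B, training = FALSE) {
  spec <- params$spec
  specs <- dec_block_specs(spec)
  h_pre <- dense_fwd(Z, params$decoder$dense$W, params$decoder$dense$b)
  hr <- relu_fwd(h_pre)
  shapes <- list(ncol(hr$Y))
  C <- rev(spec$channels)[1]                      # deep channel count (8)
  T_len <- spec$t_deep
  X <- flatten_bwd(hr$Y, T_len, B, C)             # reshape B x 16 -> (2*B) x 8
  shapes[[length(shapes) + 1L]] <- c(T_len, C)
  ups <- vector("list", 3L)
  caches <- vector("list", 3L)
  for (i in 1:3) {
    up <- upsample_fwd(X, spec$pool_factor, T_len, B)
    T_len <- T_len * spec$pool_factor
    ups[[i]] <- up
    shapes[[length(shapes) + 1L]] <- c(T_len, ncol(up$Y))
    bf <- block_fwd(up$Y, specs[[i]], params$decoder$blocks[[i]], T_len, B,
                    training)
    caches[[i]] <- bf$cache
    X <- bf$Y
    shapes[[length(shapes) + 1L]] <- c(T_len, ncol(X))
  }
  wo <- wn_effective(params$decoder$out)
  co <- conv_fwd(X, wo$W, params$decoder$out$b, 1L, T_len, B,
                 return_cols = TRUE)
  y_pre <- co$Y
  if (spec$output_activation == "tanh") {
    Y <- tanh(y_pre)
    out_cache <- list(kind = "tanh", Y = Y)
  } else {
    rr <- relu_fwd(y_pre)
    Y <- rr$Y
    out_cache <- list(kind = "relu", mask = rr$mask)
  }
  shapes[[length(shapes) + 1L]] <- c(T_len, 1L)
  list(Y = Y, cache = list(hmask = hr$mask, Z = Z, ups = ups,
                           caches = caches, Xcol_out = co$Xcol, wo = wo,
                           out_cache = out_cache, shapes = shapes))
}

#' @noRd
decoder_bwd <- function(dY, cache, params, B) {
  spec <- params$spec
  T_len <- spec$beat_length
  dy_pre <- if (cache$out_cache$kind == "tanh")
    dY * (1 - cache$out_cache$Y^2)
  else relu_bwd(dY, cache$out_cache$mask)
  go <- conv_bwd(dy_pre, cache$Xcol_out, cache$wo$W, 1L, T_len, B)
  wno <- wn_bwd(go$dW, params$decoder$out, cache$wo$nrm)
  dX <- go$dX
  grads_blocks <- vector("list", 3L)
  for (i in 3:1) {
    bb <- block_bwd(dX, cache$caches[[i]])
    grads_blocks[[i]] <- bb$grads
    dX <- upsample_bwd(bb$dX, cache$ups[[i]]$idx)
    T_len <- T_len %/% spec$pool_factor
  }
  C <- rev(spec$channels)[1]
  dflat <- flatten_fwd(dX, spec$t_deep, B)        # adjoint of the reshape
  dh_pre <- relu_bwd(dflat, cache$hmask)
  dd <- dense_bwd(dh_pre, cache$Z, params$decoder$dense$W)
  list(dZ = dd$dZ,
       grads = list(dense = list(W = dd$dW, b = dd$db),
                    blocks = grads_blocks,
                    out = list(V = wno$dV, g = wno$dg, b = go$db)))
}

# --- discriminator ----------------------------------------------------------

# Returns the pre-sigmoid logit (stable losses are formed from logits).
#' @noRd
disc_fwd <- function(X, params, B, training = FALSE) {
  spec <- params$spec
  st <- enc_stack_fwd(X, spec, params$discriminator$blocks, B, training)
  h_pre <- dense_fwd(st$flat, params$discriminator$dense1$W,
                     params$discriminator$dense1$b)
  hr <- relu_fwd(h_pre)
  logit <- dense_fwd(hr$Y, params$discriminator$dense2$W,
                     params$discriminator$dense2$b)
  shapes <- c(st$shapes, list(ncol(hr$Y), 1L))
  list(logit = as.vector(logit),
       cache = list(st = st, flat = st$flat, hmask = hr$mask, H = hr$Y,
                    shapes = shapes))
}

# dlogit: gradient w.r.t. the logit (length B). Returns input gradient and
# parameter gradients.
#' @noRd
disc_bwd <- function(dlogit, cache, params, B) {
  spec <- params$spec
  d2 <- dense_bwd(matrix(dlogit, ncol = 1L), cache$H,
                  params$discriminator$dense2$W)
  dh_pre <- relu_bwd(d2$dZ, cache$hmask)
  d1 <- dense_bwd(dh_pre, cache$flat, params$discriminator$dense1$W)
  sb <- enc_stack_bwd(d1$dZ, cache$st, spec, B)
  list(dX = sb$dX,
       grads = list(blocks = sb$blocks,
                    dense1 = list(W = d1$dW, b = d1$db),
                    dense2 = list(W = d2$dW, b = d2$db)))
}

# --- public inference maps --------------------------------------------------

# Beats arrive as rows (n x 250); activations want time fastest per beat.
#' @noRd
beats_to_act <- function(beats, beat_length) {
  if (is.null(dim(beats))) beats <- matrix(beats, nrow = 1L)
  if (ncol(beats) != beat_length)
    stopf("beats must have %d samples, got %d", beat_length, ncol(beats))
  matrix(as.vector(t(beats)), ncol = 1L)
}

#' @noRd
act_to_beats <- function(X, beat_length, B) {
  matrix(X, nrow = beat_length)  |> t()
}

# Inference runs in chunks of this many beats to bound memory.
#' @noRd
infer_chunk <- 256L

#' Encode beats into the latent space
#'
#' @param x A single 250-sample beat (vector), an `n x 250` matrix, or a
#'   [beat_matrix()]. Beats are expected normalized to \[-1, 1\].
#' @param params Trained or initialized [init_params()] object.
#' @return Latent matrix `n x latent_dim` (a vector for a single beat).
#' @export
encode <- function(x, params) {
  stopifnot(inherits(params, "aae_params"))
  single <- is.null(dim(x)) && !inherits(x, "beat_matrix")
  if (inherits(x, "beat_matrix")) x <- x$beats
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (ncol(x) != params$spec$beat_length)
    stopf("beats must have %d samples, got %d", params$spec$beat_length,
          ncol(x))
  n <- nrow(x)
  Z <- matrix(0, n, params$spec$latent_dim)
  for (lo in seq(1L, n, by = infer_chunk)) {
    hi <- min(lo + infer_chunk - 1L, n)
    X <- beats_to_act(x[lo:hi, , drop = FALSE], params$spec$beat_length)
    Z[lo:hi, ] <- encoder_fwd(X, params, hi - lo + 1L,
                              training = FALSE)$Z
  }
  if (single) as.vector(Z) else Z
}

#' Decode latent codes back into beats
#'
#' @param z A latent vector of length `latent_dim` or an `n x latent_dim`
#'   matrix.
#' @param params [init_params()] object.
#' @return Reconstructed beats, `n x 250` (a vector for a single code); with
#'   the default tanh output all values lie in \[-1, 1\].
#' @export
decode <- function(z, params) {
  stopifnot(inherits(params, "aae_params"))
  single <- is.null(dim(z))
  if (single) z <- matrix(z, nrow = 1L)
  if (ncol(z) != params$spec$latent_dim)
    stopf("latent code must have dimension %d, got %d",
          params$spec$latent_dim, ncol(z))
  n <- nrow(z)
  out <- matrix(0, n, params$spec$beat_length)
  for (lo in seq(1L, n, by = infer_chunk)) {
    hi <- min(lo + infer_chunk - 1L, n)
    Y <- decoder_fwd(z[lo:hi, , drop = FALSE], params, hi - lo + 1L,
                     training = FALSE)$Y
    out[lo:hi, ] <- act_to_beats(Y, params$spec$beat_length, hi - lo + 1L)
  }
  if (single) as.vector(out) else out
}

#' Discriminator probability that beats are real
#'
#' @inheritParams encode
#' @return Probabilities strictly inside (0, 1), one per beat.
#' @export
discriminate <- function(x, params) {
  stopifnot(inherits(params, "aae_params"))
  if (inherits(x, "beat_matrix")) x <- x$beats
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (ncol(x) != params$spec$beat_length)
    stopf("beats must have %d samples, got %d", params$spec$beat_length,
          ncol(x))
  n <- nrow(x)
  out <- numeric(n)
  for (lo in seq(1L, n, by = infer_chunk)) {
    hi <- min(lo + infer_chunk - 1L, n)
    X <- beats_to_act(x[lo:hi, , drop = FALSE], params$spec$beat_length)
    out[lo:hi] <- sigmoid(disc_fwd(X, params, hi - lo + 1L,
                                   training = FALSE)$logit)
  }
  out
}

#' Reconstruct beats through the autoencoder
#'
#' Convenience for `decode(encode(x))` sharing one forward pass convention.
#'
#' @inheritParams encode
#' @return Reconstructed beats with the shape of the input.
#' @export
reconstruct <- function(x, params) {
  single <- is.null(dim(x)) && !inherits(x, "beat_matrix")
  z <- encode(x, params)
  out <- decode(if (single) matrix(z, nrow = 1) else z, params)
  if (single) as.vector(out) else out
}

#' Per-layer output shapes of the three subnetworks
#'
#' Runs one forward pass and reports every layer's output shape, for auditing
#' the architecture against its design table.
#'
#' @param params [init_params()] object.
#' @return List with character vectors `encoder`, `decoder`, `discriminator`,
#'   e.g. `"250x32"` for a time-by-channel layer or `"8"` for a dense output.
#' @export
model_shapes <- function(params) {
  stopifnot(inherits(params, "aae_params"))
  spec <- params$spec
  X <- beats_to_act(numeric(spec$beat_length), spec$beat_length)
  fmt <- function(s) vapply(s, function(v)
    paste(v, collapse = "x"), character(1))
  ef <- encoder_fwd(X, params, 1L)
  df <- decoder_fwd(matrix(0, 1, spec$latent_dim), params, 1L)
  cf <- disc_fwd(X, params, 1L)
  list(encoder = fmt(ef$cache$shapes),
       decoder = fmt(df$cache$shapes),
       discriminator = fmt(cf$cache$shapes))
}

#' Save / load model parameters
#'
#' Parameters are written with [saveRDS()] (a binary array container); the
#' round trip is bit-exact.
#'
#' @param params [init_params()] object.
#' @param path File path (conventionally `.rds`).
#' @return `read_params` returns the restored `aae_params` object.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "aae_params"))
  saveRDS(params, path)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  p <- readRDS(path)
  if (!inherits(p, "aae_params")) stopf("'%s' does not hold aae_params", path)
  p
}
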