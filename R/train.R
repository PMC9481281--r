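# Alternating adversarial training on normal beats only. Per batch the
# discriminator is updated first (real beats vs detached reconstructions),
# then encoder + decoder descend reconstruction MSE + gamma * generator loss.
# gamma = 0 skips the discriminator entirely and reduces to a plain
# autoencoder. Losses on the record are evaluated on the full training set
# with end-of-epoch parameters and dropout off, so the history can be
# recomputed exactly from the saved parameters.

#' Mean-squared reconstruction loss
#'
#' `mean((X - X')^2)`: the squared L2 reconstruction error divided by the
#' number of samples, so values are comparable across beat lengths and batch
#' sizes.
#'
#' @param x,x_recon Numeric vectors/matrices of identical shape.
#' @return Nonnegative scalar; 0 iff the inputs are identical.
#' @export
reconstruction_loss <- function(x, x_recon) {
  if (!identical(dim(x), dim(x_recon)) || length(x) != length(x_recon))
    stopf("x and x_recon must have identical shapes")
  mean((x - x_recon)^2)
}

#' Adversarial losses of the two-player minimax game
#'
#' The discriminator ascends
#' `log D(x_real) + log(1 - D(x_recon))`, so its loss is the negative of that
#' sum (each term averaged over its batch). The autoencoder uses the
#' non-saturating generator form `-log D(x_recon)` rather than the literal
#' `log(1 - D)` (same fixed point, usable gradients when the discriminator
#' wins early).
#'
#' @param d_real,d_recon Discriminator probabilities in \[0, 1\] for real
#'   beats and reconstructions; clamped to \[1e-7, 1 - 1e-7\] before logs.
#' @return List with `d_loss` and `g_loss`.
#' @export
adversarial_losses <- function(d_real, d_recon) {
  eps <- 1e-7
  if (any(d_real < 0 | d_real > 1) || any(d_recon < 0 | d_recon > 1))
    stopf("discriminator outputs must lie in [0, 1]")
  dr <- pmin(pmax(d_real, eps), 1 - eps)
  df <- pmin(pmax(d_recon, eps), 1 - eps)
  list(d_loss = -(mean(log(dr)) + mean(log(1 - df))),
       g_loss = -mean(log(df)))
}

#' Training configuration
#'
#' @param epochs Maximum epochs.
#' @param batch_size Mini-batch size.
#' @param lr_ae,lr_d Adam learning rates for the autoencoder and the
#'   discriminator.
#' @param gamma Weight of the adversarial term in the autoencoder update
#'   (`gamma = 0`: plain autoencoder, no discriminator training).
#' @param beta1,beta2 Adam moment decay parameters.
#' @param seed Seed driving initialization, shuffling and dropout.
#' @param patience Early-stop patience: stop after this many epochs without
#'   reconstruction-loss improvement (> `min_delta`).
#' @param min_delta Minimal improvement counted as progress.
#' @return A list of class `train_config`.
#' @export
train_config <- function(epochs = 100L, batch_size = 64L, lr_ae = 1e-3,
                         lr_d = 2e-4, gamma = 0.05, beta1 = 0.5,
                         beta2 = 0.999, seed = 1L, patience = 10L,
                         min_delta = 1e-6) {
  check_scalar_num(epochs, "epochs", 1)
  check_scalar_num(batch_size, "batch_size", 1)
  check_scalar_num(lr_ae, "lr_ae", 0, strict_lower = TRUE)
  check_scalar_num(lr_d, "lr_d", 0, strict_lower = TRUE)
  check_scalar_num(gamma, "gamma", 0)
  check_scalar_num(patience, "patience", 0)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr_ae = lr_ae,
                 lr_d = lr_d, gamma = gamma, beta1 = beta1, beta2 = beta2,
                 seed = as.integer(seed), patience = as.integer(patience),
                 min_delta = min_delta),
            class = "train_config")
}

# --- Adam over nested parameter lists ---------------------------------------

#' @noRd
zero_like <- function(p) {
  if (is.null(p)) return(NULL)
  if (is.list(p)) return(lapply(p, zero_like))
  p * 0
}

#' @noRd
add_grads <- function(a, b) {
  if (is.null(a)) return(NULL)
  if (is.list(a)) return(mapply(add_grads, a, b, SIMPLIFY = FALSE))
  a + b
}

#' @noRd
adam_init <- function(params) list(m = zero_like(params),
                                   v = zero_like(params), t = 0L)

#' @noRd
adam_step <- function(params, grads, state, lr, b1, b2, eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - b1^state$t
  c2 <- 1 - b2^state$t
  walk <- function(p, g, m, v) {
    if (is.null(p)) return(list(p = NULL, m = NULL, v = NULL))
    if (is.list(p)) {
      res <- mapply(walk, p, g, m, v, SIMPLIFY = FALSE)
      return(list(p = lapply(res, `[[`, "p"),
                  m = lapply(res, `[[`, "m"),
                  v = lapply(res, `[[`, "v")))
    }
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g^2
    list(p = p - lr * (m / c1) / (sqrt(v / c2) + eps), m = m, v = v)
  }
  res <- walk(params, grads, state$m, state$v)
  list(params = res$p, state = list(m = res$m, v = res$v, t = state$t))
}

# --- chunked full-dataset evaluation ----------------------------------------

# Per-beat reconstruction MSE, dropout off (reconstruct() chunks internally).
#' @noRd
ae_recon_per_beat <- function(params, beats) {
  rowMeans((beats - reconstruct(beats, params))^2)
}

#' Train the adversarial autoencoder on normal beats
#'
#' One-class contract: if the input carries labels, every beat must be class
#' `N`. Per batch, the discriminator is updated on
#' `-log D(x) - log(1 - D(x'))` with the reconstruction `x'` treated as
#' constant, then the encoder and decoder are updated on
#' `reconstruction_loss + gamma * (-log D(x'))` with the discriminator (run
#' without dropout as a fixed critic) providing the gradient through `x'`.
#' History rows hold full-dataset losses at end-of-epoch parameters with
#' dropout off, so they are exactly recomputable from the returned weights.
#'
#' @param train A [beat_matrix()] of normal beats (or bare `n x 250` matrix),
#'   normalized to \[-1, 1\].
#' @param spec A [model_spec()].
#' @param config A [train_config()]; `config$seed` makes the run reproducible.
#' @param verbose Print per-epoch losses.
#' @return A list of class `aae_fit`: `params` ([init_params()] structure),
#'   `history` (data frame: epoch, recon_loss, d_loss, g_loss) and `config`.
#' @export
train_aae <- function(train, spec = model_spec(), config = train_config(),
                      verbose = FALSE) {
  stopifnot(inherits(spec, "model_spec"), inherits(config, "train_config"))
  if (inherits(train, "beat_matrix")) {
    if (any(train$labels != "N"))
      stopf("training data must contain only normal (N) beats; found: %s",
            paste(unique(setdiff(train$labels, "N")), collapse = ", "))
    train <- train$beats
  }
  train <- as.matrix(train)
  n <- nrow(train)
  if (n < 1L) stopf("no training beats")
  if (ncol(train) != spec$beat_length)
    stopf("training beats must have %d samples", spec$beat_length)

  params <- init_params(spec, config$seed)
  T_len <- spec$beat_length
  gamma <- config$gamma
  loop_seed <- (config$seed %% 2147483645L) + 1L

  hist_rows <- vector("list", config$epochs)
  with_seed(loop_seed, {
    st_enc <- adam_init(params$encoder)
    st_dec <- adam_init(params$decoder)
    st_dis <- adam_init(params$discriminator)
    best <- Inf
    stall <- 0L
    for (epoch in seq_len(config$epochs)) {
      perm <- sample.int(n)
      starts <- seq(1L, n, by = config$batch_size)
      for (lo in starts) {
        idx <- perm[lo:min(lo + config$batch_size - 1L, n)]
        B <- length(idx)
        X <- matrix(as.vector(t(train[idx, , drop = FALSE])), ncol = 1L)

        ef <- encoder_fwd(X, params, B, training = TRUE)
        dfw <- decoder_fwd(ef$Z, params, B, training = TRUE)
        Xp <- dfw$Y

        if (gamma > 0) {
          # discriminator step: real beats and detached reconstructions run
          # as one stacked batch of 2B
          fd <- disc_fwd(rbind(X, Xp), params, 2L * B, training = TRUE)
          p_d <- sigmoid(fd$logit)
          dlogit <- c(p_d[seq_len(B)] - 1, p_d[B + seq_len(B)]) / B
          g_d <- disc_bwd(dlogit, fd$cache, params, 2L * B)
          up <- adam_step(params$discriminator, g_d$grads, st_dis,
                          config$lr_d, config$beta1, config$beta2)
          params$discriminator <- up$params
          st_dis <- up$state
        }

        # autoencoder step
        dXp <- 2 * (Xp - X) / length(Xp)
        if (gamma > 0) {
          fc <- disc_fwd(Xp, params, B, training = FALSE)  # fixed critic
          cb <- disc_bwd(gamma * (sigmoid(fc$logit) - 1) / B, fc$cache,
                         params, B)
          dXp <- dXp + cb$dX
        }
        dec_b <- decoder_bwd(dXp, dfw$cache, params, B)
        enc_b <- encoder_bwd(dec_b$dZ, ef$cache, params, B)
        up_d <- adam_step(params$decoder, dec_b$grads, st_dec, config$lr_ae,
                          config$beta1, config$beta2)
        params$decoder <- up_d$params
        st_dec <- up_d$state
        up_e <- adam_step(params$encoder, enc_b$grads, st_enc, config$lr_ae,
                          config$beta1, config$beta2)
        params$encoder <- up_e$params
        st_enc <- up_e$state
      }

      # end-of-epoch bookkeeping, dropout off: reconstruction loss over the
      # full training set (drives early stopping and is exactly recomputable
      # from the returned weights); adversarial losses over the first
      # min(n, 512) beats to keep the accounting pass cheap
      rec_beats <- reconstruct(train, params)
      recon <- mean((train - rec_beats)^2)
      d_loss <- g_loss <- NA_real_
      if (gamma > 0) {
        sub <- seq_len(min(n, 512L))
        al <- adversarial_losses(
          discriminate(train[sub, , drop = FALSE], params),
          discriminate(rec_beats[sub, , drop = FALSE], params))
        d_loss <- al$d_loss
        g_loss <- al$g_loss
      }
      hist_rows[[epoch]] <- data.frame(epoch = epoch, recon_loss = recon,
                                       d_loss = d_loss, g_loss = g_loss)
      if (verbose)
        message(sprintf("epoch %3d  recon %.6f  d %.4f  g %.4f", epoch,
                        recon, d_loss, g_loss))
      if (recon < best - config$min_delta) {
        best <- recon
        stall <- 0L
      } else stall <- stall + 1L
      if (stall >= config$patience && config$patience > 0L) break
    }
  })
  history <- do.call(rbind, hist_rows[!vapply(hist_rows, is.null,
                                              logical(1))])
  structure(list(params = params, history = history, config = config),
            class = "aae_fit")
}

#' @export
print.aae_fit <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  cat(sprintf("<aae_fit> %d epochs, final recon loss %.6f (gamma = %g)\n",
              nrow(x$history), last$recon_loss, x$config$gamma))
  invisible(x)
}
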