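# Shared fixtures. Everything is generated in code; nothing is read from disk.

# A noiseless, baseline-free config for signal-level assertions.
clean_config <- function(seed = 1, fs = 360, hr = 70,
                         mix = c(N = 1, A = 0, L = 0, R = 0, V = 0)) {
  sim_config(fs = fs, heart_rate_bpm = hr, noise_sd = 0, baseline_amp = 0,
             seed = seed, class_mix = mix)
}

uniform_abnormal_mix <- c(N = 0, A = 0.25, L = 0.25, R = 0.25, V = 0.25)

# QRS width in samples: contiguous run around the R anchor (position 101)
# staying above `frac` of the anchor amplitude.
qrs_width <- function(beat, frac = 0.2) {
  thr <- frac * abs(beat[101])
  above <- abs(beat) > thr
  lo <- 101
  while (lo > 1 && above[lo - 1]) lo <- lo - 1
  hi <- 101
  while (hi < length(beat) && above[hi + 1]) hi <- hi + 1
  hi - lo + 1
}

# Direct-summation oracle for the dilated causal convolution: a triple loop
# over time, output channel and tap, independent of the package's matrix path.
naive_causal_conv <- function(x, W, d) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  k <- dim(W)[1]
  out <- matrix(0, nrow(x), dim(W)[3])
  for (t in seq_len(nrow(x))) {
    for (co in seq_len(dim(W)[3])) {
      acc <- 0
      for (j in seq_len(k)) {
        src <- t - (j - 1) * d
        if (src >= 1)
          acc <- acc + sum(W[j, , co] * x[src, ])
      }
      out[t, co] <- acc
    }
  }
  out
}

# A small trained plain autoencoder shared by scoring tests (computed once
# per test run; kept tiny so the suite stays fast).
tiny_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ds <- make_dataset(96, 0, 0, sim_config(seed = 400))
      cache <<- train_aae(ds$train, model_spec(dropout_rate = 0),
                          train_config(epochs = 4, batch_size = 32,
                                       gamma = 0, patience = 100,
                                       seed = 400))
    }
    cache
  }
})
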