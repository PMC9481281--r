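# Dilated causal convolution, residual block, receptive field.

test_that("a kernel-1 identity convolution returns its input", {
  x <- rnorm(20)
  expect_equal(as.vector(causal_dilated_conv(x, 1, d = 1)), x)
  expect_equal(as.vector(causal_dilated_conv(x, 1, d = 5)), x)
})

test_that("the worked two-tap example matches direct summation", {
  # y[t] = x[t] + x[t-2] with zero padding
  expect_equal(as.vector(causal_dilated_conv(c(1, 2, 3, 4), c(1, 1), d = 2)),
               c(1, 2, 4, 6))
})

test_that("convolution matches the naive triple-loop oracle", {
  set.seed(10)
  for (i in 1:100) {
    T_len <- sample(4:64, 1)
    cin <- sample(1:4, 1)
    cout <- sample(1:4, 1)
    k <- sample(1:5, 1)
    d <- sample(1:4, 1)
    x <- matrix(rnorm(T_len * cin), T_len, cin)
    W <- array(rnorm(k * cin * cout), c(k, cin, cout))
    expect_equal(causal_dilated_conv(x, W, d), naive_causal_conv(x, W, d),
                 tolerance = 1e-6)
  }
})

test_that("perturbing the input never changes earlier outputs", {
  set.seed(11)
  for (k in c(2, 3, 9)) {
    for (d in c(1, 2, 4)) {
      x <- rnorm(40)
      W <- array(rnorm(k), c(k, 1, 1))
      y0 <- causal_dilated_conv(x, W, d)
      t0 <- 25
      x2 <- x
      x2[t0] <- x2[t0] + 1
      y1 <- causal_dilated_conv(x2, W, d)
      expect_equal(y1[seq_len(t0 - 1), ], y0[seq_len(t0 - 1), ])
      expect_false(isTRUE(all.equal(y1[t0, ], y0[t0, ])))
    }
  }
})

test_that("convolution rejects invalid kernel or dilation", {
  expect_error(causal_dilated_conv(rnorm(5), c(1, 1), d = 0), "d must be")
  expect_error(causal_dilated_conv(rnorm(5),
                                   array(1, c(1, 2, 1)), d = 1), "channels")
})

test_that("a zero-F residual block is the identity on nonnegative input", {
  spec <- tcn_block_spec(3, 3, kernel_size = 5, dilation = 2,
                         dropout_rate = 0)
  set.seed(1)
  params <- ecgaae:::tcn_block_init(spec)
  params$conv2$V[] <- 0          # second conv output (before bias) is zero
  params$conv2$g[] <- 0
  params$conv2$b[] <- 0
  x <- matrix(abs(rnorm(60)), 20, 3)
  expect_equal(tcn_block_forward(x, spec, params), x)
})

test_that("block output shapes and determinism match the contract", {
  spec <- tcn_block_spec(1, 32, kernel_size = 9, dilation = 1,
                         dropout_rate = 0.5)
  set.seed(2)
  params <- ecgaae:::tcn_block_init(spec)
  x <- matrix(rnorm(250), 250, 1)
  y1 <- tcn_block_forward(x, spec, params)           # dropout disabled
  y2 <- tcn_block_forward(x, spec, params)
  expect_identical(dim(y1), c(250L, 32L))
  expect_identical(y1, y2)
  expect_error(tcn_block_forward(matrix(rnorm(20), 10, 2), spec, params),
               "channels")
})

test_that("receptive_field matches the formula and the perturbation oracle", {
  expect_identical(receptive_field(1, c(1, 2, 4)), 1L)
  expect_identical(receptive_field(9, c(1, 2, 4)), 113L)
  expect_identical(receptive_field(2, 1), 3L)
  expect_identical(receptive_field(5, integer(0)), 1L)

  # empirical oracle: earliest input index that affects the last output of a
  # stack of blocks (linear regime: positive weights, no bias clipping)
  empirical_rf <- function(k, dilations) {
    T_len <- 150L
    run <- function(x) {
      h <- matrix(x, ncol = 1)
      for (d in dilations) {
        spec <- tcn_block_spec(1, 1, kernel_size = k, dilation = d,
                               dropout_rate = 0)
        p <- list(conv1 = list(V = array(0.1, c(k, 1, 1)), g = 0.1 * sqrt(k),
                               b = 1),
                  conv2 = list(V = array(0.1, c(k, 1, 1)), g = 0.1 * sqrt(k),
                               b = 1),
                  proj = NULL)
        h <- tcn_block_forward(h, spec, p)
      }
      h[T_len, 1]
    }
    base <- run(rep(1, T_len))
    affected <- vapply(seq_len(T_len), function(i) {
      x <- rep(1, T_len)
      x[i] <- 2
      run(x) != base
    }, logical(1))
    T_len - min(which(affected)) + 1L
  }
  for (cfg in list(list(k = 2, d = 1L), list(k = 3, d = c(1L, 2L)),
                   list(k = 9, d = c(1L, 2L, 4L)))) {
    expect_identical(empirical_rf(cfg$k, cfg$d),
                     receptive_field(cfg$k, cfg$d))
  }
})
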