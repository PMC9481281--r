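# Anomaly scoring, threshold fitting, classification.

test_that("r_score is the per-beat reconstruction MSE and deterministic", {
  fit <- tiny_fit()
  ds <- make_dataset(0, 6, 6, sim_config(seed = 401))
  r <- r_score(ds$test, fit$params)
  expect_length(r, 12)
  expect_true(all(r >= 0))
  manual <- rowMeans((ds$test$beats -
                        reconstruct(ds$test$beats, fit$params))^2)
  expect_equal(r, unname(manual))
  expect_identical(r, r_score(ds$test, fit$params))
})

test_that("a beat reconstructed exactly scores zero", {
  # an all-zero model maps any input to the zero beat, so a zero beat
  # reconstructs to itself
  p <- init_params(model_spec(), seed = 1)
  p$encoder <- rapply(p$encoder, function(v) v * 0, how = "replace")
  p$decoder <- rapply(p$decoder, function(v) v * 0, how = "replace")
  expect_identical(r_score(numeric(250), p), 0)
})

test_that("anomaly_score follows (1-lambda) R + lambda / D", {
  expect_identical(anomaly_score(0.037, 0.9, 0), 0.037)
  expect_equal(anomaly_score(0.2, 0.5, 0.5), 1.1)
  # D floored at 1e-7: no overflow at lambda = 1
  expect_equal(anomaly_score(5, 1e-12, 1), 1e7)
  expect_error(anomaly_score(0.1, 0.5, 1.5), "lambda")
  expect_error(anomaly_score(-0.1, 0.5, 0.5), "nonnegative")
})

test_that("anomaly_score is monotone in R and antitone in D", {
  r <- seq(0, 1, by = 0.1)
  a <- anomaly_score(r, rep(0.5, length(r)), 0.3)
  expect_true(all(diff(a) > 0))
  d <- seq(0.05, 0.95, by = 0.05)
  a2 <- anomaly_score(rep(0.2, length(d)), d, 0.3)
  expect_true(all(diff(a2) < 0))
})

test_that("fit_threshold is mean + one sample standard deviation", {
  expect_identical(fit_threshold(c(1, 2, 3)), 3)
  expect_identical(fit_threshold(rep(4.2, 10)), 4.2)
  set.seed(1)
  s <- rnorm(100)
  expect_equal(fit_threshold(s), mean(s) + sd(s))
  expect_error(fit_threshold(0.5), "at least 2")
})

test_that("classification is strictly greater-than the threshold", {
  T0 <- 0.4
  expect_identical(classify_scores(c(T0, T0 + 1e-9, T0 - 1e-9), T0),
                   c("normal", "abnormal", "normal"))
  expect_identical(classify_scores(numeric(0), T0), character(0))
  expect_error(classify_scores(1), "threshold")
})

test_that("threshold coverage equals the empirical above-threshold count", {
  set.seed(7)
  scores <- rnorm(500, mean = 0.02, sd = 0.005)
  T0 <- fit_threshold(scores)
  called <- classify_scores(scores, T0)
  expect_identical(sum(called == "abnormal"), sum(scores > T0))
  # near-Gaussian scores put roughly 16% above mean + 1 sd
  expect_gt(mean(called == "abnormal"), 0.10)
  expect_lt(mean(called == "abnormal"), 0.22)
})

test_that("with lambda = 0 the detector ignores the discriminator", {
  fit <- tiny_fit()
  ds <- make_dataset(0, 4, 4, sim_config(seed = 402))
  a1 <- score_beats(ds$test, fit$params, lambda = 0)$scores$anomaly
  tampered <- fit$params
  tampered$discriminator <- rapply(tampered$discriminator,
                                   function(v) v + 17, how = "replace")
  a2 <- score_beats(ds$test, tampered, lambda = 0)$scores$anomaly
  expect_identical(a1, a2)
  # but with lambda > 0 the discriminator matters
  b1 <- score_beats(ds$test, fit$params, lambda = 0.5)$scores$anomaly
  b2 <- score_beats(ds$test, tampered, lambda = 0.5)$scores$anomaly
  expect_false(identical(b1, b2))
})

test_that("score_beats assembles R, D and the combined score coherently", {
  fit <- tiny_fit()
  ds <- make_dataset(0, 5, 5, sim_config(seed = 403))
  ss <- score_beats(ds$test, fit$params, lambda = 0.25)
  expect_s3_class(ss, "score_set")
  expect_identical(nrow(ss$scores), 10L)
  expect_true(all(ss$scores$d_score > 0 & ss$scores$d_score < 1))
  expect_equal(ss$scores$anomaly,
               anomaly_score(ss$scores$r_score, ss$scores$d_score, 0.25))
  expect_identical(ss$scores$label, ds$test$labels)
})
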