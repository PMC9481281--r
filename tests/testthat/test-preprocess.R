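# Resampling, wavelet denoising, segmentation, normalization.

test_that("resampling changes length by the rate ratio", {
  rec <- make_record(9, clean_config(seed = 1, fs = 560, hr = 60))
  n_in <- length(rec$samples)
  out <- resample_record(rec, 360)
  expect_equal(out$fs, 360)
  expect_identical(length(out$samples), as.integer(round(n_in * 360 / 560)))
  expect_length(out$r_peaks, length(rec$r_peaks))
})

test_that("resampling at the original rate is the identity", {
  rec <- make_record(3, clean_config(seed = 2))
  out <- resample_record(rec, 360)
  expect_identical(out$samples, rec$samples)
  expect_identical(out$r_peaks, rec$r_peaks)
})

test_that("a pure sine resamples onto the analytic curve", {
  t_in <- (0:5599) / 560
  rec <- ecg_record(sin(2 * pi * 5 * t_in), 560, 300L, "N")
  out <- resample_record(rec, 360)
  t_out <- (seq_along(out$samples) - 1) / 360
  expect_lt(max(abs(out$samples - sin(2 * pi * 5 * t_out))), 1e-3)
})

test_that("resampled R peaks re-snap to the local signal maximum", {
  rec <- make_record(6, clean_config(seed = 3, fs = 560))
  out <- resample_record(rec, 360)
  for (r in out$r_peaks) {
    win <- max(1, r - 3):min(length(out$samples), r + 3)
    expect_identical(r, win[which.max(abs(out$samples[win]))])
  }
})

test_that("resampling rejects an empty signal", {
  rec <- structure(list(samples = numeric(0), fs = 360,
                        r_peaks = integer(0), beat_labels = character(0)),
                   class = "ecg_record")
  expect_error(resample_record(rec, 360), "empty")
})

test_that("the periodized DWT reconstructs exactly", {
  set.seed(5)
  for (n in c(256L, 1024L)) {
    x <- rnorm(n)
    expect_equal(idwt(dwt(x, 8)), x, tolerance = 1e-12)
    expect_equal(idwt(dwt(x, 4, "haar"), "haar"), x, tolerance = 1e-12)
  }
  expect_error(dwt(rnorm(100), 8), "multiple")
})

test_that("denoising a zero signal returns zero", {
  rec <- ecg_record(numeric(512), 360, integer(0), character(0))
  expect_equal(denoise(rec)$samples, numeric(512))
})

test_that("denoising removes at least 90% of sub-0.5 Hz baseline power", {
  cfg <- sim_config(seed = 2, noise_sd = 0, baseline_amp = 0.5,
                    baseline_freq = 0.3,
                    class_mix = c(N = 1, A = 0, L = 0, R = 0, V = 0))
  rec <- make_record(60, cfg)
  den <- denoise(rec)
  band_power <- function(x) {
    s <- stats::spec.pgram(stats::ts(x, frequency = 360), plot = FALSE,
                           taper = 0)
    sum(s$spec[s$freq < 0.5])
  }
  expect_lt(band_power(den$samples), 0.1 * band_power(rec$samples))
})

test_that("denoising reduces white-noise RMSE", {
  # sparse beat train so the clean reference has negligible sub-0.7 Hz power
  clean <- make_record(3, clean_config(seed = 3, hr = 6))
  noisy <- clean
  set.seed(9)
  noisy$samples <- clean$samples + rnorm(length(clean$samples), 0, 0.05)
  den <- denoise(noisy)
  rmse <- function(a, b) sqrt(mean((a - b)^2))
  expect_lt(rmse(den$samples, clean$samples),
            rmse(noisy$samples, clean$samples))
})

test_that("denoise rejects signals shorter than the decomposition", {
  rec <- ecg_record(rnorm(100), 360, integer(0), character(0))
  expect_error(denoise(rec, levels = 8), "too short")
})

test_that("segmentation extracts [r-100, r+149] windows", {
  x <- rnorm(1000)
  rec <- ecg_record(x, 360, c(50L, 500L, 920L), c("N", "V", "N"))
  bm <- segment_beats(rec)
  # peak at 50 lacks pre-R context; peak at 920 lacks post-R context
  expect_identical(nrow(bm$beats), 1L)
  expect_identical(attr(bm, "n_skipped"), 2L)
  expect_equal(bm$beats[1, ], x[400:649])
  expect_identical(bm$labels, "V")
})

test_that("segmentation counts every peak as kept or skipped", {
  rec <- make_record(12, sim_config(seed = 6))
  bm <- segment_beats(rec)
  expect_identical(nrow(bm$beats) + attr(bm, "n_skipped"),
                   length(rec$r_peaks))
})

test_that("segmentation of a record with no usable peak warns, not errors", {
  rec <- ecg_record(rnorm(120), 360, 60L, "N")
  expect_warning(bm <- segment_beats(rec), "skipped")
  expect_identical(nrow(bm$beats), 0L)
})

test_that("segmentation requires 360 Hz input", {
  rec <- make_record(3, clean_config(seed = 1, fs = 560))
  expect_error(segment_beats(rec), "360")
})

test_that("normalization maps min/max to -1/+1 by the affine closed form", {
  x <- seq(0, 4, length.out = 250)
  y <- normalize_beat(x)
  expect_equal(y[1], -1)
  expect_equal(y[250], 1)
  expect_equal(y[125], 2 * (x[125] - 0) / 4 - 1)
  b <- make_beat("N", sim_config(seed = 5))
  nb <- normalize_beat(b)
  expect_equal(min(nb), -1)
  expect_equal(max(nb), 1)
})

test_that("normalization is idempotent and zero on degenerate beats", {
  b <- make_beat("L", sim_config(seed = 6))
  expect_equal(normalize_beat(normalize_beat(b)), normalize_beat(b))
  expect_identical(normalize_beat(rep(2.5, 250)), numeric(250))
  expect_error(normalize_beat(c(1, NA, rep(0, 248))), "non-finite")
  m <- rbind(seq_len(250), rep(1, 250))
  nm <- normalize_beats(m)
  expect_equal(nm[1, 1], -1)
  expect_identical(nm[2, ], rep(0, 250))
})

test_that("the full pipeline recovers template beats from a 560 Hz record", {
  cfg <- sim_config(fs = 560, seed = 5, noise_sd = 0.02, baseline_amp = 0.1,
                    class_mix = c(N = 1, A = 0, L = 0, R = 0, V = 0))
  rec <- make_record(12, cfg)
  bm <- preprocess_record(rec)
  expect_identical(ncol(bm$beats), 250L)
  expect_equal(unname(apply(bm$beats, 1, min)), rep(-1, nrow(bm$beats)))
  expect_equal(unname(apply(bm$beats, 1, max)), rep(1, nrow(bm$beats)))
  ref <- make_beat("N", clean_config(seed = 99))
  cors <- apply(bm$beats, 1, cor, y = ref)
  expect_true(all(cors > 0.95))
})
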