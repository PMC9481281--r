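# Synthetic beat and record generator.

test_that("beats are 250 samples with the R peak anchored at position 101", {
  for (cl in beat_classes()) {
    b <- make_beat(cl, sim_config(seed = 1))
    expect_length(b, 250)
    expect_identical(which.max(abs(b)), 101L)
  }
})

test_that("class morphologies are honored", {
  cfg <- clean_config(seed = 1)
  bN <- make_beat("N", cfg)
  bV <- make_beat("V", cfg)
  bA <- make_beat("A", cfg)
  # V: broader QRS than N, no P wave, inverted T
  expect_gt(qrs_width(bV), qrs_width(bN))
  p_window <- 30:60                      # N-beat P wave, clear of V's wide Q
  expect_gt(max(bN[p_window]), 3 * max(abs(bV[p_window])))
  t_window <- 160:230
  expect_gt(max(bN[t_window]), 0)
  expect_lt(min(bV[t_window]), 0)
  # A: P wave earlier and smaller than N's
  expect_lt(which.max(bA[1:90]), which.max(bN[1:90]))
  expect_lt(max(bA[1:90]), max(bN[1:90]))
  # L: notched wide QRS (secondary lobe after R), R: secondary R' deflection
  bL <- make_beat("L", cfg)
  bR <- make_beat("R", cfg)
  expect_gt(qrs_width(bL), qrs_width(bN))
  expect_gt(max(bR[115:130]), 0.3)       # R' wave ~40-80 ms after R
})

test_that("unknown class labels are rejected", {
  expect_error(make_beat("X", sim_config()), "unknown beat class")
  expect_error(make_beat("n", sim_config()), "unknown beat class")
})

test_that("generation is seed-deterministic", {
  cfg <- sim_config(seed = 7)
  expect_identical(make_beat("N", cfg), make_beat("N", cfg))
  expect_identical(make_record(5, cfg), make_record(5, cfg))
  d1 <- make_dataset(10, 5, 5, sim_config(seed = 3))
  d2 <- make_dataset(10, 5, 5, sim_config(seed = 3))
  expect_identical(d1, d2)
  expect_false(identical(make_beat("N", sim_config(seed = 1)),
                         make_beat("N", sim_config(seed = 2))))
})

test_that("records place beats at the configured rate", {
  rec <- make_record(10, clean_config(seed = 2, hr = 60))
  expect_s3_class(rec, "ecg_record")
  expect_length(rec$r_peaks, 10)
  expect_true(all(diff(rec$r_peaks) == 360L))
  expect_length(rec$beat_labels, 10)

  rec560 <- make_record(5, clean_config(seed = 2, fs = 560, hr = 60))
  expect_equal(rec560$fs, 560)
  expect_true(all(diff(rec560$r_peaks) == 560L))
})

test_that("record generation validates its inputs", {
  expect_error(make_record(0, sim_config()), ">= 1")
  expect_error(sim_config(heart_rate_bpm = -10), "heart_rate_bpm")
  expect_error(sim_config(class_mix = c(N = 0.5, A = 0.5)), "class_mix")
})

test_that("noise and baseline wander are applied as configured", {
  quiet <- make_record(5, clean_config(seed = 3))
  noisy <- make_record(5, sim_config(seed = 3, noise_sd = 0.05,
                                     baseline_amp = 0,
                                     class_mix = c(N = 1, A = 0, L = 0,
                                                   R = 0, V = 0)))
  resid <- noisy$samples - quiet$samples
  expect_gt(sd(resid), 0.04)
  expect_lt(sd(resid), 0.06)

  wander <- make_record(5, sim_config(seed = 3, noise_sd = 0,
                                      baseline_amp = 0.2, baseline_freq = 0.3,
                                      class_mix = c(N = 1, A = 0, L = 0,
                                                    R = 0, V = 0)))
  tgrid <- (seq_along(wander$samples) - 1) / wander$fs
  expect_equal(wander$samples - quiet$samples,
               0.2 * sin(2 * pi * 0.3 * tgrid), tolerance = 1e-12)
})

test_that("datasets respect the one-class split contract", {
  ds <- make_dataset(100, 50, 50, sim_config(seed = 3))
  expect_identical(dim(ds$train$beats), c(100L, 250L))
  expect_true(all(ds$train$labels == "N"))
  expect_identical(dim(ds$test$beats), c(100L, 250L))
  expect_identical(sum(ds$test$labels == "N"), 50L)
  expect_true(all(ds$test$labels[51:100] %in% c("A", "L", "R", "V")))
  # rows are normalized
  expect_equal(unname(apply(ds$train$beats, 1, min)), rep(-1, 100))
  expect_equal(unname(apply(ds$train$beats, 1, max)), rep(1, 100))
})

test_that("abnormal test beats require abnormal mass in the class mix", {
  all_n <- sim_config(seed = 1, class_mix = c(N = 1, A = 0, L = 0, R = 0,
                                              V = 0))
  expect_error(make_dataset(5, 5, 5, all_n), "no mass")
  expect_silent(make_dataset(5, 5, 0, all_n))
})

test_that("all four abnormal classes appear under a uniform mix", {
  cfg <- sim_config(seed = 3, class_mix = uniform_abnormal_mix)
  seen <- unique(unlist(lapply(1:12, function(s)
    make_dataset(0, 0, 4, sim_config(seed = s,
                                     class_mix = uniform_abnormal_mix)
    )$test$labels)))
  expect_setequal(seen, c("A", "L", "R", "V"))
  # frequencies roughly uniform over many draws
  labs <- unlist(lapply(1:50, function(s)
    make_dataset(0, 0, 4, sim_config(seed = 100 + s,
                                     class_mix = uniform_abnormal_mix)
    )$test$labels))
  tab <- table(labs) / length(labs)
  expect_true(all(tab > 0.12 & tab < 0.40))
})

test_that("V and N beats are separable at the signal level", {
  vs <- t(vapply(1:50, function(s)
    make_beat("V", clean_config(seed = s,
                                mix = c(N = 0, A = 0, L = 0, R = 0, V = 1))),
    numeric(250)))
  ns <- t(vapply(1:50, function(s) make_beat("N", clean_config(seed = s)),
                 numeric(250)))
  d_between <- mean(sqrt(rowSums((vs - ns)^2)))
  within <- as.matrix(dist(ns))
  d_within <- mean(within[upper.tri(within)])
  expect_gt(d_between, d_within)
})

test_that("segmenting a noiseless record recovers the placed beats", {
  rec <- make_record(8, clean_config(seed = 11))
  bm <- segment_beats(rec)
  ref <- make_beat("N", clean_config(seed = 99))
  cors <- apply(bm$beats, 1, cor, y = ref)
  expect_true(all(cors > 0.95))
})
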