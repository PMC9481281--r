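# Synthetic single-lead ECG: Gaussian-wave beat morphologies, annotated
# records, and ready-made train/test beat matrices. Every generator is fully
# determined by the seed in its sim_config.

#' Simulation configuration for the synthetic ECG generator
#'
#' @param fs Sampling rate in Hz. Beat-level output ([make_beat()],
#'   [make_dataset()]) is always on the 360 Hz / 250-sample grid; `fs` applies
#'   to full records from [make_record()].
#' @param heart_rate_bpm Heart rate in beats per minute (fixed RR intervals).
#' @param noise_sd Standard deviation of additive white Gaussian noise, in the
#'   same arbitrary units as the signal (R-wave amplitude is ~1).
#' @param baseline_amp,baseline_freq Amplitude (a.u.) and frequency (Hz) of a
#'   single-tone sinusoidal baseline wander added to records.
#' @param seed Integer seed; identical configs give bit-identical output.
#' @param class_mix Named numeric proportions over the five beat classes
#'   (see [beat_classes()]); must sum to 1.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(fs = 360, heart_rate_bpm = 70, noise_sd = 0.03,
                       baseline_amp = 0.1, baseline_freq = 0.3, seed = 1L,
                       class_mix = c(N = 0.8, A = 0.05, L = 0.05,
                                     R = 0.05, V = 0.05)) {
  check_scalar_num(fs, "fs", 0, strict_lower = TRUE)
  check_scalar_num(heart_rate_bpm, "heart_rate_bpm", 0, strict_lower = TRUE)
  check_scalar_num(noise_sd, "noise_sd", 0)
  check_scalar_num(baseline_amp, "baseline_amp", 0)
  check_scalar_num(baseline_freq, "baseline_freq", 0)
  if (is.null(names(class_mix)) || !setequal(names(class_mix), beat_classes()))
    stopf("`class_mix` must be named with exactly the classes %s",
          paste(beat_classes(), collapse = ", "))
  class_mix <- class_mix[beat_classes()]
  if (any(class_mix < 0) || abs(sum(class_mix) - 1) > 1e-8)
    stopf("`class_mix` proportions must be nonnegative and sum to 1")
  structure(list(fs = fs, heart_rate_bpm = heart_rate_bpm,
                 noise_sd = noise_sd, baseline_amp = baseline_amp,
                 baseline_freq = baseline_freq, seed = as.integer(seed),
                 class_mix = class_mix),
            class = "sim_config")
}

# Gaussian wave components per class: amplitude (a.u.), center (s, relative to
# the R peak) and width (s, Gaussian sigma). The R component always dominates
# in |amplitude| and sits at center 0. Abnormal morphologies are caricatures
# chosen for separability, not clinical fidelity: V drops the P wave, doubles
# the QRS width and inverts T; L adds a second merged R lobe (notched broad
# QRS); R adds a late R' deflection and a deep S; A advances the P wave by
# 40 ms at half amplitude.
#' @noRd
beat_template <- function(class_label) {
  w <- switch(class_label,
    N = list(P  = c( 0.15, -0.160, 0.022),
             Q  = c(-0.10, -0.035, 0.010),
             R  = c( 1.00,  0.000, 0.012),
             S  = c(-0.22,  0.035, 0.011),
             T  = c( 0.30,  0.250, 0.045)),
    A = list(P  = c( 0.075, -0.200, 0.022),  # advanced, halved P
             Q  = c(-0.10, -0.035, 0.010),
             R  = c( 1.00,  0.000, 0.012),
             S  = c(-0.22,  0.035, 0.011),
             T  = c( 0.30,  0.250, 0.045)),
    L = list(P  = c( 0.15, -0.160, 0.022),
             Q  = c(-0.08, -0.050, 0.012),
             R  = c( 1.00,  0.000, 0.018),
             R2 = c( 0.70,  0.040, 0.018),   # merged second lobe (notch)
             S  = c(-0.15,  0.090, 0.014),
             T  = c(-0.25,  0.270, 0.050)),
    R = list(P  = c( 0.15, -0.160, 0.022),
             Q  = c(-0.10, -0.040, 0.010),
             R  = c( 1.00,  0.000, 0.012),
             S  = c(-0.45,  0.030, 0.014),   # deep S
             Rp = c( 0.50,  0.055, 0.016),   # secondary R'
             T  = c( 0.25,  0.260, 0.045)),
    V = list(Q  = c(-0.15, -0.070, 0.020),   # no P wave
             R  = c( 1.05,  0.000, 0.024),   # broad QRS
             S  = c(-0.40,  0.070, 0.022),
             T  = c(-0.40,  0.300, 0.060)),  # inverted T
    stopf("unknown beat class '%s' (expected one of %s)", class_label,
          paste(beat_classes(), collapse = ", ")))
  m <- do.call(rbind, w)
  data.frame(wave = names(w), amp = m[, 1], center = m[, 2], width = m[, 3],
             row.names = NULL)
}

# Evaluate a (possibly jittered) template at times t (seconds from R peak).
#' @noRd
eval_template <- function(tpl, t) {
  y <- numeric(length(t))
  for (i in seq_len(nrow(tpl)))
    y <- y + tpl$amp[i] * exp(-((t - tpl$center[i])^2) / (2 * tpl$width[i]^2))
  y
}

# Draw a morphologically jittered copy of a class template from the current
# RNG stream. The R-lobe centers stay fixed so the anchor does not drift.
#' @noRd
jitter_template <- function(class_label) {
  tpl <- beat_template(class_label)
  n <- nrow(tpl)
  tpl$amp <- tpl$amp * (1 + rnorm(n, 0, 0.05))
  tpl$width <- tpl$width * (1 + rnorm(n, 0, 0.04))
  shift <- ifelse(tpl$wave %in% c("R", "R2", "Rp"), 0, rnorm(n, 0, 0.002))
  tpl$center <- tpl$center + shift
  tpl
}

# One 250-sample beat from the current RNG stream. Generated on a padded grid
# and cut around the empirical |signal| maximum of the QRS region so that the
# R peak lands exactly at position 101 (100 samples pre-R, 149 post-R).
#' @noRd
gen_beat <- function(class_label, noise_sd) {
  fs <- 360
  pad <- 30L
  t <- (seq_len(250L + 2L * pad) - (101L + pad)) / fs
  x <- eval_template(jitter_template(class_label), t)
  if (noise_sd > 0) x <- x + rnorm(length(x), 0, noise_sd)
  qrs <- (101L + pad) + (-12L:12L)       # +-33 ms search window
  r <- qrs[which.max(abs(x[qrs]))]
  x[(r - 100L):(r + 149L)]
}

#' Generate one synthetic 250-sample heartbeat
#'
#' The beat lies on the 360 Hz grid with the R peak anchored at position 101
#' (100 samples before it, 149 after), mirroring the segmentation contract of
#' [segment_beats()]. Morphology follows the class template with small random
#' amplitude/width/timing jitter plus white noise of `config$noise_sd`.
#'
#' @param class_label One of [beat_classes()].
#' @param config A [sim_config()]; its seed fully determines the output.
#' @return Numeric vector of length 250.
#' @examples
#' b <- make_beat("N", sim_config(seed = 1))
#' which.max(abs(b))  # 101
#' @export
make_beat <- function(class_label, config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.character(class_label) || length(class_label) != 1L ||
      !(class_label %in% beat_classes()))
    stopf("unknown beat class '%s' (expected one of %s)",
          as.character(class_label)[1], paste(beat_classes(), collapse = ", "))
  with_seed(config$seed, gen_beat(class_label, config$noise_sd))
}

#' Annotated ECG record container
#'
#' @param samples Numeric signal vector (arbitrary units).
#' @param fs Sampling rate (Hz).
#' @param r_peaks Strictly increasing 1-based sample indices of R peaks.
#' @param beat_labels Beat class per R peak (same length as `r_peaks`).
#' @return A list of class `ecg_record`.
#' @export
ecg_record <- function(samples, fs, r_peaks, beat_labels) {
  if (!is.numeric(samples)) stopf("`samples` must be numeric")
  check_scalar_num(fs, "fs", 0, strict_lower = TRUE)
  r_peaks <- as.integer(r_peaks)
  if (length(r_peaks) && (any(diff(r_peaks) <= 0L) ||
      r_peaks[1] < 1L || r_peaks[length(r_peaks)] > length(samples)))
    stopf("`r_peaks` must be strictly increasing indices within the signal")
  if (length(beat_labels) != length(r_peaks))
    stopf("`beat_labels` must have one entry per R peak")
  structure(list(samples = as.numeric(samples), fs = fs, r_peaks = r_peaks,
                 beat_labels = as.character(beat_labels)),
            class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record> %d samples @ %g Hz (%.1f s), %d annotated beats\n",
              length(x$samples), x$fs, length(x$samples) / x$fs,
              length(x$r_peaks)))
  invisible(x)
}

#' Generate an annotated synthetic ECG record
#'
#' Beats of classes drawn from `config$class_mix` are placed at fixed RR
#' intervals of `60 / heart_rate_bpm` seconds on a grid at `config$fs`;
#' sinusoidal baseline wander and white Gaussian noise are added on top.
#'
#' @param n_beats Number of beats (>= 1).
#' @param config A [sim_config()].
#' @return An [ecg_record()] with `r_peaks` and `beat_labels` filled in.
#' @export
make_record <- function(n_beats, config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.numeric(n_beats) || length(n_beats) != 1L || n_beats < 1)
    stopf("`n_beats` must be >= 1")
  n_beats <- as.integer(n_beats)
  if (config$heart_rate_bpm <= 0) stopf("heart rate must be positive")
  with_seed(config$seed, {
    fs <- config$fs
    rr <- 60 / config$heart_rate_bpm                   # seconds per beat
    n_samp <- as.integer(round((n_beats + 1) * rr * fs))
    tgrid <- (seq_len(n_samp) - 1L) / fs
    labels <- sample(beat_classes(), n_beats, replace = TRUE,
                     prob = config$class_mix)
    x <- numeric(n_samp)
    centers <- rr * seq_len(n_beats)
    for (i in seq_len(n_beats)) {
      tpl <- jitter_template(labels[i])
      lo <- max(1L, as.integer(floor((centers[i] - 0.45) * fs)))
      hi <- min(n_samp, as.integer(ceiling((centers[i] + 0.55) * fs)))
      idx <- lo:hi
      x[idx] <- x[idx] + eval_template(tpl, tgrid[idx] - centers[i])
    }
    if (config$baseline_amp > 0)
      x <- x + config$baseline_amp *
        sin(2 * pi * config$baseline_freq * tgrid)
    if (config$noise_sd > 0) x <- x + rnorm(n_samp, 0, config$noise_sd)
    r_peaks <- as.integer(round(centers * fs)) + 1L
    ecg_record(x, fs, r_peaks, labels)
  })
}

#' Beat matrix container
#'
#' Rows are 250-sample beats (each a network input X); `labels` carries the
#' beat class per row and `source_ids` free-form provenance strings.
#'
#' @param beats Numeric matrix with 250 columns.
#' @param labels Character vector, one class per row.
#' @param source_ids Optional provenance strings (recycled if length 1).
#' @return A list of class `beat_matrix`.
#' @export
beat_matrix <- function(beats, labels = rep("N", nrow(beats)),
                        source_ids = rep("synthetic", nrow(beats))) {
  beats <- as.matrix(beats)
  if (nrow(beats) > 0 && ncol(beats) != 250L)
    stopf("beats must have exactly 250 columns, got %d", ncol(beats))
  if (length(labels) != nrow(beats))
    stopf("`labels` must have one entry per beat row")
  if (length(source_ids) == 1L) source_ids <- rep(source_ids, nrow(beats))
  structure(list(beats = beats, labels = as.character(labels),
                 source_ids = as.character(source_ids)),
            class = "beat_matrix")
}

#' @export
print.beat_matrix <- function(x, ...) {
  tab <- table(factor(x$labels, levels = beat_classes()))
  cat(sprintf("<beat_matrix> %d beats x %d samples (%s)\n", nrow(x$beats),
              ncol(x$beats),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Generate train/test beat matrices for the one-class experiment
#'
#' The training matrix holds only normal (N) beats; the test matrix holds the
#' requested numbers of normal and abnormal beats, the abnormal classes drawn
#' from `config$class_mix` restricted to A/L/R/V. All beats are on the 250-
#' sample grid and min-max normalized to \[-1, 1\] (see [normalize_beats()]).
#'
#' @param n_train_normal,n_test_normal,n_test_abnormal Nonnegative counts.
#' @param config A [sim_config()].
#' @return List with elements `train` and `test`, both [beat_matrix()].
#' @export
make_dataset <- function(n_train_normal, n_test_normal, n_test_abnormal,
                         config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  for (n in c(n_train_normal, n_test_normal, n_test_abnormal))
    if (!is.numeric(n) || length(n) != 1L || n < 0)
      stopf("beat counts must be nonnegative")
  abn_mix <- config$class_mix[abnormal_classes()]
  if (n_test_abnormal > 0 && sum(abn_mix) <= 0)
    stopf("cannot draw abnormal beats: class_mix assigns no mass to A/L/R/V")
  with_seed(config$seed, {
    draw <- function(labels) {
      if (!length(labels))
        return(matrix(numeric(0), nrow = 0, ncol = 250L))
      t(vapply(labels, function(cl) gen_beat(cl, config$noise_sd),
               numeric(250L)))
    }
    train_lab <- rep("N", n_train_normal)
    abn_lab <- if (n_test_abnormal > 0)
      sample(abnormal_classes(), n_test_abnormal, replace = TRUE,
             prob = abn_mix / sum(abn_mix)) else character(0)
    test_lab <- c(rep("N", n_test_normal), abn_lab)
    train <- beat_matrix(normalize_beats(draw(train_lab)), train_lab,
                         rep("sim-train", length(train_lab)))
    test <- beat_matrix(normalize_beats(draw(test_lab)), test_lab,
                        rep("sim-test", length(test_lab)))
    list(train = train, test = test)
  })
}
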