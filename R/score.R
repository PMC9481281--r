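# Outlier detector: per-beat anomaly scores, threshold fitted on training
# scores as mean + 1 standard deviation, strict-> classification.

#' Per-beat reconstruction-error score R(x)
#'
#' Mean-squared error between each beat and its autoencoder reconstruction,
#' with dropout disabled (deterministic). Abnormal beats, which the one-class
#' autoencoder never saw, reconstruct worse and score higher.
#'
#' @param x Beats: vector, `n x 250` matrix or [beat_matrix()].
#' @param params Trained [init_params()] object.
#' @return Nonnegative score per beat.
#' @export
r_score <- function(x, params) {
  stopifnot(inherits(params, "aae_params"))
  if (inherits(x, "beat_matrix")) x <- x$beats
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  as.vector(rowMeans((x - reconstruct(x, params))^2))
}

#' Combined anomaly score a(x)
#'
#' `a(x) = (1 - lambda) R(x) + lambda / D(x)`: the discriminator assigns low
#' probabilities to abnormal beats, so its reciprocal adds to the anomaly
#' evidence. `D` is floored at 1e-7 before division so the term stays finite.
#' With `lambda = 0` (the default operating point) the score reduces exactly
#' to the reconstruction error.
#'
#' @param r Reconstruction scores, `>= 0`.
#' @param d Discriminator probabilities in (0, 1\].
#' @param lambda Mixing weight in \[0, 1\].
#' @return Numeric anomaly scores.
#' @export
anomaly_score <- function(r, d, lambda = 0) {
  check_scalar_num(lambda, "lambda", 0, 1)
  if (any(r < 0)) stopf("reconstruction scores must be nonnegative")
  if (lambda == 0) return(as.numeric(r))
  (1 - lambda) * r + lambda / pmax(d, 1e-7)
}

#' Fit the outlier threshold from training scores
#'
#' `T = mean(scores) + sd(scores)` with the sample (n-1) standard deviation:
#' one standard deviation above the mean of the anomaly scores that the
#' training set (normal beats only) receives.
#'
#' @param scores At least two numeric training-set anomaly scores.
#' @return The threshold T.
#' @examples
#' fit_threshold(c(1, 2, 3))  # 3
#' @export
fit_threshold <- function(scores) {
  if (length(scores) < 2L)
    stopf("need at least 2 scores to fit a threshold, got %d", length(scores))
  mean(scores) + sd(scores)
}

#' Classify beats by anomaly score
#'
#' A beat is abnormal iff its score is strictly greater than the threshold;
#' a score exactly equal to T is called normal.
#'
#' @param scores Numeric anomaly scores (possibly empty).
#' @param threshold Fitted threshold T.
#' @return Character vector in `{"normal", "abnormal"}`, same length.
#' @export
classify_scores <- function(scores, threshold) {
  if (missing(threshold) || is.null(threshold) || !is.finite(threshold))
    stopf("a fitted threshold is required")
  if (!length(scores)) return(character(0))
  ifelse(scores > threshold, "abnormal", "normal")
}

#' Score a beat set with the full detector
#'
#' Computes R(x), D(x) and the combined anomaly score for every beat; the
#' threshold slot stays empty until [fit_threshold()] scores are available.
#'
#' @param x Beats (vector, matrix or [beat_matrix()]).
#' @param params Trained [init_params()] object.
#' @param lambda Mixing weight of [anomaly_score()].
#' @return A list of class `score_set`: data frame `scores` (columns
#'   `r_score`, `d_score`, `anomaly`, plus `label` when the input carried
#'   labels), `lambda` and `threshold` (NA until set).
#' @export
score_beats <- function(x, params, lambda = 0) {
  labels <- if (inherits(x, "beat_matrix")) x$labels else NULL
  r <- r_score(x, params)
  d <- discriminate(x, params)
  a <- anomaly_score(r, d, lambda)
  df <- data.frame(r_score = r, d_score = d, anomaly = a)
  if (!is.null(labels)) df$label <- labels
  structure(list(scores = df, lambda = lambda, threshold = NA_real_),
            class = "score_set")
}

#' @export
print.score_set <- function(x, ...) {
  cat(sprintf(
    "<score_set> %d beats, lambda = %g, threshold = %s\n  anomaly: %s\n",
    nrow(x$scores), x$lambda,
    if (is.na(x$threshold)) "unset" else format(x$threshold, digits = 4),
    paste(format(quantile(x$scores$anomaly, c(0, .5, 1)), digits = 3),
          collapse = " / ")))
  invisible(x)
}
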