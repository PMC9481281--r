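# Periodized multilevel discrete wavelet transform. The analysis operator is
# the orthonormal matrix whose rows are even circular translates of the
# scaling/wavelet filters, so the inverse is its adjoint and reconstruction is
# exact to machine precision (tested). Implemented here because no wavelet
# package ships with the R stack this package targets.

# Daubechies-6 (12-tap) scaling filter; the wavelet filter is derived by the
# quadrature-mirror relation g[k] = (-1)^(k+1) h[M-1-k].
#' @noRd
db6_filter <- function() {
  c(-0.0010773010853084796, 0.004777257510945511, 0.0005538422011614961,
    -0.03158203931748603, 0.027522865530305727, 0.09750160558732304,
    -0.12976686756726194, -0.22626469396543983, 0.31525035170919763,
    0.7511339080210954, 0.49462389039845306, 0.11154074335010947)
}

#' @noRd
wavelet_filters <- function(wavelet = "db6") {
  h <- if (is.numeric(wavelet)) wavelet
  else if (identical(wavelet, "db6")) db6_filter()
  else if (identical(wavelet, "haar")) rep(1 / sqrt(2), 2)
  else stopf("unknown wavelet '%s' (use 'db6', 'haar' or a scaling filter)",
             wavelet)
  m <- length(h)
  if (m %% 2L != 0L) stopf("scaling filter length must be even")
  g <- (-1)^(seq_len(m)) * rev(h)      # (-1)^(k+1) with 0-based k
  list(lo = h, hi = g)
}

# One analysis step on an even-length vector (circular).
#' @noRd
dwt_step <- function(x, flt) {
  n <- length(x)
  n2 <- n %/% 2L
  k2 <- 2L * (seq_len(n2) - 1L)                 # 0-based even translates
  a <- numeric(n2); d <- numeric(n2)
  for (m in seq_along(flt$lo)) {
    idx <- ((k2 + m - 1L) %% n) + 1L
    a <- a + flt$lo[m] * x[idx]
    d <- d + flt$hi[m] * x[idx]
  }
  list(a = a, d = d)
}

# Adjoint (exact inverse) of dwt_step.
#' @noRd
idwt_step <- function(a, d, flt) {
  n2 <- length(a)
  n <- 2L * n2
  x <- numeric(n)
  k2 <- 2L * (seq_len(n2) - 1L)
  for (m in seq_along(flt$lo)) {
    idx <- ((k2 + m - 1L) %% n) + 1L
    contrib <- flt$lo[m] * a + flt$hi[m] * d
    x[idx] <- x[idx] + contrib
  }
  x
}

#' Multilevel periodized discrete wavelet transform
#'
#' @param x Numeric vector whose length is a multiple of `2^levels`.
#' @param levels Number of decomposition levels.
#' @param wavelet `"db6"` (default), `"haar"`, or an even-length numeric
#'   scaling filter.
#' @return List with `approx` (deepest-level approximation) and `details`
#'   (list of detail coefficient vectors, level 1 first).
#' @seealso [idwt()] for the exact inverse, [denoise()] for the ECG use.
#' @export
dwt <- function(x, levels, wavelet = "db6") {
  flt <- wavelet_filters(wavelet)
  n <- length(x)
  if (levels < 1L) stopf("`levels` must be >= 1")
  if (n %% (2^levels) != 0L)
    stopf("signal length %d is not a multiple of 2^%d", n, levels)
  details <- vector("list", levels)
  a <- x
  for (j in seq_len(levels)) {
    s <- dwt_step(a, flt)
    details[[j]] <- s$d
    a <- s$a
  }
  list(approx = a, details = details)
}

#' Inverse multilevel periodized discrete wavelet transform
#'
#' @param coef List as returned by [dwt()].
#' @param wavelet Same filter used for the forward transform.
#' @return Reconstructed numeric vector.
#' @export
idwt <- function(coef, wavelet = "db6") {
  flt <- wavelet_filters(wavelet)
  a <- coef$approx
  for (j in rev(seq_along(coef$details)))
    a <- idwt_step(a, coef$details[[j]], flt)
  a
}
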