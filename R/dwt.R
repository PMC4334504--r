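## Daubechies-4 (8-tap) decomposition filters. dec_hi is the quadrature
## mirror of dec_lo; sum(dec_hi) == 0, so detail bands annihilate constant
## signals exactly, including across the symmetric boundary extension.
DB4_DEC_LO <- c(-0.010597401785069032, 0.0328830116668852,
                 0.030841381835560764, -0.18703481171909309,
                -0.027983769416859854, 0.6308807679298589,
                 0.7148465705529157,    0.2303778133088965)
DB4_DEC_HI <- c(-0.2303778133088965,   0.7148465705529157,
                -0.6308807679298589,  -0.027983769416859854,
                 0.18703481171909309,  0.030841381835560764,
                -0.0328830116668852,  -0.010597401785069032)

## Half-point symmetric extension: [x_p .. x_1 | x | x_n .. x_{n-p+1}].
symmetric_pad <- function(x, p) {
  n <- length(x)
  if (p > n) stop("signal too short for symmetric extension", call. = FALSE)
  c(rev(x[seq_len(p)]), x, rev(x)[seq_len(p)])
}

## Single analysis step: symmetric pad by (filter length - 1), valid
## convolution, keep every second output sample.
dwt_step <- function(x, filt) {
  p <- length(filt) - 1L
  xp <- symmetric_pad(x, p)
  n_out <- length(xp) - p
  y <- numeric(n_out)
  for (i in seq_len(n_out)) {
    y[i] <- sum(filt * xp[(i + p):i])
  }
  y[seq(2L, length(y), by = 2L)]
}

#' Multilevel db4 wavelet decomposition
#'
#' Pyramid decomposition of a real signal with the Daubechies-4 filter pair
#' and half-point symmetric boundary extension. Each level convolves the
#' current approximation with the low- and high-pass analysis filters and
#' downsamples by two.
#'
#' @param x Numeric signal.
#' @param level Decomposition depth (default 4).
#' @return List with `approximation` (the level-`level` coefficients) and
#'   `details` (list of detail coefficients, element `i` from level `i`;
#'   level 1 is the finest band).
#' @export
dwt_decompose <- function(x, level = 4L) {
  if (length(x) < 2^level) {
    stop(sprintf(
      "signal length %d too short for a level-%d decomposition (needs >= %d); use a lower level",
      length(x), level, 2^level), call. = FALSE)
  }
  details <- vector("list", level)
  a <- x
  for (l in seq_len(level)) {
    details[[l]] <- dwt_step(a, DB4_DEC_HI)
    a <- dwt_step(a, DB4_DEC_LO)
  }
  list(approximation = a, details = details)
}
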