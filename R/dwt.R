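# Single-level 2-D discrete wavelet transform, Daubechies-2 (two vanishing
# moments), periodized so every sub-band of an even-sized input is exactly
# half resolution. The analysis operator is orthonormal, which gives exact
# (adjoint = inverse) reconstruction and Parseval energy conservation; the
# network exploits the adjoint for backpropagation through the wavelet gate.

# Db2 analysis filters. dec_lo is the reversed scaling filter
# ((1+sqrt3, 3+sqrt3, 3-sqrt3, 1-sqrt3)/(4 sqrt2)); dec_hi is its quadrature
# mirror. Both have unit norm; dec_lo sums to sqrt(2), dec_hi to 0.
.db2_dec_lo <- local({
  s3 <- sqrt(3)
  rev(c(1 + s3, 3 + s3, 3 - s3, 1 - s3) / (4 * sqrt(2)))
})
.db2_dec_hi <- local({
  lo <- .db2_dec_lo
  c(-lo[4], lo[3], -lo[2], lo[1])
})

# Cache of periodized analysis matrices (N/2 x N), keyed by N.
.dwt_cache <- new.env(parent = emptyenv())

.dwt_matrices <- function(n) {
  key <- as.character(n)
  if (!is.null(.dwt_cache[[key]])) return(.dwt_cache[[key]])
  lo <- matrix(0, n / 2, n)
  hi <- matrix(0, n / 2, n)
  # periodized analysis: a[i] = sum_j f[j] x[(2i - 1 + j - 1) mod n + 1]
  # with f the time-reversed decomposition filter (the convention of the
  # usual reference implementations, so coefficients agree exactly)
  flo <- rev(.db2_dec_lo)
  fhi <- rev(.db2_dec_hi)
  for (i in seq_len(n / 2)) {
    for (j in 1:4) {
      col <- ((2 * (i - 1) - 1 + (j - 1)) %% n) + 1
      lo[i, col] <- lo[i, col] + flo[j]
      hi[i, col] <- hi[i, col] + fhi[j]
    }
  }
  m <- list(lo = lo, hi = hi)
  .dwt_cache[[key]] <- m
  m
}

.dwt2_mat <- function(x) {
  h <- nrow(x); w <- ncol(x)
  mr <- .dwt_matrices(h); mc <- .dwt_matrices(w)
  lr <- mr$lo %*% x
  hr <- mr$hi %*% x
  list(LL = lr %*% t(mc$lo), LH = hr %*% t(mc$lo),
       HL = lr %*% t(mc$hi), HH = hr %*% t(mc$hi))
}

.idwt2_mat <- function(b) {
  h <- 2 * nrow(b$LL); w <- 2 * ncol(b$LL)
  mr <- .dwt_matrices(h); mc <- .dwt_matrices(w)
  t(mr$lo) %*% (b$LL %*% mc$lo + b$HL %*% mc$hi) +
    t(mr$hi) %*% (b$LH %*% mc$lo + b$HH %*% mc$hi)
}

#' Single-level Db2 wavelet decomposition of a feature map
#'
#' Decomposes each channel of a feature map into the four half-resolution
#' sub-bands of a single-level 2-D discrete wavelet transform: LL
#' (approximation), LH (horizontal detail, high-pass along rows), HL
#' (vertical detail, high-pass along columns) and HH (diagonal detail).
#' Daubechies-2 filters in periodization mode are used, so the transform is
#' orthonormal: energy is conserved across the four bands and
#' [idwt_bands()] reconstructs the input exactly (to numerical precision).
#'
#' @param x a numeric matrix (height x width) or 3-d array
#'   (height x width x channels) with even spatial dimensions.
#' @return an object of class `wavelet_bands`: a list with elements
#'   `LL`, `LH`, `HL`, `HH`, each of the same type as `x` at half the
#'   spatial resolution.
#' @examples
#' x <- matrix(rnorm(64), 8, 8)
#' b <- dwt_bands(x)
#' max(abs(idwt_bands(b) - x)) < 1e-10
#' @export
dwt_bands <- function(x) {
  mat_in <- is.matrix(x)
  if (mat_in) x <- array(x, c(dim(x), 1L))
  if (length(dim(x)) != 3L)
    stop("x must be a matrix or a height x width x channels array")
  d <- dim(x)
  if (d[1] %% 2 != 0 || d[2] %% 2 != 0)
    stop("dwt_bands requires even spatial dimensions, got ",
         d[1], " x ", d[2])
  if (d[1] < 4 || d[2] < 4)
    stop("dwt_bands requires spatial dimensions >= 4")
  if (!all(is.finite(x))) stop("x contains non-finite values")
  out <- list(LL = NULL, LH = NULL, HL = NULL, HH = NULL)
  half <- c(d[1] / 2, d[2] / 2, d[3])
  for (nm in names(out)) out[[nm]] <- array(0, half)
  for (c_ in seq_len(d[3])) {
    b <- .dwt2_mat(x[, , c_])
    for (nm in names(out)) out[[nm]][, , c_] <- b[[nm]]
  }
  if (mat_in) out <- lapply(out, function(a) a[, , 1])
  structure(out, class = "wavelet_bands")
}

#' Inverse of [dwt_bands()]
#'
#' @param bands a `wavelet_bands` object (or plain list with `LL`, `LH`,
#'   `HL`, `HH` entries of equal shape).
#' @return the reconstructed matrix or array at twice the sub-band
#'   resolution.
#' @export
idwt_bands <- function(bands) {
  b <- bands[c("LL", "LH", "HL", "HH")]
  if (any(vapply(b, is.null, logical(1))))
    stop("bands must contain LL, LH, HL and HH")
  mat_in <- is.matrix(b$LL)
  if (mat_in) b <- lapply(b, function(a) array(a, c(dim(a), 1L)))
  d <- dim(b$LL)
  out <- array(0, c(2 * d[1], 2 * d[2], d[3]))
  for (c_ in seq_len(d[3])) {
    out[, , c_] <- .idwt2_mat(lapply(b, function(a) a[, , c_]))
  }
  if (mat_in) out <- out[, , 1]
  out
}

# Batched DWT on (H, W, C, N) arrays; returns list of four (H/2, W/2, C, N)
# arrays. Used inside the wavelet gate.
.dwt_fwd_batch <- function(x) {
  d <- dim(x)
  half <- c(d[1] / 2, d[2] / 2, d[3], d[4])
  out <- list(LL = array(0, half), LH = array(0, half),
              HL = array(0, half), HH = array(0, half))
  for (n in seq_len(d[4])) for (c_ in seq_len(d[3])) {
    b <- .dwt2_mat(x[, , c_, n])
    for (nm in names(out)) out[[nm]][, , c_, n] <- b[[nm]]
  }
  out
}

# Adjoint (= inverse, orthonormal transform) of .dwt_fwd_batch: maps band
# gradients back to the input gradient.
.dwt_bwd_batch <- function(bands) {
  d <- dim(bands$LL)
  out <- array(0, c(2 * d[1], 2 * d[2], d[3], d[4]))
  for (n in seq_len(d[4])) for (c_ in seq_len(d[3])) {
    out[, , c_, n] <- .idwt2_mat(lapply(bands, function(a) a[, , c_, n]))
  }
  out
}
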