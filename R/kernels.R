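# Separable linear operators (sparse) used by resampling, filtering and the
# wavelet transform. All boundary handling is half-sample ("whole-sample
# mirror without repeating the edge" is NOT used): index q < 0 maps to
# -1 - q, q > n - 1 maps to 2n - 1 - q, applied repeatedly. Half-sample
# reflection keeps symmetric kernels mass-preserving, so constant planes are
# preserved exactly and block-mean decimation of an upsampled plane returns
# the original global mean.

reflect_index <- function(q, n) {
  # 0-based indices, vectorised
  while (any(q < 0 | q > n - 1)) {
    q <- ifelse(q < 0, -1 - q, q)
    q <- ifelse(q > n - 1, 2 * n - 1 - q, q)
  }
  q
}

cubic_weight <- function(x, a = -0.5) {
  # Keys cubic (Catmull-Rom at a = -0.5)
  x <- abs(x)
  ifelse(x <= 1,
         (a + 2) * x^3 - (a + 3) * x^2 + 1,
         ifelse(x < 2, a * x^3 - 5 * a * x^2 + 8 * a * x - 4 * a, 0))
}

# (r*n x n) sparse interpolation operator, block-centred sample positions
interp_operator <- function(n, r, method) {
  m <- n * r
  k <- seq_len(m) - 1
  p <- (k + 0.5) / r - 0.5    # source coordinate of each output sample
  if (method == "nearest") {
    j <- floor(p + 0.5)
    i_idx <- k + 1
    j_idx <- reflect_index(j, n) + 1
    w <- rep(1, m)
  } else if (method == "bilinear") {
    base <- floor(p)
    t <- p - base
    i_idx <- rep(k + 1, 2)
    j_idx <- reflect_index(c(base, base + 1), n) + 1
    w <- c(1 - t, t)
  } else if (method == "bicubic") {
    base <- floor(p)
    t <- p - base
    offs <- -1:2
    i_idx <- rep(k + 1, length(offs))
    j_idx <- reflect_index(rep(base, length(offs)) +
                             rep(offs, each = m), n) + 1
    w <- as.vector(vapply(offs, function(o) cubic_weight(t - o),
                          numeric(m)))
  } else {
    abort(paste0("unknown interpolation method: ", method))
  }
  keep <- w != 0
  Matrix::sparseMatrix(i = i_idx[keep], j = j_idx[keep], x = w[keep],
                       dims = c(m, n))
}

# (n/r x n) block-mean operator
block_mean_operator <- function(n, r) {
  m <- n %/% r
  Matrix::sparseMatrix(
    i = rep(seq_len(m), each = r),
    j = seq_len(n),
    x = rep(1 / r, n),
    dims = c(m, n)
  )
}

# n x n convolution operator for an odd symmetric kernel with optional
# dilation (`spacing` zeros-between-taps factor for the a-trous scheme)
conv_operator <- function(n, kernel, spacing = 1) {
  len <- length(kernel)
  if (len %% 2 == 0) abort("convolution kernel must have odd length")
  half <- (len - 1) / 2
  offs <- (-half:half) * spacing
  i_idx <- rep(seq_len(n), length(offs))
  j_idx <- reflect_index(rep(seq_len(n) - 1, length(offs)) +
                           rep(offs, each = n), n) + 1
  w <- rep(kernel, each = n)
  Matrix::sparseMatrix(i = i_idx, j = j_idx, x = w, dims = c(n, n))
}

# separable filtering of a matrix with reflection boundaries
sep_filter <- function(x, kernel, spacing = 1) {
  A <- conv_operator(nrow(x), kernel, spacing)
  B <- if (ncol(x) == nrow(x)) A else conv_operator(ncol(x), kernel, spacing)
  as.matrix(A %*% x %*% Matrix::t(B))
}

# frequency response of a symmetric odd kernel at normalised frequency f
# (cycles/sample)
kernel_response <- function(kernel, f) {
  half <- (length(kernel) - 1) / 2
  k <- -half:half
  as.vector(vapply(f, function(ff) sum(kernel * cos(2 * pi * ff * k)),
                   numeric(1)))
}

#' Gaussian kernel matched to a sensor MTF gain at Nyquist
#'
#' Builds a 1-D discrete Gaussian low-pass kernel whose frequency response
#' equals `gain` at the Nyquist frequency of the `ratio`-times-reduced grid
#' (normalised frequency `1/(2*ratio)` cycles/sample) and 1 at DC. The
#' standard deviation is solved numerically on the discrete response, so
#' the target gain is met to much better than 1e-3 even for narrow kernels
#' where the continuous-Gaussian formula is biased by aliasing.
#'
#' @param gain Target amplitude response in (0, 1) at the reduced-grid
#'   Nyquist frequency.
#' @param ratio Integer grid-reduction factor (1 targets the native grid's
#'   own Nyquist).
#' @return Numeric vector (odd length, sums to 1).
#' @export
mtf_gaussian_kernel <- function(gain, ratio) {
  if (gain <= 0 || gain >= 1) abort("`gain` must be in (0, 1)")
  if (ratio < 1) abort("`ratio` must be >= 1")
  f <- 1 / (2 * ratio)
  sigma0 <- ratio * sqrt(-2 * log(gain)) / pi  # continuous-domain solution
  make_kernel <- function(sigma, half) {
    k <- -half:half
    h <- exp(-k^2 / (2 * sigma^2))
    h / sum(h)
  }
  half <- max(3L, ceiling(4.5 * sigma0) + 1L)
  obj <- function(sigma) kernel_response(make_kernel(sigma, half), f) - gain
  sol <- uniroot(obj, lower = 0.05, upper = 4 * sigma0 + 4, tol = 1e-12)
  make_kernel(sol$root, half)
}

#' Apply an MTF-matched Gaussian low-pass filter to an image plane
#'
#' Separable Gaussian blur whose response at the Nyquist frequency of the
#' `ratio`-reduced grid equals `gain_at_nyquist`; DC gain is exactly 1, so
#' constant planes pass unchanged. Mimics the spatial-frequency response of
#' a satellite sensor characterised by its gain at Nyquist.
#'
#' @param plane Numeric matrix.
#' @param gain_at_nyquist Amplitude response in (0, 1) at the reduced-grid
#'   Nyquist.
#' @param ratio Integer reduction factor of the target grid.
#' @return Filtered matrix of the same size.
#' @export
mtf_filter <- function(plane, gain_at_nyquist, ratio) {
  kernel <- mtf_gaussian_kernel(gain_at_nyquist, ratio)
  sep_filter(as_pan_matrix(plane), kernel)
}

# orthonormal DCT-II basis matrix of order n
dct_matrix <- function(n) {
  x <- 0:(n - 1)
  C <- outer(x, x, function(u, xx) cos(pi * (2 * xx + 1) * u / (2 * n)))
  C <- C * sqrt(2 / n)
  C[1, ] <- C[1, ] / sqrt(2)
  C
}
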