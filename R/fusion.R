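# The four pansharpening algorithms and their shared machinery. All fusers
# take the multispectral image already expanded to the panchromatic grid
# (see upsample_ms) plus the panchromatic plane, and return a fused_image
# on the PAN grid. Negative fused values are clipped to zero; there is no
# upper clip.

fused_image <- function(pixels, bands, gsd, algorithm, params = list()) {
  out <- ms_image(pmax(pixels, 0), bands = bands, gsd = gsd)
  out$provenance <- c(list(algorithm = algorithm), params)
  class(out) <- c("fused_image", class(out))
  out
}

#' @export
print.fused_image <- function(x, ...) {
  NextMethod()
  cat("algorithm:", x$provenance$algorithm, "\n")
  invisible(x)
}

check_pan_grid <- function(ms_up, pan) {
  p <- as_pan_matrix(pan)
  d <- dim(as_ms_array(ms_up))
  if (d[1] != nrow(p) || d[2] != ncol(p)) {
    abort(sprintf(
      "multispectral grid (%d x %d) does not match PAN grid (%d x %d); upsample first",
      d[1], d[2], nrow(p), ncol(p)))
  }
  p
}

#' Match the first two moments of one image plane to another
#'
#' Linearly rescales `source` so its mean and standard deviation equal the
#' reference's. Used to make the panchromatic plane radiometrically
#' comparable to an intensity component or a spectral band before detail
#' extraction.
#'
#' @param source Numeric matrix to rescale.
#' @param reference Numeric matrix supplying the target moments.
#' @return Matrix with `mean == mean(reference)` and `sd == sd(reference)`.
#' @export
histogram_match <- function(source, reference) {
  source <- as_pan_matrix(source)
  reference <- as_pan_matrix(reference)
  mu_s <- mean(source); sd_s <- sd(as.vector(source))
  mu_r <- mean(reference); sd_r <- sd(as.vector(reference))
  if (sd_s == 0) {
    if (sd_r == 0) {
      # both flat: place the source at the reference level
      return(matrix(mu_r, nrow(source), ncol(source)))
    }
    abort("cannot moment-match a zero-variance source to a varying reference")
  }
  (source - mu_s) * (sd_r / sd_s) + mu_r
}

# ---------------------------------------------------------------------------
# 'a trous' wavelet transform

#' Undecimated ('a trous') wavelet decomposition of an image plane
#'
#' Shift-invariant dyadic decomposition with the separable B3-spline kernel
#' `[1, 4, 6, 4, 1] / 16`. Level `k` convolves with the kernel dilated by
#' `2^(k-1)`; the detail plane at level `k` is the difference of successive
#' approximations, so `residual + sum(details)` reconstructs the input
#' exactly. Two levels span the detail band between a grid and its
#' 4-times-coarser version.
#'
#' @param plane Numeric matrix.
#' @param levels Number of decomposition levels (>= 1).
#' @return List of class `atrous_decomposition` with elements `residual`
#'   (matrix), `details` (list of matrices, finest first) and `kernel`.
#' @export
atrous_decompose <- function(plane, levels) {
  if (levels < 1) abort("`levels` must be >= 1")
  plane <- as_pan_matrix(plane)
  kernel <- c(1, 4, 6, 4, 1) / 16
  approx <- plane
  details <- vector("list", levels)
  for (k in seq_len(levels)) {
    nxt <- sep_filter(approx, kernel, spacing = 2^(k - 1))
    details[[k]] <- approx - nxt
    approx <- nxt
  }
  structure(
    list(residual = approx, details = details, kernel = kernel),
    class = "atrous_decomposition"
  )
}

#' Reconstruct a plane from its 'a trous' decomposition
#'
#' @param decomposition An [atrous_decompose()] result.
#' @return The reconstructed matrix (`residual + sum(details)`).
#' @export
atrous_reconstruct <- function(decomposition) {
  Reduce(`+`, decomposition$details, decomposition$residual)
}

# ---------------------------------------------------------------------------
# Fast intensity-hue-saturation (FIHS)

#' Fuse by fast intensity-hue-saturation substitution
#'
#' The intensity component `I` is the unweighted mean of the injected
#' bands; the spatial detail is the difference between the (moment-matched)
#' panchromatic plane and `I`, and the same detail plane is added to every
#' injected band.
#'
#' @param ms_up Multispectral image on the PAN grid ([upsample_ms()] it
#'   first).
#' @param pan Panchromatic image or matrix on the same grid.
#' @param inject_bands Integer band indices to sharpen (default all).
#' @param pan_match `"moment"` (default) matches the PAN plane's mean and
#'   standard deviation to the intensity before differencing; `"none"`
#'   uses the PAN plane as given.
#' @return A `fused_image`.
#' @export
fuse_fihs <- function(ms_up, pan, inject_bands = NULL,
                      pan_match = c("moment", "none")) {
  pan_match <- match.arg(pan_match)
  p <- check_pan_grid(ms_up, pan)
  pix <- as_ms_array(ms_up)
  nb <- dim(pix)[3]
  if (is.null(inject_bands)) inject_bands <- seq_len(nb)
  if (any(inject_bands < 1 | inject_bands > nb)) {
    abort("`inject_bands` out of range")
  }
  intensity <- rowMeans(pix[, , inject_bands, drop = FALSE], dims = 2)
  pan_m <- if (pan_match == "moment") histogram_match(p, intensity) else p
  detail <- pan_m - intensity
  out <- pix
  for (k in inject_bands) out[, , k] <- pix[, , k] + detail
  fused_image(out, ms_up$bands, ms_up$gsd, "fihs",
              list(inject_bands = inject_bands, pan_match = pan_match))
}

# ---------------------------------------------------------------------------
# Hyperspherical colour sharpening (HCS)

#' Fuse by hyperspherical colour sharpening
#'
#' Each pixel's band vector is viewed in hyperspherical coordinates: the
#' radius is the Euclidean norm of the vector and the angles encode the
#' spectral direction ("colour"). The radius is replaced by a PAN-derived
#' intensity while the angles are kept, which preserves every band ratio
#' exactly — the whole vector is rescaled by `pan / radius`. This is the
#' direct-substitution form; no smoothing variant is applied.
#'
#' @inheritParams fuse_fihs
#' @param pan_match `"moment"` (default) moment-matches PAN to the radius
#'   component first; `"none"` substitutes the raw PAN.
#' @return A `fused_image`.
#' @export
fuse_hcs <- function(ms_up, pan, pan_match = c("moment", "none")) {
  pan_match <- match.arg(pan_match)
  p <- check_pan_grid(ms_up, pan)
  pix <- as_ms_array(ms_up)
  if (dim(pix)[3] < 2) abort("hyperspherical sharpening needs >= 2 bands")
  radius <- sqrt(rowSums(pix^2, dims = 2))
  pan_m <- if (pan_match == "moment") histogram_match(p, radius) else p
  pan_m <- pmax(pan_m, 0)  # a radius cannot be negative
  scale <- ifelse(radius > 0, pan_m / radius, 0)
  out <- pix * as.vector(scale)  # recycles over bands (leading dims match)
  fused_image(out, ms_up$bands, ms_up$gsd, "hcs",
              list(pan_match = pan_match))
}

# ---------------------------------------------------------------------------
# MTF-matched generalized Laplacian pyramid with high-pass modulation

#' Fuse by MTF-matched GLP with high-pass modulation
#'
#' A low-resolution version of the panchromatic plane is synthesised by
#' filtering with a Gaussian matched to each band's sensor MTF gain,
#' block-averaging down by `ratio` and re-expanding (one pyramid stage with
#' scale factor `ratio`). High-pass modulation then multiplies each
#' multispectral band by `pan / pan_low`, which injects detail while
#' preserving per-pixel band ratios. Pixels where `pan_low` falls below
#' `1e-6 * mean(pan)` pass the multispectral value through unchanged.
#'
#' @inheritParams fuse_fihs
#' @param gains Per-band MTF gain at the reduced-grid Nyquist (recycled if
#'   scalar; default 0.35 for every band).
#' @param ratio Resolution ratio of the PAN to the original MS grid.
#' @return A `fused_image`.
#' @export
fuse_mtf_glp_hpm <- function(ms_up, pan, gains = 0.35, ratio = 4L) {
  p <- check_pan_grid(ms_up, pan)
  pix <- as_ms_array(ms_up)
  nb <- dim(pix)[3]
  gains <- rep_len(gains, nb)
  eps <- 1e-6 * mean(p)
  out <- pix
  pan_low_cache <- list()
  for (k in seq_len(nb)) {
    key <- sprintf("%.10g", gains[k])
    if (is.null(pan_low_cache[[key]])) {
      filt <- sep_filter(p, mtf_gaussian_kernel(gains[k], ratio))
      dec <- block_downsample(filt, ratio)
      pan_low_cache[[key]] <- upsample_ms(
        ms_image(array(dec, c(dim(dec), 1L)),
                 bands = wv2_bands()[1, ], gsd = 1),
        ratio, "bicubic")$pixels[, , 1]
    }
    pan_low <- pan_low_cache[[key]]
    mod <- ifelse(pan_low > eps, p / pmax(pan_low, eps), 1)
    out[, , k] <- pix[, , k] * mod
  }
  fused_image(out, ms_up$bands, ms_up$gsd, "mtf_glp_hpm",
              list(gains = gains, ratio = ratio))
}

# ---------------------------------------------------------------------------
# Fractal dimension maps and weighted wavelet 'a trous' fusion

#' Per-pixel fractal dimension map of an image plane
#'
#' Estimates the local surface fractal dimension at every pixel by
#' differential box counting over a sliding `window x window`
#' neighbourhood (edges handled by reflection). A flat surface has
#' dimension 2, white noise approaches 3. The map `alpha` rescales the
#' dimension linearly from `[2, 3]` to `[0, 1]` for use as a spatially
#' adaptive detail-injection weight.
#'
#' @param plane Numeric matrix.
#' @param window Odd window size, at least 7. The sizes 7, 15 and 27 are
#'   the usual choices; other odd sizes are accepted with a warning.
#' @return List of class `fdm_map` with `alpha`, `raw_dimension` (both
#'   matrices of the input size) and `window`.
#' @export
fractal_dimension_map <- function(plane, window) {
  plane <- as_pan_matrix(plane)
  if (window %% 2 == 0) abort("`window` must be odd")
  if (window < 7) abort("`window` must be at least 7")
  if (!window %in% c(7L, 15L, 27L)) {
    warn(sprintf("window size %d is outside the usual set {7, 15, 27}",
                 window))
  }
  half <- (window - 1L) %/% 2L
  padded <- reflect_pad(plane, half)
  raw <- dbc_fdm_cpp(padded, as.integer(window))
  raw <- pmin(pmax(raw, 2), 3)
  structure(
    list(alpha = raw - 2, raw_dimension = raw, window = as.integer(window)),
    class = "fdm_map"
  )
}

reflect_pad <- function(m, half) {
  n1 <- nrow(m); n2 <- ncol(m)
  ri <- reflect_index(seq(-half, n1 - 1 + half), n1) + 1
  ci <- reflect_index(seq(-half, n2 - 1 + half), n2) + 1
  m[ri, ci, drop = FALSE]
}

#' Fuse by weighted wavelet 'a trous' with fractal dimension maps
#'
#' For each band the panchromatic plane is moment-matched to the band,
#' decomposed with the 'a trous' transform (`log2(ratio)` levels), and the
#' summed detail planes are injected with a per-pixel weight
#' `alpha_i(x, y)` given by the band's fractal dimension map: flat areas
#' (dimension near 2) receive no detail, highly textured areas (dimension
#' near 3) receive it fully. One alpha map per band weights all levels
#' identically.
#'
#' @inheritParams fuse_fihs
#' @param window Odd fractal-analysis window (7 for very heterogeneous
#'   scenes, 27 for smooth water-dominated scenes, 15 in between).
#' @param ratio Resolution ratio of the PAN to the original MS grid;
#'   determines the number of wavelet levels (`log2(ratio)`).
#' @param alpha Optional fixed injection weight overriding the fractal
#'   maps: a scalar, a matrix, or a list of per-band matrices. `alpha = 1`
#'   gives plain additive 'a trous' fusion; `alpha = 0` returns the input.
#' @return A `fused_image`.
#' @export
fuse_wat_frac <- function(ms_up, pan, window = 7L, ratio = 4L, alpha = NULL) {
  p <- check_pan_grid(ms_up, pan)
  pix <- as_ms_array(ms_up)
  nb <- dim(pix)[3]
  levels <- max(1L, as.integer(round(log2(ratio))))
  get_alpha <- function(k) {
    if (is.null(alpha)) {
      fractal_dimension_map(pix[, , k], window)$alpha
    } else if (is.list(alpha)) {
      alpha[[k]]
    } else {
      alpha
    }
  }
  out <- pix
  for (k in seq_len(nb)) {
    pan_m <- histogram_match(p, pix[, , k])
    dec <- atrous_decompose(pan_m, levels)
    detail <- Reduce(`+`, dec$details)
    out[, , k] <- pix[, , k] + get_alpha(k) * detail
  }
  fused_image(out, ms_up$bands, ms_up$gsd, "wat_frac",
              list(window = as.integer(window), ratio = ratio,
                   fixed_alpha = !is.null(alpha)))
}

# algorithm registry used by the pipeline and the CLI
fusion_algorithms <- function() c("fihs", "hcs", "mtf_glp_hpm", "wat_frac")

apply_fusion <- function(algorithm, ms_up, pan, ratio = 4L, window = 7L,
                         mtf_gains = 0.35) {
  switch(algorithm,
    fihs = fuse_fihs(ms_up, pan),
    hcs = fuse_hcs(ms_up, pan),
    mtf_glp_hpm = fuse_mtf_glp_hpm(ms_up, pan, gains = mtf_gains,
                                   ratio = ratio),
    wat_frac = fuse_wat_frac(ms_up, pan, window = window, ratio = ratio),
    abort(paste0("unknown fusion algorithm: ", algorithm))
  )
}
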