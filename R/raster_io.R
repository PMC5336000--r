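#' Multispectral image container
#'
#' Holds an `H x W x nband` array of non-negative pixel values plus a band
#' catalog and the ground sample distance. Values are carried as doubles
#' regardless of on-disk type; no rescaling is ever applied.
#'
#' @param pixels Numeric `H x W x nband` array (a matrix is promoted to a
#'   single-band array). Must be finite and non-negative.
#' @param bands Band catalog tibble, one row per band (see [wv2_bands()]).
#' @param gsd Ground sample distance in meters/pixel.
#'
#' @return An object of class `ms_image`.
#' @export
ms_image <- function(pixels, bands = wv2_bands(), gsd = 1.84) {
  if (is.matrix(pixels)) {
    pixels <- array(pixels, c(dim(pixels), 1L))
  }
  if (!is.array(pixels) || length(dim(pixels)) != 3) {
    abort("`pixels` must be an H x W x nband array")
  }
  storage.mode(pixels) <- "double"
  if (anyNA(pixels) || any(!is.finite(pixels))) {
    abort("pixel values must be finite (no NA/NaN/Inf)")
  }
  if (any(pixels < 0)) {
    abort("negative pixel values are not allowed in an ms_image")
  }
  nband <- dim(pixels)[3]
  if (nband < 1) abort("nband must be >= 1")
  if (nrow(bands) != nband) {
    abort(sprintf("band catalog has %d bands but pixels have %d",
                  nrow(bands), nband))
  }
  structure(
    list(pixels = pixels, bands = bands, gsd = gsd),
    class = "ms_image"
  )
}

#' Panchromatic image container
#'
#' @param pixels Numeric matrix of non-negative values.
#' @param gsd Ground sample distance in meters/pixel.
#' @param ratio Positive integer resolution ratio to the paired
#'   multispectral grid (PAN has `ratio` times more pixels per side).
#'
#' @return An object of class `pan_image`.
#' @export
pan_image <- function(pixels, gsd = 0.46, ratio = 4L) {
  if (!is.matrix(pixels)) abort("`pixels` must be a matrix")
  storage.mode(pixels) <- "double"
  if (anyNA(pixels) || any(!is.finite(pixels))) {
    abort("pixel values must be finite (no NA/NaN/Inf)")
  }
  if (any(pixels < 0)) abort("negative pixel values are not allowed")
  ratio <- as.integer(ratio)
  if (is.na(ratio) || ratio < 1) abort("`ratio` must be a positive integer")
  structure(
    list(pixels = pixels, gsd = gsd, ratio = ratio),
    class = "pan_image"
  )
}

#' @export
print.ms_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<ms_image> %d x %d pixels, %d bands, gsd %.3g m\n",
              d[1], d[2], d[3], x$gsd))
  cat("bands:", paste(x$bands$name, collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.pan_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<pan_image> %d x %d pixels, gsd %.3g m, ratio %d\n",
              d[1], d[2], x$gsd, x$ratio))
  invisible(x)
}

#' @export
dim.ms_image <- function(x) dim(x$pixels)

#' @export
dim.pan_image <- function(x) dim(x$pixels)

n_bands <- function(ms) dim(ms$pixels)[3]

# accept either a pan_image or a bare matrix in fusion/metric code
as_pan_matrix <- function(pan) {
  if (inherits(pan, "pan_image")) pan$pixels else as.matrix(pan)
}

as_ms_array <- function(ms) {
  if (inherits(ms, "ms_image")) ms$pixels else ms
}

# ---------------------------------------------------------------------------
# ENVI-style flat binary (float64, band sequential) with plain-text header

write_envi <- function(pixels, path) {
  d <- dim(pixels)
  if (length(d) == 2) {
    pixels <- array(pixels, c(d, 1L))
    d <- dim(pixels)
  }
  hdr <- c(
    "ENVI",
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 5",
    "interleave = bsq",
    "byte order = 0"
  )
  writeLines(hdr, paste0(path, ".hdr"))
  con <- file(path, "wb")
  on.exit(close(con))
  # BSQ: whole band contiguous, row-major within band
  for (k in seq_len(d[3])) {
    writeBin(as.vector(t(pixels[, , k])), con, size = 8, endian = "little")
  }
  invisible(path)
}

read_envi <- function(path) {
  hdr_path <- paste0(path, ".hdr")
  if (!file.exists(hdr_path)) abort(paste0("missing ENVI header: ", hdr_path))
  hdr <- readLines(hdr_path, warn = FALSE)
  get_field <- function(name) {
    line <- grep(paste0("^", name, "\\s*="), hdr, value = TRUE)
    if (!length(line)) abort(paste0("ENVI header lacks field: ", name))
    trimws(sub(".*=", "", line[1]))
  }
  samples <- as.integer(get_field("samples"))
  lines_n <- as.integer(get_field("lines"))
  bands <- as.integer(get_field("bands"))
  dtype <- as.integer(get_field("data type"))
  interleave <- tolower(get_field("interleave"))
  if (interleave != "bsq") abort("only BSQ interleave is supported")
  spec <- switch(as.character(dtype),
    "4" = list(what = "numeric", size = 4),
    "5" = list(what = "numeric", size = 8),
    "2" = list(what = "integer", size = 2),
    "12" = list(what = "integer", size = 2),
    "3" = list(what = "integer", size = 4),
    abort(sprintf("unsupported ENVI data type %d", dtype))
  )
  con <- file(path, "rb")
  on.exit(close(con))
  n <- samples * lines_n * bands
  raw_vals <- readBin(con, spec$what, n = n, size = spec$size,
                      endian = "little",
                      signed = !(dtype == 12))
  if (length(raw_vals) != n) abort("ENVI file shorter than header declares")
  out <- array(0, c(lines_n, samples, bands))
  for (k in seq_len(bands)) {
    band <- raw_vals[((k - 1) * samples * lines_n + 1):(k * samples * lines_n)]
    out[, , k] <- matrix(band, nrow = lines_n, byrow = TRUE)
  }
  out
}

is_tiff_path <- function(path) {
  grepl("\\.tiff?$", path, ignore.case = TRUE)
}

read_raster_array <- function(path) {
  if (!file.exists(path)) abort(paste0("raster file not found: ", path))
  if (is_tiff_path(path)) {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
    if (!is.list(pages)) pages <- list(pages)
    planes <- unlist(lapply(pages, function(p) {
      if (length(dim(p)) == 3) {
        lapply(seq_len(dim(p)[3]), function(k) p[, , k])
      } else {
        list(p)
      }
    }), recursive = FALSE)
    simplify2array(planes)
  } else {
    read_envi(path)
  }
}

write_raster_array <- function(pixels, path) {
  if (length(dim(pixels)) == 2) pixels <- array(pixels, c(dim(pixels), 1L))
  if (is_tiff_path(path)) {
    if (max(pixels) > 1) {
      abort(paste0(
        "TIFF output supports values in [0, 1] only; ",
        "use an ENVI path (no .tif extension) for unscaled data"))
    }
    pages <- lapply(seq_len(dim(pixels)[3]), function(k) pixels[, , k])
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  } else {
    write_envi(pixels, path)
  }
  invisible(path)
}

#' Load a multispectral raster
#'
#' Reads a multiband raster (multi-page/multi-channel TIFF, or ENVI-style
#' flat binary with a `.hdr` sidecar) and attaches a band catalog. Band
#' order is preserved and pixel values are taken as stored.
#'
#' @param path Raster file path. `.tif`/`.tiff` is read with
#'   \pkg{tiff}; anything else is treated as ENVI flat binary.
#' @param band_catalog Band catalog tibble; its row count must match the
#'   raster band count.
#' @param gsd Ground sample distance in meters/pixel.
#' @return An [ms_image()].
#' @export
load_ms <- function(path, band_catalog = wv2_bands(), gsd = 1.84) {
  arr <- read_raster_array(path)
  if (dim(arr)[3] != nrow(band_catalog)) {
    abort(sprintf(
      "raster has %d bands but the catalog describes %d",
      dim(arr)[3], nrow(band_catalog)))
  }
  ms_image(arr, bands = band_catalog, gsd = gsd)
}

#' Load a panchromatic raster
#'
#' @inheritParams load_ms
#' @param ratio Resolution ratio to the paired multispectral grid.
#' @return A [pan_image()].
#' @export
load_pan <- function(path, gsd = 0.46, ratio = 4L) {
  arr <- read_raster_array(path)
  if (dim(arr)[3] != 1) abort("panchromatic raster must have exactly 1 band")
  pan_image(arr[, , 1], gsd = gsd, ratio = ratio)
}

#' Write a multispectral or panchromatic image to disk
#'
#' ENVI flat binary (float64 BSQ, exact round trip) unless the path ends in
#' `.tif`/`.tiff`, in which case a multi-page 32-bit TIFF is written
#' (unit-range data only, a limitation of the TIFF writer).
#'
#' @param x An [ms_image()] or [pan_image()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_raster <- function(x, path) {
  pix <- if (inherits(x, "pan_image")) x$pixels else as_ms_array(x)
  write_raster_array(pix, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Resampling

#' Upsample a multispectral image to a finer grid
#'
#' Expands each band by an integer factor using nearest-neighbour, bilinear
#' or bicubic (Catmull-Rom) interpolation. The grid convention is
#' block-centred: coarse pixel `(i, j)` (0-based) corresponds to the fine
#' block `[r*i, r*i + r) x [r*j, r*j + r)`, and interpolation sample points
#' sit at the fine pixel centres. Boundaries are handled by half-sample
#' reflection, which makes the scheme conserve each band's global mean
#' under block-mean decimation.
#'
#' @param ms An [ms_image()].
#' @param ratio Integer expansion factor (>= 1).
#' @param method One of `"bicubic"` (default), `"bilinear"`, `"nearest"`.
#' @return An [ms_image()] on the fine grid.
#' @export
upsample_ms <- function(ms, ratio, method = c("bicubic", "bilinear", "nearest")) {
  method <- match.arg(method)
  if (length(ratio) != 1 || ratio != round(ratio) || ratio < 1) {
    abort("`ratio` must be a single positive integer")
  }
  ratio <- as.integer(ratio)
  if (ratio == 1L) return(ms)
  pix <- as_ms_array(ms)
  d <- dim(pix)
  rows_op <- interp_operator(d[1], ratio, method)
  cols_op <- interp_operator(d[2], ratio, method)
  out <- array(0, c(d[1] * ratio, d[2] * ratio, d[3]))
  for (k in seq_len(d[3])) {
    up <- as.matrix(rows_op %*% pix[, , k] %*% Matrix::t(cols_op))
    out[, , k] <- pmax(up, 0)  # cubic overshoot can dip below zero
  }
  ms_image(out, bands = ms$bands, gsd = ms$gsd / ratio)
}

#' Downsample an image by block averaging
#'
#' Each coarse pixel is the mean of its `r x r` fine block — the adjoint of
#' the block-centred upsampling convention.
#'
#' @param x An [ms_image()], [pan_image()], matrix or 3-d array.
#' @param ratio Integer reduction factor; dimensions must be divisible.
#' @return Same container type as the input, on the coarse grid.
#' @export
block_downsample <- function(x, ratio) {
  ratio <- as.integer(ratio)
  if (ratio < 1) abort("`ratio` must be >= 1")
  down_mat <- function(m) {
    d <- dim(m)
    if (any(d %% ratio != 0)) {
      abort("image dimensions are not divisible by `ratio`")
    }
    A <- block_mean_operator(d[1], ratio)
    B <- block_mean_operator(d[2], ratio)
    as.matrix(A %*% m %*% Matrix::t(B))
  }
  if (inherits(x, "pan_image")) {
    pan_image(down_mat(x$pixels), gsd = x$gsd * ratio,
              ratio = max(1L, x$ratio %/% ratio))
  } else if (inherits(x, "ms_image")) {
    pix <- x$pixels
    out <- array(0, c(dim(pix)[1] %/% ratio, dim(pix)[2] %/% ratio,
                      dim(pix)[3]))
    for (k in seq_len(dim(pix)[3])) out[, , k] <- down_mat(pix[, , k])
    ms_image(out, bands = x$bands, gsd = x$gsd * ratio)
  } else if (is.matrix(x)) {
    down_mat(x)
  } else {
    out <- array(0, c(dim(x)[1] %/% ratio, dim(x)[2] %/% ratio, dim(x)[3]))
    for (k in seq_len(dim(x)[3])) out[, , k] <- down_mat(x[, , k])
    out
  }
}

#' Select a band subset by position relative to the panchromatic range
#'
#' `"in_pan"` keeps the bands whose wavelength interval overlaps the PAN
#' range (bands 2--6 for the WorldView-2 layout), `"out_pan"` the
#' complement (bands 1, 7, 8), `"all"` returns the input unchanged.
#'
#' @param ms An [ms_image()] with `inside_pan` flags in its band catalog.
#' @param subset `"all"`, `"in_pan"` or `"out_pan"`.
#' @return An [ms_image()] restricted to the selected bands.
#' @export
select_band_subset <- function(ms, subset = c("all", "in_pan", "out_pan")) {
  subset <- match.arg(subset)
  if (subset == "all") return(ms)
  if (is.null(ms$bands$inside_pan)) {
    abort("band catalog lacks the `inside_pan` flag")
  }
  keep <- if (subset == "in_pan") ms$bands$inside_pan else !ms$bands$inside_pan
  if (!any(keep)) abort(sprintf("subset '%s' selects no bands", subset))
  ms_image(ms$pixels[, , keep, drop = FALSE],
           bands = ms$bands[keep, ], gsd = ms$gsd)
}
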