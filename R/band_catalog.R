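#' WorldView-2 band catalog
#'
#' Returns the standard eight-band WorldView-2 spectral layout as a tibble.
#' Bands are ordered by wavelength: coastal, blue, green, yellow, red,
#' red-edge, nir1 and nir2. The `inside_pan` flag marks the bands whose
#' wavelength interval overlaps the panchromatic range (450--800 nm by
#' default), which for this layout is exactly bands 2--6.
#'
#' @param pan_range Length-2 numeric, the panchromatic sensor's wavelength
#'   span in nm. Default `c(450, 800)`.
#'
#' @return A tibble with columns `index`, `name`, `wavelength_lo`,
#'   `wavelength_hi` (nm) and `inside_pan`.
#' @examples
#' wv2_bands()
#' @export
wv2_bands <- function(pan_range = c(450, 800)) {
  bands <- tibble::tibble(
    index = 1:8,
    name = c("coastal", "blue", "green", "yellow", "red",
             "red-edge", "nir1", "nir2"),
    wavelength_lo = c(400, 450, 510, 585, 630, 705, 770, 860),
    wavelength_hi = c(450, 510, 580, 625, 690, 745, 895, 1040)
  )
  flag_inside_pan(bands, pan_range)
}

#' Flag catalog bands inside a panchromatic range
#'
#' A band is `inside_pan` when the majority of its wavelength interval
#' lies within `pan_range`. For the WorldView-2 layout with the 450--800
#' nm PAN range this selects exactly bands 2--6: the first NIR band
#' (770--895 nm) touches the range with a 30 nm sliver but is not covered
#' by it.
#'
#' @param bands Band catalog tibble with `wavelength_lo`/`wavelength_hi`.
#' @inheritParams wv2_bands
#' @return The catalog with an `inside_pan` logical column.
#' @export
flag_inside_pan <- function(bands, pan_range = c(450, 800)) {
  stopifnot(length(pan_range) == 2, pan_range[1] < pan_range[2])
  overlap <- pmin(bands$wavelength_hi, pan_range[2]) -
    pmax(bands$wavelength_lo, pan_range[1])
  width <- bands$wavelength_hi - bands$wavelength_lo
  bands$inside_pan <- overlap > 0.5 * width
  bands
}

#' Read a band catalog from a plain-text file
#'
#' One band per line: `index name lo_nm hi_nm`, whitespace- or
#' comma-separated. Lines starting with `#` are ignored.
#'
#' @param path File path.
#' @inheritParams wv2_bands
#' @return A band catalog tibble (see [wv2_bands()]).
#' @export
read_band_catalog <- function(path, pan_range = c(450, 800)) {
  if (!file.exists(path)) {
    abort(paste0("band catalog file not found: ", path))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "[,[:space:]]+")
  bad <- lengths(fields) != 4
  if (any(bad)) {
    abort(paste0("malformed band catalog line: ", lines[bad][1]))
  }
  mat <- do.call(rbind, fields)
  bands <- tibble::tibble(
    index = as.integer(mat[, 1]),
    name = mat[, 2],
    wavelength_lo = as.numeric(mat[, 3]),
    wavelength_hi = as.numeric(mat[, 4])
  )
  if (any(is.na(bands$index)) || any(is.na(bands$wavelength_lo)) ||
      any(is.na(bands$wavelength_hi))) {
    abort("band catalog contains non-numeric index or wavelength fields")
  }
  bands <- bands[order(bands$index), ]
  flag_inside_pan(bands, pan_range)
}

#' Spectral weights of multispectral bands within the panchromatic range
#'
#' Weight of each in-PAN band (see [flag_inside_pan()]) proportional to
#' the overlap of its wavelength interval with the panchromatic range;
#' out-of-PAN bands get weight zero; weights sum to one. Used to
#' synthesise a panchromatic plane as a weighted sum of in-range bands.
#'
#' @inheritParams flag_inside_pan
#' @return Numeric vector of length `nrow(bands)` summing to 1.
#' @export
band_overlap_weights <- function(bands, pan_range = c(450, 800)) {
  bands <- flag_inside_pan(bands, pan_range)
  overlap <- pmin(bands$wavelength_hi, pan_range[2]) -
    pmax(bands$wavelength_lo, pan_range[1])
  overlap <- pmax(overlap, 0) * bands$inside_pan
  if (sum(overlap) <= 0) {
    abort("no band overlaps the panchromatic range")
  }
  overlap / sum(overlap)
}
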