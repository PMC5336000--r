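# Six reference-based quality indices for pansharpened imagery, plus
# band-subset evaluation and block quality maps. Spectral indices compare
# the fused product to a multispectral reference on the same grid; spatial
# indices compare each fused band to the panchromatic plane.

check_same_grid <- function(a, b, what = "images") {
  da <- dim(a); db <- dim(b)
  if (length(da) != length(db) || any(da != db)) {
    abort(sprintf("%s have mismatching shapes (%s vs %s)", what,
                  paste(da, collapse = "x"), paste(db, collapse = "x")))
  }
}

#' Spectral angle mapper
#'
#' Mean over pixels of the angle between the per-pixel band vectors of the
#' reference and fused images, in degrees. Invariant to per-pixel scaling,
#' so it isolates spectral-direction distortion. Pixels where either
#' vector has zero norm are skipped.
#'
#' @param reference Multispectral reference ([ms_image()] or array) on the
#'   same grid as `fused`.
#' @param fused Fused image on the same grid with the same bands.
#' @return Mean spectral angle in degrees (0 = spectrally identical).
#' @export
sam <- function(reference, fused) {
  ref <- as_ms_array(reference); fus <- as_ms_array(fused)
  check_same_grid(ref, fus)
  dot <- rowSums(ref * fus, dims = 2)
  nref <- sqrt(rowSums(ref^2, dims = 2))
  nfus <- sqrt(rowSums(fus^2, dims = 2))
  ok <- nref > 0 & nfus > 0
  if (!any(ok)) abort("all pixels have zero-norm band vectors")
  cosang <- pmin(pmax(dot[ok] / (nref[ok] * nfus[ok]), -1), 1)
  mean(acos(cosang)) * 180 / pi
}

band_rmse <- function(ref, fus) {
  nb <- dim(ref)[3]
  vapply(seq_len(nb),
         function(k) sqrt(mean((ref[, , k] - fus[, , k])^2)),
         numeric(1))
}

#' Spectral ERGAS (relative dimensionless global error)
#'
#' `100 * (h/l) * sqrt(mean_i((rmse_i / mean(ref_i))^2))` with `h/l` the
#' ratio of the fine (PAN) to coarse (MS) resolution. Sensitive to mean
#' shifts and dynamic-range changes; 0 for identical images.
#'
#' @inheritParams sam
#' @param h_over_l Resolution ratio `h/l` (PAN over MS), 0.25 for a 4:1
#'   pair.
#' @return Non-negative ERGAS value.
#' @export
ergas_spectral <- function(reference, fused, h_over_l = 0.25) {
  ref <- as_ms_array(reference); fus <- as_ms_array(fused)
  check_same_grid(ref, fus)
  means <- vapply(seq_len(dim(ref)[3]), function(k) mean(ref[, , k]),
                  numeric(1))
  if (any(means == 0)) abort("a reference band has zero mean")
  rmse <- band_rmse(ref, fus)
  100 * h_over_l * sqrt(mean((rmse / means)^2))
}

#' Spatial ERGAS
#'
#' ERGAS computed against the panchromatic plane: for each fused band the
#' RMSE to a per-band reference PAN is normalised by that reference's mean.
#' In `"matched"` mode (default) the PAN plane is first moment-matched to
#' each fused band so only structural differences are scored; `"raw"` uses
#' the PAN plane as-is.
#'
#' @param pan Panchromatic image or matrix on the fused grid.
#' @param fused Fused multispectral image on the PAN grid.
#' @param h_over_l Resolution ratio `h/l` (PAN over MS).
#' @param pan_adjust `"matched"` or `"raw"`.
#' @return Non-negative ERGAS value.
#' @export
ergas_spatial <- function(pan, fused, h_over_l = 0.25,
                          pan_adjust = c("matched", "raw")) {
  pan_adjust <- match.arg(pan_adjust)
  p <- as_pan_matrix(pan)
  fus <- as_ms_array(fused)
  check_same_grid(p, fus[, , 1], "PAN and fused band")
  nb <- dim(fus)[3]
  terms <- vapply(seq_len(nb), function(k) {
    pk <- if (pan_adjust == "matched") histogram_match(p, fus[, , k]) else p
    mu <- mean(pk)
    if (mu == 0) abort("per-band PAN reference has zero mean")
    rmse <- sqrt(mean((fus[, , k] - pk)^2))
    (rmse / mu)^2
  }, numeric(1))
  100 * h_over_l * sqrt(mean(terms))
}

#' Frequency comparison index
#'
#' For each band, both the PAN plane and the fused band are cut into
#' `block x block` tiles, each tile is transformed with the 2-D discrete
#' cosine transform, and the Pearson correlation of all AC coefficients
#' (DC excluded) is pooled over tiles. FC is the mean correlation over
#' bands; 1 means the fused bands carry exactly the PAN's spatial-frequency
#' content. Images are reflection-padded to a multiple of the block size.
#'
#' @inheritParams ergas_spatial
#' @param block DCT tile size (default 8).
#' @return Value in `[-1, 1]`.
#' @export
fc <- function(pan, fused, block = 8L) {
  if (block < 2) abort("`block` must be >= 2")
  p <- as_pan_matrix(pan)
  fus <- as_ms_array(fused)
  check_same_grid(p, fus[, , 1], "PAN and fused band")
  pan_ac <- dct_ac_coeffs(p, block)
  vals <- vapply(seq_len(dim(fus)[3]), function(k) {
    cor(pan_ac, dct_ac_coeffs(fus[, , k], block))
  }, numeric(1))
  mean(vals)
}

# all AC coefficients of the blockwise DCT, as one vector
dct_ac_coeffs <- function(m, block) {
  d <- dim(m)
  pad_to <- ceiling(d / block) * block
  if (any(pad_to != d)) {
    ri <- reflect_index(seq_len(pad_to[1]) - 1, d[1]) + 1
    ci <- reflect_index(seq_len(pad_to[2]) - 1, d[2]) + 1
    m <- m[ri, ci, drop = FALSE]
    d <- pad_to
  }
  C <- dct_matrix(block)
  nbr <- d[1] %/% block; nbc <- d[2] %/% block
  # stack row-bands: (block x d2) slabs -> C %*% slab, then per column-block
  out <- matrix(0, block * block, nbr * nbc)
  idx <- 1
  for (i in seq_len(nbr)) {
    slab <- C %*% m[((i - 1) * block + 1):(i * block), , drop = FALSE]
    for (j in seq_len(nbc)) {
      blk <- slab[, ((j - 1) * block + 1):(j * block), drop = FALSE] %*% t(C)
      out[, idx] <- as.vector(blk)
      idx <- idx + 1
    }
  }
  as.vector(out[-1L, , drop = FALSE])  # drop the DC entry of every tile
}

#' Zhou high-pass correlation index
#'
#' Per band, both the fused band and the PAN plane are filtered with a 3x3
#' Laplacian (centre +8, neighbours -1) and the Pearson correlation of the
#' two high-pass planes is computed; the index is the mean over bands.
#'
#' @inheritParams ergas_spatial
#' @return Value in `[-1, 1]`; 1 when the fused bands carry the PAN's
#'   high-frequency structure exactly.
#' @export
zhou <- function(pan, fused) {
  p <- as_pan_matrix(pan)
  fus <- as_ms_array(fused)
  check_same_grid(p, fus[, , 1], "PAN and fused band")
  pan_hp <- laplacian_filter(p)
  if (sd(as.vector(pan_hp)) == 0) {
    abort("high-pass filtered PAN has zero variance")
  }
  vals <- vapply(seq_len(dim(fus)[3]), function(k) {
    f_hp <- laplacian_filter(fus[, , k])
    if (sd(as.vector(f_hp)) == 0) {
      abort("high-pass filtered fused band has zero variance")
    }
    cor(as.vector(pan_hp), as.vector(f_hp))
  }, numeric(1))
  mean(vals)
}

laplacian_filter <- function(m) {
  d <- dim(m)
  padded <- reflect_pad(m, 1L)
  core <- 8 * m
  shifts <- expand.grid(dr = -1:1, dc = -1:1)
  shifts <- shifts[!(shifts$dr == 0 & shifts$dc == 0), ]
  for (s in seq_len(nrow(shifts))) {
    core <- core - padded[(2 + shifts$dr[s]):(d[1] + 1 + shifts$dr[s]),
                          (2 + shifts$dc[s]):(d[2] + 1 + shifts$dc[s])]
  }
  core
}

# universal quality index of two equal-length vectors;
# degenerate 0/0 blocks: 1 if identical, else 0
q_scalar <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
  cxy <- mean((x - mx) * (y - my))
  denom <- (vx + vy) * (mx^2 + my^2)
  if (denom == 0) {
    return(if (isTRUE(all.equal(x, y, tolerance = 0))) 1 else 0)
  }
  4 * cxy * mx * my / denom
}

#' Universal image quality index (Q), per band and aggregated
#'
#' The Q index combines correlation, luminance closeness and contrast
#' closeness: `4 * cov * mean_x * mean_y / ((var_x + var_y) *
#' (mean_x^2 + mean_y^2))`, equal to 1 only for identical images. With a
#' `block` size it is computed per tile and averaged, which is the usual
#' way to apply it to large scenes; with `block = NULL` it is global. The
#' scalar index is the mean of the per-band values (the eight-band variant
#' is this band mean).
#'
#' @inheritParams sam
#' @param block Tile size, or `NULL` for a single global computation.
#' @return List with `q` (scalar, mean over bands) and `per_band`
#'   (numeric vector).
#' @export
q_global <- function(reference, fused, block = NULL) {
  ref <- as_ms_array(reference); fus <- as_ms_array(fused)
  check_same_grid(ref, fus)
  nb <- dim(ref)[3]
  per_band <- vapply(seq_len(nb), function(k) {
    if (is.null(block)) {
      q_scalar(as.vector(ref[, , k]), as.vector(fus[, , k]))
    } else {
      mean(block_q_values(ref[, , k], fus[, , k], block))
    }
  }, numeric(1))
  list(q = mean(per_band), per_band = per_band)
}

block_q_values <- function(rm, fm, block) {
  d <- dim(rm)
  nbr <- ceiling(d[1] / block); nbc <- ceiling(d[2] / block)
  vals <- matrix(0, nbr, nbc)
  for (i in seq_len(nbr)) {
    rows <- ((i - 1) * block + 1):min(i * block, d[1])
    for (j in seq_len(nbc)) {
      cols <- ((j - 1) * block + 1):min(j * block, d[2])
      vals[i, j] <- q_scalar(as.vector(rm[rows, cols]),
                             as.vector(fm[rows, cols]))
    }
  }
  vals
}

#' Block quality map
#'
#' Computes the Q index on non-overlapping `block x block` tiles of every
#' band, giving a `ceil(H/block) x ceil(W/block)` map per band that
#' localises fusion quality (the usual rendering clamps to `[0, 1]`).
#'
#' @inheritParams sam
#' @param block Tile size in pixels (default 64, minimum 8).
#' @return A tibble of class `quality_map` with columns `band`,
#'   `block_row`, `block_col` and `q`; block size and grid dimensions are
#'   stored as attributes.
#' @export
quality_map <- function(reference, fused, block = 64L) {
  if (block < 8) abort("`block` must be at least 8")
  ref <- as_ms_array(reference); fus <- as_ms_array(fused)
  check_same_grid(ref, fus)
  if (block > dim(ref)[1] || block > dim(ref)[2]) {
    abort("`block` is larger than the image")
  }
  nb <- dim(ref)[3]
  band_names <- if (inherits(reference, "ms_image")) {
    reference$bands$name
  } else if (inherits(fused, "ms_image")) {
    fused$bands$name
  } else {
    paste0("band", seq_len(nb))
  }
  maps <- purrr::map(seq_len(nb), function(k) {
    vals <- block_q_values(ref[, , k], fus[, , k], block)
    tibble::tibble(
      band = factor(band_names[k], levels = band_names),
      block_row = rep(seq_len(nrow(vals)), times = ncol(vals)),
      block_col = rep(seq_len(ncol(vals)), each = nrow(vals)),
      q = as.vector(vals)
    )
  })
  out <- dplyr::bind_rows(maps)
  vals1 <- maps[[1]]
  structure(out,
            block_size = as.integer(block),
            grid_dims = c(max(vals1$block_row), max(vals1$block_col)),
            class = c("quality_map", class(out)))
}

#' Evaluate a fused product with all six quality indices
#'
#' Computes SAM, spectral ERGAS, spatial ERGAS, FC, Zhou and Q for each
#' requested band subset. By default the comparison is made on the PAN
#' grid: the multispectral reference is bicubically upsampled to the fused
#' grid (`compare_at = "pan"`); alternatively the fused product is
#' block-averaged down to the reference grid (`compare_at = "ms"`), in
#' which case the spatial indices use a block-averaged PAN.
#'
#' @param reference Original multispectral image (MS grid).
#' @param pan Panchromatic image on the fused grid.
#' @param fused Fused image on the PAN grid.
#' @param subsets Character vector from `{"all", "in_pan", "out_pan"}`.
#' @param h_over_l Resolution ratio `h/l` (PAN over MS, default
#'   0.46/1.84 = 0.25).
#' @param compare_at `"pan"` (default) or `"ms"`.
#' @param pan_adjust Spatial-ERGAS PAN mode, `"matched"` or `"raw"`.
#' @param fc_block DCT tile size for FC (default 8).
#' @param q_block Tile size for Q, or `NULL` for global Q.
#' @return A tibble of class `quality_report`, one row per subset, with
#'   the six index columns, `n_bands`, a `per_band_q` list-column and the
#'   comparison settings.
#' @export
evaluate_fusion <- function(reference, pan, fused,
                            subsets = c("all", "in_pan", "out_pan"),
                            h_over_l = 0.25,
                            compare_at = c("pan", "ms"),
                            pan_adjust = c("matched", "raw"),
                            fc_block = 8L, q_block = NULL) {
  compare_at <- match.arg(compare_at)
  pan_adjust <- match.arg(pan_adjust)
  if (!length(subsets)) abort("`subsets` must not be empty")
  bad <- setdiff(subsets, c("all", "in_pan", "out_pan"))
  if (length(bad)) abort(paste0("unknown subset label: ", bad[1]))
  p <- as_pan_matrix(pan)
  d_ref <- dim(as_ms_array(reference))
  d_fus <- dim(as_ms_array(fused))
  ratio <- d_fus[1] %/% d_ref[1]
  if (compare_at == "pan") {
    ref_cmp <- if (ratio > 1) upsample_ms(reference, ratio) else reference
    fus_cmp <- fused
    pan_cmp <- p
  } else {
    ref_cmp <- reference
    fus_cmp <- block_downsample(fused, ratio)
    pan_cmp <- block_downsample(p, ratio)
  }
  rows <- purrr::map(subsets, function(ss) {
    ref_s <- select_band_subset(ref_cmp, ss)
    fus_s <- select_band_subset(fus_cmp, ss)
    qg <- q_global(ref_s, fus_s, block = q_block)
    tibble::tibble(
      subset = ss,
      n_bands = n_bands(ref_s),
      sam_deg = sam(ref_s, fus_s),
      ergas_spectral = ergas_spectral(ref_s, fus_s, h_over_l),
      ergas_spatial = ergas_spatial(pan_cmp, fus_s, h_over_l, pan_adjust),
      fc = fc(pan_cmp, fus_s, fc_block),
      zhou = zhou(pan_cmp, fus_s),
      q = qg$q,
      per_band_q = list(qg$per_band),
      ratio_h_over_l = h_over_l,
      compare_at = compare_at,
      pan_adjust = pan_adjust
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("quality_report", class(out))
  out
}
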