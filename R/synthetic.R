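# Seeded synthetic multispectral/panchromatic scene pairs emulating three
# ecosystem archetypes: heterogeneous shrubland, water-dominated coastal,
# and mixed urban/water/dune. A high-resolution "truth" scene is painted on
# the PAN grid and degraded to an MS/PAN pair with sensor-like MTF blur,
# decimation and noise, so a true reference exists for every fused product.

#' Configuration for a synthetic scene
#'
#' @param archetype `"shrubland"`, `"coastal"` or `"mixed"`.
#' @param ms_size Pixels per side of the multispectral product (default
#'   512; the truth/PAN grid is `ms_size * ratio`).
#' @param ratio Integer PAN:MS resolution ratio (default 4).
#' @param seed Integer seed; fully determines the scene.
#' @param noise_sd Additive Gaussian noise s.d. on the MS product, as a
#'   fraction of each band's mean (default 0.01).
#' @param mtf_gain_ms Per-band MS sensor MTF gain at the Nyquist of the
#'   decimated grid (default 0.35).
#' @param mtf_gain_pan PAN sensor MTF gain at its own Nyquist (default
#'   0.15).
#' @return Object of class `scene_config`.
#' @export
scene_config <- function(archetype = c("shrubland", "coastal", "mixed"),
                         ms_size = 512L, ratio = 4L, seed = 1L,
                         noise_sd = 0.01, mtf_gain_ms = 0.35,
                         mtf_gain_pan = 0.15) {
  archetype <- match.arg(archetype)
  ms_size <- as.integer(ms_size)
  ratio <- as.integer(ratio)
  if (ms_size < 8) abort("`ms_size` must be at least 8")
  if (ratio < 1) abort("`ratio` must be >= 1")
  structure(
    list(archetype = archetype, ms_size = ms_size, ratio = ratio,
         seed = as.integer(seed), noise_sd = noise_sd,
         mtf_gain_ms = mtf_gain_ms, mtf_gain_pan = mtf_gain_pan),
    class = "scene_config"
  )
}

#' @export
print.scene_config <- function(x, ...) {
  cat(sprintf(
    "<scene_config> %s, %d x %d MS (ratio %d), seed %d, noise %.3g\n",
    x$archetype, x$ms_size, x$ms_size, x$ratio, x$seed, x$noise_sd))
  invisible(x)
}

#' Spectral signatures of the synthetic scene materials
#'
#' Reflectance-like eight-band signatures on the WorldView-2 band layout.
#' They encode the qualitative shapes the indices respond to: vegetation
#' peaks in the NIR bands, water decays toward the NIR (bands 7--8
#' lowest), sand and buildings are bright and spectrally flat.
#'
#' @return Tibble with a `material` column and `b1`..`b8` signature
#'   columns.
#' @export
material_signatures <- function() {
  tibble::tribble(
    ~material,        ~b1,   ~b2,   ~b3,   ~b4,   ~b5,   ~b6,   ~b7,   ~b8,
    "shrub",          0.040, 0.050, 0.080, 0.070, 0.050, 0.200, 0.450, 0.480,
    "bare_soil",      0.180, 0.220, 0.280, 0.330, 0.380, 0.400, 0.430, 0.450,
    "sand",           0.250, 0.300, 0.360, 0.400, 0.420, 0.440, 0.460, 0.470,
    "shallow_water",  0.120, 0.140, 0.120, 0.080, 0.050, 0.030, 0.015, 0.010,
    "deep_water",     0.060, 0.050, 0.040, 0.020, 0.012, 0.008, 0.004, 0.003,
    "building",       0.300, 0.320, 0.340, 0.350, 0.360, 0.360, 0.370, 0.370,
    "road",           0.100, 0.100, 0.110, 0.110, 0.110, 0.110, 0.120, 0.120,
    "lagoon",         0.100, 0.120, 0.140, 0.090, 0.060, 0.030, 0.020, 0.015
  )
}

signature_vector <- function(material) {
  sig <- material_signatures()
  row <- sig[sig$material == material, ]
  if (!nrow(row)) abort(paste0("unknown material: ", material))
  as.numeric(row[1, -1])
}

water_materials <- function() c("shallow_water", "deep_water", "lagoon")

# smooth random field: white noise blurred with a wide Gaussian
smooth_field <- function(n, m, sigma_ratio = 8) {
  f <- matrix(rnorm(n * m), n, m)
  f <- sep_filter(f, mtf_gaussian_kernel(0.05, sigma_ratio))
  f / max(sd(as.vector(f)), 1e-12)
}

#' Paint a ground-truth scene at the panchromatic grid
#'
#' Builds an eight-band truth image of side `ms_size * ratio` for the
#' configured archetype. Shrubland: a bare-soil matrix densely scattered
#' with small irregular shrub ellipses (2--10 PAN pixels across). Coastal:
#' at least 60% water with a smooth depth-driven brightness gradient and a
#' textured sand/dune shore. Mixed: a lagoon water body, an axis-aligned
#' building grid with roads, and a rippled dune field. A multiplicative
#' texture field gives every material fine-scale detail. Deterministic per
#' seed; the material label matrix is attached as attribute `"labels"`.
#'
#' @param config A [scene_config()].
#' @return An [ms_image()] on the PAN grid (gsd 0.46).
#' @export
paint_truth_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  n <- config$ms_size * config$ratio
  withr::with_seed(config$seed, {
    labels <- switch(config$archetype,
      shrubland = paint_shrubland(n),
      coastal = paint_coastal(n),
      mixed = paint_mixed(n),
      abort(paste0("unknown archetype: ", config$archetype))
    )
    depth <- attr(labels, "depth")  # in [0,1] over water, NA elsewhere
    mats <- sort(unique(as.vector(labels)))
    pix <- array(0, c(n, n, 8))
    for (mat in mats) {
      mask <- labels == mat
      sig <- signature_vector(mat)
      for (k in 1:8) {
        plane <- pix[, , k]
        plane[mask] <- sig[k]
        pix[, , k] <- plane
      }
    }
    # wet-sand blending toward the shallow-water signature near a shoreline
    wet <- attr(labels, "wet")
    if (!is.null(wet)) {
      shallow <- signature_vector("shallow_water")
      wmask <- wet > 0
      for (k in 1:8) {
        plane <- pix[, , k]
        plane[wmask] <- plane[wmask] * (1 - wet[wmask]) +
          shallow[k] * wet[wmask]
        pix[, , k] <- plane
      }
    }
    # depth-driven darkening of water: deeper water blends toward the
    # deep-water signature
    if (!is.null(depth)) {
      deep <- signature_vector("deep_water")
      wmask <- !is.na(depth)
      for (k in 1:8) {
        plane <- pix[, , k]
        plane[wmask] <- plane[wmask] * (1 - depth[wmask]) +
          deep[k] * depth[wmask]
        pix[, , k] <- plane
      }
    }
    # fine-scale multiplicative texture shared across bands, plus a gentle
    # illumination field and any archetype-specific shading
    texture <- 1 + 0.08 * matrix(rnorm(n * n), n, n)
    illum <- 1 + 0.05 * smooth_field(n, n)
    shade <- attr(labels, "shade")
    if (!is.null(shade)) illum <- illum * shade
    for (k in 1:8) pix[, , k] <- pmax(pix[, , k] * texture * illum, 0)
    out <- ms_image(pix, bands = wv2_bands(), gsd = 1.84 / config$ratio)
    attr(out, "labels") <- labels
    out
  })
}

paint_shrubland <- function(n) {
  labels <- matrix("bare_soil", n, n)
  # dense scattering of small irregular patches; ~40% cover on average so
  # the heterogeneity survives decimation to the MS grid
  n_patch <- max(1L, round(0.40 * n^2 / (pi * 2.5^2)))
  cx <- runif(n_patch, 1, n); cy <- runif(n_patch, 1, n)
  ax <- runif(n_patch, 1, 5); ay <- runif(n_patch, 1, 5)
  th <- runif(n_patch, 0, pi)
  xs <- matrix(rep(seq_len(n), each = n), n, n)   # column coordinate
  ys <- matrix(rep(seq_len(n), times = n), n, n)  # row coordinate
  for (i in seq_len(n_patch)) {
    dx <- xs - cx[i]; dy <- ys - cy[i]
    u <- dx * cos(th[i]) + dy * sin(th[i])
    v <- -dx * sin(th[i]) + dy * cos(th[i])
    inside <- (u / ax[i])^2 + (v / ay[i])^2 <= 1
    labels[inside] <- "shrub"
  }
  labels
}

paint_coastal <- function(n) {
  labels <- matrix("sand", n, n)
  xs <- matrix(rep(seq_len(n), each = n), n, n)
  ys <- matrix(rep(seq_len(n), times = n), n, n)
  # coastline at ~35% from the left with a gentle random wiggle; water on
  # the right covers >= 60% of the scene by construction
  phase <- runif(2, 0, 2 * pi)
  wiggle <- 0.02 * n * (sin(2 * pi * ys[, 1] / n + phase[1]) +
                          0.5 * sin(6 * pi * ys[, 1] / n + phase[2]))
  shoreline <- 0.35 * n + wiggle
  water <- xs > matrix(shoreline, n, n)
  labels[water] <- "shallow_water"
  # depth ramps smoothly offshore
  depth <- matrix(NA_real_, n, n)
  dist_off <- (xs - matrix(shoreline, n, n)) / (n - 0.35 * n)
  depth[water] <- pmin(pmax(dist_off[water], 0), 1)^1.5
  # gentle dune brightness ripples on land (no material switch: the
  # coastal scene must stay the smoothest archetype)
  ripple <- 1 + 0.04 * sin(2 * pi * (xs + 0.3 * ys) / (0.05 * n))
  ripple[water] <- 1
  # wet-sand transition: the beach blends smoothly into shallow water over
  # ~12% of the scene width, so the shoreline is a soft gradient
  onshore <- matrix(shoreline, n, n) - xs
  wet <- matrix(0, n, n)
  zone <- !water & onshore < 0.12 * n
  wet[zone] <- (1 - onshore[zone] / (0.12 * n))^2
  attr(labels, "depth") <- depth
  attr(labels, "shade") <- ripple
  attr(labels, "wet") <- wet
  labels
}

paint_mixed <- function(n) {
  labels <- matrix("sand", n, n)
  xs <- matrix(rep(seq_len(n), each = n), n, n)
  ys <- matrix(rep(seq_len(n), times = n), n, n)
  # lagoon occupying the left ~40%, wiggly edge
  phase <- runif(1, 0, 2 * pi)
  edge <- 0.40 * n + 0.03 * n * sin(2 * pi * ys[, 1] / n + phase)
  water <- xs < matrix(edge, n, n)
  labels[water] <- "lagoon"
  depth <- matrix(NA_real_, n, n)
  depth[water] <- pmin(pmax((matrix(edge, n, n) - xs)[water] / (0.4 * n), 0),
                       1)^0.8
  # building blocks with roads in the upper-right quadrant
  block <- max(6L, round(n / 16))
  street <- max(2L, round(block / 3))
  urban_rows <- ys <= 0.45 * n
  urban_cols <- xs >= 0.55 * n
  urban <- urban_rows & urban_cols & !water
  labels[urban] <- "road"
  pitch <- block + street
  in_block <- ((ys - 1) %% pitch) < block & ((xs - 1) %% pitch) < block
  labels[urban & in_block] <- "building"
  # dune field in the lower-right: rippled sand/soil
  dunes <- ys > 0.55 * n & xs >= 0.45 * n & !water
  ripple <- sin(2 * pi * (xs + 0.5 * ys) / (0.04 * n)) > 0.5
  labels[dunes & ripple] <- "bare_soil"
  attr(labels, "depth") <- depth
  labels
}

#' Degrade a truth scene to a multispectral/panchromatic pair
#'
#' Reduced-resolution construction: the MS product is obtained per band by
#' a Gaussian MTF blur (gain `mtf_gain_ms` at the Nyquist of the decimated
#' grid), block-mean decimation by `ratio` and additive Gaussian noise
#' with s.d. `noise_sd` times the band mean. The PAN product is the
#' overlap-weighted sum of the truth bands inside the 450--800 nm range
#' (weights proportional to each band's wavelength overlap, summing to 1)
#' blurred by the PAN MTF. Deterministic given the config seed.
#'
#' @param truth Truth [ms_image()] on the PAN grid.
#' @param config The [scene_config()] used to paint it.
#' @return List with `ms` (an [ms_image()] on the coarse grid) and `pan`
#'   (a [pan_image()]).
#' @export
degrade_to_pair <- function(truth, config) {
  pix <- as_ms_array(truth)
  d <- dim(pix)
  r <- config$ratio
  if (any(d[1:2] %% r != 0)) {
    abort("truth dimensions are not divisible by `ratio`")
  }
  nb <- d[3]
  ms_kernel <- mtf_gaussian_kernel(config$mtf_gain_ms, r)
  ms_pix <- array(0, c(d[1] %/% r, d[2] %/% r, nb))
  band_means <- numeric(nb)
  for (k in seq_len(nb)) {
    blurred <- sep_filter(pix[, , k], ms_kernel)
    ms_pix[, , k] <- block_downsample(blurred, r)
    band_means[k] <- mean(ms_pix[, , k])
  }
  if (config$noise_sd > 0) {
    withr::with_seed(config$seed + 7919L, {
      for (k in seq_len(nb)) {
        ms_pix[, , k] <- ms_pix[, , k] +
          rnorm(length(ms_pix[, , k]), sd = config$noise_sd * band_means[k])
      }
    })
  }
  ms_pix <- pmax(ms_pix, 0)
  w <- band_overlap_weights(truth$bands)
  pan0 <- matrix(0, d[1], d[2])
  for (k in which(w > 0)) pan0 <- pan0 + w[k] * pix[, , k]
  pan <- sep_filter(pan0, mtf_gaussian_kernel(config$mtf_gain_pan, 1))
  pan <- pmax(pan, 0)
  list(
    ms = ms_image(ms_pix, bands = truth$bands, gsd = truth$gsd * r),
    pan = pan_image(pan, gsd = truth$gsd, ratio = r)
  )
}

#' Simulate a complete synthetic scene
#'
#' Convenience wrapper: paints the truth scene and degrades it to an
#' MS/PAN pair.
#'
#' @param config A [scene_config()].
#' @return List with `truth`, `ms`, `pan` and `config`.
#' @export
simulate_scene <- function(config) {
  truth <- paint_truth_scene(config)
  pair <- degrade_to_pair(truth, config)
  list(truth = truth, ms = pair$ms, pan = pair$pan, config = config)
}

#' Evaluate a fused product against the synthetic ground truth
#'
#' Full-reference check available only in simulation: the truth scene is
#' both the spectral reference and (through its in-PAN intensity, the same
#' overlap-weighted band sum used to synthesise the PAN) the spatial
#' reference.
#'
#' @param truth Truth [ms_image()] on the PAN grid.
#' @param fused Fused image on the same grid.
#' @param ... Passed to [evaluate_fusion()].
#' @return A `quality_report` tibble.
#' @export
ground_truth_report <- function(truth, fused, ...) {
  check_same_grid(as_ms_array(truth), as_ms_array(fused))
  w <- band_overlap_weights(truth$bands)
  pix <- as_ms_array(truth)
  pan_ref <- matrix(0, dim(pix)[1], dim(pix)[2])
  for (k in which(w > 0)) pan_ref <- pan_ref + w[k] * pix[, , k]
  evaluate_fusion(truth, pan_ref, fused, ...)
}

#' Recommended fractal-analysis window per archetype
#'
#' The more heterogeneous the scene, the smaller the window: 7 for
#' shrubland, 15 for mixed, 27 for coastal.
#'
#' @param archetype Archetype name.
#' @return Odd integer window size.
#' @export
default_wat_window <- function(archetype) {
  switch(archetype, shrubland = 7L, mixed = 15L, coastal = 27L,
         abort(paste0("unknown archetype: ", archetype)))
}
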