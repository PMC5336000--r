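test_that("the 'a trous' decomposition reconstructs exactly", {
  set.seed(21)
  x <- matrix(runif(48 * 40) * 100, 48, 40)
  for (levels in 1:3) {
    dec <- atrous_decompose(x, levels)
    expect_length(dec$details, levels)
    err <- max(abs(atrous_reconstruct(dec) - x)) / max(abs(x))
    expect_lt(err, 1e-9)
  }
  expect_equal(sum(atrous_decompose(x, 1)$kernel), 1)
  const <- atrous_decompose(matrix(7, 16, 16), 2)
  expect_true(all(vapply(const$details, function(d) max(abs(d)), 1) < 1e-12))
  expect_error(atrous_decompose(x, 0), ">= 1")
})

test_that("moment matching reproduces the reference statistics", {
  set.seed(22)
  src <- matrix(rnorm(400, 100, 10), 20, 20)
  ref <- matrix(rnorm(400, 50, 5), 20, 20)
  out <- histogram_match(src, ref)
  expect_equal(mean(out), mean(ref), tolerance = 1e-9)
  expect_equal(sd(as.vector(out)), sd(as.vector(ref)), tolerance = 1e-9)
  expect_equal(histogram_match(src, src), src)
  expect_equal(histogram_match(matrix(3, 4, 4), matrix(9, 4, 4)),
               matrix(9, 4, 4))
  expect_error(histogram_match(matrix(3, 4, 4), ref), "zero-variance")
})

test_that("MTF-matched kernels meet their Nyquist gain exactly", {
  for (gain in c(0.15, 0.35)) {
    for (ratio in c(1, 4)) {
      k <- mtf_gaussian_kernel(gain, ratio)
      expect_equal(sum(k), 1, tolerance = 1e-12)  # DC gain
      resp <- fuseval:::kernel_response(k, 1 / (2 * ratio))
      expect_equal(resp, gain, tolerance = 1e-3)
    }
  }
  # smaller gain blurs strictly more at every non-zero frequency
  k35 <- mtf_gaussian_kernel(0.35, 4)
  k15 <- mtf_gaussian_kernel(0.15, 4)
  freqs <- seq(0.02, 0.5, by = 0.02)
  expect_true(all(fuseval:::kernel_response(k15, freqs) <
                    fuseval:::kernel_response(k35, freqs)))
  # constant plane unchanged
  expect_equal(mtf_filter(matrix(4, 12, 12), 0.35, 4), matrix(4, 12, 12),
               tolerance = 1e-12)
  expect_error(mtf_filter(matrix(1, 4, 4), 1.2, 4), "gain")
})

test_that("FIHS follows the additive injection rule", {
  # hand case: one pixel, bands (10, 20), I = 15, matched PAN 19 -> (14, 24)
  msu <- ms_image(array(c(10, 20), c(1, 1, 2)), wv2_bands()[1:2, ])
  f <- fuse_fihs(msu, matrix(19, 1, 1), pan_match = "none")
  expect_equal(as.vector(f$pixels), c(14, 24))

  set.seed(23)
  pix <- array(runif(16 * 16 * 4) + 1, c(16, 16, 4))
  msu <- ms_image(pix, wv2_bands()[1:4, ])
  intensity <- rowMeans(pix, dims = 2)
  # zero detail: PAN identical to the intensity
  expect_equal(fuse_fihs(msu, intensity)$pixels, pix, tolerance = 1e-9)
  # additivity: a constant offset on the PAN lifts every band by it
  f_off <- fuse_fihs(msu, intensity + 5, pan_match = "none")
  expect_equal(f_off$pixels, pix + 5, tolerance = 1e-12)
  expect_error(fuse_fihs(msu, matrix(1, 4, 4)), "grid")
})

test_that("HCS substitutes the radius and preserves spectral angles", {
  # Pythagoras: bands (3, 4) have hyperspherical radius 5
  msu <- ms_image(array(c(3, 4), c(1, 1, 2)), wv2_bands()[1:2, ])
  f <- fuse_hcs(msu, matrix(10, 1, 1), pan_match = "none")
  expect_equal(as.vector(f$pixels), c(3, 4) * 2)  # radius 5 -> 10

  set.seed(24)
  pix <- array(runif(16 * 16 * 3) + 0.5, c(16, 16, 3))
  msu <- ms_image(pix, wv2_bands()[1:3, ])
  radius <- sqrt(rowSums(pix^2, dims = 2))
  expect_equal(fuse_hcs(msu, radius)$pixels, pix, tolerance = 1e-9)
  pan <- matrix(runif(256) + 0.5, 16, 16)
  expect_lt(sam(msu, fuse_hcs(msu, pan)), 0.01)
  expect_error(fuse_hcs(ms_image(pix[, , 1, drop = FALSE],
                                 wv2_bands()[1, ]), pan), "2 bands")
})

test_that("high-pass modulation injects detail multiplicatively", {
  # modulation rule: fused = MS * PAN / PAN_low (hand case: MS 10,
  # PAN 200, PAN_low 100 -> fused 20); verified by recomputing PAN_low
  # exactly as documented and checking the quotient
  set.seed(28)
  msu1 <- ms_image(array(10, c(16, 16, 1)), wv2_bands()[1, ])
  pan1 <- matrix(runif(256) + 1, 16, 16)
  f1 <- fuse_mtf_glp_hpm(msu1, pan1, gains = 0.35, ratio = 4)
  filt <- fuseval:::sep_filter(pan1, mtf_gaussian_kernel(0.35, 4))
  dec <- block_downsample(filt, 4)
  pan_low <- upsample_ms(ms_image(array(dec, c(dim(dec), 1)),
                                  wv2_bands()[1, ]), 4)$pixels[, , 1]
  expect_equal(f1$pixels[, , 1], 10 * pan1 / pan_low, tolerance = 1e-9)

  set.seed(25)
  pixr <- array(runif(24 * 24 * 3) + 1, c(24, 24, 3))
  msu <- ms_image(pixr, wv2_bands()[1:3, ])
  panr <- matrix(runif(24 * 24) + 1, 24, 24)
  f <- fuse_mtf_glp_hpm(msu, panr, ratio = 4)
  # per-pixel band ratios preserved wherever defined
  expect_equal(f$pixels[, , 1] / f$pixels[, , 2],
               pixr[, , 1] / pixr[, , 2], tolerance = 1e-9)
  # constant PAN is the identity
  f_const <- fuse_mtf_glp_hpm(msu, matrix(7, 24, 24), ratio = 4)
  expect_equal(f_const$pixels, pixr, tolerance = 1e-9)
})

test_that("fractal dimension maps respond to surface complexity", {
  flat <- fractal_dimension_map(matrix(5, 32, 32), 7)
  expect_equal(dim(flat$raw_dimension), c(32, 32))
  expect_true(all(abs(flat$raw_dimension - 2) <= 0.1))
  expect_true(all(flat$alpha >= 0 & flat$alpha <= 1))

  set.seed(26)
  noise <- fractal_dimension_map(matrix(runif(32 * 32), 32, 32), 7)
  gradient <- fractal_dimension_map(outer(1:32, 1:32, "+") / 64, 7)
  expect_gt(mean(noise$raw_dimension), mean(gradient$raw_dimension))

  expect_error(fractal_dimension_map(matrix(1, 32, 32), 8), "odd")
  expect_warning(fractal_dimension_map(matrix(runif(32 * 32), 32, 32), 9),
                 "usual")
})

test_that("weighted wavelet fusion reduces to its limiting forms", {
  set.seed(27)
  pix <- array(runif(32 * 32 * 3) + 1, c(32, 32, 3))
  msu <- ms_image(pix, wv2_bands()[1:3, ])
  pan <- matrix(runif(32 * 32) + 1, 32, 32)

  # alpha = 0: identity
  f0 <- fuse_wat_frac(msu, pan, window = 7, alpha = 0)
  expect_equal(f0$pixels, pix, tolerance = 1e-12)

  # alpha = 1: plain additive 'a trous' fusion (independent oracle)
  f1 <- fuse_wat_frac(msu, pan, window = 7, alpha = 1)
  oracle <- pix
  for (k in 1:3) {
    pm <- (pan - mean(pan)) * (sd(as.vector(pix[, , k])) /
                                 sd(as.vector(pan))) + mean(pix[, , k])
    dec <- atrous_decompose(pm, 2)
    oracle[, , k] <- pix[, , k] + dec$details[[1]] + dec$details[[2]]
  }
  expect_equal(f1$pixels, pmax(oracle, 0), tolerance = 1e-12)

  # different windows give different (non-degenerate) weightings
  fw7 <- fuse_wat_frac(msu, pan, window = 7)
  fw27 <- fuse_wat_frac(msu, pan, window = 27)
  expect_false(isTRUE(all.equal(fw7$pixels, fw27$pixels)))
  expect_error(fuse_wat_frac(msu, pan, window = 8), "odd")
})

test_that("every algorithm returns the upsampled MS when the PAN adds no detail", {
  scn <- zero_detail_scene()
  pix <- scn$ms$pixels
  expect_equal(fuse_fihs(scn$ms, scn$pan)$pixels, pix, tolerance = 1e-6)
  expect_equal(fuse_hcs(scn$ms, scn$pan)$pixels, pix, tolerance = 1e-6)
  expect_equal(fuse_mtf_glp_hpm(scn$ms, scn$pan)$pixels, pix,
               tolerance = 1e-6)
  expect_equal(fuse_wat_frac(scn$ms, scn$pan, 7)$pixels, pix,
               tolerance = 1e-6)
})

test_that("fused products stay spectrally consistent with the original MS", {
  scn <- simulate_scene(scene_config("mixed", ms_size = 24, seed = 9))
  ms_up <- upsample_ms(scn$ms, 4)
  set.seed(31)
  for (alg in c("fihs", "hcs", "mtf_glp_hpm", "wat_frac")) {
    fused <- fuseval:::apply_fusion(alg, ms_up, scn$pan, ratio = 4,
                                    window = 15)
    back <- block_downsample(fused, 4)
    e_fused <- ergas_spectral(scn$ms, back)
    # random-permutation control: same values, scrambled locations
    perm <- back
    idx <- sample(length(back$pixels[, , 1]))
    for (k in 1:8) perm$pixels[, , k] <- back$pixels[, , k][idx]
    e_perm <- ergas_spectral(scn$ms, perm)
    expect_lt(e_fused, e_perm)
    for (k in 1:8) {
      expect_gt(cor(as.vector(back$pixels[, , k]),
                    as.vector(scn$ms$pixels[, , k])), 0.95)
    }
  }
})
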