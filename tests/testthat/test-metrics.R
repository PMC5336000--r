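test_that("indices satisfy their defining identities and hand values", {
  set.seed(41)
  pix <- array(runif(16 * 16 * 3) + 0.5, c(16, 16, 3))
  ms <- ms_image(pix, wv2_bands()[1:3, ])

  # SAM: identity, scale invariance, 45-degree geometry
  expect_lt(sam(ms, ms), 1e-4)
  expect_lt(sam(ms, ms_image(3 * pix, wv2_bands()[1:3, ])), 1e-4)
  expect_equal(sam(array(c(1, 0), c(1, 1, 2)), array(c(1, 1), c(1, 1, 2))),
               45)
  expect_error(sam(array(0, c(2, 2, 2)), array(0, c(2, 2, 2))), "zero-norm")

  # spectral ERGAS: identity, hand value, homogeneity
  expect_equal(ergas_spectral(ms, ms), 0)
  expect_equal(ergas_spectral(array(10, c(2, 2, 1)),
                              array(11, c(2, 2, 1)), 0.25), 2.5)
  e1 <- ergas_spectral(ms, ms_image(pix + 0.05, wv2_bands()[1:3, ]))
  e2 <- ergas_spectral(ms, ms_image(pix + 0.10, wv2_bands()[1:3, ]))
  expect_equal(e2, 2 * e1, tolerance = 1e-9)

  # spatial ERGAS: matched identity and hand value
  pan <- matrix(runif(256) + 0.5, 16, 16)
  fus_pan <- array(pan, c(16, 16, 1))
  expect_lt(ergas_spatial(pan, fus_pan), 1e-9)
  expect_equal(ergas_spatial(matrix(20, 2, 2), array(22, c(2, 2, 1)),
                             0.25, "raw"), 2.5)
  # moment matching can only reduce the error on a biased band
  biased <- array(pan + 3, c(16, 16, 1))
  expect_lte(ergas_spatial(pan, biased, 0.25, "matched"),
             ergas_spatial(pan, biased, 0.25, "raw"))
})

test_that("spatial structure indices score resemblance to the PAN", {
  set.seed(42)
  pan <- matrix(runif(64 * 64) + 0.5, 64, 64)
  as_fused <- function(m) array(m, c(dim(m), 1))

  expect_equal(fc(pan, as_fused(pan)), 1, tolerance = 1e-12)
  expect_equal(fc(pan, as_fused(pan + 5)), 1, tolerance = 1e-9)  # DC excluded
  blurred <- fuseval:::sep_filter(pan, mtf_gaussian_kernel(0.1, 4))
  expect_lt(fc(pan, as_fused(blurred)), fc(pan, as_fused(pan)))
  expect_error(fc(pan, as_fused(pan), block = 1), ">= 2")

  expect_equal(zhou(pan, as_fused(pan)), 1, tolerance = 1e-12)
  neg <- max(pan) - pan  # anti-correlated high-pass structure
  expect_equal(zhou(pan, as_fused(neg)), -1, tolerance = 1e-12)
  expect_lt(zhou(pan, as_fused(blurred)), 1)
  expect_error(zhou(matrix(1, 8, 8), as_fused(matrix(1, 8, 8))),
               "zero variance")
})

test_that("the Q index matches direct evaluation and penalises shifts", {
  set.seed(43)
  pix <- array(runif(16 * 16 * 2) + 0.5, c(16, 16, 2))
  ms <- ms_image(pix, wv2_bands()[1:2, ])
  expect_equal(q_global(ms, ms)$q, 1)
  expect_equal(q_global(ms, ms)$per_band, c(1, 1))
  shifted <- ms_image(pix + 2, wv2_bands()[1:2, ])
  expect_lt(q_global(ms, shifted)$q, 1)

  # 2x2 single-band instance against the raw formula
  ref <- array(c(1, 3, 2, 4), c(2, 2, 1))
  expect_equal(q_global(ref, ref)$q, 1)
  rev <- array(c(4, 2, 3, 1), c(2, 2, 1))
  x <- c(1, 3, 2, 4); y <- c(4, 2, 3, 1)
  expected <- 4 * mean((x - mean(x)) * (y - mean(y))) * mean(x) * mean(y) /
    ((mean((x - mean(x))^2) + mean((y - mean(y))^2)) *
       (mean(x)^2 + mean(y)^2))
  expect_equal(q_global(ref, rev)$q, expected)
  # degenerate flat blocks: 1 when identical, 0 otherwise
  expect_equal(q_global(array(2, c(2, 2, 1)), array(2, c(2, 2, 1)))$q, 1)
  expect_equal(q_global(array(2, c(2, 2, 1)), array(5, c(2, 2, 1)))$q, 0)
})

test_that("all six indices match naive loop-based oracles on small instances", {
  for (seed in c(101, 102, 103)) {
    p <- random_pair(8, 8, 2, seed)
    pan <- p$ref[, , 1] * 0.6 + p$ref[, , 2] * 0.4
    rel <- function(a, b) abs(a - b) / max(abs(b), 1e-12)

    expect_lt(rel(sam(p$ref, p$fus), oracle_sam(p$ref, p$fus)), 1e-9)
    expect_lt(rel(ergas_spectral(p$ref, p$fus, 0.25),
                  oracle_ergas_spectral(p$ref, p$fus, 0.25)), 1e-9)
    expect_lt(rel(ergas_spatial(pan, p$fus, 0.25, "matched"),
                  oracle_ergas_spatial(pan, p$fus, 0.25, TRUE)), 1e-9)
    expect_lt(rel(ergas_spatial(pan, p$fus, 0.25, "raw"),
                  oracle_ergas_spatial(pan, p$fus, 0.25, FALSE)), 1e-9)
    expect_lt(rel(fc(pan, p$fus, block = 4),
                  oracle_fc(pan, p$fus, 4)), 1e-9)
    expect_lt(rel(zhou(pan, p$fus), oracle_zhou(pan, p$fus)), 1e-9)
    expect_lt(rel(q_global(p$ref, p$fus)$q, oracle_q(p$ref, p$fus)), 1e-9)
  }
})

test_that("indices move monotonically with added noise and blur", {
  scn <- simulate_scene(scene_config("shrubland", ms_size = 24, seed = 13))
  ms_up <- upsample_ms(scn$ms, 4)
  fused <- fuse_fihs(ms_up, scn$pan)
  pan <- scn$pan$pixels

  set.seed(44)
  noise <- array(rnorm(length(fused$pixels)), dim(fused$pixels))
  sams <- ergs <- numeric(3)
  for (i in 1:3) {
    lvl <- c(0, 0.01, 0.03)[i]
    noisy <- ms_image(pmax(fused$pixels + lvl * noise, 1e-6),
                      fused$bands, fused$gsd)
    sams[i] <- sam(ms_up, noisy)
    ergs[i] <- ergas_spectral(ms_up, noisy)
  }
  expect_true(all(diff(sams) > 0))
  expect_true(all(diff(ergs) > 0))

  fcs <- zhous <- numeric(3)
  for (i in 1:3) {
    gain <- c(0.9, 0.4, 0.1)[i]  # stronger blur as gain drops
    blurred_pix <- fused$pixels
    for (k in 1:8) {
      blurred_pix[, , k] <- fuseval:::sep_filter(
        fused$pixels[, , k], mtf_gaussian_kernel(gain, 2))
    }
    blurred <- ms_image(pmax(blurred_pix, 0), fused$bands, fused$gsd)
    fcs[i] <- fc(pan, blurred)
    zhous[i] <- zhou(pan, blurred)
  }
  expect_true(all(diff(fcs) < 0))
  expect_true(all(diff(zhous) < 0))
})

test_that("quality maps have block geometry and localise distortion", {
  set.seed(45)
  pix <- array(runif(128 * 128 * 2) + 0.5, c(128, 128, 2))
  ms <- ms_image(pix, wv2_bands()[1:2, ])
  qm <- quality_map(ms, ms, block = 32)
  expect_equal(attr(qm, "grid_dims"), c(4, 4))
  expect_true(all(abs(qm$q - 1) < 1e-12))

  distorted <- pix
  distorted[1:64, 1:64, ] <- distorted[64:1, 64:1, ]  # scramble one quadrant
  qmd <- quality_map(ms, ms_image(distorted, wv2_bands()[1:2, ]), block = 32)
  hit <- qmd$block_row <= 2 & qmd$block_col <= 2
  expect_lt(max(qmd$q[hit]), min(qmd$q[!hit]))
  expect_true(all(abs(qmd$q[!hit] - 1) < 1e-12))

  expect_error(quality_map(ms, ms, block = 4), "at least 8")
  expect_error(quality_map(ms, ms, block = 256), "larger")
})

test_that("evaluation reports cover subsets consistently", {
  scn <- simulate_scene(scene_config("coastal", ms_size = 16, seed = 14))
  ms_up <- upsample_ms(scn$ms, 4)
  fused <- fuse_fihs(ms_up, scn$pan)
  rep3 <- evaluate_fusion(scn$ms, scn$pan, fused)
  expect_equal(nrow(rep3), 3)
  expect_equal(rep3$n_bands, c(8L, 5L, 3L))

  # identical fused/reference: SAM 0 and Q 1 in every subset
  self_rep <- evaluate_fusion(scn$ms, scn$pan, upsample_ms(scn$ms, 4))
  expect_true(all(self_rep$sam_deg < 1e-4))
  expect_true(all(abs(self_rep$q - 1) < 1e-9))

  # the all-bands ERGAS is the band-count-weighted quadratic mean of the
  # subset values
  e_all <- rep3$ergas_spectral[1]; e_in <- rep3$ergas_spectral[2]
  e_out <- rep3$ergas_spectral[3]
  expect_equal(e_all, sqrt((5 * e_in^2 + 3 * e_out^2) / 8),
               tolerance = 1e-9)

  # serialisation round trip
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(rep3[, !(names(rep3) %in% "per_band_q")], path,
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$sam_deg, rep3$sam_deg)
  expect_equal(back$q, rep3$q)

  expect_error(evaluate_fusion(scn$ms, scn$pan, fused, subsets = "bogus"),
               "unknown subset")
  expect_error(evaluate_fusion(scn$ms, scn$pan, fused,
                               subsets = character()), "empty")
})
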