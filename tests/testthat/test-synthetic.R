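test_that("scene painting is deterministic per seed and varies across seeds", {
  cfg <- scene_config("shrubland", ms_size = 32, seed = 1)
  a <- paint_truth_scene(cfg)
  b <- paint_truth_scene(cfg)
  expect_identical(a$pixels, b$pixels)
  c2 <- paint_truth_scene(scene_config("shrubland", ms_size = 32, seed = 2))
  expect_false(identical(a$pixels, c2$pixels))
})

test_that("archetypes have their constructed land-cover composition", {
  coastal <- paint_truth_scene(scene_config("coastal", ms_size = 32, seed = 3))
  lab <- attr(coastal, "labels")
  water_frac <- mean(lab %in% c("shallow_water", "deep_water", "lagoon"))
  expect_gte(water_frac, 0.6)

  mixed <- paint_truth_scene(scene_config("mixed", ms_size = 32, seed = 3))
  labm <- unique(as.vector(attr(mixed, "labels")))
  expect_true("lagoon" %in% labm)   # water body
  expect_true("building" %in% labm)
  expect_true("sand" %in% labm)

  shrub <- paint_truth_scene(scene_config("shrubland", ms_size = 32, seed = 3))
  labs <- unique(as.vector(attr(shrub, "labels")))
  expect_setequal(labs, c("shrub", "bare_soil"))
})

test_that("material signatures satisfy their spectral-shape constraints", {
  sig <- material_signatures()
  mat <- as.matrix(sig[, -1])
  expect_true(all(mat >= 0))
  for (w in c("shallow_water", "deep_water", "lagoon")) {
    s <- as.numeric(sig[sig$material == w, -1])
    expect_equal(sort(order(s)[1:2]), c(7, 8))  # NIR bands lowest
  }
  veg <- as.numeric(sig[sig$material == "shrub", -1])
  expect_equal(which.max(veg), 8)  # NIR peak
})

test_that("degradation produces the right grids and preserves constants", {
  cfg <- scene_config("shrubland", ms_size = 16, ratio = 4, seed = 1,
                      noise_sd = 0)
  truth <- paint_truth_scene(cfg)
  pair <- degrade_to_pair(truth, cfg)
  expect_equal(dim(pair$ms$pixels), c(16, 16, 8))
  expect_equal(dim(pair$pan$pixels), c(64, 64))

  const_truth <- ms_image(array(rep(1:8 / 10, each = 64 * 64), c(64, 64, 8)),
                          gsd = 0.46)
  cp <- degrade_to_pair(const_truth, cfg)
  expect_equal(as.vector(apply(cp$ms$pixels, 3, range)),
               rep(1:8 / 10, each = 2), tolerance = 1e-12)
  # PAN of a constant scene is the overlap-weighted constant
  w <- band_overlap_weights(wv2_bands())
  expect_equal(unique(round(as.vector(cp$pan$pixels), 12)),
               round(sum(w * 1:8 / 10), 12))

  bad <- ms_image(array(1, c(30, 30, 8)), gsd = 0.46)
  expect_error(degrade_to_pair(bad, cfg), "divisible")
})

test_that("PAN weights cover exactly the in-range bands and sum to one", {
  w <- band_overlap_weights(wv2_bands())
  expect_equal(sum(w), 1)
  expect_equal(which(w > 0), 2:6)
  # proportional to the wavelength overlap with 450-800 nm
  expect_equal(w[2:6], c(60, 70, 40, 60, 40) / 270)
})

test_that("block-mean PAN tracks the in-range MS intensity on noise-free scenes", {
  for (arch in c("shrubland", "coastal", "mixed")) {
    scn <- simulate_scene(scene_config(arch, ms_size = 24, seed = 7,
                                       noise_sd = 0))
    pan_block <- block_downsample(scn$pan$pixels, 4)
    intensity <- rowMeans(scn$ms$pixels[, , 2:6], dims = 2)
    expect_gt(cor(as.vector(pan_block), as.vector(intensity)), 0.95)
  }
})

test_that("shrubland is more locally variable than coastal on the MS product", {
  local_var <- function(ms) {
    m <- rowMeans(ms$pixels, dims = 2)
    k <- rep(1 / 5, 5)
    v <- fuseval:::sep_filter(m^2, k) - fuseval:::sep_filter(m, k)^2
    mean(pmax(v, 0))
  }
  for (seed in 1:3) {
    shrub <- simulate_scene(scene_config("shrubland", ms_size = 32,
                                         seed = seed, noise_sd = 0))
    coast <- simulate_scene(scene_config("coastal", ms_size = 32,
                                         seed = seed, noise_sd = 0))
    expect_gt(local_var(shrub$ms), local_var(coast$ms))
  }
})

test_that("ground-truth reports behave like a full-reference check", {
  cfg <- scene_config("mixed", ms_size = 16, seed = 2)
  truth <- paint_truth_scene(cfg)
  self_rep <- ground_truth_report(truth, truth, subsets = "all")
  expect_lt(self_rep$sam_deg, 1e-4)
  expect_equal(self_rep$q, 1, tolerance = 1e-9)

  blurred <- truth
  for (k in 1:8) {
    blurred$pixels[, , k] <- fuseval:::sep_filter(
      truth$pixels[, , k], fuseval:::mtf_gaussian_kernel(0.1, 2))
  }
  blur_rep <- ground_truth_report(truth, blurred, subsets = "all")
  expect_lt(blur_rep$zhou, 1)

  swapped <- truth
  swapped$pixels <- truth$pixels[, , c(8, 1:7)]
  swap_rep <- ground_truth_report(truth, swapped, subsets = "all")
  expect_gt(swap_rep$sam_deg, 1)

  wrong <- ms_image(truth$pixels[1:32, 1:32, ], gsd = truth$gsd)
  expect_error(ground_truth_report(truth, wrong), "mismatch")
})
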