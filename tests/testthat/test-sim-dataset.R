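test_that("disabling the background makes input and target identical", {
  vol <- tiny_vol()
  pf <- place_particles(vol, c(3, 5), 2, seed = 4)
  bg <- background_params(beta = 0, seed = 4)
  pr <- render_pair(pf, vol, 2, bg, noise_params(seed = 4))
  expect_identical(pr$input, pr$target)
})

test_that("a null scene with all noise disabled renders an all-zero frame", {
  vol <- tiny_vol()
  pf <- place_particles(vol, c(0, 0), 2, seed = 1)
  pr <- render_pair(pf, vol, 0, background_params(beta = 0),
                    noise_params(gaussian_level = 0, poisson_gamma = Inf))
  expect_true(all(pr$input == 0))
  expect_true(all(pr$target == 0))
})

test_that("pair differs only by the blurred background when Poisson is off", {
  vol <- tiny_vol()
  pf <- place_particles(vol, c(3, 5), 2, seed = 8)
  bg <- background_params(seed = 8)
  pr <- render_pair(pf, vol, 1, bg, noise_params(poisson_gamma = Inf,
                                                 seed = 8))
  blurred_bg <- apply_psf(0.8 * 255 * upunet:::normalize01(
    perlin_field(vol$n, bg)), 2)
  expect_equal(pr$input - pr$target, blurred_bg, tolerance = 1e-10)
})

test_that("the generated input satisfies the exact relative-noise identity", {
  vol <- tiny_vol()
  pf <- place_particles(vol, c(3, 5), 2, seed = 13)
  bg <- background_params(seed = 13)
  pr <- render_pair(pf, vol, 1, bg, noise_params(poisson_gamma = Inf,
                                                 seed = 13))
  ras <- rasterize_slice(pf, vol, 1)
  blurred <- apply_psf(ras$image + 0.8 * 255 * upunet:::normalize01(
    perlin_field(vol$n, bg)), 2)
  rel <- sqrt(sum((pr$input - blurred)^2)) / sqrt(sum(blurred^2))
  expect_equal(rel, 0.03, tolerance = 1e-10)
})

test_that("truth discs of a pair match rasterize_slice exactly", {
  vol <- tiny_vol()
  pf <- place_particles(vol, c(4, 6), 2, seed = 21)
  pr <- render_pair(pf, vol, 3, background_params(seed = 21),
                    noise_params(seed = 21))
  expect_identical(pr$truth, rasterize_slice(pf, vol, 3)$truth)
})

test_that("split sizes follow the floor rule with remainder to train", {
  s <- split_dataset(500, c(0.9, 0.05, 0.05), seed = 1)
  expect_equal(lengths(s), c(train = 450, val = 25, test = 25))
  expect_setequal(c(s$train, s$val, s$test), 1:500)
  expect_length(intersect(s$train, s$val), 0)
  expect_length(intersect(s$train, s$test), 0)
  s2 <- split_dataset(10, c(1, 0, 0), seed = 1)
  expect_equal(sort(s2$train), 1:10)
})

test_that("dataset generation is a pure function of its spec", {
  spec <- make_fixture("smoke", seed = 77)
  d1 <- generate_dataset(spec)
  d2 <- generate_dataset(spec)
  expect_identical(d1, d2)
  d3 <- generate_dataset(make_fixture("smoke", seed = 78))
  expect_false(identical(d1$pairs[[1]]$input, d3$pairs[[1]]$input))
})

test_that("variable-radius preset bounds counts and profile radii", {
  spec <- make_fixture("radii-0.5-4", seed = 5)
  spec$n_images <- 6L
  spec$split <- c(1, 0, 0)
  # keep runtime small: shrink the frame but preserve the physical setup
  spec$vol <- volume_spec(76, 76, 5, n = 64, nz = 5)
  ds <- generate_dataset(spec)
  for (pr in ds$pairs) {
    expect_lte(nrow(pr$truth), 15)
    if (nrow(pr$truth) > 0)
      expect_true(all(pr$truth$radius_px <= 4 / ds$spec$vol$dx + 1e-9))
  }
})

test_that("study-condition fixtures carry the pinned settings", {
  f128 <- make_fixture("table1-128", seed = 1)
  expect_equal(f128$n_images, 500L)
  expect_equal(f128$vol$n, 128L)
  expect_equal(f128$vol$Dx, 76)
  expect_equal(f128$noise$psf_sigma, 2)
  expect_equal(f128$noise$gaussian_level, 0.03)
  expect_equal(f128$radius_spec, 2)
  expect_equal(f128$count_range, c(10, 15))
  expect_equal(f128$bead_value, 229.5)
  v22 <- make_fixture("volume-22", seed = 1)
  expect_equal(v22$vol$n, 512L)
  expect_equal(v22$vol$nz, 22L)
  expect_equal(v22$vol$Dz, 6)
  expect_error(make_fixture("bogus"), "unknown fixture")
  expect_identical(make_fixture("unit", 3), make_fixture("unit", 3))
})
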