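test_that("particle placement respects counts, bounds and non-intersection", {
  vol <- volume_spec(76, 76, 5, n = 128, nz = 5)
  for (seed in 1:5) {
    pf <- place_particles(vol, c(10, 15), 2, seed = seed)
    expect_gte(pf$count, 10)
    expect_lte(pf$count, 15)
    expect_true(all(pf$centers[, 1] >= 0 & pf$centers[, 1] <= 76))
    expect_true(all(pf$centers[, 2] >= 0 & pf$centers[, 2] <= 76))
    expect_true(all(pf$centers[, 3] >= 0 & pf$centers[, 3] <= 5))
    # exhaustive O(p^2) pairwise check
    for (i in seq_len(pf$count - 1))
      for (j in (i + 1):pf$count)
        expect_gte(sqrt(sum((pf$centers[i, ] - pf$centers[j, ])^2)),
                   pf$radii[i] + pf$radii[j])
  }
})

test_that("zero-count placement yields an empty field without error", {
  pf <- place_particles(tiny_vol(), c(0, 0), 2, seed = 1)
  expect_equal(pf$count, 0)
  expect_equal(nrow(pf$centers), 0)
})

test_that("placement is deterministic in the seed", {
  vol <- tiny_vol()
  expect_identical(place_particles(vol, c(5, 10), 2, seed = 42),
                   place_particles(vol, c(5, 10), 2, seed = 42))
})

test_that("overcrowded volumes raise an explicit error", {
  vol <- volume_spec(10, 10, 10, n = 16, nz = 4)
  expect_error(place_particles(vol, c(50, 50), 4, seed = 1, max_tries = 50),
               "too crowded")
})

test_that("rasterization agrees pixel-for-pixel with the 3D distance oracle", {
  vol <- volume_spec(76, 76, 5, n = 48, nz = 5)
  for (seed in c(2, 9)) {
    pf <- place_particles(vol, c(3, 6), 2, seed = seed)
    for (z in c(0, 2, 4)) {
      got <- rasterize_slice(pf, vol, z)
      expect_identical(got$image, oracle_rasterize(pf, vol, z))
    }
  }
})

test_that("in-plane disc has the analytic profile radius and bead value", {
  vol <- volume_spec(76, 76, 5, n = 128, nz = 5)
  # sphere centred exactly on the plane of slice 2 (z = 2.5 um)
  pf <- structure(list(centers = matrix(c(38, 38, 2.5), 1, 3),
                       radii = 2, count = 1L), class = "particle_field")
  got <- rasterize_slice(pf, vol, 2)
  expect_equal(got$truth$radius_px, 2 / vol$dx, tolerance = 1e-12)
  expect_equal(got$truth$radius_px, 3.368, tolerance = 1e-3)
  expect_true(all(got$image[got$image != 0] == 229.5))
  # measured area consistent with a disc of that radius
  area <- sum(got$image > 0)
  expect_equal(area, pi * (2 / vol$dx)^2, tolerance = 0.15)
})

test_that("off-plane intersection follows the chord-of-sphere formula", {
  vol <- volume_spec(76, 76, 8, n = 64, nz = 8)
  r <- 2
  zc <- 4.5 + r / 2  # half a radius above the plane of slice 4 (z = 4.5)
  pf <- structure(list(centers = matrix(c(38, 38, zc), 1, 3),
                       radii = r, count = 1L), class = "particle_field")
  got <- rasterize_slice(pf, vol, 4)
  expect_equal(got$truth$radius_px, r * sqrt(3) / 2 / vol$dx,
               tolerance = 1e-12)
  expect_identical(got$image, oracle_rasterize(pf, vol, 4))
})

test_that("spheres missing the slice contribute no pixels and no truth", {
  vol <- volume_spec(76, 76, 8, n = 32, nz = 8)
  pf <- structure(list(centers = matrix(c(38, 38, 7.5), 1, 3),
                       radii = 2, count = 1L), class = "particle_field")
  got <- rasterize_slice(pf, vol, 0)  # plane z = 0.5, distance 7 > r
  expect_true(all(got$image == 0))
  expect_equal(nrow(got$truth), 0)
})
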