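test_that("detection on an empty frame returns an empty table", {
  expect_equal(nrow(detect_particles(matrix(0, 64, 64))), 0)
})

test_that("a clean disc is recovered with sub-pixel centre and radius", {
  frame <- make_disc_frame(128, cx = 40, cy = 60, r = 5)
  det <- detect_particles(frame)
  expect_equal(nrow(det), 1)
  expect_lt(abs(det$cx - 40), 0.5)
  expect_lt(abs(det$cy - 60), 0.5)
  expect_lt(abs(det$radius - 5), 0.5)
  expect_equal(det$score, 229.5)
})

test_that("well-separated discs give one detection each", {
  frame <- make_disc_frame(128, 30, 30, 4) + make_disc_frame(128, 70, 30, 4)
  det <- detect_particles(frame)
  expect_equal(nrow(det), 2)
})

test_that("sub-threshold and sub-area components are discarded", {
  frame <- matrix(0, 64, 64)
  frame[10, 10] <- 200  # single pixel: below min_area = 4
  frame[30:33, 30:33] <- 50  # below default threshold 76.5
  expect_equal(nrow(detect_particles(frame)), 0)
  expect_equal(nrow(detect_particles(frame, threshold = 40)), 1)
})

test_that("perfect detections all match and produce no false positives", {
  truth <- data.frame(id = 1:3, cx_px = c(10, 40, 90),
                      cy_px = c(15, 45, 95), radius_px = 3, z_um = 1)
  det <- data.frame(cx = truth$cx_px, cy = truth$cy_px, radius = 3,
                    score = 200)
  m <- match_detections(det, truth)
  expect_equal(nrow(m$matches), 3)
  expect_length(m$false_det, 0)
  expect_length(m$missed, 0)
})

test_that("an equidistant detection matches the lowest-index truth", {
  truth <- data.frame(id = 1:2, cx_px = c(10, 14), cy_px = c(10, 10),
                      radius_px = 2, z_um = 1)
  det <- data.frame(cx = 12, cy = 10, radius = 2, score = 200)
  m <- match_detections(det, truth, d_match = 5)
  expect_equal(nrow(m$matches), 1)
  expect_equal(m$matches$truth, 1)
  expect_equal(m$missed, 2)
})

test_that("greedy matching attains the optimal matched count (<= 6 particles)", {
  set.seed(314)
  for (trial in 1:40) {
    nt <- sample(0:6, 1)
    nd <- sample(0:6, 1)
    truth <- data.frame(id = seq_len(nt),
                        cx_px = runif(nt, 0, 30), cy_px = runif(nt, 0, 30),
                        radius_px = rep(2, nt), z_um = rep(1, nt))
    det <- data.frame(cx = runif(nd, 0, 30), cy = runif(nd, 0, 30),
                      radius = rep(2, nd), score = rep(1, nd))
    m <- match_detections(det, truth, d_match = 6)
    expect_equal(nrow(m$matches), oracle_max_matching(det, truth, 6),
                 label = sprintf("trial %d", trial))
    # conservation identities
    expect_equal(nrow(m$matches) + length(m$false_det), nd)
    expect_equal(nrow(m$matches) + length(m$missed), nt)
  }
})

test_that("TPR and phi arithmetic follow their definitions", {
  expect_equal(compute_tpr(10, 10), 1)
  expect_equal(compute_tpr(9, 10), 0.9)
  expect_true(is.na(compute_tpr(0, 0)))
  expect_equal(compute_phi(rep(0, 5)), 0)
  expect_equal(compute_phi(c(rep(0, 99), 10)), 0.1)
  expect_equal(compute_phi(3), 3)
  expect_error(compute_phi(numeric(0)), "undefined")
})

test_that("an oracle restorer on clean high-contrast scenes attains TPR 1, phi 0", {
  # crisp, well-separated discs well above threshold and min_area
  set.seed(7)
  pairs <- lapply(1:4, function(s) {
    centres <- cbind(c(25, 70, 100), c(30, 90, 50)) + runif(6, -3, 3)
    frame <- Reduce(`+`, lapply(1:3, function(k)
      make_disc_frame(128, centres[k, 1], centres[k, 2], r = 6)))
    structure(list(input = frame, target = frame,
                   truth = data.frame(id = 1:3, cx_px = centres[, 1],
                                      cy_px = centres[, 2],
                                      radius_px = rep(6, 3),
                                      z_um = rep(1, 3)),
                   slice_index = 0L, seeds = list()),
              class = "frame_pair")
  })
  rep <- evaluate_restorations(function(f) f, pairs)
  expect_equal(rep$tpr, 1)
  expect_equal(rep$phi, 0)
})

test_that("per-frame identities hold in evaluation reports", {
  vol <- tiny_vol()
  pairs <- lapply(1:4, function(s) {
    pf <- place_particles(vol, c(3, 6), 2, seed = 200 + s)
    render_pair(pf, vol, 1, background_params(seed = s),
                noise_params(seed = s))
  })
  rep <- evaluate_restorations(function(f) f, pairs)
  with(rep$per_frame, {
    expect_true(all(matched_n + false_n == detected_n))
    expect_true(all(matched_n <= truth_n))
  })
  expect_gte(rep$phi, 0)
})

test_that("3D reconstruction recovers a single synthetic sphere within a voxel", {
  vol <- volume_spec(32, 32, 4, n = 64, nz = 8)
  pf <- structure(list(centers = matrix(c(16, 12, 2.1), 1, 3),
                       radii = 1.5, count = 1L), class = "particle_field")
  stack <- lapply(0:(vol$nz - 1), function(z)
    rasterize_slice(pf, vol, z)$image)
  est <- reconstruct_volume_3d(function(f) f, stack, vol)
  expect_equal(nrow(est), 1)
  # truth in voxel units
  tx <- 16 / vol$dx - 0.5
  ty <- 12 / vol$dy - 0.5
  tz <- 2.1 / vol$dz - 0.5
  expect_lt(abs(est$cx - tx), 1)
  expect_lt(abs(est$cy - ty), 1)
  expect_lt(abs(est$cz - tz), 1)
  expect_gt(est$n_slices, 1)
})

test_that("empty stacks yield no 3D estimates and far spheres two clusters", {
  vol <- volume_spec(32, 32, 4, n = 64, nz = 6)
  zero_stack <- replicate(6, matrix(0, 64, 64), simplify = FALSE)
  expect_equal(nrow(reconstruct_volume_3d(function(f) f, zero_stack, vol)),
               0)
  pf <- structure(list(centers = rbind(c(8, 8, 2), c(24, 24, 2)),
                       radii = c(1.5, 1.5), count = 2L),
                  class = "particle_field")
  stack <- lapply(0:5, function(z) rasterize_slice(pf, vol, z)$image)
  est <- reconstruct_volume_3d(function(f) f, stack, vol)
  expect_equal(nrow(est), 2)
})
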