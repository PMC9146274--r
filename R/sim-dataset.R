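#' Synthetic dataset specification
#'
#' Bundles every parameter of the frame simulator: volume geometry,
#' particle statistics, background-emission field, blur/noise model and
#' the train/validation/test split.
#'
#' @param n_images number of frame pairs to generate (default 500).
#' @param split train/validation/test fractions summing to 1
#'   (default 0.90/0.05/0.05).
#' @param count_range inclusive range of particles per volume
#'   (default `c(10, 15)`).
#' @param radius_spec bead radius in micrometres, fixed or a range
#'   (default 2).
#' @param bead_value voxel intensity inside a bead (default 229.5, 90% of
#'   the 8-bit maximum).
#' @param vol a [volume_spec()].
#' @param bg a [background_params()] template (its seed is re-derived per
#'   image).
#' @param noise a [noise_params()] template (its seed is re-derived per
#'   image).
#' @param seed master seed; the full dataset is a pure function of this
#'   spec.
#' @return An object of class `dataset_spec`.
#' @export
dataset_spec <- function(n_images = 500, split = c(0.90, 0.05, 0.05),
                         count_range = c(10, 15), radius_spec = 2,
                         bead_value = 229.5,
                         vol = volume_spec(76, 76, 5, n = 128, nz = 5),
                         bg = background_params(),
                         noise = noise_params(), seed = 1) {
  stopifnot(n_images >= 1, length(split) == 3,
            abs(sum(split) - 1) < 1e-9, all(split >= 0),
            bead_value > 0, bead_value <= 255)
  structure(list(n_images = as.integer(n_images), split = split,
                 count_range = count_range, radius_spec = radius_spec,
                 bead_value = bead_value, vol = vol, bg = bg, noise = noise,
                 seed = as.integer(seed)),
            class = "dataset_spec")
}

#' Render one corrupted/clean frame pair
#'
#' Implements the forward model: the rasterised bead slice plus the
#' intensity-scaled background field is blurred by the Gaussian PSF and
#' corrupted by Frobenius-calibrated Gaussian read noise and Poisson shot
#' noise (in the order given by `noise$noise_order`).  The target frame
#' runs the identical pipeline with the background disabled and the SAME
#' statistical-noise realisation, so a pair differs only by the
#' background contribution: the restoration task is to remove the
#' background while leaving signal and statistical noise intact.
#'
#' @param field a [place_particles()] result.
#' @param vol the [volume_spec()].
#' @param z_index 0-based slice index.
#' @param bg [background_params()]; `bg$beta` scales the per-frame
#'   min-max-normalised Perlin field before blurring.
#' @param noise [noise_params()].
#' @param bead_value in-bead voxel intensity.
#' @return An object of class `frame_pair`: `input`, `target` (matrices,
#'   `[0, 255]` scale), `truth` (data frame), `slice_index`, `seeds`.
#' @export
render_pair <- function(field, vol, z_index, bg = background_params(),
                        noise = noise_params(), bead_value = 229.5) {
  ras <- rasterize_slice(field, vol, z_index, bead_value)
  background <- if (bg$beta > 0)
    bg$beta * normalize01(perlin_field(vol$n, bg)) else matrix(0, vol$n, vol$n)
  blur_in <- apply_psf(ras$image + background, noise$psf_sigma)
  blur_tg <- if (bg$beta > 0) apply_psf(ras$image, noise$psf_sigma) else blur_in

  seed_g <- derive_seed(noise$seed, 1L)
  seed_p <- derive_seed(noise$seed, 2L)
  apply_noise <- function(img, noise_arr = NULL) {
    # returns list(frame, noise): noise_arr reuses a realisation
    if (is.null(noise_arr)) {
      gn <- add_gaussian_noise(img, noise$gaussian_level, seed_g)
    } else {
      gn <- list(frame = img + noise_arr, noise = noise_arr)
    }
    gn
  }
  if (noise$noise_order == "gaussian_then_poisson") {
    gin <- apply_noise(blur_in)
    gtg <- apply_noise(blur_tg, gin$noise)
    input <- add_poisson_noise(gin$frame, noise$poisson_gamma, seed_p)
    target <- add_poisson_noise(gtg$frame, noise$poisson_gamma, seed_p)
  } else {
    pin <- add_poisson_noise(blur_in, noise$poisson_gamma, seed_p)
    ptg <- add_poisson_noise(blur_tg, noise$poisson_gamma, seed_p)
    gin <- apply_noise(pin)
    input <- gin$frame
    target <- ptg + gin$noise
  }
  structure(list(input = input, target = target, truth = ras$truth,
                 slice_index = as.integer(z_index),
                 seeds = list(gaussian = seed_g, poisson = seed_p,
                              background = bg$seed)),
            class = "frame_pair")
}

#' @export
print.frame_pair <- function(x, ...) {
  cat(sprintf("Frame pair %dx%d, slice %d, %d truth disc(s)\n",
              nrow(x$input), ncol(x$input), x$slice_index, nrow(x$truth)))
  invisible(x)
}

#' Split indices into train/validation/test
#'
#' Seeded permutation split: validation and test receive
#' `floor(fraction * n)` items each, the remainder goes to training; the
#' three index sets are disjoint and exhaustive.
#'
#' @param n number of items (or a list whose length is used).
#' @param fractions length-3 fractions summing to 1.
#' @param seed RNG seed for the permutation.
#' @return list with integer index vectors `train`, `val`, `test`.
#' @export
split_dataset <- function(n, fractions = c(0.9, 0.05, 0.05), seed = 1) {
  if (!is.numeric(n) || length(n) > 1) n <- length(n)
  stopifnot(length(fractions) == 3, abs(sum(fractions) - 1) < 1e-9)
  n_val <- floor(fractions[2] * n)
  n_test <- floor(fractions[3] * n)
  n_train <- n - n_val - n_test
  if (fractions[1] > 0 && n_train == 0) stop("training split is empty")
  perm <- with_seed(seed, sample.int(n))
  list(train = sort(perm[seq_len(n_train)]),
       val = sort(perm[n_train + seq_len(n_val)]),
       test = sort(perm[n_train + n_val + seq_len(n_test)]))
}

#' Generate a full synthetic dataset
#'
#' Draws `spec$n_images` independent scenes (each with its own seeded
#' particle placement, uniformly random slice index, background field and
#' noise realisation), renders the frame pairs and splits them.  The
#' result is a pure function of `spec`.
#'
#' @param spec a [dataset_spec()].
#' @param progress print a dot every 50 images.
#' @return An object of class `bead_dataset`: `pairs` (list of
#'   `frame_pair`), `split` (index sets), `spec`.
#' @export
generate_dataset <- function(spec, progress = FALSE) {
  stopifnot(inherits(spec, "dataset_spec"))
  pairs <- vector("list", spec$n_images)
  for (i in seq_len(spec$n_images)) {
    s <- derive_seed(spec$seed, i * 10L)
    field <- place_particles(spec$vol, spec$count_range, spec$radius_spec,
                             seed = derive_seed(s, 1L))
    z_index <- with_seed(derive_seed(s, 2L),
                         sample.int(spec$vol$nz, 1) - 1L)
    bg_i <- spec$bg; bg_i$seed <- derive_seed(s, 3L)
    noise_i <- spec$noise; noise_i$seed <- derive_seed(s, 4L)
    pairs[[i]] <- render_pair(field, spec$vol, z_index, bg_i, noise_i,
                              spec$bead_value)
    pairs[[i]]$id <- i
    if (progress && i %% 50 == 0) cat(".")
  }
  if (progress) cat("\n")
  split <- split_dataset(spec$n_images, spec$split,
                         seed = derive_seed(spec$seed, 999983L))
  structure(list(pairs = pairs, split = split, spec = spec),
            class = "bead_dataset")
}

#' @export
print.bead_dataset <- function(x, ...) {
  cat(sprintf("Synthetic bead dataset: %d pairs (%d/%d/%d train/val/test), %dx%d px\n",
              length(x$pairs), length(x$split$train), length(x$split$val),
              length(x$split$test), x$spec$vol$n, x$spec$vol$n))
  invisible(x)
}

#' Named study-condition fixtures
#'
#' Returns ready-made [dataset_spec()]s for the study conditions:
#' `unit` and `smoke` are miniature 64x64 configurations for fast checks;
#' `table1-128`, `table1-256` and `table1-512` are the full 500-image
#' training conditions at the three frame sizes (76x76x5 um volume,
#' 10-15 beads of radius 2 um, PSF sigma 2, sigma_n 0.03);
#' `radii-0.5-4` uses 0-15 beads with radii drawn from `[0.5, 4]` um at
#' 256x256; `volume-22` is the 3D reconstruction scenario: a
#' 76x76x6 um volume discretised into 512x512x22 voxels.
#'
#' @param kind one of `"unit"`, `"smoke"`, `"table1-128"`, `"table1-256"`,
#'   `"table1-512"`, `"radii-0.5-4"`, `"volume-22"`.
#' @param seed master seed.
#' @return A [dataset_spec()].
#' @export
make_fixture <- function(kind, seed = 1) {
  switch(kind,
    "unit" = dataset_spec(n_images = 4, split = c(0.5, 0.25, 0.25),
                          count_range = c(2, 4),
                          vol = volume_spec(76, 76, 5, n = 64, nz = 5),
                          seed = seed),
    "smoke" = dataset_spec(n_images = 8, split = c(0.75, 0.125, 0.125),
                           count_range = c(3, 6),
                           vol = volume_spec(76, 76, 5, n = 64, nz = 5),
                           seed = seed),
    "table1-128" = dataset_spec(vol = volume_spec(76, 76, 5, n = 128, nz = 5),
                                seed = seed),
    "table1-256" = dataset_spec(vol = volume_spec(76, 76, 5, n = 256, nz = 5),
                                seed = seed),
    "table1-512" = dataset_spec(vol = volume_spec(76, 76, 5, n = 512, nz = 5),
                                seed = seed),
    "radii-0.5-4" = dataset_spec(count_range = c(0, 15),
                                 radius_spec = c(0.5, 4),
                                 vol = volume_spec(76, 76, 5, n = 256, nz = 5),
                                 seed = seed),
    "volume-22" = dataset_spec(n_images = 1,
                               vol = volume_spec(76, 76, 6, n = 512, nz = 22),
                               seed = seed),
    stop("unknown fixture kind: ", kind)
  )
}
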