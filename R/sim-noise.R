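#' Optical blur and statistical-noise parameters
#'
#' @param psf_sigma standard deviation (pixels) of the Gaussian
#'   point-spread function (default 2).
#' @param gaussian_level relative Gaussian noise level `sigma_n`: the
#'   Frobenius norm of the added read noise is `sigma_n` times the
#'   Frobenius norm of the clean frame (default 0.03).
#' @param poisson_gamma photons per intensity unit for the shot-noise
#'   model; `Inf` disables Poisson noise (default 1 on the `[0, 255]`
#'   scale).
#' @param noise_order `"gaussian_then_poisson"` (default, the procedural
#'   order) or `"poisson_then_gaussian"`.
#' @param seed RNG seed for the statistical noise.
#' @return An object of class `noise_params`.
#' @export
noise_params <- function(psf_sigma = 2, gaussian_level = 0.03,
                         poisson_gamma = 1,
                         noise_order = c("gaussian_then_poisson",
                                         "poisson_then_gaussian"),
                         seed = 1) {
  noise_order <- match.arg(noise_order)
  stopifnot(psf_sigma > 0, gaussian_level >= 0, poisson_gamma > 0)
  structure(list(psf_sigma = psf_sigma, gaussian_level = gaussian_level,
                 poisson_gamma = poisson_gamma, noise_order = noise_order,
                 seed = as.integer(seed)),
            class = "noise_params")
}

# normalized 1D Gaussian taps, truncation radius ceiling(4*sigma)
.gauss_taps <- function(sigma) {
  r <- ceiling(4 * sigma)
  w <- exp(-(-r:r)^2 / (2 * sigma^2))
  w / sum(w)
}

# 1D correlation along rows with edge-excluding mirror boundary
.blur_rows <- function(img, taps) {
  r <- (length(taps) - 1) / 2
  n <- nrow(img)
  idx <- seq_len(n + 2 * r) - r - 1  # 0-based padded indices
  idx <- vapply(idx, function(i) {
    while (i < 0 || i >= n) {
      if (i < 0) i <- -i
      if (i >= n) i <- 2 * n - 2 - i
    }
    i
  }, numeric(1)) + 1
  padded <- img[idx, , drop = FALSE]
  out <- matrix(0, n, ncol(img))
  for (k in seq_along(taps))
    out <- out + taps[k] * padded[k:(k + n - 1), , drop = FALSE]
  out
}

#' Gaussian point-spread-function blur
#'
#' Convolves a frame with a unit-sum discrete Gaussian kernel (separable,
#' truncation radius `ceiling(4*sigma)`), using mirror boundary handling
#' that does not duplicate the edge pixel.  A constant frame is returned
#' unchanged and the total intensity of an interior impulse is preserved.
#'
#' @param img numeric matrix.
#' @param sigma Gaussian standard deviation in pixels.
#' @return Blurred matrix of the same shape.
#' @export
apply_psf <- function(img, sigma) {
  stopifnot(is.matrix(img), sigma > 0)
  if (min(dim(img)) < 2) stop("frame too small to blur")
  taps <- .gauss_taps(sigma)
  t(.blur_rows(t(.blur_rows(img, taps)), taps))
}

#' Add Frobenius-calibrated Gaussian read noise
#'
#' Draws a standard-normal array `eta` of the frame's shape and returns
#' `g + sigma_n * eta / ||eta||_F * ||g||_F`, so the relative noise level
#' `||g_n - g||_F / ||g||_F` equals `sigma_n` exactly.  The output is not
#' clipped.  An all-zero frame is returned unchanged with a warning.
#'
#' @param g numeric matrix (the clean frame).
#' @param sigma_n relative noise level (>= 0).
#' @param seed RNG seed.
#' @return list with `frame` (the noisy frame) and `noise` (the realised
#'   absolute noise array, needed to share one noise realisation between
#'   the corrupted input and its background-free target).
#' @export
add_gaussian_noise <- function(g, sigma_n = 0.03, seed = 1) {
  stopifnot(is.matrix(g), sigma_n >= 0)
  if (sigma_n == 0) return(list(frame = g, noise = g * 0))
  ng <- frobenius(g)
  if (ng == 0) {
    warning("zero-norm frame: Gaussian noise level is undefined, returning unchanged")
    return(list(frame = g, noise = g * 0))
  }
  eta <- with_seed(seed, matrix(rnorm(length(g)), nrow(g), ncol(g)))
  noise <- sigma_n * eta / frobenius(eta) * ng
  list(frame = g + noise, noise = noise)
}

#' Add Poisson shot noise
#'
#' Each pixel value `v` is replaced by `Poisson(gamma * v) / gamma`,
#' modelling photon counting with `gamma` photons per intensity unit.
#' Negative inputs (possible after unclipped Gaussian noise) are clamped
#' to zero first.  `gamma = Inf` returns the frame unchanged.
#'
#' @param g numeric matrix, interpreted on the `[0, 255]` scale.
#' @param gamma photons per intensity unit (> 0, possibly `Inf`).
#' @param seed RNG seed.
#' @return The noisy matrix.
#' @export
add_poisson_noise <- function(g, gamma = 1, seed = 1) {
  stopifnot(is.matrix(g), gamma > 0)
  if (!is.finite(gamma)) return(g)
  neg <- g < 0
  if (any(neg)) g[neg] <- 0
  out <- with_seed(seed, rpois(length(g), gamma * g) / gamma)
  matrix(out, nrow(g), ncol(g))
}
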