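#' Background-emission parameters
#'
#' Parameters of the multi-octave Perlin gradient-noise field used to
#' emulate diffuse background emission (auto-fluorescence, reflections,
#' medium diffraction).  Octave `k` (1-based) samples the lattice at
#' frequency `base_frequency * 2^(k-1)` with amplitude
#' `base_amplitude * persistence^(k-1)`.
#'
#' @param octaves number of octaves (default 8).
#' @param base_frequency lattice frequency of the first octave (default 1).
#' @param base_amplitude amplitude of the first octave (default 1).
#' @param persistence per-octave amplitude multiplier in (0, 1] (default 0.5).
#' @param beta peak background intensity on the `[0, 255]` scale after
#'   per-frame min-max normalisation (default `0.8 * 255`); `beta = 0`
#'   disables the background.
#' @param seed RNG seed for the gradient hash.
#' @return An object of class `background_params`.
#' @export
background_params <- function(octaves = 8, base_frequency = 1,
                              base_amplitude = 1, persistence = 0.5,
                              beta = 0.8 * 255, seed = 1) {
  stopifnot(octaves >= 1, persistence > 0, persistence <= 1, beta >= 0,
            base_frequency > 0, base_amplitude >= 0)
  structure(list(octaves = as.integer(octaves),
                 base_frequency = base_frequency,
                 base_amplitude = base_amplitude, persistence = persistence,
                 beta = beta, seed = as.integer(seed)),
            class = "background_params")
}

# hashed unit gradients: 8 directions at multiples of 45 degrees
.perlin_grads <- {
  ang <- (0:7) * pi / 4
  cbind(cos(ang), sin(ang))
}

# improved Perlin gradient noise evaluated at arbitrary coordinates,
# with a permutation table drawn from `seed`
.perlin_eval <- function(xs, ys, seed) {
  perm <- with_seed(seed, sample(0L:255L))
  hash2 <- function(xi, yi) {
    # double hash through the permutation table
    perm[(perm[(xi %% 256L) + 1L] + (yi %% 256L)) %% 256L + 1L]
  }
  x0 <- floor(xs); y0 <- floor(ys)
  tx <- xs - x0; ty <- ys - y0
  fade <- function(t) t * t * t * (t * (t * 6 - 15) + 10)
  u <- fade(tx); v <- fade(ty)
  corner <- function(ox, oy) {
    h <- hash2(as.integer(x0) + ox, as.integer(y0) + oy) %% 8L + 1L
    g <- .perlin_grads[h, , drop = FALSE]
    g[, 1] * (tx - ox) + g[, 2] * (ty - oy)
  }
  n00 <- corner(0L, 0L); n10 <- corner(1L, 0L)
  n01 <- corner(0L, 1L); n11 <- corner(1L, 1L)
  nx0 <- n00 + u * (n10 - n00)
  nx1 <- n01 + u * (n11 - n01)
  nx0 + v * (nx1 - nx0)
}

#' Multi-octave Perlin gradient-noise field
#'
#' Generates the raw (unscaled) background field: a sum of improved
#' Perlin gradient noise octaves.  Pixel `(i, j)` (0-based row = y,
#' column = x) of octave `k` samples lattice coordinates
#' `(j, i) / shape * base_frequency * 2^(k-1)`, so the first octave spans
#' `base_frequency` lattice cells across the frame and each further
#' octave doubles the spatial frequency while multiplying the amplitude
#' by `persistence`.  Interpolation uses the quintic fade
#' `6t^5 - 15t^4 + 10t^3`; gradients are hashed unit vectors, so each
#' octave is bounded by `sqrt(2)/2` times its amplitude.
#'
#' @param shape frame side length(s) in pixels; length 1 (square) or 2
#'   (rows, cols).
#' @param bg a [background_params()] object.
#' @return A numeric matrix of the requested shape (zero-mean-ish raw
#'   field, not yet intensity-scaled).
#' @examples
#' f <- perlin_field(64, background_params(seed = 7))
#' identical(f, perlin_field(64, background_params(seed = 7)))
#' @export
perlin_field <- function(shape, bg = background_params()) {
  stopifnot(all(shape >= 1))
  if (length(shape) == 1) shape <- c(shape, shape)
  H <- as.integer(shape[1]); W <- as.integer(shape[2])
  out <- matrix(0, H, W)
  xs0 <- (rep(seq_len(W), each = H) - 1)   # column index = x
  ys0 <- (rep(seq_len(H), times = W) - 1)  # row index = y
  for (k in seq_len(bg$octaves)) {
    freq <- bg$base_frequency * 2^(k - 1)
    amp <- bg$base_amplitude * bg$persistence^(k - 1)
    vals <- .perlin_eval(xs0 / W * freq, ys0 / H * freq,
                         derive_seed(bg$seed, k))
    out <- out + amp * matrix(vals, H, W)
  }
  out
}

# per-frame min-max normalisation to [0, 1]; constant fields map to 0
normalize01 <- function(x) {
  rng <- range(x)
  if (rng[2] - rng[1] < .Machine$double.eps) return(x * 0)
  (x - rng[1]) / (rng[2] - rng[1])
}
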