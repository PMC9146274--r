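#' Imaging volume geometry
#'
#' Describes the continuous imaging volume and its voxel discretisation.
#' Frames are square (`n` by `n` pixels laterally); the axial direction is
#' discretised into `nz` slices.  Voxel pitches are derived as
#' `dx = Dx/n`, `dy = Dy/n`, `dz = Dz/nz` (micrometres per voxel).
#'
#' @param Dx,Dy,Dz physical extent of the volume in micrometres.
#' @param n lateral voxel count per axis (frame side length in pixels).
#' @param nz number of axial slices.
#' @return An object of class `volume_spec`.
#' @examples
#' vol <- volume_spec(76, 76, 5, n = 128, nz = 5)
#' vol$dx * vol$n == vol$Dx
#' @export
volume_spec <- function(Dx = 76, Dy = 76, Dz = 5, n = 128, nz = 5) {
  stopifnot(Dx > 0, Dy > 0, Dz > 0, n >= 1, nz >= 1)
  structure(list(Dx = Dx, Dy = Dy, Dz = Dz, n = as.integer(n),
                 nz = as.integer(nz), dx = Dx / n, dy = Dy / n, dz = Dz / nz),
            class = "volume_spec")
}

#' @export
print.volume_spec <- function(x, ...) {
  cat(sprintf("Imaging volume: %g x %g x %g um, %d x %d x %d voxels (dx=%.4g, dy=%.4g, dz=%.4g um)\n",
              x$Dx, x$Dy, x$Dz, x$n, x$n, x$nz, x$dx, x$dy, x$dz))
  invisible(x)
}

#' Randomly place non-intersecting spherical beads in a volume
#'
#' Bead centres are drawn uniformly over the full volume; a candidate is
#' rejected and redrawn whenever its sphere would intersect an already
#' accepted one (centre distance below the sum of radii; touching is
#' allowed).  Spheres may protrude past the volume boundary, mirroring a
#' real suspension imaged through a finite window.
#'
#' @param vol a [volume_spec()].
#' @param count_range integer vector of length 1 or 2: the particle count,
#'   or an inclusive range from which the count is drawn uniformly.
#' @param radius_spec bead radius in micrometres: a single value, or a
#'   length-2 range from which each particle's radius is drawn uniformly.
#' @param seed RNG seed.
#' @param max_tries rejection-sampling cap per particle before a
#'   "volume too crowded" error is raised.
#' @return An object of class `particle_field` with elements `centers`
#'   (p x 3 matrix, micrometres), `radii` (length p) and `count`.
#' @examples
#' vol <- volume_spec(76, 76, 5, n = 128, nz = 5)
#' pf <- place_particles(vol, c(10, 15), 2, seed = 1)
#' pf$count
#' @export
place_particles <- function(vol, count_range = c(10, 15), radius_spec = 2,
                            seed = 1, max_tries = 10000) {
  stopifnot(inherits(vol, "volume_spec"), all(count_range >= 0),
            all(radius_spec > 0))
  if (length(count_range) == 1) count_range <- rep(count_range, 2)
  if (max(radius_spec) * 2 > min(vol$Dx, vol$Dy))
    stop("bead radius too large for the lateral extent of the volume")
  with_seed(seed, {
    p <- if (count_range[1] == count_range[2]) count_range[1] else
      sample(count_range[1]:count_range[2], 1)
    centers <- matrix(numeric(0), 0, 3,
                      dimnames = list(NULL, c("x", "y", "z")))
    radii <- numeric(0)
    if (p > 0) {
      for (i in seq_len(p)) {
        r <- if (length(radius_spec) == 1) radius_spec else
          runif(1, radius_spec[1], radius_spec[2])
        ok <- FALSE
        for (try in seq_len(max_tries)) {
          cand <- c(runif(1, 0, vol$Dx), runif(1, 0, vol$Dy),
                    runif(1, 0, vol$Dz))
          if (nrow(centers) == 0 ||
              all(sqrt(colSums((t(centers) - cand)^2)) >= radii + r)) {
            ok <- TRUE
            break
          }
        }
        if (!ok) stop("volume too crowded: could not place particle ", i,
                      " after ", max_tries, " tries")
        centers <- rbind(centers, cand)
        radii <- c(radii, r)
      }
    }
    rownames(centers) <- NULL
    structure(list(centers = centers, radii = radii, count = p),
              class = "particle_field")
  })
}

#' @export
print.particle_field <- function(x, ...) {
  cat(sprintf("Particle field: %d bead(s)", x$count))
  if (x$count > 0)
    cat(sprintf(", radius %s um", paste(signif(range(x$radii), 3),
                                        collapse = "-")))
  cat("\n")
  invisible(x)
}

#' Rasterise one horizontal slice of a particle field
#'
#' Every pixel whose centre point lies strictly within distance `r` of a
#' bead centre is set to `bead_value`; all other pixels are 0.  Pixel
#' centres sit at `(i + 0.5) * dx` for 0-based index `i`; rows index y and
#' columns index x.  The returned ground truth lists each bead whose
#' sphere cuts the slice plane with an observable circular profile
#' (analytic profile radius `sqrt(r^2 - (zc - zslice)^2) / dx` of at least
#' `min_profile_px` pixels).
#'
#' @param field a [place_particles()] result.
#' @param vol the [volume_spec()] used to discretise.
#' @param z_index 0-based slice index in `0:(nz - 1)`.
#' @param bead_value intensity given to in-bead voxels (default 229.5,
#'   90% of the 8-bit maximum 255).
#' @param min_profile_px smallest profile radius (pixels) recorded as
#'   ground truth; sub-half-pixel intersections are unobservable.
#' @return list with `image` (n x n matrix) and `truth` (data frame with
#'   columns `id`, `cx_px`, `cy_px`, `radius_px`, `z_um`).
#' @export
rasterize_slice <- function(field, vol, z_index, bead_value = 229.5,
                            min_profile_px = 0.5) {
  stopifnot(inherits(field, "particle_field"), inherits(vol, "volume_spec"),
            z_index >= 0, z_index < vol$nz)
  n <- vol$n
  img <- matrix(0, n, n)
  z_slice <- (z_index + 0.5) * vol$dz
  truth <- data.frame(id = integer(0), cx_px = numeric(0), cy_px = numeric(0),
                      radius_px = numeric(0), z_um = numeric(0))
  if (field$count == 0) return(list(image = img, truth = truth))
  px <- (seq_len(n) - 0.5) * vol$dx  # pixel-centre x for 0-based col index
  py <- (seq_len(n) - 0.5) * vol$dy
  for (i in seq_len(field$count)) {
    ctr <- field$centers[i, ]
    r <- field$radii[i]
    h <- abs(ctr[3] - z_slice)
    if (h >= r) next
    rp_um <- sqrt(r^2 - h^2)
    # rows = y, cols = x
    d2 <- outer((py - ctr[2])^2, (px - ctr[1])^2, `+`)
    img[d2 < rp_um^2] <- bead_value
    rp_px <- rp_um / vol$dx
    if (rp_px >= min_profile_px)
      truth <- rbind(truth, data.frame(
        id = i, cx_px = ctr[1] / vol$dx - 0.5, cy_px = ctr[2] / vol$dy - 0.5,
        radius_px = rp_px, z_um = ctr[3]))
  }
  rownames(truth) <- NULL
  list(image = img, truth = truth)
}
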