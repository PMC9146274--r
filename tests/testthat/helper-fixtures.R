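# shared miniature fixtures, built in code at test time

tiny_vol <- function(n = 64) volume_spec(76, 76, 5, n = n, nz = 5)

# brute-force 3D-distance rasterizer used as the oracle for
# rasterize_slice: checks every pixel centre against every sphere
oracle_rasterize <- function(field, vol, z_index, bead_value = 229.5) {
  n <- vol$n
  img <- matrix(0, n, n)
  z <- (z_index + 0.5) * vol$dz
  for (i in seq_len(n)) {       # row = y
    for (j in seq_len(n)) {     # col = x
      px <- (j - 0.5) * vol$dx
      py <- (i - 0.5) * vol$dy
      for (k in seq_len(field$count)) {
        d <- sqrt(sum((c(px, py, z) - field$centers[k, ])^2))
        if (d < field$radii[k]) img[i, j] <- bead_value
      }
    }
  }
  img
}

# exhaustive optimal assignment: maximum number of detection-truth
# pairs within d_match, by brute force over all injections
oracle_max_matching <- function(det, truth, d_match) {
  nd <- nrow(det); nt <- nrow(truth)
  if (nd == 0 || nt == 0) return(0)
  dmat <- sqrt(outer(det$cx, truth$cx_px, `-`)^2 +
               outer(det$cy, truth$cy_px, `-`)^2)
  ok <- dmat <= d_match
  best <- 0
  k <- min(nd, nt)
  # recursively try all assignments of detections to truths
  recurse <- function(di, used, count) {
    best <<- max(best, count)
    if (di > nd || count + (nd - di + 1) <= best) return()
    recurse(di + 1, used, count)  # leave detection di unmatched
    for (tj in seq_len(nt)) {
      if (!used[tj] && ok[di, tj]) {
        used[tj] <- TRUE
        recurse(di + 1, used, count + 1)
        used[tj] <- FALSE
      }
    }
  }
  recurse(1, logical(nt), 0)
  best
}

make_disc_frame <- function(n = 128, cx = 40, cy = 60, r = 5,
                            value = 229.5) {
  # 0-based centre coordinates (cx = column/x, cy = row/y)
  d2 <- outer(((seq_len(n) - 1) - cy)^2, ((seq_len(n) - 1) - cx)^2, `+`)
  m <- matrix(0, n, n)
  m[d2 < r^2] <- value
  m
}

derive_seed_for_test <- function(seed, k) upunet:::derive_seed(seed, k)
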