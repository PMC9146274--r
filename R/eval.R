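#' Detect bead profiles in a restored frame
#'
#' Simple threshold detector: the frame is binarised at `threshold`,
#' 8-connected components smaller than `min_area` pixels are discarded,
#' and each surviving component is reported with its intensity-weighted
#' centroid (0-based pixel coordinates), equivalent radius
#' `sqrt(area / pi)` and mean intensity.
#'
#' @param frame non-negative numeric matrix (rows = y, cols = x).
#' @param threshold binarisation level (default `0.3 * 255` on the
#'   restored `[0, 255]` scale).
#' @param min_area minimum component area in pixels (default 4).
#' @return Data frame with columns `cx`, `cy` (0-based, sub-pixel),
#'   `radius`, `score`, `area`.
#' @export
detect_particles <- function(frame, threshold = 0.3 * 255, min_area = 4) {
  stopifnot(is.matrix(frame))
  lab <- .label8_cpp(frame > threshold)
  k <- max(lab)
  empty <- data.frame(cx = numeric(0), cy = numeric(0), radius = numeric(0),
                      score = numeric(0), area = integer(0))
  if (k == 0) return(empty)
  keep <- which(tabulate(lab[lab > 0], k) >= min_area)
  if (length(keep) == 0) return(empty)
  rows <- row(frame) - 1  # y
  cols <- col(frame) - 1  # x
  out <- lapply(keep, function(l) {
    sel <- lab == l
    w <- frame[sel]
    data.frame(cx = sum(cols[sel] * w) / sum(w),
               cy = sum(rows[sel] * w) / sum(w),
               radius = sqrt(sum(sel) / pi),
               score = mean(w), area = sum(sel))
  })
  out <- do.call(rbind, out)
  out[order(out$cx, out$cy), , drop = FALSE]
}

#' Match detections to ground truth
#'
#' One-to-one greedy matching by ascending centre distance: candidate
#' pairs within `d_match` pixels are accepted closest-first (ties broken
#' by lowest detection then truth index); every detection and truth
#' participates in at most one match.  Leftover detections are false
#' positives, leftover truths are misses.
#'
#' @param detections data frame with `cx`, `cy` (from
#'   [detect_particles()]).
#' @param truth data frame with `cx_px`, `cy_px` (from
#'   [rasterize_slice()]).
#' @param d_match maximum matching distance in pixels (default 5).
#' @return list with `matches` (data frame: `det`, `truth`, `dist`),
#'   `false_det` (detection row indices) and `missed` (truth row
#'   indices).
#' @export
match_detections <- function(detections, truth, d_match = 5) {
  stopifnot(d_match > 0)
  nd <- nrow(detections)
  nt <- nrow(truth)
  matches <- data.frame(det = integer(0), truth = integer(0),
                        dist = numeric(0))
  if (nd > 0 && nt > 0) {
    dmat <- outer(detections$cx, truth$cx_px, `-`)^2 +
      outer(detections$cy, truth$cy_px, `-`)^2
    dmat <- sqrt(dmat)
    cand <- which(dmat <= d_match, arr.ind = TRUE)
    if (nrow(cand) > 0) {
      ord <- order(dmat[cand], cand[, 1], cand[, 2])
      cand <- cand[ord, , drop = FALSE]
      used_d <- logical(nd)
      used_t <- logical(nt)
      for (r in seq_len(nrow(cand))) {
        i <- cand[r, 1]; j <- cand[r, 2]
        if (!used_d[i] && !used_t[j]) {
          used_d[i] <- TRUE
          used_t[j] <- TRUE
          matches <- rbind(matches,
                           data.frame(det = i, truth = j,
                                      dist = dmat[i, j]))
        }
      }
    }
  }
  list(matches = matches,
       false_det = setdiff(seq_len(nd), matches$det),
       missed = setdiff(seq_len(nt), matches$truth))
}

#' True-positive ratio of one frame
#'
#' The fraction of ground-truth particles recovered by the detector.
#' Frames without any true particle have an undefined ratio and are
#' flagged (`NA`) so aggregation can exclude them.
#'
#' @param matched_count number of matched truth particles.
#' @param truth_count number of true particles in the frame.
#' @return `matched_count / truth_count`, or `NA` when `truth_count` is
#'   zero.
#' @export
compute_tpr <- function(matched_count, truth_count) {
  stopifnot(truth_count >= 0, matched_count >= 0,
            matched_count <= max(truth_count, matched_count))
  if (truth_count == 0) return(NA_real_)
  matched_count / truth_count
}

#' Average number of false particles per frame
#'
#' @param false_counts_per_frame integer vector, one entry per frame.
#' @return The mean count of detections not matching any true particle.
#' @export
compute_phi <- function(false_counts_per_frame) {
  if (length(false_counts_per_frame) == 0)
    stop("no frames: the false-particle rate is undefined")
  mean(false_counts_per_frame)
}

#' Evaluate a restorer on a set of frame pairs
#'
#' Restores every input frame, detects particles, matches them against
#' that frame's ground truth and aggregates the true-positive ratio and
#' the average false-particle count.
#'
#' @param net a `restoration_net`, or a function taking and returning a
#'   matrix (e.g. `identity` for the no-restoration baseline).
#' @param test_pairs list of `frame_pair` objects.
#' @param threshold,min_area,d_match detector and matching parameters.
#' @return An object of class `eval_report`: `per_frame` (data frame:
#'   `truth_n`, `detected_n`, `matched_n`, `false_n`, `tpr`), `tpr`
#'   (mean over frames with at least one true particle), `phi`,
#'   `n_frames`, `n_excluded` (zero-truth frames).
#' @export
evaluate_restorations <- function(net, test_pairs, threshold = 0.3 * 255,
                                  min_area = 4, d_match = 5) {
  stopifnot(length(test_pairs) > 0)
  restorer <- if (is.function(net)) net else function(f) restore_frame(net, f)
  rows <- lapply(test_pairs, function(pair) {
    rest <- restorer(pair$input)
    det <- detect_particles(rest, threshold, min_area)
    m <- match_detections(det, pair$truth, d_match)
    data.frame(truth_n = nrow(pair$truth), detected_n = nrow(det),
               matched_n = nrow(m$matches), false_n = length(m$false_det))
  })
  per_frame <- do.call(rbind, rows)
  per_frame$tpr <- mapply(compute_tpr, per_frame$matched_n,
                          per_frame$truth_n)
  structure(list(per_frame = per_frame,
                 tpr = mean(per_frame$tpr, na.rm = TRUE),
                 phi = compute_phi(per_frame$false_n),
                 n_frames = nrow(per_frame),
                 n_excluded = sum(is.na(per_frame$tpr))),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Particle-estimation report over %d frames: mean TPR %.4f (%.2f%%), phi %.3f",
              x$n_frames, x$tpr, 100 * x$tpr, x$phi))
  if (x$n_excluded > 0)
    cat(sprintf(" [%d zero-truth frame(s) excluded from TPR]", x$n_excluded))
  cat("\n")
  invisible(x)
}

#' Reconstruct 3D bead positions from a restored z-stack
#'
#' Restores every frame of the stack, detects per-frame profiles, links
#' detections across adjacent slices whose xy-centres lie within
#' `r_link` pixels, and reports one 3D estimate per cluster: the
#' score-weighted mean centre (with z from the member slice indices, in
#' voxel units) and the largest member profile radius.
#'
#' @param net a `restoration_net` or a restorer function.
#' @param frame_stack list of matrices, slice 1 first.
#' @param vol the [volume_spec()] of the stack (for micrometre output).
#' @param r_link maximum xy linking distance in pixels (default 5).
#' @param threshold,min_area detector parameters.
#' @return Data frame with voxel-unit `cx`, `cy`, `cz`, `radius_px`,
#'   micrometre `x_um`, `y_um`, `z_um`, and `n_slices` per cluster.
#' @export
reconstruct_volume_3d <- function(net, frame_stack, vol, r_link = 5,
                                  threshold = 0.3 * 255, min_area = 4) {
  restorer <- if (is.function(net)) net else function(f) restore_frame(net, f)
  det_all <- list()
  for (z in seq_along(frame_stack)) {
    det <- detect_particles(restorer(frame_stack[[z]]), threshold, min_area)
    if (nrow(det) > 0) {
      det$z <- z - 1L  # 0-based slice index
      det_all[[length(det_all) + 1]] <- det
    }
  }
  empty <- data.frame(cx = numeric(0), cy = numeric(0), cz = numeric(0),
                      radius_px = numeric(0), x_um = numeric(0),
                      y_um = numeric(0), z_um = numeric(0),
                      n_slices = integer(0))
  if (length(det_all) == 0) return(empty)
  det <- do.call(rbind, det_all)
  # single-linkage clustering restricted to adjacent slices
  n <- nrow(det)
  cluster <- seq_len(n)
  find_root <- function(i) { while (cluster[i] != i) i <- cluster[i]; i }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      if (abs(det$z[i] - det$z[j]) == 1 &&
          sqrt((det$cx[i] - det$cx[j])^2 + (det$cy[i] - det$cy[j])^2) <=
          r_link) {
        ri <- find_root(i); rj <- find_root(j)
        if (ri != rj) cluster[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(n), find_root, integer(1))
  out <- lapply(unique(roots), function(r) {
    mem <- det[roots == r, , drop = FALSE]
    w <- mem$score
    data.frame(cx = sum(mem$cx * w) / sum(w),
               cy = sum(mem$cy * w) / sum(w),
               cz = sum(mem$z * w) / sum(w),
               radius_px = max(mem$radius),
               n_slices = nrow(mem))
  })
  out <- do.call(rbind, out)
  out$x_um <- (out$cx + 0.5) * vol$dx
  out$y_um <- (out$cy + 0.5) * vol$dy
  out$z_um <- (out$cz + 0.5) * vol$dz
  out[order(out$cx), c("cx", "cy", "cz", "radius_px", "x_um", "y_um",
                       "z_um", "n_slices")]
}
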