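#' Convert a height-map scan to a point cloud
#'
#' Every foreground pixel (height > `background`) becomes one point, scaled
#' by the scanner intrinsics: x = (col - cx) * mm_per_pixel_x,
#' y = (row - cy) * mm_per_pixel_y, z = height. Pixel indices are 0-based
#' with pixel centers at integer coordinates.
#'
#' @param scan a `seed_scan` (or plain height matrix).
#' @param intrinsics a [scan_intrinsics()]; defaults to the intrinsics
#'   stored on the scan, if any.
#' @param background heights <= this value are background (default 0).
#' @return a [seed_cloud()] with one point per foreground pixel.
#' @examples
#' h <- matrix(0, 5, 5); h[3, 4] <- 1.5
#' scan_to_cloud(h, scan_intrinsics(1, 1, c(0, 0)))
#' @export
scan_to_cloud <- function(scan, intrinsics = attr(scan, "intrinsics"),
                          background = 0) {
  h <- as.matrix(scan)
  if (is.null(intrinsics))
    stop_carposort("no intrinsics supplied or stored on the scan",
                   class = "carposort_parameter_error")
  fg <- which(h > background, arr.ind = TRUE)
  if (nrow(fg) == 0L)
    stop_carposort("scan has no foreground pixels",
                   class = "carposort_empty_input_error")
  col0 <- fg[, "col"] - 1L
  row0 <- fg[, "row"] - 1L
  seed_cloud(cbind(
    (col0 - intrinsics$principal_point[1]) * intrinsics$mm_per_pixel_x,
    (row0 - intrinsics$principal_point[2]) * intrinsics$mm_per_pixel_y,
    h[fg]))
}

#' Canonicalize the pose of a pip cloud
#'
#' Centers the cloud at its centroid and rotates it so the principal axes of
#' the point scatter align with (x, y, z) in decreasing-variance order, with
#' determinant +1. Sign conventions: the tapered beak end — detected as the
#' outer x-quartile with the smaller cross-sectional spread — points toward
#' -x (ties keep +x), and the ventral (grooved) face — the z side whose
#' points sit closer to the midplane — toward +z. The y sign completes a
#' right-handed frame. The result is invariant to rigid motion of the
#' input.
#'
#' @param cloud a [seed_cloud()] with at least 3 points and full-rank
#'   scatter.
#' @return the canonicalized [seed_cloud()].
#' @export
canonicalize_pose <- function(cloud) {
  stopifnot(inherits(cloud, "seed_cloud"))
  pts <- cloud_matrix(cloud)
  if (nrow(pts) < 3L)
    stop_carposort("need at least 3 points to canonicalize",
                   class = "carposort_degenerate_error")
  ctr <- colMeans(pts)
  pts <- sweep(pts, 2, ctr)
  eg <- eigen(cov(pts), symmetric = TRUE)
  if (eg$values[3] <= 1e-12 * eg$values[1])
    stop_carposort("degenerate (rank-deficient) point scatter",
                   class = "carposort_degenerate_error")
  R <- eg$vectors                        # columns: decreasing variance
  if (det(R) < 0) R[, 3] <- -R[, 3]
  pts <- pts %*% R
  # beak (tapered, smaller cross-section) to -x
  qs <- stats::quantile(pts[, 1], c(0.25, 0.75))
  lo <- pts[, 1] <= qs[1]
  hi <- pts[, 1] >= qs[2]
  spread_lo <- mean(pts[lo, 2]^2 + pts[lo, 3]^2)
  spread_hi <- mean(pts[hi, 2]^2 + pts[hi, 3]^2)
  if (spread_lo > spread_hi) {           # tie keeps orientation (+x)
    pts[, 1] <- -pts[, 1]
    pts[, 2] <- -pts[, 2]                # rotate pi about z: det stays +1
  }
  # ventral (grooved, mass pulled toward midplane) to +z
  up <- pts[, 3] > 0
  if (any(up) && any(!up)) {
    if (mean(pts[up, 3]) > -mean(pts[!up, 3])) {
      pts[, 3] <- -pts[, 3]
      pts[, 2] <- -pts[, 2]              # rotate pi about x: det stays +1
    }
  }
  out <- seed_cloud(pts)
  attr(out, "canonical") <- TRUE
  out
}

#' Cloud length along the canonical length axis
#' @param cloud a [seed_cloud()].
#' @return extent along x in mm.
#' @export
cloud_length <- function(cloud) diff(range(cloud[, 1]))

#' Rescale a cloud to a common length
#'
#' Multiplies every coordinate by the single factor target_length / length,
#' presenting pips with equal length while preserving their structural
#' ratios (L/W and W/DVI are unchanged). Used before ICP so that similarity
#' reflects shape, not physical size. Idempotent after the first
#' application.
#'
#' @param cloud a canonical [seed_cloud()].
#' @param target_length target length in mm (default 1).
#' @return the rescaled [seed_cloud()].
#' @export
normalize_length <- function(cloud, target_length = 1) {
  stopifnot(inherits(cloud, "seed_cloud"), target_length > 0)
  len <- cloud_length(cloud)
  if (len <= 0)
    stop_carposort("cloud has zero length",
                   class = "carposort_degenerate_error")
  out <- seed_cloud(cloud_matrix(cloud) * (target_length / len))
  attributes(out)[names(attributes(cloud))] <- attributes(cloud)
  out
}

#' Canonicalize and length-normalize a list of clouds
#'
#' The standard preprocessing applied before registration: pose
#' canonicalization followed by equal-length scaling.
#'
#' @param clouds list of [seed_cloud()]s.
#' @param target_length common length in mm.
#' @return list of preprocessed clouds (attributes preserved).
#' @export
preprocess_clouds <- function(clouds, target_length = 1) {
  out <- lapply(clouds, function(cl)
    normalize_length(canonicalize_pose(cl), target_length))
  attributes(out) <- attributes(clouds)
  out
}
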