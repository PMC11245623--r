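#' Nearest-neighbour correspondences between two clouds
#'
#' For each source point, the index of its nearest target point by Euclidean
#' distance; ties are broken toward the lowest index.
#'
#' @param source,target [seed_cloud()]s (or plain n x 3 matrices).
#' @return integer vector of 1-based target indices, one per source point.
#' @export
nearest_correspondences <- function(source, target) {
  src <- as_pts(source)
  tgt <- as_pts(target)
  if (nrow(tgt) < 1L || nrow(src) < 1L)
    stop_carposort("both clouds must be non-empty",
                   class = "carposort_empty_input_error")
  cpp_nearest_indices(src, tgt)
}

as_pts <- function(x) {
  m <- as.matrix(unclass(x))
  if (ncol(m) != 3L)
    stop_carposort("expected an n x 3 coordinate matrix",
                   class = "carposort_parameter_error")
  storage.mode(m) <- "double"
  dimnames(m) <- NULL
  m
}

#' Rigid transform
#'
#' @param rotation 3 x 3 rotation matrix (orthonormal, det +1).
#' @param translation length-3 numeric.
#' @return an object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9 ||
      abs(det(rotation) - 1) > 1e-9)
    stop_carposort("rotation must be orthonormal with det +1",
                   class = "carposort_parameter_error")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(x$rotation)) - 1) / 2))) * 180 / pi
  cat(sprintf("<rigid_transform> rotation %.2f deg, translation (%.3f, %.3f, %.3f)\n",
              ang, x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

#' Apply a rigid transform to points
#' @param transform a [rigid_transform()].
#' @param points n x 3 matrix or [seed_cloud()].
#' @return transformed coordinates (plain matrix).
#' @export
apply_transform <- function(transform, points) {
  pts <- as_pts(points)
  sweep(pts %*% t(transform$rotation), 2, transform$translation, `+`)
}

#' Invert a rigid transform
#' @param transform a [rigid_transform()].
#' @return the inverse [rigid_transform()].
#' @export
invert_transform <- function(transform) {
  Rt <- t(transform$rotation)
  rigid_transform(Rt, -as.numeric(Rt %*% transform$translation))
}

#' Least-squares rigid alignment of paired points
#'
#' The Procrustes step inside ICP: finds the rotation (det +1, reflections
#' corrected via the SVD sign trick) and translation minimizing the mean
#' squared distance between transformed source and target over all rigid
#' motions. Implemented in R with [base::svd()]; the compiled ICP loop uses
#' an equivalent C++ routine.
#'
#' @param source_pts,target_pts paired n x 3 coordinate matrices (n >= 3,
#'   non-collinear).
#' @return a [rigid_transform()] mapping source onto target.
#' @export
best_rigid_transform <- function(source_pts, target_pts) {
  src <- as_pts(source_pts)
  tgt <- as_pts(target_pts)
  if (nrow(src) != nrow(tgt) || nrow(src) < 3L)
    stop_carposort("need >= 3 paired points",
                   class = "carposort_degenerate_error")
  cs <- colMeans(src)
  ct <- colMeans(tgt)
  Xc <- sweep(src, 2, cs)
  Yc <- sweep(tgt, 2, ct)
  H <- crossprod(Xc, Yc)
  sv <- svd(H)
  if (sv$d[2] < 1e-12 * max(sv$d[1], 1e-300))
    stop_carposort("collinear or degenerate point configuration",
                   class = "carposort_degenerate_error")
  D <- diag(c(1, 1, sign(det(sv$v %*% t(sv$u)))))
  R <- sv$v %*% D %*% t(sv$u)
  rigid_transform(R, ct - as.numeric(R %*% cs))
}

#' Iterative Closest Point registration
#'
#' Point-to-point ICP: alternates nearest-neighbour correspondence with the
#' least-squares rigid update until the relative MSE change falls below
#' `tolerance` or `max_iterations` is reached. Clouds are expected to arrive
#' canonicalized and length-normalized, so the iteration starts from the
#' identity. The reported MSE — the mean squared nearest-neighbour distance
#' under the final transform — is non-increasing across iterations (the
#' classic point-to-point guarantee) and serves as the pairwise shape
#' dissimilarity feature for classification. Note MSE is directional
#' (source into target); the similarity matrix is not symmetrized.
#'
#' @param source,target [seed_cloud()]s.
#' @param max_iterations iteration cap (default 50).
#' @param tolerance relative MSE change for convergence (default 1e-6).
#' @return an object of class `icp_result`: list with `transform`
#'   ([rigid_transform()]), `mse` (mm^2), `mse_trace`, `n_iterations`,
#'   `converged`.
#' @examples
#' a <- generate_fresh_cloud(cabernet_shape(), 300, rng_seed = 1)
#' icp(a, a)$mse
#' @export
icp <- function(source, target, max_iterations = 50, tolerance = 1e-6) {
  src <- as_pts(source)
  tgt <- as_pts(target)
  if (nrow(src) < 3L || nrow(tgt) < 3L)
    stop_carposort("both clouds must have at least 3 points",
                   class = "carposort_empty_input_error")
  res <- cpp_icp(src, tgt, as.integer(max_iterations), tolerance)
  structure(list(transform = rigid_transform(res$rotation,
                                             res$translation),
                 mse = res$mse, mse_trace = as.numeric(res$mse_trace),
                 n_iterations = res$n_iterations,
                 converged = res$converged),
            class = "icp_result")
}

#' @export
print.icp_result <- function(x, ...) {
  cat(sprintf("<icp_result> mse %.3g mm^2 after %d iterations (%s)\n",
              x$mse, x$n_iterations,
              if (x$converged) "converged" else "max iterations"))
  invisible(x)
}
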