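# shared fixtures: all built in code at test time

# points on an axis-aligned ellipsoid surface (uniform on the sphere, mapped)
ellipsoid_cloud <- function(a, b, c, n = 500, seed = 1) {
  set.seed(seed)
  u <- runif(n, -1, 1)
  phi <- runif(n, 0, 2 * pi)
  r <- sqrt(1 - u^2)
  seed_cloud(cbind(a * u, b * r * cos(phi), c * r * sin(phi)))
}

rotation_z <- function(theta) {
  matrix(c(cos(theta), -sin(theta), 0,
           sin(theta), cos(theta), 0,
           0, 0, 1), 3, 3, byrow = TRUE)
}

random_rotation <- function(seed) {
  set.seed(seed)
  qr_res <- qr(matrix(rnorm(9), 3))
  Q <- qr.Q(qr_res)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

rigidly_move <- function(cloud, R, t) {
  seed_cloud(sweep(unclass(cloud) %*% t(R), 2, t, `+`))
}

# jittered grid: points at least ~1 apart, so small rigid motions keep
# nearest-neighbour correspondences exact (constructed ICP ground truth)
separated_cloud <- function(n_side = 4, seed = 1, jitter = 0.05) {
  set.seed(seed)
  g <- as.matrix(expand.grid(x = seq_len(n_side), y = seq_len(n_side),
                             z = seq_len(3)))
  seed_cloud(g + matrix(runif(nrow(g) * 3, -jitter, jitter), ncol = 3))
}

# O(n^2) nearest-neighbour oracle, independent of the compiled path
nn_bruteforce <- function(src, tgt) {
  apply(src, 1, function(p) {
    d2 <- (tgt[, 1] - p[1])^2 + (tgt[, 2] - p[2])^2 + (tgt[, 3] - p[3])^2
    which.min(d2)
  })
}

# memoized deformation model / curve (cheap but used everywhere)
local_cache <- new.env(parent = emptyenv())
table2_model <- function() {
  if (is.null(local_cache$model))
    local_cache$model <- calibrate_deformation()
  local_cache$model
}
table2_curve <- function() {
  if (is.null(local_cache$curve))
    local_cache$curve <- fit_curve(reference_curve_observations())
  local_cache$curve
}
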