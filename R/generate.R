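#' Construct a seed point cloud
#'
#' A `seed_cloud` is an n x 3 numeric matrix of surface points in mm, columns
#' `x` (length axis), `y` (breadth axis), `z` (dorsoventral axis, ventral
#' toward +z in canonical pose).
#'
#' @param points numeric matrix with 3 columns (or something coercible).
#' @return an object of class `seed_cloud`.
#' @export
seed_cloud <- function(points) {
  points <- as.matrix(points)
  if (ncol(points) != 3L)
    stop_carposort("a seed cloud needs exactly 3 coordinate columns",
                   class = "carposort_parameter_error")
  if (nrow(points) < 1L || !all(is.finite(points)))
    stop_carposort("cloud points must be finite and non-empty",
                   class = "carposort_parameter_error")
  storage.mode(points) <- "double"
  colnames(points) <- c("x", "y", "z")
  rownames(points) <- NULL
  structure(points, class = c("seed_cloud", "matrix", "array"))
}

#' @export
print.seed_cloud <- function(x, ...) {
  ext <- apply(x, 2, function(cc) diff(range(cc)))
  cat(sprintf("<seed_cloud> %d points; extent %.2f x %.2f x %.2f mm\n",
              nrow(x), ext[1], ext[2], ext[3]))
  invisible(x)
}

# strip the class for raw matrix math, keep as helper
cloud_matrix <- function(cloud) {
  m <- unclass(cloud)
  attributes(m) <- list(dim = dim(m))
  m
}

#' Generate a fresh synthetic pip point cloud
#'
#' Samples the surface of a tapered ovoid pip: an ellipsoid with semi-axes
#' (base_length, base_width, base_height)/2, a narrowed stalk (beak) end, a
#' slight fore-aft asymmetry of the widest section, and two
#' Gaussian-profile grooves (the ventral infolds) dented into the +z face at
#' y = +/- infold_separation/2. The measured length and width of the output
#' track the requested base dimensions to within about 2% for a few hundred
#' points. Output is in canonical pose (beak toward -x, ventral toward +z)
#' and deterministic given `rng_seed`.
#'
#' @param shape a [variety_shape()].
#' @param n_points number of surface points (>= 200).
#' @param rng_seed integer seed.
#' @param surface_noise SD in mm of isotropic jitter emulating scanner
#'   roughness (default 0.01).
#' @return a [seed_cloud()].
#' @examples
#' cloud <- generate_fresh_cloud(cabernet_shape(), 500, rng_seed = 1)
#' morphometrics(cloud)
#' @export
generate_fresh_cloud <- function(shape, n_points = 600, rng_seed = 1,
                                 surface_noise = 0.01) {
  stopifnot(inherits(shape, "variety_shape"))
  if (n_points < 200)
    stop_carposort("n_points must be >= 200 for a usable surface sampling",
                   class = "carposort_parameter_error")
  a <- shape$base_length / 2
  b <- shape$base_width / 2
  cc <- shape$base_height / 2
  with_seed(rng_seed, {
    u <- runif(n_points, -1, 1)          # cos(polar) — uniform on sphere
    phi <- runif(n_points, 0, 2 * pi)
    r <- sqrt(1 - u^2)
    sx <- u
    sy <- r * cos(phi)
    sz <- r * sin(phi)
    x <- a * sx
    y <- b * sy
    z <- cc * sz
    xi <- sx
    # widest section nudged toward the stalk-opposite (chalaza) end
    bulge <- 1 + shape$asymmetry * 0.25 * xi * (1 - xi^2)
    # beak taper: narrow y/z progressively toward the -x tip
    taper <- ifelse(xi < -0.1,
                    1 - shape$beak_fraction * ((-xi - 0.1) / 0.9)^2, 1)
    y <- y * bulge * taper
    z <- z * bulge * taper
    # ventral infold grooves on the +z face
    if (shape$infold_depth > 0 && shape$infold_separation > 0) {
      s2 <- shape$infold_separation / 2
      sigma <- max(0.08, 0.12 * shape$infold_separation)
      dent <- shape$infold_depth *
        (exp(-(y - s2)^2 / (2 * sigma^2)) + exp(-(y + s2)^2 / (2 * sigma^2)))
      along <- pmax(0, 1 - xi^2)          # grooves fade at the tips
      w <- pmin(1, pmax(0, z) / (0.5 * cc))
      z <- z - dent * along * w
    }
    pts <- cbind(x, y, z)
    if (surface_noise > 0)
      pts <- pts + matrix(rnorm(3 * n_points, sd = surface_noise),
                          ncol = 3)
    seed_cloud(pts)
  })
}

#' Apply a charring deformation to a pip cloud
#'
#' Scales x by the calibrated length shrink factor and y/z by the width
#' shrink factor (so the length/width ratio of the output is the input ratio
#' times shrink_length/shrink_width in expectation), optionally with
#' per-seed multiplicative variability at the calibrated CVs, and above
#' 300 degrees C removes and jitters points in 2-4 narrow transverse crack
#' bands. Fresh conditions return the cloud unchanged.
#'
#' @param cloud a [seed_cloud()] in canonical pose.
#' @param condition a [charring_condition()].
#' @param model a [calibrate_deformation()] model covering the condition.
#' @param rng_seed integer seed for variability and crack placement.
#' @param variety variety name used for factor lookup; defaults to the mean
#'   over calibrated varieties.
#' @param variability logical; draw per-seed shrink noise at the calibrated
#'   CVs (default TRUE). With `variability = FALSE` and no cracks the
#'   deformation is the exact affine map.
#' @return a deformed [seed_cloud()].
#' @export
apply_charring <- function(cloud, condition, model, rng_seed = 1,
                           variety = NULL, variability = TRUE) {
  stopifnot(inherits(cloud, "seed_cloud"),
            inherits(condition, "charring_condition"),
            inherits(model, "deformation_model"))
  if (is_fresh(condition)) return(cloud)
  fac <- shrink_factors(model, variety %||% "(panel mean)",
                        condition$temperature_C, condition$duration_h)
  intensity <- crack_intensity(condition$temperature_C,
                               condition$duration_h)
  with_seed(rng_seed, {
    sL <- fac$length
    sW <- fac$width
    if (variability) {
      sL <- sL * max(0.05, 1 + rnorm(1, sd = fac$cv_length))
      sW <- sW * max(0.05, 1 + rnorm(1, sd = fac$cv_width))
    }
    pts <- cloud_matrix(cloud)
    pts[, 1] <- pts[, 1] * sL
    pts[, 2] <- pts[, 2] * sW
    pts[, 3] <- pts[, 3] * sW
    if (intensity > 0) {
      n_bands <- sample(2:4, 1)
      xr <- range(pts[, 1])
      centers <- runif(n_bands, xr[1] + 0.15 * diff(xr),
                       xr[2] - 0.15 * diff(xr))
      half_width <- 0.05                       # 0.1 mm crack bands
      keep <- rep(TRUE, nrow(pts))
      for (ctr in centers) {
        inside <- abs(pts[, 1] - ctr) < half_width
        keep[inside] <- keep[inside] & (runif(sum(inside)) > intensity)
        near <- abs(pts[, 1] - ctr) < 2 * half_width
        n_near <- sum(near)
        if (n_near > 0)
          pts[near, ] <- pts[near, ] +
            matrix(rnorm(3 * n_near, sd = 0.02), ncol = 3)
      }
      if (sum(keep) >= 3) pts <- pts[keep, , drop = FALSE]
    }
    seed_cloud(pts)
  })
}

#' Generate a labeled batch of pips under one charring condition
#'
#' Draws `n_seeds` pips of one variety with per-seed fresh-size variability
#' — a shared size factor plus independent length and width parts, with CVs
#' decomposed from the variety's tabulated fresh SDs (including the L/W
#' ratio SD) where calibrated — then chars each one independently. The
#' per-seed RNG seeds are derived from `rng_seed`, so the batch is
#' reproducible and grows stably (seed k is the same whatever `n_seeds`).
#'
#' @param shape a [variety_shape()].
#' @param n_seeds number of pips.
#' @param condition a [charring_condition()]; default fresh.
#' @param model deformation model (required unless fresh).
#' @param n_points points per cloud.
#' @param rng_seed integer seed.
#' @return list of [seed_cloud()]s with attributes `variety` and
#'   `condition`.
#' @export
generate_seed_batch <- function(shape, n_seeds,
                                condition = charring_condition("fresh"),
                                model = NULL, n_points = 600, rng_seed = 1) {
  stopifnot(inherits(shape, "variety_shape"), n_seeds >= 1)
  if (!is_fresh(condition) && is.null(model))
    stop_carposort("a deformation model is required for charred batches",
                   class = "carposort_parameter_error")
  cvs <- if (!is.null(model) && shape$name %in% names(model$fresh_cv)) {
    model$fresh_cv[[shape$name]]
  } else c(size = 0.025, length_ind = 0.035, width_ind = 0.035)
  clouds <- lapply(seq_len(n_seeds), function(k) {
    sk <- derive_seed(rng_seed, k)
    pert <- with_seed(sk, {
      size <- 1 + rnorm(1, sd = cvs["size"])
      c(max(0.5, size * (1 + rnorm(1, sd = cvs["length_ind"]))),
        max(0.5, size * (1 + rnorm(1, sd = cvs["width_ind"]))))
    })
    sh <- shape
    sh$base_length <- shape$base_length * pert[1]
    sh$base_width <- min(shape$base_width * pert[2],
                         0.999 * sh$base_length)
    sh$base_height <- shape$base_height * pert[2]
    sh$infold_separation <- min(shape$infold_separation * pert[2],
                                0.9 * sh$base_width)
    cl <- generate_fresh_cloud(sh, n_points, rng_seed = derive_seed(sk, 2L))
    if (!is_fresh(condition))
      cl <- apply_charring(cl, condition, model,
                           rng_seed = derive_seed(sk, 3L),
                           variety = shape$name)
    cl
  })
  attr(clouds, "variety") <- shape$name
  attr(clouds, "condition") <- condition
  clouds
}

#' Scanner intrinsic parameters
#'
#' Constants mapping 0-based pixel indices and height values of a
#' stereoscopic height-map scan to metric coordinates: x = (col - cx) *
#' mm_per_pixel_x, y = (row - cy) * mm_per_pixel_y, z = height.
#'
#' @param mm_per_pixel_x,mm_per_pixel_y pixel pitch in mm (> 0).
#' @param principal_point length-2 numeric, (cx, cy) in 0-based pixels.
#' @return an object of class `scan_intrinsics`.
#' @export
scan_intrinsics <- function(mm_per_pixel_x = 0.05, mm_per_pixel_y = 0.05,
                            principal_point = c(0, 0)) {
  if (mm_per_pixel_x <= 0 || mm_per_pixel_y <= 0)
    stop_carposort("pixel pitch must be > 0",
                   class = "carposort_parameter_error")
  structure(list(mm_per_pixel_x = mm_per_pixel_x,
                 mm_per_pixel_y = mm_per_pixel_y,
                 principal_point = as.numeric(principal_point)),
            class = "scan_intrinsics")
}

#' Simulate a top-surface height-map scan of a pip
#'
#' Projects a canonical, ventral-up cloud onto a rows x cols pixel grid:
#' each pixel records the maximum height (z, shifted by `z_offset` so all
#' surface heights are positive) among the points in its footprint;
#' background pixels are 0. This is the forward model inverted by
#' [scan_to_cloud()].
#'
#' @param cloud a [seed_cloud()] in canonical pose.
#' @param intrinsics a [scan_intrinsics()].
#' @param rows,cols grid size in pixels.
#' @param z_offset added to z before recording heights; default lifts the
#'   lowest point to 0.001 mm so every imaged pixel is foreground.
#' @return an object of class `seed_scan`: a rows x cols height matrix with
#'   the intrinsics stored as an attribute.
#' @export
simulate_scan <- function(cloud, intrinsics, rows = 128, cols = 160,
                          z_offset = NULL) {
  stopifnot(inherits(cloud, "seed_cloud"),
            inherits(intrinsics, "scan_intrinsics"))
  pts <- cloud_matrix(cloud)
  z_offset <- z_offset %||% (0.001 - min(pts[, 3]))
  col_idx <- round(pts[, 1] / intrinsics$mm_per_pixel_x +
                     intrinsics$principal_point[1])
  row_idx <- round(pts[, 2] / intrinsics$mm_per_pixel_y +
                     intrinsics$principal_point[2])
  if (any(col_idx < 0 | col_idx >= cols | row_idx < 0 | row_idx >= rows))
    stop_carposort("grid %d x %d too small for the cloud footprint",
                   rows, cols, class = "carposort_bounds_error")
  h <- matrix(0, nrow = rows, ncol = cols)
  z <- pts[, 3] + z_offset
  ord <- order(z)                       # later (higher) writes win
  for (i in ord) h[row_idx[i] + 1L, col_idx[i] + 1L] <- z[i]
  structure(h, class = c("seed_scan", "matrix", "array"),
            intrinsics = intrinsics)
}

#' @export
print.seed_scan <- function(x, ...) {
  cat(sprintf("<seed_scan> %d x %d px, %d foreground, max height %.2f mm\n",
              nrow(x), ncol(x), sum(x > 0), max(x)))
  invisible(x)
}
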