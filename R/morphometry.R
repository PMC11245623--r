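#' Measure pip length and maximal breadth
#'
#' Length is the extent along the canonical x axis. Breadth (width) is the
#' widest cross-section: the maximum y extent over thin x slabs, which
#' matches placing the calipers at the widest point rather than at
#' mid-length. The x position of the widest slab is returned for the DVI
#' transect.
#'
#' @param cloud a canonical [seed_cloud()].
#' @param slab_mm slab thickness for cross-sections; the default is 2% of
#'   the cloud length (about 0.12 mm on a fresh pip), proportional so that
#'   measurements commute exactly with uniform rescaling.
#' @return list with `length_mm`, `width_mm`, `width_x` (transect
#'   position).
#' @export
measure_length_width <- function(cloud, slab_mm = NULL) {
  stopifnot(inherits(cloud, "seed_cloud"))
  pts <- cloud_matrix(cloud)
  len <- diff(range(pts[, 1]))
  if (len <= 0 || nrow(pts) < 4L)
    stop_carposort("degenerate cloud: no measurable length",
                   class = "carposort_degenerate_error")
  slab_mm <- slab_mm %||% (0.02 * len)
  centers <- seq(min(pts[, 1]) + slab_mm / 2, max(pts[, 1]) - slab_mm / 2,
                 by = slab_mm / 2)
  widths <- vapply(centers, function(ctr) {
    inside <- abs(pts[, 1] - ctr) <= slab_mm / 2
    if (sum(inside) < 2L) return(0)
    diff(range(pts[inside, 2]))
  }, numeric(1))
  k <- which.max(widths)
  list(length_mm = len, width_mm = widths[k], width_x = centers[k])
}

#' Measure the distance between the ventral infolds (DVI)
#'
#' On the transect at the x position of maximal breadth, the ventral (top,
#' +z) surface profile z(y) is extracted by binning y and taking the
#' maximum z per bin, smoothed with a moving average. The DVI is the
#' distance between the two groove minima — interior local minima of the
#' profile, the deepest on each side of the midline — refined to sub-bin
#' precision by a local parabola. Clouds without two detectable grooves
#' (e.g. a plain ellipsoid) are not measurable and yield `NA` rather than
#' an error.
#'
#' @param cloud a canonical [seed_cloud()], ventral face toward +z.
#' @param slab_mm transect slab thickness; default 25% of the length (the
#'   grooves run along the body, so a generous slab stabilizes the surface
#'   profile without moving the minima).
#' @param n_bins number of y bins across the transect (default 48; reliable
#'   groove detection wants roughly 1000+ points on the cloud).
#' @param smooth_window moving-average window in bins (default 3).
#' @param prominence minimum height of the midline ridge above the groove
#'   floors for the grooves to count as detected; default 0.35% of the
#'   cloud length (about 0.02 mm on a fresh pip), proportional so that
#'   detection commutes with uniform rescaling.
#' @return DVI in mm, or `NA_real_` when fewer than two groove minima are
#'   detectable.
#' @export
measure_dvi <- function(cloud, slab_mm = NULL, n_bins = 48,
                        smooth_window = 3, prominence = NULL) {
  stopifnot(inherits(cloud, "seed_cloud"))
  pts <- cloud_matrix(cloud)
  lw <- measure_length_width(cloud)
  slab_mm <- slab_mm %||% (0.25 * lw$length_mm)
  prominence <- prominence %||% (0.0035 * lw$length_mm)
  inside <- abs(pts[, 1] - lw$width_x) <= slab_mm / 2 &
    pts[, 3] > 0                      # ventral (upper) surface only
  sect <- pts[inside, , drop = FALSE]
  if (nrow(sect) < 24L) return(NA_real_)
  yr <- range(sect[, 2])
  edges <- seq(yr[1], yr[2], length.out = n_bins + 1L)
  bin <- pmin(pmax(findInterval(sect[, 2], edges, rightmost.closed = TRUE),
                   1L), n_bins)
  prof <- rep(NA_real_, n_bins)
  # mean height per bin: a symmetric (box) filter of the ventral surface,
  # which unlike a max/envelope filter does not displace groove minima
  top <- tapply(sect[, 3], bin, mean)
  prof[as.integer(names(top))] <- top
  ok <- which(!is.na(prof))
  if (length(ok) < smooth_window + 4L) return(NA_real_)
  ycent <- (edges[-1] + edges[-(n_bins + 1L)]) / 2
  ycent <- ycent[ok]
  prof <- prof[ok]
  # moving-average smoothing against sampling noise
  kern <- rep(1 / smooth_window, smooth_window)
  pad <- (smooth_window - 1L) %/% 2L
  smoothed <- as.numeric(stats::filter(c(rep(prof[1], pad), prof,
                                         rep(prof[length(prof)], pad)),
                                       kern, sides = 2))
  smoothed <- smoothed[(pad + 1L):(pad + length(prof))]
  m <- length(smoothed)
  interior <- 3:(m - 2)
  is_min <- vapply(interior, function(i) {
    smoothed[i] <= smoothed[i - 1] && smoothed[i] <= smoothed[i + 1] &&
      smoothed[i] < smoothed[i - 2] && smoothed[i] < smoothed[i + 2]
  }, logical(1))
  minima <- interior[is_min]
  # the grooves flank the midline ridge: keep minima in the central portion
  # of the breadth (the outer shoulders fall off toward the seed edge)
  half_width <- diff(range(ycent)) / 2
  minima <- minima[abs(ycent[minima]) <= 0.7 * half_width]
  if (length(minima) < 2L) return(NA_real_)
  refine <- function(i) {
    if (i <= 1L || i >= m) return(ycent[i])
    y3 <- ycent[(i - 1):(i + 1)]
    z3 <- smoothed[(i - 1):(i + 1)]
    denom <- z3[1] - 2 * z3[2] + z3[3]
    if (abs(denom) < 1e-12) return(ycent[i])
    ycent[i] + 0.5 * (z3[1] - z3[3]) / denom * (y3[2] - y3[1])
  }
  left <- minima[ycent[minima] < 0]
  right <- minima[ycent[minima] > 0]
  if (length(left) < 1L || length(right) < 1L) return(NA_real_)
  # one groove per side: the minimum nearest the ridge
  li <- left[which.max(ycent[left])]
  ri <- right[which.min(ycent[right])]
  ridge <- max(smoothed[li:ri])
  if (ridge - max(smoothed[li], smoothed[ri]) < prominence)
    return(NA_real_)                  # no real infolds (e.g. ellipsoid)
  refine(ri) - refine(li)
}

#' Full morphometrics of one pip
#'
#' Length, maximal breadth, DVI and the two shape ratios used throughout:
#' L/W (length over width, the charring-deformation indicator) and W/DVI.
#' Ratios are size-invariant, so they are unchanged by [normalize_length()].
#'
#' @param cloud a canonical [seed_cloud()].
#' @param ... passed to [measure_dvi()].
#' @return an object of class `seed_morphometrics`: a one-row data.frame
#'   with `length_mm`, `width_mm`, `dvi_mm`, `lw_ratio`, `w_dvi_ratio`,
#'   `dvi_missing`.
#' @export
morphometrics <- function(cloud, ...) {
  lw <- measure_length_width(cloud)
  if (lw$width_mm <= 0)
    stop_carposort("degenerate cloud: no measurable width",
                   class = "carposort_degenerate_error")
  dvi <- measure_dvi(cloud, ...)
  out <- data.frame(length_mm = lw$length_mm, width_mm = lw$width_mm,
                    dvi_mm = dvi,
                    lw_ratio = lw$length_mm / lw$width_mm,
                    w_dvi_ratio = if (is.na(dvi)) NA_real_ else
                      lw$width_mm / dvi,
                    dvi_missing = is.na(dvi))
  class(out) <- c("seed_morphometrics", "data.frame")
  out
}

#' Morphometrics table for a batch of clouds
#'
#' @param clouds list of canonical [seed_cloud()]s.
#' @param ids optional row identifiers.
#' @param ... passed to [morphometrics()].
#' @return data.frame with one row per cloud (columns as in
#'   [morphometrics()], plus `id`).
#' @export
morphometrics_table <- function(clouds, ids = NULL, ...) {
  rows <- lapply(clouds, morphometrics, ...)
  out <- do.call(rbind, rows)
  class(out) <- "data.frame"
  out <- cbind(id = ids %||% seq_along(clouds), out)
  rownames(out) <- NULL
  out
}

#' Summarize a morphometrics batch
#'
#' Reports, per group, both the mean of per-seed L/W ratios and the ratio
#' of mean length to mean width — these differ in general, and the per-seed
#' mean is the one used for curve calibration.
#'
#' @param table a [morphometrics_table()] result.
#' @param groups optional grouping factor (one per row).
#' @return data.frame with `group`, `n`, `mean_length`, `mean_width`,
#'   `mean_dvi`, `mean_lw_ratio` (mean of per-seed ratios),
#'   `ratio_of_means`.
#' @export
summarize_morphometrics <- function(table, groups = NULL) {
  g <- factor(groups %||% rep("all", nrow(table)))
  do.call(rbind, lapply(levels(g), function(lev) {
    sub <- table[g == lev, , drop = FALSE]
    data.frame(group = lev, n = nrow(sub),
               mean_length = mean(sub$length_mm),
               mean_width = mean(sub$width_mm),
               mean_dvi = mean(sub$dvi_mm, na.rm = TRUE),
               mean_lw_ratio = mean(sub$lw_ratio),
               ratio_of_means = mean(sub$length_mm) / mean(sub$width_mm))
  }))
}
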