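#' Calibrate the charring deformation model from condition means
#'
#' Charring shrinks pips anisotropically: length shrinks faster than width,
#' so the length/width ratio falls with temperature. The deformation model is
#' calibrated directly from per-condition mean dimensions: the length shrink
#' factor for (variety, T, t) is the mean charred length divided by the mean
#' fresh length, and analogously for width. Between tabulated temperatures
#' the factors are linearly interpolated at fixed duration. Per-seed
#' variability is carried as coefficients of variation (CVs) derived from the
#' tabulated SDs; crack intensity is zero below 300 degrees C and ramps
#' linearly to 0.3 at 350 degrees C (on the line through zero at 250).
#'
#' @param table a reference-means table in the layout of
#'   [charring_reference_means()] (the default); must contain a fresh row
#'   and at least one charred row per variety.
#' @return an object of class `deformation_model`.
#' @seealso [shrink_factors()], [crack_intensity()], [apply_charring()]
#' @examples
#' model <- calibrate_deformation()
#' shrink_factors(model, "Cabernet Sauvignon", 350, 8)
#' @export
calibrate_deformation <- function(table = charring_reference_means()) {
  stopifnot(is.data.frame(table))
  varieties <- unique(table$variety)
  rows <- list()
  fresh_cv <- list()
  for (v in varieties) {
    sub <- table[table$variety == v, , drop = FALSE]
    fresh <- sub[sub$temperature_C == "fresh", , drop = FALSE]
    if (nrow(fresh) != 1L)
      stop_carposort("variety '%s' lacks a fresh reference row", v,
                     class = "carposort_calibration_error")
    charred <- sub[sub$temperature_C != "fresh", , drop = FALSE]
    if (nrow(charred) < 1L)
      stop_carposort("variety '%s' has no charred rows", v,
                     class = "carposort_calibration_error")
    cvf_L <- fresh$length_sd / fresh$length_mm
    cvf_W <- fresh$width_sd / fresh$width_mm
    cvf_R <- fresh$lw_sd / fresh$lw_ratio
    # decompose per-seed variability into a shared size factor plus
    # independent length/width parts, so that the simulated L, W *and* L/W
    # spreads all match the tabulated SDs (ratio variance = l^2 + w^2)
    s2 <- max(0, (cvf_L^2 + cvf_W^2 - cvf_R^2) / 2)
    fresh_cv[[v]] <- c(length = cvf_L, width = cvf_W,
                       size = sqrt(s2),
                       length_ind = sqrt(max(cvf_L^2 - s2, 1e-8)),
                       width_ind = sqrt(max(cvf_W^2 - s2, 1e-8)))
    rows[[v]] <- data.frame(
      variety = v,
      temperature_C = as.numeric(charred$temperature_C),
      duration_h = charred$duration_h,
      shrink_length = charred$length_mm / fresh$length_mm,
      shrink_width = charred$width_mm / fresh$width_mm,
      # per-seed multiplicative spread of the factor beyond fresh spread
      cv_length = sqrt(pmax((charred$length_sd / charred$length_mm)^2 -
                              cvf_L^2, 0)),
      cv_width = sqrt(pmax((charred$width_sd / charred$width_mm)^2 -
                             cvf_W^2, 0))
    )
  }
  factors <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (any(factors$shrink_length <= 0 | factors$shrink_length > 1 |
            factors$shrink_width <= 0 | factors$shrink_width > 1))
    stop_carposort("shrink factors must lie in (0, 1]",
                   class = "carposort_calibration_error")
  structure(list(factors = factors, fresh_cv = fresh_cv,
                 varieties = varieties),
            class = "deformation_model")
}

#' @export
print.deformation_model <- function(x, ...) {
  cat(sprintf("<deformation_model> %d varieties, %d charred conditions\n",
              length(x$varieties), nrow(x$factors)))
  cat("  varieties:", paste(x$varieties, collapse = ", "), "\n")
  invisible(x)
}

interp_column <- function(sub, column, temperature) {
  if (nrow(sub) == 1L) {
    if (abs(sub$temperature_C - temperature) > 1e-9) return(NA_real_)
    return(sub[[column]])
  }
  rng <- range(sub$temperature_C)
  if (temperature < rng[1] - 1e-9 || temperature > rng[2] + 1e-9)
    return(NA_real_)
  stats::approx(sub$temperature_C, sub[[column]], xout = temperature,
                ties = "ordered")$y
}

#' Shrink factors for one charring condition
#'
#' Looks up (or linearly interpolates in temperature, at fixed duration) the
#' calibrated length and width shrink factors and their per-seed CVs. For a
#' variety absent from the calibration table, the factors are averaged over
#' the calibrated varieties. Fresh conditions return unit factors.
#'
#' @param model a [calibrate_deformation()] model.
#' @param variety variety name (character).
#' @param temperature_C numeric temperature, or `"fresh"`.
#' @param duration_h duration in hours; must match a calibrated duration.
#' @return list with `length`, `width` (factors in (0, 1]), `cv_length`,
#'   `cv_width`.
#' @export
shrink_factors <- function(model, variety, temperature_C, duration_h = 2) {
  stopifnot(inherits(model, "deformation_model"))
  if (identical(temperature_C, "fresh"))
    return(list(length = 1, width = 1, cv_length = 0, cv_width = 0))
  vs <- if (variety %in% model$varieties) variety else model$varieties
  per <- lapply(vs, function(v) {
    sub <- model$factors[model$factors$variety == v &
                           model$factors$duration_h == duration_h, ,
                         drop = FALSE]
    if (nrow(sub) == 0L)
      stop_carposort("duration %g h not calibrated for variety '%s'",
                     duration_h, v, class = "carposort_coverage_error")
    sub <- sub[order(sub$temperature_C), , drop = FALSE]
    vals <- vapply(c("shrink_length", "shrink_width", "cv_length",
                     "cv_width"),
                   function(cl) interp_column(sub, cl, temperature_C),
                   numeric(1))
    if (any(is.na(vals)))
      stop_carposort(
        "temperature %g degC outside the calibrated range for '%s'",
        temperature_C, v, class = "carposort_coverage_error")
    vals
  })
  m <- Reduce(`+`, per) / length(per)
  list(length = unname(m["shrink_length"]), width = unname(m["shrink_width"]),
       cv_length = unname(m["cv_length"]), cv_width = unname(m["cv_width"]))
}

#' Crack intensity at a charring condition
#'
#' Cracks appear on pip surfaces at 300 degrees C and become widespread at
#' 350 degrees C. Intensity (the fraction of points dropped inside a crack
#' band) is 0 below 300 degrees C and follows the line 0.3 * (T - 250) / 100
#' from there, reaching 0.15 at 300 and 0.3 at 350 degrees C. Duration
#' nudges the intensity (8 h 20% stronger than 2 h), capped at 1.
#'
#' @param temperature_C numeric temperature or `"fresh"`.
#' @param duration_h duration in hours.
#' @return intensity in [0, 1].
#' @export
crack_intensity <- function(temperature_C, duration_h = 2) {
  if (identical(temperature_C, "fresh") || temperature_C < 300) return(0)
  base <- 0.3 * (temperature_C - 250) / 100
  mult <- 1 + 0.2 * (duration_h >= 8)
  min(1, base * mult)
}
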