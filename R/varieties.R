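#' Variety shape parameters for the synthetic pip generator
#'
#' A `variety_shape` bundles the per-variety geometry of a fresh grape pip:
#' overall dimensions, the separation and depth of the two ventral infold
#' grooves, how strongly the stalk (beak) end tapers, and a small
#' fore-aft asymmetry. Fresh dimensions for the two calibrated cultivars are
#' anchored to the published fresh-pip means (see
#' [charring_reference_means()]).
#'
#' @param name character label for the variety.
#' @param base_length,base_width,base_height fresh pip dimensions in mm;
#'   `base_length >= base_width` and `base_height` is the dorsoventral
#'   thickness.
#' @param infold_separation distance in mm between the two ventral grooves
#'   (the fresh DVI); must be smaller than `base_width`.
#' @param infold_depth groove depth in mm (0 disables grooves).
#' @param beak_fraction unitless taper strength of the beak end, in [0, 0.5).
#' @param asymmetry unitless fore-aft asymmetry of the outline, small.
#' @return an object of class `variety_shape`.
#' @examples
#' variety_shape("Cabernet Sauvignon", 5.81, 3.81, 2.9, 0.96, 0.25)
#' @export
variety_shape <- function(name, base_length, base_width,
                          base_height = 0.75 * base_width,
                          infold_separation = 0.25 * base_width,
                          infold_depth = 0.06 * base_width,
                          beak_fraction = 0.3, asymmetry = 0.1) {
  lens <- c(base_length = base_length, base_width = base_width,
            base_height = base_height, infold_separation = infold_separation)
  if (any(!is.finite(lens)) || any(lens[1:3] <= 0) || infold_separation < 0)
    stop_carposort("shape dimensions must be finite and positive",
                   class = "carposort_parameter_error")
  if (base_length < base_width)
    stop_carposort("base_length must be >= base_width (pip longer than wide)",
                   class = "carposort_parameter_error")
  if (infold_separation >= base_width)
    stop_carposort("infold_separation must be < base_width",
                   class = "carposort_parameter_error")
  if (infold_depth < 0)
    stop_carposort("infold_depth must be >= 0",
                   class = "carposort_parameter_error")
  if (beak_fraction < 0 || beak_fraction >= 0.5)
    stop_carposort("beak_fraction must lie in [0, 0.5)",
                   class = "carposort_parameter_error")
  structure(list(name = as.character(name),
                 base_length = base_length, base_width = base_width,
                 base_height = base_height,
                 infold_separation = infold_separation,
                 infold_depth = infold_depth,
                 beak_fraction = beak_fraction,
                 asymmetry = asymmetry),
            class = "variety_shape")
}

#' @export
print.variety_shape <- function(x, ...) {
  cat(sprintf("<variety_shape> %s: L %.2f x W %.2f x H %.2f mm, DVI %.2f mm\n",
              x$name, x$base_length, x$base_width, x$base_height,
              x$infold_separation))
  invisible(x)
}

#' Built-in variety shapes
#'
#' `cabernet_shape()` and `tzuriman_shape()` carry the fresh dimensions of
#' the two cultivars used in the charring calibration (mean fresh length,
#' width and DVI). `default_varieties()` returns a five-variety reference
#' panel: the two calibrated cultivars plus three plausibly distinct table /
#' wine varieties spanning the length/width-ratio range seen across
#' cultivars, for use as a training library in classification experiments.
#'
#' @return a `variety_shape`, or for `default_varieties()` a named list of
#'   five of them.
#' @export
cabernet_shape <- function() {
  variety_shape("Cabernet Sauvignon", base_length = 5.81, base_width = 3.81,
                base_height = 2.70, infold_separation = 0.96,
                infold_depth = 0.24, beak_fraction = 0.32, asymmetry = 0.12)
}

#' @rdname cabernet_shape
#' @export
tzuriman_shape <- function() {
  variety_shape("Tzuriman S", base_length = 5.83, base_width = 4.27,
                base_height = 3.55, infold_separation = 1.14,
                infold_depth = 0.28, beak_fraction = 0.26, asymmetry = 0.08)
}

#' @rdname cabernet_shape
#' @export
default_varieties <- function() {
  list(
    `Cabernet Sauvignon` = cabernet_shape(),
    `Tzuriman S` = tzuriman_shape(),
    # stand-ins for the additional library varieties: cultivars are
    # morphometrically distinct, so the panel spreads along several
    # normalized axes at once (width and height per unit length, groove
    # separation and depth, beak taper)
    `V9043` = variety_shape("V9043", base_length = 6.40, base_width = 3.45,
                            base_height = 2.40, infold_separation = 0.85,
                            infold_depth = 0.22, beak_fraction = 0.40,
                            asymmetry = 0.18),
    `V98` = variety_shape("V98", base_length = 5.10, base_width = 4.45,
                          base_height = 3.60, infold_separation = 1.45,
                          infold_depth = 0.34, beak_fraction = 0.16,
                          asymmetry = 0.04),
    `V138` = variety_shape("V138", base_length = 5.85, base_width = 3.50,
                           base_height = 2.85, infold_separation = 0.75,
                           infold_depth = 0.15, beak_fraction = 0.22,
                           asymmetry = 0.14)
  )
}

#' Charring condition
#'
#' A temperature/duration pair from the controlled charring grid. The
#' sentinel temperature `"fresh"` denotes an uncharred pip (duration
#' ignored).
#'
#' @param temperature_C `"fresh"` or one of 150, 200, 250, 300, 350 degrees
#'   C; intermediate temperatures are allowed when a deformation model that
#'   interpolates covers them.
#' @param duration_h heating duration in hours, one of 1, 2, 4, 8, 24.
#' @return an object of class `charring_condition`.
#' @export
charring_condition <- function(temperature_C, duration_h = 2) {
  if (identical(temperature_C, "fresh")) {
    return(structure(list(temperature_C = "fresh", duration_h = NA_real_),
                     class = "charring_condition"))
  }
  if (!is.numeric(temperature_C) || length(temperature_C) != 1L ||
      temperature_C < 150 || temperature_C > 350)
    stop_carposort("temperature must be 'fresh' or in [150, 350] degrees C",
                   class = "carposort_parameter_error")
  if (!duration_h %in% c(1, 2, 4, 8, 24))
    stop_carposort("duration must be one of 1, 2, 4, 8, 24 h",
                   class = "carposort_parameter_error")
  structure(list(temperature_C = temperature_C, duration_h = duration_h),
            class = "charring_condition")
}

is_fresh <- function(condition) identical(condition$temperature_C, "fresh")

#' @export
print.charring_condition <- function(x, ...) {
  if (is_fresh(x)) cat("<charring_condition> fresh\n")
  else cat(sprintf("<charring_condition> %g degC, %g h\n",
                   x$temperature_C, x$duration_h))
  invisible(x)
}

#' @export
format.charring_condition <- function(x, ...) {
  if (is_fresh(x)) "fresh" else sprintf("%gC/%gh", x$temperature_C, x$duration_h)
}
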