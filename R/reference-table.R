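#' Published per-condition morphometric means for the calibration cultivars
#'
#' The controlled charring experiments measured 20 pips per treatment for two
#' cultivars (Cabernet Sauvignon and Tzuriman S) at 200-350 degrees C for 2
#' and 8 h, plus fresh controls. This table ships with the package and is the
#' calibration source for the deformation model and the length/width-ratio
#' calibration curve: per condition it holds the mean and SD of length,
#' width and DVI (distance between the ventral infolds) in mm, and the mean
#' and SD of the per-seed length/width ratio.
#'
#' @return a data.frame with columns `variety`, `temperature_C` (`"fresh"`
#'   or the numeric temperature as character), `duration_h`, `length_mm`,
#'   `length_sd`, `width_mm`, `width_sd`, `dvi_mm`, `dvi_sd`, `lw_ratio`,
#'   `lw_sd`.
#' @examples
#' tab <- charring_reference_means()
#' subset(tab, variety == "Cabernet Sauvignon" & temperature_C == "fresh")
#' @export
charring_reference_means <- function() {
  path <- system.file("extdata", "table2_means.csv", package = "carposort",
                      mustWork = TRUE)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  tab$temperature_C <- as.character(tab$temperature_C)
  tab
}

#' Condition-mean length/width ratios for curve fitting
#'
#' Convenience extraction of the charred condition means used to calibrate
#' the ratio-versus-temperature curve: one row per (variety, temperature,
#' duration) with the mean per-seed length/width ratio. Fresh rows are
#' excluded (the curve is defined on the charred range).
#'
#' @param table a reference-means table, by default
#'   [charring_reference_means()].
#' @param durations durations (h) to keep; default both tabulated (2, 8).
#' @return a data.frame with columns `variety`, `temperature_C` (numeric),
#'   `duration_h`, `mean_lw_ratio`.
#' @export
reference_curve_observations <- function(table = charring_reference_means(),
                                         durations = c(2, 8)) {
  tab <- table[table$temperature_C != "fresh" &
                 table$duration_h %in% durations, , drop = FALSE]
  data.frame(variety = tab$variety,
             temperature_C = as.numeric(tab$temperature_C),
             duration_h = tab$duration_h,
             mean_lw_ratio = tab$lw_ratio,
             row.names = NULL)
}
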