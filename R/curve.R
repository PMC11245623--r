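#' Fit the quadratic length/width-ratio versus temperature curve
#'
#' Ordinary least squares of the mean L/W ratio on x^2 with intercept,
#' r = a * x^2 + b, where the charring temperature is scaled as
#' x = (T - 200) / 150 so the calibrated range 200-350 degrees C maps to
#' [0, 1]. Fitted to per-condition mean ratios of charred seeds (fresh rows
#' excluded); durations enter only through which condition means are
#' supplied. On the published condition means the fit gives a close to
#' -0.28 and b close to 1.44.
#'
#' @param observations data.frame with columns `temperature_C` (numeric,
#'   degrees C), `duration_h`, and `mean_lw_ratio`; at least 3 rows at >= 2
#'   distinct temperatures. See [reference_curve_observations()].
#' @param t_zero,t_one temperatures mapped to x = 0 and x = 1 (defaults
#'   200, 350).
#' @return an object of class `charring_curve`: `a`, `b`, `t_zero`,
#'   `t_one`, `fit_residual` (residual sum of squares), `n_obs`.
#' @examples
#' curve <- fit_curve(reference_curve_observations())
#' curve$a; curve$b
#' @export
fit_curve <- function(observations, t_zero = 200, t_one = 350) {
  stopifnot(is.data.frame(observations),
            all(c("temperature_C", "mean_lw_ratio") %in%
                  names(observations)))
  obs <- observations[is.finite(observations$temperature_C), , drop = FALSE]
  if (nrow(obs) < 3L)
    stop_carposort("need >= 3 charred observations",
                   class = "carposort_parameter_error")
  if (length(unique(obs$temperature_C)) < 2L)
    stop_carposort("observations span a single temperature: rank-deficient",
                   class = "carposort_rank_error")
  x <- (obs$temperature_C - t_zero) / (t_one - t_zero)
  fit <- lm(obs$mean_lw_ratio ~ I(x^2))
  structure(list(a = unname(coef(fit)[2]), b = unname(coef(fit)[1]),
                 t_zero = t_zero, t_one = t_one,
                 fit_residual = sum(resid(fit)^2), n_obs = nrow(obs)),
            class = "charring_curve")
}

#' @export
print.charring_curve <- function(x, ...) {
  cat(sprintf(
    "<charring_curve> r = %.3f x^2 + %.3f (x = (T - %g)/%g), RSS %.3g on %d means\n",
    x$a, x$b, x$t_zero, x$t_one - x$t_zero, x$fit_residual, x$n_obs))
  invisible(x)
}

#' Evaluate the curve forward model
#' @param curve a [charring_curve()].
#' @param temperature_C temperatures in degrees C.
#' @return predicted mean L/W ratios.
#' @export
predict_ratio <- function(curve, temperature_C) {
  x <- (temperature_C - curve$t_zero) / (curve$t_one - curve$t_zero)
  curve$b + curve$a * x^2
}

#' Estimate charring temperature from a length/width ratio
#'
#' Inverts the fitted curve: for a ratio r <= b, x_hat = sqrt((b - r) / -a)
#' and temperature_hat = t_zero + x_hat * (t_one - t_zero). Extrapolation
#' beyond t_one is permitted (and visible in temperature_hat); ratios above
#' the intercept b indicate milder-than-calibration charring and clamp to
#' x = 0 with reason `"ratio-above-intercept-clamped"`.
#'
#' @param lw_ratio numeric vector of per-seed L/W ratios (finite).
#' @param curve a valid [charring_curve()] (a < 0).
#' @return data.frame with `lw_ratio`, `x_hat`, `temperature_hat`,
#'   `clamped`.
#' @examples
#' curve <- fit_curve(reference_curve_observations())
#' estimate_temperature(c(1.44, 1.16, 1.00), curve)
#' @export
estimate_temperature <- function(lw_ratio, curve) {
  stopifnot(inherits(curve, "charring_curve"))
  if (curve$a >= 0)
    stop_carposort("curve is not decreasing (a >= 0): cannot invert",
                   class = "carposort_parameter_error")
  if (any(!is.finite(lw_ratio)))
    stop_carposort("lw_ratio must be finite",
                   class = "carposort_parameter_error")
  clamped <- lw_ratio > curve$b
  x_hat <- sqrt(pmax(0, curve$b - lw_ratio) / -curve$a)
  data.frame(lw_ratio = lw_ratio, x_hat = x_hat,
             temperature_hat = curve$t_zero +
               x_hat * (curve$t_one - curve$t_zero),
             clamped = clamped)
}

#' Sort seeds of unknown charring history for classifiability
#'
#' Projects each seed's L/W ratio onto the calibration curve to estimate
#' its charring temperature and accepts it for downstream classification
#' when the estimate is at or below `threshold_C` (default 275 degrees C,
#' the upper edge of the range where variety classification remains
#' accurate). Ratios above the intercept clamp to t_zero and are accepted
#' (milder-than-calibration charring). The decision is deterministic.
#'
#' @param morph_table data.frame with a `lw_ratio` column (e.g. from
#'   [morphometrics_table()]); an optional `group` column drives the
#'   per-group summary.
#' @param curve a valid [charring_curve()].
#' @param threshold_C acceptance threshold in degrees C; the boundary
#'   counts as accepted.
#' @return an object of class `seed_sorting`: list with `decisions` (per
#'   seed: `lw_ratio`, `x_hat`, `temperature_hat`, `accepted`, `reason`)
#'   and `summary` (per group: n, accepted count and fraction).
#' @export
sort_seeds <- function(morph_table, curve, threshold_C = 275) {
  stopifnot(inherits(curve, "charring_curve"))
  if (nrow(morph_table) == 0L) {
    return(structure(list(decisions = data.frame(),
                          summary = data.frame(group = character(0),
                                               n = integer(0),
                                               n_accepted = integer(0),
                                               accepted_fraction = numeric(0)),
                          threshold_C = threshold_C),
                     class = "seed_sorting"))
  }
  est <- estimate_temperature(morph_table$lw_ratio, curve)
  # the boundary counts as accepted; tolerance absorbs inversion round-off
  accepted <- est$temperature_hat <= threshold_C * (1 + 1e-12)
  reason <- ifelse(est$clamped, "ratio-above-intercept-clamped",
                   ifelse(accepted, "in-range", "above-threshold"))
  decisions <- cbind(est[c("lw_ratio", "x_hat", "temperature_hat")],
                     accepted = accepted, reason = reason)
  if (!is.null(morph_table$id)) decisions <- cbind(id = morph_table$id,
                                                   decisions)
  g <- factor(morph_table$group %||% rep("all", nrow(morph_table)))
  summary <- do.call(rbind, lapply(levels(g), function(lev) {
    sel <- g == lev
    data.frame(group = lev, n = sum(sel),
               n_accepted = sum(accepted[sel]),
               accepted_fraction = mean(accepted[sel]))
  }))
  structure(list(decisions = decisions, summary = summary,
                 threshold_C = threshold_C),
            class = "seed_sorting")
}

#' @export
print.seed_sorting <- function(x, ...) {
  n <- nrow(x$decisions)
  cat(sprintf("<seed_sorting> %d seeds at threshold %g degC: %d accepted (%.0f%%)\n",
              n, x$threshold_C, sum(x$decisions$accepted),
              100 * mean(x$decisions$accepted)))
  if (nrow(x$summary) > 1L) print(x$summary)
  invisible(x)
}
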