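#' Fit the occupancy-to-OD600 calibration line
#'
#' Ordinary least squares of OD600 on droplet occupancy, built from droplets
#' sealed with media of known OD600. The regression direction matches the
#' screen's use case: measured occupancy is converted to an OD600 estimate.
#' One curve should be fitted per species, since cell size and contrast
#' differ.
#'
#' @param data data frame of calibration points.
#' @param occupancy,od columns (unquoted) with occupancy percent and OD600.
#' @return a `calibration_curve`: `slope` (OD600 per occupancy point),
#'   `intercept`, `r_squared`, `n_points`, `occupancy_range`. `tidy()` and
#'   `glance()` methods are provided.
#' @examples
#' tb <- tibble::tibble(occ = c(0, 40, 80), od = c(0, 0.8, 1.6))
#' fit_calibration(tb, occ, od)
#' @export
fit_calibration <- function(data, occupancy = occupancy_pct, od = od600) {
  occ <- dplyr::pull(data, {{ occupancy }})
  odv <- dplyr::pull(data, {{ od }})
  check_number(occ, "occupancy")
  check_number(odv, "od")
  if (length(occ) < 3) abort("calibration needs at least 3 points")
  if (sd(occ) == 0) abort("occupancy values are all identical; cannot fit")
  fit <- lm(odv ~ occ)
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((odv - mean(odv))^2)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
                 n_points = length(occ),
                 occupancy_range = range(occ)),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat("Occupancy -> OD600 calibration\n")
  cat(sprintf("  OD600 = %.5g + %.5g * occupancy%%   (R^2 = %.4f, n = %d)\n",
              x$intercept, x$slope, x$r_squared, x$n_points))
  invisible(x)
}

#' @export
tidy.calibration_curve <- function(x, ...) {
  tibble(term = c("intercept", "slope"),
         estimate = c(x$intercept, x$slope))
}

#' @export
glance.calibration_curve <- function(x, ...) {
  tibble(r.squared = x$r_squared, n = x$n_points)
}

#' Convert measured occupancy to OD600
#'
#' Applies a fitted [fit_calibration()] line. Values outside the occupancy
#' range used to fit the curve are converted anyway but flagged as
#' extrapolated.
#'
#' @param curve a `calibration_curve`.
#' @param occupancy_pct occupancy values in percent.
#' @return tibble: `occupancy_pct`, `od600`, `extrapolated`.
#' @examples
#' cc <- fit_calibration(tibble::tibble(o = c(0, 40, 80), d = c(0, .8, 1.6)),
#'                       o, d)
#' occupancy_to_od(cc, 50)
#' @export
occupancy_to_od <- function(curve, occupancy_pct) {
  stopifnot(inherits(curve, "calibration_curve"))
  check_number(occupancy_pct, "occupancy_pct")
  tibble(occupancy_pct = occupancy_pct,
         od600 = curve$intercept + curve$slope * occupancy_pct,
         extrapolated = occupancy_pct < curve$occupancy_range[1] |
           occupancy_pct > curve$occupancy_range[2])
}

#' Run a full synthetic calibration experiment
#'
#' End-to-end exercise of the calibration workflow: render one droplet image
#' per OD600 level with the default generator noise, measure each image
#' through droplet detection and interior segmentation, and fit the
#' occupancy-to-OD600 line. The defaults define the package's standard
#' scenario: six OD600 levels spanning the linear range at 50 occupancy
#' points per OD unit.
#'
#' @param seed integer seed for the rendering.
#' @param spec an [image_spec()]; the default carries the standard noise.
#' @param od_values OD600 levels imaged.
#' @param occupancy_per_od occupancy points per OD600 unit.
#' @return list: `curve` (the fitted `calibration_curve`) and `data` (per
#'   image: `od600`, measured `occupancy_pct`).
#' @examples
#' \donttest{
#' run_calibration_experiment(seed = 1)$curve
#' }
#' @export
run_calibration_experiment <- function(seed, spec = image_spec(),
                                       od_values = c(0.1, 0.4, 0.7, 1.0,
                                                     1.3, 1.6),
                                       occupancy_per_od = 50) {
  series <- generate_calibration_series(spec, od_values = od_values,
                                        occupancy_per_od = occupancy_per_od,
                                        seed = seed)
  measured <- measure_droplets(series$image)
  data <- tibble(od600 = series$od600,
                 occupancy_pct = measured$occupancy_pct)
  list(curve = fit_calibration(data), data = data)
}

#' @describeIn fit_calibration plot calibration points with the fitted line.
#' @param object a `calibration_curve`.
#' @param data optional data frame with `occupancy_pct` and `od600` columns.
#' @param ... ignored.
#' @export
autoplot.calibration_curve <- function(object, data = NULL, ...) {
  p <- ggplot2::ggplot() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "steelblue") +
    ggplot2::labs(x = "occupancy (%)", y = "OD600",
                  title = sprintf("R^2 = %.4f", object$r_squared))
  if (!is.null(data)) {
    p <- p + ggplot2::geom_point(
      data = data, ggplot2::aes(.data$occupancy_pct, .data$od600))
  }
  p
}
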