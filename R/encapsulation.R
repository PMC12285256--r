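#' Poisson encapsulation probability
#'
#' Probability that a droplet receives exactly `k` cells when loading is
#' Poisson with mean `lambda` cells per droplet.
#'
#' @param k non-negative integer cell count(s).
#' @param lambda mean cells per droplet (>= 0).
#' @return probability (vectorised over `k`).
#' @examples
#' poisson_pmf(0, 0.314)
#' @export
poisson_pmf <- function(k, lambda) {
  check_number(k, "k", min = 0)
  if (any(k != floor(k))) abort("`k` must be integer-valued")
  check_scalar(lambda, "lambda", min = 0)
  dpois(k, lambda)
}

#' Fraction of droplets containing at least one cell
#'
#' `1 - exp(-lambda)`: the encapsulation rate. At `lambda = 1` this is
#' 63% to the nearest percent, the figure used to translate droplet counts
#' into microorganisms analysed.
#'
#' @param lambda mean cells per droplet (vectorised, >= 0).
#' @return occupied fraction in [0, 1).
#' @examples
#' occupied_fraction(1)      # 0.632...
#' occupied_fraction(0.213)
#' @export
occupied_fraction <- function(lambda) {
  check_number(lambda, "lambda", min = 0)
  -expm1(-lambda)
}

#' Estimate lambda from the observed empty-droplet fraction
#'
#' Inverse of [occupied_fraction()]: `lambda = -log(empty_fraction)`.
#'
#' @param empty_fraction fraction of droplets with no cells, in (0, 1].
#' @return estimated mean cells per droplet.
#' @export
estimate_lambda <- function(empty_fraction) {
  check_number(empty_fraction, "empty_fraction", min = .Machine$double.xmin,
               max = 1)
  -log(empty_fraction)
}

#' Droplet volume from its diameter
#'
#' Sphere volume `(pi/6) d^3`, returned in nanolitres. A 120 um droplet is
#' about 0.905 nL.
#'
#' @param droplet_diameter_um diameter in micrometres (> 0).
#' @return volume in nL.
#' @export
droplet_volume_nl <- function(droplet_diameter_um = 120) {
  check_number(droplet_diameter_um, "droplet_diameter_um",
               min = .Machine$double.xmin)
  pi / 6 * droplet_diameter_um^3 * 1e-6  # um^3 -> nL
}

#' Mean cells per droplet from a cell density
#'
#' `lambda = density x droplet volume`, linking hemocytometer counts to the
#' Poisson loading parameter.
#'
#' @param cells_per_ml cell density from a hemocytometer count (> 0 unless 0).
#' @param droplet_diameter_um droplet diameter in micrometres.
#' @return lambda, mean cells per droplet.
#' @examples
#' lambda_from_density(1.105e6, 120) # ~1
#' @export
lambda_from_density <- function(cells_per_ml, droplet_diameter_um = 120) {
  check_number(cells_per_ml, "cells_per_ml", min = 0)
  cells_per_ml * droplet_volume_nl(droplet_diameter_um) * 1e-6  # nL -> mL
}

#' Co-encapsulation fractions for two independently loaded strains
#'
#' With strains loaded independently at `lambda_a` and `lambda_b`, the
#' droplet population splits into empty, only-A, only-B and both classes by
#' products of Poisson zero/nonzero probabilities.
#'
#' @param lambda_a,lambda_b mean cells per droplet for each strain.
#' @return tibble with columns `class` (`none`, `only_a`, `only_b`, `both`)
#'   and `fraction`; fractions sum to 1.
#' @examples
#' mixture_fractions(0.250, 0.173)
#' @export
mixture_fractions <- function(lambda_a, lambda_b) {
  check_scalar(lambda_a, "lambda_a", min = 0)
  check_scalar(lambda_b, "lambda_b", min = 0)
  pa0 <- exp(-lambda_a)
  pb0 <- exp(-lambda_b)
  tibble(class = c("none", "only_a", "only_b", "both"),
         fraction = c(pa0 * pb0,
                      (1 - pa0) * pb0,
                      pa0 * (1 - pb0),
                      (1 - pa0) * (1 - pb0)))
}

#' Expected number of microorganisms analysed in a screen
#'
#' `n_droplets x (1 - exp(-lambda))`: the expected count of cell-bearing
#' droplets, i.e. microorganisms interrogated one-per-droplet. The headline
#' value is reported at 2 significant figures alongside the exact
#' expectation.
#'
#' @param n_droplets droplets analysed (>= 0).
#' @param lambda mean cells per droplet.
#' @return tibble: `n_droplets`, `lambda`, `expected_exact`,
#'   `expected_2sf`.
#' @examples
#' expected_cells_analyzed(1002443, 1) # ~630,000 at 2 s.f.
#' @export
expected_cells_analyzed <- function(n_droplets, lambda) {
  check_scalar(n_droplets, "n_droplets", min = 0)
  check_scalar(lambda, "lambda", min = 0)
  exact <- n_droplets * occupied_fraction(lambda)
  tibble(n_droplets = n_droplets, lambda = lambda,
         expected_exact = exact, expected_2sf = signif(exact, 2))
}
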