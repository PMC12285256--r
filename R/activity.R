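#' Kinetic slope of a fluorescence time course
#'
#' OLS slope of fluorescence on time over the read window (a 20-min kinetic
#' read by default uses the full series). An optional auto-trim restricts
#' the fit to the initial linear region by dropping trailing points until
#' the linear R-squared exceeds 0.99 (never below 3 points).
#'
#' @param data data frame with one row per read.
#' @param time,fluorescence columns (unquoted): minutes and intensity.
#' @param trim_linear auto-trim to the initial linear region?
#' @param trim_r2 linearity criterion used while trimming.
#' @return slope in intensity units per minute.
#' @examples
#' kinetic_slope(tibble::tibble(t = 0:20, f = 100 + 50 * (0:20)), t, f)
#' @export
kinetic_slope <- function(data, time = time_min, fluorescence = fluorescence,
                          trim_linear = FALSE, trim_r2 = 0.999) {
  t <- dplyr::pull(data, {{ time }})
  f <- dplyr::pull(data, {{ fluorescence }})
  check_number(t, "time")
  check_number(f, "fluorescence")
  if (length(t) < 3) abort("kinetic slope needs at least 3 points")
  if (is.unsorted(t, strictly = TRUE)) abort("times must be strictly increasing")
  n <- length(t)
  if (trim_linear) {
    while (n > 3) {
      fit <- lm(f[1:n] ~ t[1:n])
      # summary.lm warns on numerically perfect fits; that is the stop case
      r2 <- suppressWarnings(summary(fit)$r.squared)
      if (is.na(r2) || r2 >= trim_r2) break
      n <- n - 1
    }
  }
  unname(coef(lm(f[1:n] ~ t[1:n]))[2])
}

#' Fit a linear standard curve (Nma fluorescence or Bradford protein)
#'
#' OLS of signal on standard amount, with the fitted intercept retained
#' (the curve is not forced through the origin). The valid range is the
#' span of the standards: 16 pmol–1 nmol Nma equivalents for the
#' fluorogenic-substrate curve, 0–0.25 mg/mL gamma globulin for Bradford.
#'
#' @param data data frame of standards.
#' @param amount,signal columns (unquoted): standard amount and measured
#'   signal.
#' @param kind `"nma_fluorescence"` or `"bradford_protein"`.
#' @return a `standard_curve`: `kind`, `slope` (signal per amount unit),
#'   `intercept`, `r_squared`, `valid_range`, `n`.
#' @export
fit_standard_curve <- function(data, amount = amount, signal = signal,
                               kind = c("nma_fluorescence",
                                        "bradford_protein")) {
  kind <- match.arg(kind)
  a <- dplyr::pull(data, {{ amount }})
  s <- dplyr::pull(data, {{ signal }})
  check_number(a, "amount")
  check_number(s, "signal")
  if (length(a) < 3) abort("standard curve needs at least 3 standards")
  if (sd(a) == 0) abort("degenerate standards: amounts are all identical")
  fit <- lm(s ~ a)
  if (coef(fit)[2] <= 0) abort("standard curve slope must be positive")
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((s - mean(s))^2)
  structure(list(kind = kind, slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
                 valid_range = range(a), n = length(a)),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("standard_curve [%s]: signal = %.5g + %.5g * amount (R^2 = %.4f)\n",
              x$kind, x$intercept, x$slope, x$r_squared))
  cat(sprintf("  valid range: %.4g to %.4g\n", x$valid_range[1],
              x$valid_range[2]))
  invisible(x)
}

#' @export
tidy.standard_curve <- function(x, ...) {
  tibble(term = c("intercept", "slope"),
         estimate = c(x$intercept, x$slope))
}

#' @export
glance.standard_curve <- function(x, ...) {
  tibble(kind = x$kind, r.squared = x$r_squared, n = x$n)
}

#' Invert a standard curve: signal to amount
#'
#' @param curve a [fit_standard_curve()] result.
#' @param signal measured signal(s).
#' @return tibble: `signal`, `amount`, `extrapolated` (outside the standard
#'   range).
#' @export
signal_to_amount <- function(curve, signal) {
  stopifnot(inherits(curve, "standard_curve"))
  check_number(signal, "signal")
  amount <- (signal - curve$intercept) / curve$slope
  tibble(signal = signal, amount = amount,
         extrapolated = amount < curve$valid_range[1] |
           amount > curve$valid_range[2])
}

#' Specific protease activity per mg of supernatant protein
#'
#' Fluorescence intensity increase per minute divided by the protein mass
#' (mg) in the assayed supernatant aliquot.
#'
#' @param dF_per_min kinetic slope, intensity/min (vectorised).
#' @param protein_mg protein mass in the reaction, mg (> 0).
#' @return specific activity, intensity/min/mg.
#' @examples
#' specific_activity(500, 0.25) # 2000
#' @export
specific_activity <- function(dF_per_min, protein_mg) {
  check_number(dF_per_min, "dF_per_min")
  check_number(protein_mg, "protein_mg", min = .Machine$double.xmin)
  dF_per_min / protein_mg
}

#' Volumetric activity in IU/mL via the Nma standard curve
#'
#' Converts a fluorescence slope to product formation (nmol Nma equivalents
#' per minute) through the Nma curve slope, then to international units
#' (umol/min) referred to the supernatant volume in the reaction (50 uL by
#' default, matching a 50 uL + 50 uL assay mix).
#'
#' @param dF_per_min kinetic slope, intensity/min.
#' @param nma_curve a `standard_curve` of kind `nma_fluorescence` with
#'   amounts in nmol.
#' @param supernatant_volume_ml supernatant volume assayed, mL.
#' @return activity in IU/mL (umol/min/mL supernatant).
#' @export
activity_iu_per_ml <- function(dF_per_min, nma_curve,
                               supernatant_volume_ml = 0.05) {
  stopifnot(inherits(nma_curve, "standard_curve"))
  if (nma_curve$kind != "nma_fluorescence") {
    abort("`nma_curve` must be an Nma fluorescence standard curve")
  }
  check_number(dF_per_min, "dF_per_min", min = 0)
  check_scalar(supernatant_volume_ml, "supernatant_volume_ml",
               min = .Machine$double.xmin)
  nmol_per_min <- dF_per_min / nma_curve$slope
  (nmol_per_min / 1000) / supernatant_volume_ml
}

#' Express activities relative to a reference strain
#'
#' Adds `relative_pct = 100 * specific_activity / reference activity`; the
#' reference strain gets exactly 100.
#'
#' @param records data frame with `strain_id` and `specific_activity`
#'   columns.
#' @param reference_strain `strain_id` of the 100% reference.
#' @return `records` with a `relative_pct` column appended.
#' @examples
#' tb <- tibble::tibble(strain_id = c("ref", "x"),
#'                      specific_activity = c(100, 240))
#' relative_to_reference(tb, "ref")
#' @export
relative_to_reference <- function(records, reference_strain) {
  if (!all(c("strain_id", "specific_activity") %in% names(records))) {
    abort("`records` needs `strain_id` and `specific_activity` columns")
  }
  ref <- records$specific_activity[records$strain_id == reference_strain]
  if (length(ref) != 1) abort("reference strain missing or duplicated")
  if (!is.finite(ref) || ref <= 0) abort("reference activity must be > 0")
  dplyr::mutate(records,
                relative_pct = 100 * .data$specific_activity / ref)
}

#' The 19 proteinogenic P1 residues assayed (no Cys)
#' @return character vector of 19 one-letter codes.
#' @export
p1_amino_acids <- function() {
  c("A", "R", "N", "D", "E", "Q", "G", "H", "I", "L",
    "K", "M", "F", "P", "S", "T", "W", "Y", "V")
}

#' Substrate P1-specificity profile
#'
#' Normalises activities against the 19 FRETS-25Xaa substrates (one per
#' amino acid in the P1 position, cysteine excluded) so the highest
#' activity is 100%.
#'
#' @param data data frame with 19 rows.
#' @param amino_acid,activity columns (unquoted): residue label and
#'   activity (IU/mL, >= 0).
#' @return tibble: `amino_acid`, `activity_iu_per_ml`, `relative_pct`
#'   (max exactly 100; ties at the maximum all 100).
#' @export
specificity_profile <- function(data, amino_acid = amino_acid,
                                activity = activity_iu_per_ml) {
  aa <- dplyr::pull(data, {{ amino_acid }})
  act <- dplyr::pull(data, {{ activity }})
  if (length(aa) != 19) abort("a specificity profile has exactly 19 residues")
  if (anyDuplicated(aa)) abort("duplicate amino-acid labels")
  check_number(act, "activity", min = 0)
  if (all(act == 0)) abort("all activities are zero; profile undefined")
  tibble(amino_acid = aa, activity_iu_per_ml = act,
         relative_pct = 100 * act / max(act))
}

#' Plot a substrate-specificity profile
#'
#' @param profile tibble from [specificity_profile()].
#' @return a ggplot bar chart of relative activity per P1 residue.
#' @export
plot_specificity <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$amino_acid,
                                        y = .data$relative_pct)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = "P1 residue", y = "relative activity (%)")
}
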