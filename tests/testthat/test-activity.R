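test_that("kinetic slopes are exact on linear series and guarded", {
  lin <- tibble::tibble(time_min = 0:20, fluorescence = 100 + 50 * (0:20))
  expect_equal(kinetic_slope(lin), 50)
  flat <- tibble::tibble(time_min = 0:10, fluorescence = rep(300, 11))
  expect_equal(kinetic_slope(flat), 0)
  expect_error(kinetic_slope(lin[1:2, ]), "3 points")

  set.seed(4)
  noisy <- tibble::tibble(time_min = 0:20,
                          fluorescence = 10 * (0:20) + rnorm(21, 0, 5))
  fit <- lm(fluorescence ~ time_min, noisy)
  se <- summary(fit)$coefficients["time_min", "Std. Error"]
  expect_lt(abs(kinetic_slope(noisy) - 10), 3 * se)

  # auto-trim recovers the initial slope when the curve saturates
  sat <- tibble::tibble(time_min = 0:20,
                        fluorescence = pmin(40 * (0:20), 300))
  expect_equal(kinetic_slope(sat, trim_linear = TRUE), 40, tolerance = 0.02)
})

test_that("standard curves fit, invert and record their valid range", {
  nma_amt <- c(0.016, 0.05, 0.1, 0.25, 0.5, 1) # nmol
  standards <- tibble::tibble(amount = nma_amt,
                              signal = 12 + 4800 * nma_amt)
  cc <- fit_standard_curve(standards, kind = "nma_fluorescence")
  expect_equal(cc$slope, 4800)
  expect_equal(cc$intercept, 12)
  expect_equal(cc$r_squared, 1)
  expect_equal(cc$valid_range, c(0.016, 1))

  # inverse prediction on a held-out standard within 2%
  set.seed(12)
  noisy <- tibble::tibble(amount = nma_amt,
                          signal = 12 + 4800 * nma_amt + rnorm(6, 0, 5))
  cn <- fit_standard_curve(noisy, kind = "nma_fluorescence")
  held_out <- 0.35
  est <- signal_to_amount(cn, 12 + 4800 * held_out)$amount
  expect_lt(abs(est - held_out) / held_out, 0.02)

  expect_error(fit_standard_curve(standards[1, ]), "3 standards")
  expect_error(fit_standard_curve(
    tibble::tibble(amount = rep(1, 4), signal = 1:4)), "degenerate")
})

test_that("bradford curve covers the 0-0.25 mg/mL range", {
  br <- tibble::tibble(amount = seq(0, 0.25, length.out = 6),
                       signal = 0.05 + 2.4 * seq(0, 0.25, length.out = 6))
  cb <- fit_standard_curve(br, kind = "bradford_protein")
  expect_equal(cb$valid_range, c(0, 0.25))
  expect_false(signal_to_amount(cb, 0.05 + 2.4 * 0.1)$extrapolated)
  expect_true(signal_to_amount(cb, 0.05 + 2.4 * 0.4)$extrapolated)
})

test_that("specific activity is the exact quotient with guarded domain", {
  expect_equal(specific_activity(500, 0.25), 2000)
  expect_equal(specific_activity(0, 1), 0)
  expect_error(specific_activity(10, 0), ">=")
})

test_that("relative activity sets the reference to exactly 100", {
  tb <- tibble::tibble(strain_id = c("p_mexicana", "iso1", "iso2"),
                       specific_activity = c(80, 192, 40))
  out <- relative_to_reference(tb, "p_mexicana")
  expect_equal(out$relative_pct, c(100, 240, 50))
  # scale invariance: common factor cancels
  out2 <- relative_to_reference(
    dplyr::mutate(tb, specific_activity = specific_activity * 3.7),
    "p_mexicana")
  expect_equal(out2$relative_pct, out$relative_pct)
  expect_error(relative_to_reference(tb, "absent"), "missing")
  expect_error(relative_to_reference(
    dplyr::mutate(tb, specific_activity = c(0, 1, 2)), "p_mexicana"), "> 0")
})

test_that("IU conversion is unit-consistent", {
  nma <- fit_standard_curve(
    tibble::tibble(amount = c(0.016, 0.1, 0.5, 1),
                   signal = 5000 * c(0.016, 0.1, 0.5, 1) + 3),
    kind = "nma_fluorescence")
  iu <- activity_iu_per_ml(500, nma, supernatant_volume_ml = 0.05)
  expect_equal(iu, (500 / 5000) / 1000 / 0.05)
  # doubling the referred volume at fixed product rate halves IU/mL
  expect_equal(activity_iu_per_ml(500, nma, 0.1), iu / 2)
  # scaling fluorescence units and the curve slope together cancels
  nma2 <- fit_standard_curve(
    tibble::tibble(amount = c(0.016, 0.1, 0.5, 1),
                   signal = 3 * (5000 * c(0.016, 0.1, 0.5, 1) + 3)),
    kind = "nma_fluorescence")
  expect_equal(activity_iu_per_ml(3 * 500, nma2, 0.05), iu)
})

test_that("specificity profiles normalise the best residue to 100", {
  aas <- p1_amino_acids()
  expect_length(aas, 19)
  expect_false("C" %in% aas)

  one <- tibble::tibble(amino_acid = aas,
                        activity_iu_per_ml = c(3, rep(0, 18)))
  prof <- specificity_profile(one)
  expect_equal(prof$relative_pct, c(100, rep(0, 18)))

  uniform <- tibble::tibble(amino_acid = aas,
                            activity_iu_per_ml = rep(2, 19))
  expect_equal(specificity_profile(uniform)$relative_pct, rep(100, 19))

  set.seed(14)
  rnd <- tibble::tibble(amino_acid = aas,
                        activity_iu_per_ml = runif(19, 0.01, 5))
  pr <- specificity_profile(rnd)
  expect_equal(max(pr$relative_pct), 100)
  expect_equal(which.max(pr$relative_pct), which.max(rnd$activity_iu_per_ml))
  expect_true(all(pr$relative_pct >= 0 & pr$relative_pct <= 100))

  expect_error(specificity_profile(
    tibble::tibble(amino_acid = aas, activity_iu_per_ml = rep(0, 19))),
    "zero")
  expect_error(specificity_profile(one[1:5, ]), "19")
})
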