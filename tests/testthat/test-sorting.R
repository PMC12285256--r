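test_that("the top-fraction gate selects the requested share", {
  tb <- tibble::tibble(intensity = as.numeric(1:1000))
  g <- top_fraction_gate(tb, 0.01)
  expect_equal(g$selected_count, 10)
  expect_true(all(which(g$selected) > 990))
  expect_lte(g$selected_count / g$n, 0.01 + 1 / g$n)
})

test_that("a tied population yields a degenerate, flagged gate", {
  tb <- tibble::tibble(intensity = rep(5, 100))
  g <- top_fraction_gate(tb, 0.01)
  expect_equal(g$selected_count, 0)
  expect_true(g$degenerate)
  expect_error(top_fraction_gate(tibble::tibble(intensity = numeric()), 0.01),
               "empty")
})

test_that("gate selection is invariant under strictly monotone transforms", {
  set.seed(3)
  tb <- tibble::tibble(intensity = rlnorm(5000, 3, 1))
  base <- top_fraction_gate(tb, 0.02)$selected
  for (f in list(function(x) 10 * x + 3, log, sqrt, function(x) x^3)) {
    tr <- tibble::tibble(intensity = f(tb$intensity))
    expect_identical(top_fraction_gate(tr, 0.02)$selected, base)
  }
})

test_that("a large simulated screen gates close to one percent", {
  pop <- generate_screen_population(2e5, c(p_mexicana = 0.25,
                                           e_coli = 0.173), seed = 31)
  g <- top_fraction_gate(pop, 0.01)
  expect_lt(abs(g$selected_count / g$n - 0.01), 0.0005)
})

test_that("threshold-exceedance fractions behave and decrease", {
  tb <- tibble::tibble(intensity = c(10, 20, 30, 40))
  fe <- fraction_exceeding(tb, c(0, 25, 100))
  expect_equal(fe$fraction, c(1, 0.5, 0))
  set.seed(5)
  rnd <- tibble::tibble(intensity = rlnorm(2000, 3, 1.5))
  fr <- fraction_exceeding(rnd, c(1000, 2000, 3000, 4000, 5000))
  expect_true(all(diff(fr$fraction) <= 0))
  expect_error(fraction_exceeding(rnd, c(5, 1)), "sorted")
})

test_that("exceedance above a fixed cut grows with culture time", {
  fracs <- vapply(c(24, 48, 72), function(tt) {
    pop <- generate_screen_population(5000, c(p_mexicana = 0.25),
                                      culture_time_h = tt, seed = 37)
    fraction_exceeding(pop, 1000)$fraction
  }, numeric(1))
  expect_true(all(diff(fracs) >= 0))
})

test_that("histograms conserve counts and reject bad log input", {
  set.seed(6)
  tb <- tibble::tibble(intensity = rlnorm(3000, log(14), 0.35))
  h <- intensity_histogram(tb, n_bins = 30)
  expect_equal(sum(h$count), 3000)
  hl <- intensity_histogram(tb, n_bins = 17, log_axis = FALSE)
  expect_equal(sum(hl$count), 3000)
  expect_equal(nrow(intensity_histogram(tibble::tibble(intensity = numeric()))),
               0)
  one <- intensity_histogram(tibble::tibble(intensity = rep(7, 50)))
  expect_equal(sum(one$count), 50)
  expect_error(intensity_histogram(tibble::tibble(intensity = c(-1, 2))),
               "positive")
})

test_that("the empty-droplet fluorescence peak sits in the 10-20 band", {
  pop <- generate_screen_population(3e4, c(p_mexicana = 0, e_coli = 0),
                                    seed = 41)
  h <- intensity_histogram(pop, n_bins = 40)
  modal <- h$bin_mid[which.max(h$count)]
  expect_gte(modal, 10)
  expect_lte(modal, 20)
})

test_that("gate composition partitions droplets and respects the gate", {
  pop <- generate_screen_population(5000, c(p_mexicana = 0.25,
                                            e_coli = 0.173), seed = 43)
  gate <- top_fraction_gate(pop, 0.01)
  comp <- gate_composition(pop, gate)
  expect_equal(sum(comp$n_pre), 5000)
  expect_equal(sum(comp$n_post), gate$selected_count)
  expect_true(all(comp$n_post <= comp$n_pre))
  expect_error(gate_composition(pop, gate, strain_cols = "nope"), "unknown")

  # single-strain table never produces a multiple class
  solo <- generate_screen_population(1000, c(p_mexicana = 0.3), seed = 44)
  comp_solo <- gate_composition(solo, top_fraction_gate(solo, 0.05))
  expect_false("multiple" %in% comp_solo$class)

  # a gate selecting nothing leaves all post counts at zero
  g0 <- fixed_threshold_gate(pop, max(pop$intensity) + 1)
  expect_true(all(gate_composition(pop, g0)$n_post == 0))
})

test_that("a low gate isolates the weak strain exclusively", {
  # strong producer droplets sit far above the empties; gating below the
  # producer band must recover only empties and the weak strain
  pop <- generate_screen_population(2e4, c(p_mexicana = 0.25,
                                           e_coli = 0.173), seed = 47)
  producer <- pop$p_mexicana > 0
  low_cut <- min(pop$intensity[producer]) * 0.99
  low <- dplyr::filter(pop, intensity < low_cut)
  expect_equal(sum(low$p_mexicana), 0)
  expect_gt(sum(low$e_coli > 0), 0)

  # enrichment property: gating the top never reduces producer frequency
  gate <- top_fraction_gate(pop, 0.05)
  expect_gte(mean(producer[gate$selected]), mean(producer))
})
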