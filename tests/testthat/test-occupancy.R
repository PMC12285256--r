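test_that("droplet detection recovers the rendered geometry", {
  g <- generate_droplet_image(small_spec(), 30, seed = 3)
  geom <- detect_droplet(g$image)
  expect_lt(abs(geom$radius_px - g$geometry$radius_px), 2)
  expect_lt(abs(geom$center_x - g$geometry$center_x), 2)
  expect_lt(abs(geom$center_y - g$geometry$center_y), 2)
  # fitted circle covers >= 95% of true droplet pixels
  nr <- nrow(g$image$pixels)
  true_circ <- dropscreen:::circle_mask(nr, ncol(g$image$pixels),
                                        g$geometry$center_x,
                                        g$geometry$center_y,
                                        g$geometry$radius_px)
  est_circ <- dropscreen:::circle_mask(nr, ncol(g$image$pixels),
                                       geom$center_x, geom$center_y,
                                       geom$radius_px)
  expect_gt(sum(true_circ & est_circ) / sum(true_circ), 0.95)
})

test_that("blank and edge-touching frames are rejected", {
  set.seed(42)
  blank <- droplet_image(matrix(0.9, 96, 96) +
                           matrix(rnorm(96^2, 0, 0.01), 96), 1)
  expect_error(detect_droplet(blank), "no droplet")

  # shift the droplet so it crosses the frame edge
  g <- generate_droplet_image(small_spec(0), 20, seed = 4)
  px <- g$image$pixels
  shifted <- cbind(px[, 61:112], px[, 1:60])
  expect_error(detect_droplet(droplet_image(shifted, 1.5)), "edge")
})

test_that("segmentation handles empty, confluent and partial droplets", {
  spec0 <- small_spec(0)
  for (target in c(0, 100)) {
    g <- generate_droplet_image(spec0, target, seed = 6)
    m <- measure_image(g$image)
    expect_equal(m$occupancy_pct, target)
    if (target == 0) expect_equal(m$a_ex_px, m$a_droplet_px)
    if (target == 100) expect_equal(m$a_ex_px, 0)
  }
  g84 <- generate_droplet_image(spec0, 84, seed = 6)
  expect_lt(abs(measure_image(g84$image)$occupancy_pct - 84), 2)
})

test_that("occupancy formula is exact and guards its domain", {
  expect_equal(compute_occupancy(10000, 10000), 0)
  expect_equal(compute_occupancy(10000, 0), 100)
  expect_equal(compute_occupancy(10000, 1600), 84)
  expect_error(compute_occupancy(10000, 10001), "exceed")
  expect_error(compute_occupancy(0, 0), ">=")
})

test_that("estimator tracks rendered ground truth on noise-free fixtures", {
  set.seed(7)
  targets <- runif(12, 2, 98)
  errs <- vapply(seq_along(targets), function(i) {
    g <- generate_droplet_image(small_spec(0), targets[i], n_blobs = 10,
                                seed = 700 + i)
    measure_image(g$image)$occupancy_pct - g$truth$occupancy_pct
  }, numeric(1))
  expect_lt(max(abs(errs)), 1)
})

test_that("occupancy is invariant under affine intensity rescaling", {
  g <- generate_droplet_image(small_spec(), 35, seed = 8)
  base <- measure_image(g$image)$occupancy_pct
  for (ab in list(c(0.5, 0.1), c(0.8, 0.15), c(1.0, -0.05))) {
    rescaled <- droplet_image(pmin(pmax(ab[1] * g$image$pixels + ab[2], 0), 1),
                              g$image$um_per_px)
    expect_equal(measure_image(rescaled)$occupancy_pct, base,
                 tolerance = 1e-6)
  }
})

test_that("adding cell area never decreases estimated occupancy", {
  est <- vapply(c(10, 30, 50, 70, 90), function(target) {
    g <- generate_droplet_image(small_spec(0), target, n_blobs = 8,
                                seed = 99)
    measure_image(g$image)$occupancy_pct
  }, numeric(1))
  expect_true(all(diff(est) > 0))
})

test_that("batch measurement reports replicate mean and SD", {
  images <- lapply(1:5, function(i) {
    generate_droplet_image(small_spec(), 40, seed = 40 + i)$image
  })
  tb <- measure_droplets(images)
  expect_equal(nrow(tb), 5)
  expect_equal(tb$droplet_id, 1:5)
  st <- occupancy_stats(tb)
  expect_equal(st$n, 5)
  expect_equal(st$mean_occupancy_pct, mean(tb$occupancy_pct))
  expect_equal(st$sd_occupancy_pct, sd(tb$occupancy_pct))
  expect_lt(abs(st$mean_occupancy_pct - 40), 1.5)
})

test_that("a user-supplied geometry bypasses automatic detection", {
  g <- generate_droplet_image(small_spec(0), 50, seed = 12)
  manual <- tibble::tibble(center_x = g$geometry$center_x,
                           center_y = g$geometry$center_y,
                           radius_px = g$geometry$radius_px)
  m <- measure_image(g$image, geometry = manual)
  expect_equal(m$a_droplet_px, g$truth$a_droplet_px)
  expect_lt(abs(m$occupancy_pct - g$truth$occupancy_pct), 1)
})
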