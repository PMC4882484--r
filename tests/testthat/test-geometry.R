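# RF pattern geometry: modulator waveform, radius profiles, composites,
# contour sampling and lobe counting.

test_that("triangular modulator reduces to the pure sinusoid at spikiness 0", {
  expect_identical(triangular_modulator(0, frequency = 4), sin(0))
  expect_equal(triangular_modulator(pi / 8, frequency = 4), 1)
  # bit-identical to the closed form over a grid
  th <- seq(0, 2 * pi, length.out = 257)
  expect_identical(triangular_modulator(th, frequency = 7, phase = 0.3),
                   sin(7 * th + 0.3))
})

test_that("modulator rejects invalid parameters", {
  expect_error(triangular_modulator(0, frequency = 0), "frequency")
  expect_error(triangular_modulator(0, frequency = 4, spikiness = -1),
               "spikiness")
  expect_error(rf_spec(frequency = 4, amplitude = 1.2), "amplitude")
  expect_error(rf_spec(frequency = 4, amplitude = 0.2, r_mean = 0), "r_mean")
})

test_that("modulator has unit peak for every design frequency/spikiness pair", {
  th <- seq(0, 2 * pi, length.out = 1e5)
  for (w in 4:9) {
    for (k in c(0L, 1L, 30L)) {
      m <- triangular_modulator(th, frequency = w, spikiness = k)
      expect_lt(abs(max(m) - 1), 1e-6)
      expect_lte(max(abs(m)), 1 + 1e-12)
    }
  }
})

test_that("high-spikiness modulator tracks an ideal triangle wave", {
  th <- seq(0, 2 * pi, length.out = 1e5)
  m <- triangular_modulator(th, frequency = 4, spikiness = 30)
  tri <- triangle_wave(4 * th)
  expect_gt(stats::cor(m, tri), 0.99)
  expect_lt(abs(max(m) - 1), 1e-6)
})

test_that("zero amplitude gives a circle for any frequency, phase, spikiness", {
  th <- seq(0, 2 * pi, length.out = 1000)
  for (w in c(4L, 7L, 9L)) {
    for (k in c(0L, 30L)) {
      spec <- rf_spec(frequency = w, amplitude = 0, phase = 1.1,
                      spikiness = k, r_mean = 2.5)
      expect_lt(max(abs(radius_profile(spec, th) - 2.5)), 1e-9)
    }
  }
})

test_that("radius profile peaks at r_mean * (1 + amplitude)", {
  expect_equal(radius_profile(rf_spec(4, 0.4), pi / 8), 1.4)
  th <- seq(0, 2 * pi, length.out = 2e5)
  r <- radius_profile(rf_spec(frequency = 5, amplitude = 0.3, spikiness = 1),
                      th)
  expect_lt(abs(max(r) - 1.3), 1e-4)
  expect_true(all(r >= 1 - 0.3 - 1e-12 & r <= 1 + 0.3 + 1e-12))
})

test_that("composite radius matches the preset peak arithmetic", {
  single <- composite_spec(7L, 0.4, pi / 2)
  expect_equal(composite_radius(single, 0), 1.4)
  expect_equal(radius_profile(composite_preset("angular"), 0),
               1 + 0.4 + 0.2 + 0.1 + 0.05 + 0.025)
  expect_equal(radius_profile(composite_preset("rounded"), 0),
               1 + 0.4 - 0.2 + 0.1 - 0.05 + 0.025)
  # a composite whose summed modulation reaches -1 is rejected
  expect_error(composite_spec(4L, 1.2, pi / 2), "non-positive")
})

test_that("sampled contours are closed, well-sized and star-shaped", {
  cont <- sample_contour(rf_spec(4, 0), n_points = 4096)
  d <- sqrt(rowSums(cont$vertices^2))
  expect_lt(max(abs(d - 1)), 1e-9)
  expect_identical(cont$vertices[1, ], cont$vertices[nrow(cont$vertices), ])
  expect_identical(nrow(cont$vertices), 4097L)
  expect_error(sample_contour(rf_spec(4, 0.1), n_points = 8), "n_points")
  # no self-intersection across the 72 design conditions (segment oracle)
  grid <- design_grid(stimulus_design())
  for (i in seq_len(nrow(grid))) {
    cont <- sample_contour(rf_spec(grid$frequency[i], grid$amplitude[i],
                                   spikiness = grid$spikiness[i]),
                           n_points = 128)
    expect_false(polygon_self_intersects(cont$vertices))
  }
})

test_that("lobe count equals the radial frequency for all design conditions", {
  expect_identical(count_lobes(sample_contour(rf_spec(4, 0))), 0L)
  grid <- design_grid(stimulus_design())
  counts <- integer(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cont <- sample_contour(rf_spec(grid$frequency[i], grid$amplitude[i],
                                   spikiness = grid$spikiness[i]),
                           n_points = 2048)
    counts[i] <- count_lobes(cont)
  }
  expect_identical(counts, grid$frequency)
  expect_identical(count_lobes(sample_contour(composite_preset("angular"))),
                   7L)
})

test_that("changing phase rotates the contour", {
  n <- 4096L
  w <- 6L
  shift <- 17L
  delta <- w * 2 * pi * shift / n            # grid-aligned phase change
  c1 <- sample_contour(rf_spec(w, 0.3, spikiness = 1), n_points = n)
  c2 <- sample_contour(rf_spec(w, 0.3, phase = delta, spikiness = 1),
                       n_points = n)
  ang <- -2 * pi * shift / n                  # rotation by -delta / w
  rot <- cbind(c1$vertices[, 1] * cos(ang) - c1$vertices[, 2] * sin(ang),
               c1$vertices[, 1] * sin(ang) + c1$vertices[, 2] * cos(ang))
  # rotated original = new contour up to a circular index shift
  idx <- c((shift + 1):n, 1:shift)
  expect_lt(max(abs(rot[idx, ] - c2$vertices[seq_len(n), ])), 1e-6)
})

test_that("spikes sharpen monotonically with the harmonic count", {
  th <- seq(0, 2 * pi, length.out = 20000)
  curv <- sapply(c(0L, 1L, 30L), function(k) {
    r <- radius_profile(rf_spec(5, 0.3, spikiness = k), th)
    max(abs(diff(r, differences = 2)))
  })
  expect_true(all(diff(curv) >= 0))
})

test_that("the factorial design crosses to the expected conditions", {
  grid <- design_grid(stimulus_design())
  expect_identical(nrow(grid), 72L)
  expect_identical(nrow(unique(grid)), 72L)
  small <- design_grid(mini_design())
  expect_identical(nrow(small), 12L)
  expect_error(stimulus_design(frequency = c(4, 4)), "distinct")
})
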