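test_that("the wavenumber-distance correlation and its inverse behave", {
  # direct evaluation at the bulk-water most-probable distance
  expect_equal(distance_to_wavenumber(2.827),
               2727 - exp(16.01 - 3.73 * 2.827), tolerance = 1e-12)
  expect_equal(distance_to_wavenumber(2.827), 2490.6, tolerance = 1e-4)
  # exponent-zero point
  expect_equal(distance_to_wavenumber(16.01 / 3.73), 2726)
  expect_equal(wavenumber_to_distance(2726), 16.01 / 3.73)
  # strict monotonicity
  r <- seq(2.4, 3.4, 0.05)
  expect_true(all(diff(distance_to_wavenumber(r)) > 0))
  # inverse pair over the hydrogen-bond range
  r <- seq(2.3, 3.5, 1e-3)
  expect_lt(max(abs(wavenumber_to_distance(distance_to_wavenumber(r)) - r)),
            1e-9)
  expect_error(wavenumber_to_distance(2727), "2727")
  expect_error(distance_to_wavenumber(0), "> 0")
})

test_that("band_maximum refines the discrete peak quadratically", {
  g <- seq(2300, 2700, 4)
  s <- gaussian_band(2496, 60, g)
  expect_equal(band_maximum(s), 2496, tolerance = 0.5)

  # monotone segment: boundary maximum is flagged
  s2 <- hdo_spectrum(seq(2400, 2500, 10), seq(0.1, 1.1, 0.1))
  m <- band_maximum(s2, window = c(2400, 2500))
  expect_true(isTRUE(attr(m, "boundary")))
  expect_equal(as.numeric(m), 2500)

  # flat segment is degenerate
  s3 <- hdo_spectrum(seq(2400, 2500, 10), rep(1, 11))
  expect_error(band_maximum(s3, window = c(2400, 2500)), "flat")
})

test_that("gravity_center is the first moment of the band", {
  g <- seq(2200, 2700, 0.5)
  # symmetric band: center recovered to high accuracy
  s <- gaussian_band(2450, 40, g)
  expect_equal(gravity_center(s, window = c(2250, 2650)), 2450,
               tolerance = 1e-6)

  # two equal-area peaks at 2400 and 2600 balance at 2500
  s2 <- hdo_spectrum(g, exp(-(g - 2400)^2 / 800) + exp(-(g - 2600)^2 / 800))
  expect_equal(gravity_center(s2, window = c(2200, 2700)), 2500,
               tolerance = 1e-6)

  # red-tailed skewed band: gravity center below the maximum, as in
  # experimental HDO bands; oracle is the dense numerical moment
  sk <- make_band(2560, 95, -1.54, grid = g)
  gc <- gravity_center(sk, window = range(g))
  oracle <- sum(g * sk$value) / sum(sk$value)
  expect_equal(gc, oracle, tolerance = 1e-3)
  expect_lt(gc, band_maximum(sk, window = range(g)))

  expect_error(gravity_center(hdo_spectrum(g, rep(0, length(g))),
                              window = c(2300, 2600)), "zero integrated")
})

test_that("distance distributions conserve probability and match the flat-band closed form", {
  g <- seq(2000, 2800, 1)
  # flat spectrum: p(R) proportional to the Jacobian, normalised
  flat <- hdo_spectrum(g, rep(1, length(g)), unit = "molar_absorption")
  pd <- distance_distribution(flat, r_range = c(2.6, 3.2))
  r <- pd$r_grid
  jac <- 3.73 * exp(16.01 - 3.73 * r)
  closed <- jac / pracma::trapz(r, jac)
  expect_lt(max(abs(pd$p_values - closed) / max(closed)), 1e-6)
  expect_equal(pracma::trapz(r, pd$p_values), 1, tolerance = 1e-6)

  # normalization holds for random skew-normal bands
  set.seed(3)
  for (i in 1:20) {
    b <- make_band(runif(1, 2350, 2600), runif(1, 40, 120),
                   runif(1, -4, 1), grid = g)
    p <- distance_distribution(b)
    expect_equal(pracma::trapz(p$r_grid, p$p_values), 1, tolerance = 1e-6)
    expect_true(all(p$p_values >= 0))
  }
})

test_that("the Jacobian shifts the distribution maximum off the naive image", {
  g <- seq(2000, 2800, 0.5)
  widths <- c(40, 20, 10, 5)
  offs <- vapply(widths, function(w) {
    b <- gaussian_band(2500, w, g)
    pd <- distance_distribution(b, r_range = c(2.55, 3.05))
    # dense brute-force oracle agrees with the implementation
    bf <- brute_force_distribution(b, 2.55, 3.05)
    expect_equal(pd$r_max, bf$r[which.max(bf$p)], tolerance = 1e-3)
    abs(pd$r_max - wavenumber_to_distance(2500))
  }, numeric(1L))
  # offset shrinks strictly as the band narrows
  expect_true(all(diff(offs) < 0))
})

test_that("red-shifting a band shifts the distance distribution to shorter R", {
  g <- seq(2000, 2800, 1)
  p1 <- distance_distribution(gaussian_band(2450, 60, g))
  p2 <- distance_distribution(gaussian_band(2500, 60, g))
  expect_lt(p1$r_max, p2$r_max)
  expect_lt(p1$r_gravity, p2$r_gravity)
})

test_that("distribution differences integrate to zero and sign the shift", {
  g <- seq(2000, 2800, 1)
  p1 <- distance_distribution(gaussian_band(2450, 60, g),
                              r_range = c(2.55, 3.2))
  p2 <- distance_distribution(gaussian_band(2500, 60, g),
                              r_range = c(2.55, 3.2))
  # identical inputs: identically zero
  d0 <- distribution_difference(p1, p1)
  expect_equal(max(abs(d0$dp)), 0)

  # strengthening signature: positive below the crossing, negative above
  d <- distribution_difference(p1, p2)
  expect_equal(pracma::trapz(d$r_grid, d$dp), 0, tolerance = 1e-6)
  cross <- d$r_grid[which(diff(sign(d$dp)) != 0)][1L]
  expect_true(all(d$dp[d$r_grid < cross - 0.05] >= 0))
  expect_true(any(d$dp[d$r_grid > cross + 0.02] < 0))
})

test_that("negative baselines are clipped within tolerance, rejected beyond", {
  g <- seq(2000, 2800, 1)
  b <- gaussian_band(2500, 60, g)
  small <- hdo_spectrum(g, b$value - 0.005 * max(b$value),
                        unit = "molar_absorption")
  expect_warning(distance_distribution(small), "clipping")
  big <- hdo_spectrum(g, b$value - 0.05 * max(b$value),
                      unit = "molar_absorption")
  expect_error(distance_distribution(big), "negative")
})
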