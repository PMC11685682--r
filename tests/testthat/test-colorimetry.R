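test_that("sRGB transfer functions match the piecewise standard and invert", {
  expect_identical(srgb_decode(0), 0)
  expect_identical(srgb_decode(1), 1)
  # direct one-line evaluation of the decoding formula at mid-gray
  expect_equal(srgb_decode(128 / 255), ((128 / 255 + 0.055) / 1.055)^2.4,
               tolerance = 1e-12)
  expect_equal(srgb_decode(128 / 255), 0.2159, tolerance = 5e-4)
  x <- seq(0, 1, length.out = 101)
  expect_equal(srgb_encode(srgb_decode(x)), x, tolerance = 1e-9)
  expect_equal(srgb_decode(srgb_encode(x)), x, tolerance = 1e-9)
  expect_true(all(diff(srgb_decode(x)) > 0))   # strictly monotone
  expect_error(srgb_decode(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(srgb_encode(-0.1), "\\[0, 1\\]")
})

test_that("sRGB matrix transforms map white to D65 and round-trip", {
  expect_equal(srgb_to_xyz(c(0, 0, 0)), c(X = 0, Y = 0, Z = 0))
  w <- srgb_to_xyz(c(1, 1, 1))
  expect_equal(unname(w), c(95.05, 100.00, 108.88), tolerance = 1e-4)
  expect_equal(unname(w[2]), 100, tolerance = 1e-9)
  set.seed(11)
  rgb <- matrix(runif(30), ncol = 3)
  back <- xyz_to_srgb(srgb_to_xyz(rgb), clip = FALSE)
  expect_equal(unname(back), unname(srgb_encode(rgb)), tolerance = 1e-6)
  # clipping contract for out-of-gamut tristimuli
  out <- xyz_to_srgb(c(5, 80, 120), clip = TRUE)
  expect_true(all(out >= 0 & out <= 1))
  expect_equal(unname(xyz_to_srgb(c(0, 0, 0))), c(0, 0, 0))
  expect_equal(unname(xyz_to_srgb(d65_white())), c(1, 1, 1), tolerance = 1e-9)
})

test_that("spectrum integration normalizes a perfect reflector to Y = 100", {
  grid <- wavelength_grid()
  cmf <- cie1931_cmf(grid)
  one <- rep(1, grid_length(grid))
  for (sd in 1:5) {
    set.seed(sd)
    E <- spd(grid, runif(grid_length(grid), 0.05, 2))
    expect_equal(unname(spectrum_to_xyz(one, E, cmf)[2]), 100,
                 tolerance = 1e-9)
  }
  E <- generate_wli_illuminant(grid)
  expect_equal(unname(spectrum_to_xyz(rep(0, 401), E, cmf)),
               c(0, 0, 0), tolerance = 1e-12)
  # equal-energy illuminant: X of the perfect reflector from raw CMF sums
  flat <- spd(grid, rep(1, 401))
  expect_equal(unname(spectrum_to_xyz(one, flat, cmf)[1]),
               100 * sum(cmf$xbar) / sum(cmf$ybar), tolerance = 1e-9)
  expect_error(spectrum_to_xyz(one, spd(grid, rep(0, 401)), cmf),
               "degenerate")
})

test_that("spectrum integration is linear in reflectance", {
  grid <- wavelength_grid()
  cmf <- cie1931_cmf(grid)
  E <- generate_wli_illuminant(grid)
  set.seed(21)
  for (i in 1:10) {
    r1 <- runif(401); r2 <- runif(401)
    a <- runif(1, 0, 0.6); b <- runif(1, 0, 1 - a)
    lhs <- spectrum_to_xyz(a * r1 + b * r2, E, cmf)
    rhs <- a * spectrum_to_xyz(r1, E, cmf) + b * spectrum_to_xyz(r2, E, cmf)
    expect_equal(lhs, rhs, tolerance = 1e-9)
  }
})

test_that("Lab conversion honors the reference white and the L* = 50 gray", {
  expect_equal(unname(xyz_to_lab(d65_white())), c(100, 0, 0),
               tolerance = 1e-9)
  expect_equal(unname(xyz_to_lab(c(0, 0, 0))), c(0, 0, 0), tolerance = 1e-9)
  # invert L* = 50 through the cube-root formula: Y/Yn = ((50+16)/116)^3
  yr <- ((50 + 16) / 116)^3
  expect_equal(yr, 0.18419, tolerance = 1e-4)
  gray <- d65_white() * yr
  lab <- xyz_to_lab(gray)
  expect_equal(unname(lab), c(50, 0, 0), tolerance = 1e-9)
  expect_error(xyz_to_lab(c(50, 50, 50), white = c(95, 0, 108)), "positive")
})

test_that("delta_e handles identity, symmetry and published DE2000 pairs", {
  labs <- random_labs(20, seed = 5)
  for (m in c("DE76", "DE94", "DE2000")) {
    expect_equal(delta_e(labs, labs, m), rep(0, 20), tolerance = 1e-12)
  }
  a <- random_labs(50, seed = 6); b <- random_labs(50, seed = 7)
  expect_equal(delta_e(a, b, "DE2000"), delta_e(b, a, "DE2000"),
               tolerance = 1e-12)
  expect_equal(delta_e(a, b, "DE76"), sqrt(rowSums((a - b)^2)),
               tolerance = 1e-12)
  # reference pairs with published CIEDE2000 values
  ref <- rbind(
    c(50, 2.6772, -79.7751, 50, 0, -82.7485, 2.0425),
    c(50, 3.1571, -77.2803, 50, 0, -82.7485, 2.8615),
    c(50, 2.8361, -74.0200, 50, 0, -82.7485, 3.4412),
    c(50, 2.5, 0, 50, 0, -2.5, 4.3065),
    c(50, 2.5, 0, 73, 25, -18, 27.1492),
    c(50, 2.5, 0, 50, 3.2592, 0.3350, 1.0000))
  got <- delta_e(ref[, 1:3], ref[, 4:6], "DE2000")
  expect_equal(got, ref[, 7], tolerance = 5e-4)
  expect_error(delta_e(c(1, 2, 3), c(1, 2, 3), method = "DE00"))
})

test_that("DE2000 equals the independent term-by-term oracle", {
  a <- random_labs(1000, seed = 101)
  b <- random_labs(1000, seed = 202)
  fast <- delta_e(a, b, "DE2000")
  slow <- vapply(seq_len(nrow(a)),
                 function(i) oracle_de2000(a[i, ], b[i, ]), numeric(1))
  expect_lt(max(abs(fast - slow)), 1e-4)
})

test_that("DE76 satisfies the triangle inequality on random triples", {
  a <- random_labs(200, seed = 1); b <- random_labs(200, seed = 2)
  c_ <- random_labs(200, seed = 3)
  expect_true(all(delta_e(a, c_, "DE76") <=
                  delta_e(a, b, "DE76") + delta_e(b, c_, "DE76") + 1e-12))
})

test_that("CMF tables validate shape and sign and round-trip through CSV", {
  grid <- wavelength_grid(400, 700, 5)
  cmf <- cie1931_cmf(grid)
  expect_length(cmf$xbar, grid_length(grid))
  expect_true(all(cmf$xbar >= 0 & cmf$ybar >= 0 & cmf$zbar >= 0))
  expect_error(cmf_table(grid, cmf$xbar[-1], cmf$ybar, cmf$zbar), "length")
  path <- withr::local_tempfile(fileext = ".csv")
  write_cmf_csv(cmf, path)
  back <- read_cmf_csv(path)
  expect_equal(back$xbar, cmf$xbar)
  expect_equal(back$grid, cmf$grid)
})

test_that("wavelength grids validate their invariants", {
  g <- wavelength_grid()
  expect_equal(grid_length(g), 401L)
  expect_equal(wavelengths(g)[c(1, 401)], c(380, 780))
  expect_error(wavelength_grid(780, 380), "start")
  expect_error(wavelength_grid(380, 780, -1), "step")
  expect_error(wavelength_grid(380, 780, 3), "multiple")
})
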