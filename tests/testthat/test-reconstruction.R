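test_that("fit_pca produces an orthonormal, variance-ordered, signed basis", {
  grid <- wavelength_grid()
  set.seed(8)
  spectra <- generate_checker_reflectances(fixture_config(seed = 8))
  basis <- fit_pca(spectra, n_pc = 5, grid = grid)
  G <- basis$components %*% t(basis$components)
  expect_equal(G, diag(5), tolerance = 1e-8)
  evr <- basis$explained_variance_ratio
  expect_true(all(diff(evr) <= 1e-12))
  expect_true(all(evr >= 0 & evr <= 1))
  expect_lte(sum(evr), 1 + 1e-12)
  # deterministic sign: the largest-magnitude loading is positive
  for (i in 1:5) {
    expect_gt(basis$components[i, which.max(abs(basis$components[i, ]))], 0)
  }
})

test_that("exact low-rank data concentrates all variance in k components", {
  grid <- wavelength_grid()
  wl <- wavelengths(grid)
  set.seed(15)
  B <- cbind(exp(-((wl - 450) / 40)^2), exp(-((wl - 600) / 50)^2),
             rep(1, 401))
  spectra <- matrix(runif(72, 0, 0.3), 24, 3) %*% t(B)
  basis <- fit_pca(spectra, n_pc = 3, grid = grid)
  expect_equal(sum(basis$explained_variance_ratio), 1, tolerance = 1e-10)
  expect_error(fit_pca(matrix(0.5, 24, 401), n_pc = 3, grid = grid),
               "degenerate")
  expect_error(fit_pca(spectra, n_pc = 24, grid = grid), "n_pc")
})

test_that("PCA matches a brute-force eigendecomposition of the Gram matrix", {
  grid <- wavelength_grid()
  set.seed(23)
  spectra <- matrix(runif(24 * 401, 0, 1), 24, 401)
  basis <- fit_pca(spectra, n_pc = 6, grid = grid)
  Xc <- sweep(spectra, 2, colMeans(spectra))
  eg <- eigen(Xc %*% t(Xc), symmetric = TRUE)   # 24 x 24 Gram matrix
  ev_oracle <- eg$values / (24 - 1)
  expect_equal(basis$explained_variance_ratio,
               (ev_oracle / sum(ev_oracle))[1:6], tolerance = 1e-10)
  # components from the Gram route: X'c u / ||.||, up to sign
  for (i in 1:6) {
    comp <- drop(t(Xc) %*% eg$vectors[, i])
    comp <- comp / sqrt(sum(comp^2))
    if (comp[which.max(abs(comp))] < 0) comp <- -comp
    expect_equal(basis$components[i, ], comp, tolerance = 1e-8)
  }
})

test_that("projection and reconstruction obey the projector identities", {
  set.seed(4)
  spectra <- generate_checker_reflectances(fixture_config(seed = 4))
  basis <- fit_pca(spectra, n_pc = 3)
  expect_equal(project_scores(basis, basis$mean_spectrum), rep(0, 3),
               tolerance = 1e-12)
  s <- basis$mean_spectrum + basis$components[1, ]
  expect_equal(project_scores(basis, s), c(1, 0, 0), tolerance = 1e-8)
  # in-span spectra reconstruct exactly; projecting again is idempotent
  coef <- c(0.21, -0.13, 0.05)
  in_span <- basis$mean_spectrum + drop(coef %*% basis$components)
  sc <- project_scores(basis, in_span)
  expect_equal(sc, coef, tolerance = 1e-10)
  rec <- basis$mean_spectrum + drop(sc %*% basis$components)
  expect_equal(rec, in_span, tolerance = 1e-10)
  expect_equal(project_scores(basis, rec), sc, tolerance = 1e-10)
})

test_that("fit_conversion_matrix recovers a planted M and is separable", {
  ex <- variable_expansion()
  set.seed(77)
  xyz <- matrix(runif(72, 5, 95), 24, 3)
  V <- expand_xyz(xyz, ex)
  M0 <- matrix(rnorm(5 * 11), 5, 11)
  scores <- V %*% t(M0)
  fit <- fit_conversion_matrix(scores, xyz, ex)
  expect_lt(max(abs(fit$M - M0)), 1e-8)
  # all-zero scores give a zero matrix
  z <- fit_conversion_matrix(matrix(0, 24, 5), xyz, ex)
  expect_equal(z$M, matrix(0, 5, 11), tolerance = 1e-12)
  # rows are solvable independently
  one <- fit_conversion_matrix(scores[, 2, drop = FALSE], xyz, ex)
  expect_equal(drop(one$M), fit$M[2, ], tolerance = 1e-10)
})

test_that("reconstruct_spectrum is affine in the expansion and clips", {
  p <- fit_planted_pipeline(seed = 1)
  zero_model <- structure(list(expansion = variable_expansion(),
                               M = matrix(0, 12, 11)),
                          class = "conversion_model")
  out <- reconstruct_spectrum(p$basis, zero_model, c(40, 50, 60))
  expect_equal(out, pmin(pmax(p$basis$mean_spectrum, 0), 1),
               tolerance = 1e-12)
  got <- reconstruct_spectrum(p$basis, p$conv, p$corrected, clip = FALSE)
  V <- expand_xyz(p$corrected, p$conv$expansion)
  manual <- sweep((V %*% t(p$conv$M)) %*% p$basis$components, 2,
                  p$basis$mean_spectrum, "+")
  expect_equal(got, manual, tolerance = 1e-12)
  clipped <- reconstruct_spectrum(p$basis, p$conv, p$corrected)
  expect_true(all(clipped >= 0 & clipped <= 1))
})

test_that("clipping never hurts against a target inside [0,1]", {
  p <- fit_planted_pipeline(seed = 2)
  raw <- reconstruct_spectrum(p$basis, p$conv, p$corrected, clip = FALSE)
  clp <- reconstruct_spectrum(p$basis, p$conv, p$corrected, clip = TRUE)
  for (i in 1:24) {
    expect_lte(spectrum_rmse(clp[i, ], p$refl[i, ]),
               spectrum_rmse(raw[i, ], p$refl[i, ]) + 1e-12)
  }
})

test_that("projection error onto the basis shrinks as n_pc grows", {
  train <- generate_checker_reflectances(fixture_config(seed = 5,
                                                        n_gaussians = 6))
  held <- generate_checker_reflectances(fixture_config(seed = 6,
                                                       n_gaussians = 6))
  errs <- vapply(1:12, function(k) {
    basis <- fit_pca(train, n_pc = k)
    sc <- project_scores(basis, held)
    rec <- sweep(sc %*% basis$components, 2, basis$mean_spectrum, "+")
    mean(sqrt(rowMeans((rec - held)^2)))
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-9))
})

test_that("spectrum_rmse matches a brute-force sum of squares", {
  set.seed(12)
  a <- runif(401); b <- runif(401)
  expect_equal(spectrum_rmse(a, a), 0)
  expect_equal(spectrum_rmse(a, a + 0.17), 0.17, tolerance = 1e-12)
  expect_equal(spectrum_rmse(a, b), sqrt(sum((a - b)^2) / 401),
               tolerance = 1e-12)
  expect_error(spectrum_rmse(a, b[-1]), "length")
})

test_that("image_to_cube agrees with the scalar pipeline per pixel", {
  p <- fit_planted_pipeline(seed = 3)
  mosaic <- generate_checker_image(p$rgb, p$fx)
  cube <- image_to_cube(mosaic$image, p$correction, p$basis, p$conv)
  expect_equal(dim(cube$values), c(dim(mosaic$image)[1:2], 401L))
  # a uniform region reconstructs to one spectrum
  ids <- mosaic$patch_id
  px <- which(ids == 7, arr.ind = TRUE)
  s1 <- cube$values[px[1, 1], px[1, 2], ]
  s2 <- cube$values[px[nrow(px), 1], px[nrow(px), 2], ]
  expect_equal(s1, s2, tolerance = 1e-14)
  # scalar-path oracle on one random pixel
  set.seed(9)
  i <- sample(dim(mosaic$image)[1], 1); j <- sample(dim(mosaic$image)[2], 1)
  rgb1 <- mosaic$image[i, j, ]
  xyz1 <- apply_correction(p$correction, srgb_to_xyz(srgb_decode(rgb1)))
  expect_equal(cube$values[i, j, ],
               reconstruct_spectrum(p$basis, p$conv, xyz1),
               tolerance = 1e-12)
  expect_error(image_to_cube(array(0, c(4, 4, 2)), p$correction, p$basis,
                             p$conv), "3")
})
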