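# Independent scalar transcription of the CIEDE2000 formula, written
# term by term in radians (the package implementation is vectorized and
# works in degrees). Used as the reference the fast path must reproduce.
oracle_de2000 <- function(lab1, lab2) {
  L1 <- lab1[1]; a1 <- lab1[2]; b1 <- lab1[3]
  L2 <- lab2[1]; a2 <- lab2[2]; b2 <- lab2[3]
  C1 <- sqrt(a1 * a1 + b1 * b1)
  C2 <- sqrt(a2 * a2 + b2 * b2)
  Cbar <- (C1 + C2) / 2
  G <- 0.5 * (1 - sqrt(Cbar^7 / (Cbar^7 + 25^7)))
  a1p <- (1 + G) * a1
  a2p <- (1 + G) * a2
  C1p <- sqrt(a1p * a1p + b1 * b1)
  C2p <- sqrt(a2p * a2p + b2 * b2)
  h1p <- if (C1p == 0) 0 else atan2(b1, a1p)
  if (h1p < 0) h1p <- h1p + 2 * pi
  h2p <- if (C2p == 0) 0 else atan2(b2, a2p)
  if (h2p < 0) h2p <- h2p + 2 * pi

  dLp <- L2 - L1
  dCp <- C2p - C1p
  if (C1p * C2p == 0) {
    dhp <- 0
  } else {
    dhp <- h2p - h1p
    if (dhp > pi) dhp <- dhp - 2 * pi
    if (dhp < -pi) dhp <- dhp + 2 * pi
  }
  dHp <- 2 * sqrt(C1p * C2p) * sin(dhp / 2)

  Lbp <- (L1 + L2) / 2
  Cbp <- (C1p + C2p) / 2
  if (C1p * C2p == 0) {
    hbp <- h1p + h2p
  } else if (abs(h1p - h2p) <= pi) {
    hbp <- (h1p + h2p) / 2
  } else if (h1p + h2p < 2 * pi) {
    hbp <- (h1p + h2p) / 2 + pi
  } else {
    hbp <- (h1p + h2p) / 2 - pi
  }

  T <- 1 - 0.17 * cos(hbp - pi / 6) +
       0.24 * cos(2 * hbp) +
       0.32 * cos(3 * hbp + 6 * pi / 180) -
       0.20 * cos(4 * hbp - 63 * pi / 180)
  hbp_deg <- hbp * 180 / pi
  dtheta_deg <- 30 * exp(-((hbp_deg - 275) / 25)^2)
  RC <- 2 * sqrt(Cbp^7 / (Cbp^7 + 25^7))
  SL <- 1 + 0.015 * (Lbp - 50)^2 / sqrt(20 + (Lbp - 50)^2)
  SC <- 1 + 0.045 * Cbp
  SH <- 1 + 0.015 * Cbp * T
  RT <- -sin(2 * dtheta_deg * pi / 180) * RC

  sqrt((dLp / SL)^2 + (dCp / SC)^2 + (dHp / SH)^2 +
       RT * (dCp / SC) * (dHp / SH))
}

# Random in-gamut-ish Lab colors for property tests.
random_labs <- function(n, seed) {
  set.seed(seed)
  cbind(L = runif(n, 0, 100), a = runif(n, -90, 90), b = runif(n, -90, 90))
}

# Fits the whole planted calibration chain on the default fixtures and
# returns every intermediate product; several suites start from this.
fit_planted_pipeline <- function(seed = 0, n_pc = 12, patch_pixels = 8L) {
  fx <- fixture_config(seed = seed, patch_pixels = patch_pixels)
  refl <- generate_checker_reflectances(fx)
  illum <- generate_wli_illuminant(fx$grid)
  rgb <- render_camera_rgb(refl, illum, config = fx)
  camera_xyz <- srgb_to_xyz(srgb_decode(rgb / 255))
  spectrum_xyz <- spectrum_to_xyz(refl, illum, cie1931_cmf(fx$grid))
  correction <- fit_correction(camera_xyz, spectrum_xyz)
  corrected <- apply_correction(correction, camera_xyz)
  basis <- fit_pca(refl, n_pc = n_pc, grid = fx$grid)
  conv <- fit_conversion_matrix(project_scores(basis, refl), corrected)
  list(fx = fx, refl = refl, illum = illum, rgb = rgb,
       camera_xyz = camera_xyz, spectrum_xyz = spectrum_xyz,
       correction = correction, corrected = corrected,
       basis = basis, conv = conv)
}

# Mean Lab of the two phantom regions of an encoded sRGB image.
phantom_region_labs <- function(image, mask) {
  m <- vapply(1:3, function(ch) {
    p <- image[, , ch]
    c(mean(p[mask]), mean(p[!mask]))
  }, numeric(2))
  xyz_to_lab(srgb_to_xyz(srgb_decode(m)))
}
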