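#' Fixture generator configuration
#'
#' Controls for the synthetic checker / illuminant / phantom generators.
#' Every generator is a pure function of its config: the same seed gives
#' bitwise-identical output.
#'
#' @param seed Integer seed.
#' @param n_gaussians Number of smooth Gaussian atoms shared by the
#'   chromatic patch reflectances (see
#'   [generate_checker_reflectances()]).
#' @param noise_sd Additive reflectance noise SD (0 = noiseless).
#' @param patch_pixels Side length (pixels) of each rendered checker patch.
#' @param grid The [wavelength_grid()] fixtures are generated on.
#' @return An object of class `fixture_config`.
#' @export
fixture_config <- function(seed = 0L, n_gaussians = 2, noise_sd = 0,
                           patch_pixels = 16L, grid = wavelength_grid()) {
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (patch_pixels < 1) stop("patch_pixels must be >= 1")
  structure(list(seed = as.integer(seed), n_gaussians = as.integer(n_gaussians),
                 noise_sd = noise_sd, patch_pixels = as.integer(patch_pixels),
                 grid = grid), class = "fixture_config")
}

# Gray-ramp reflectances of patches 19-24 (roughly geometric over the
# checker's dynamic range).
CHECKER_GRAYS <- c(0.03, 0.09, 0.19, 0.36, 0.59, 0.90)

#' Synthetic 24-patch checker reflectances
#'
#' Patches 1-18 are random non-negative combinations of a fixed
#' dictionary: the neutral (spectrally flat) axis plus `n_gaussians` smooth
#' Gaussian atoms, the first two centered on the hemoglobin Soret (415 nm)
#' and Q (540 nm) absorption bands. Patches 19-24 are the spectrally flat
#' gray ramp 0.03, 0.09, 0.19, 0.36, 0.59, 0.90, emulating the checker's
#' six neutral patches.
#'
#' The default of two atoms makes the whole set span a three-dimensional
#' linear family -- mirroring the well-known low intrinsic dimensionality
#' of measured reflectance sets, and matching the three degrees of freedom
#' a tristimulus camera can observe, so the planted calibration chain is
#' solvable; placing the chromatic variation in the hemoglobin bands makes
#' the set representative of the endoscopic scenes the pipeline targets.
#' Raise `n_gaussians` to generate richer (metameric) families for stress
#' tests.
#'
#' @param config A [fixture_config()].
#' @return 24 x grid-length matrix of reflectances in [0,1]; row i is
#'   patch_id i.
#' @export
generate_checker_reflectances <- function(config = fixture_config()) {
  wl <- wavelengths(config$grid)
  set.seed(config$seed)
  # The dictionary atoms are fixed by design, like the pigments of a
  # physical calibration target; only the mixing amplitudes are random.
  # The first two atoms sit exactly on the hemoglobin Soret (415 nm) and Q
  # (540 nm) absorption bands -- where endoscopic reflectance actually
  # varies -- which also keeps the dictionary's camera-space directions
  # well conditioned (amplitudes recoverable from 8-bit camera data).
  # Extra atoms, if requested, are drawn over the red end of the grid.
  atom_mu <- c(415, 540)
  atom_sd <- c(22, 22)
  if (config$n_gaussians > 2) {
    k <- config$n_gaussians - 2L
    atom_mu <- c(atom_mu, stats::runif(k, 560, min(config$grid$stop_nm, 700)))
    atom_sd <- c(atom_sd, stats::runif(k, 20, 80))
  }
  atoms <- vapply(seq_len(config$n_gaussians), function(g)
    exp(-0.5 * ((wl - atom_mu[g]) / atom_sd[g])^2), numeric(length(wl)))
  illum <- generate_wli_illuminant(config$grid)
  cmf <- cie1931_cmf(config$grid)
  lin_of <- function(s)
    drop((matrix(spectrum_to_xyz(s, illum, cmf), 1) / 100) %*% t(XYZ_TO_SRGB))
  lin_flat <- lin_of(rep(1, length(wl)))
  lin_atoms <- apply(atoms, 2, lin_of)        # 3 x n_gaussians
  R <- matrix(0, 24, length(wl))
  for (i in 1:18) {
    base <- stats::runif(1, 0.04, 0.25)      # floor: tissue is never black
    amps <- stats::runif(config$n_gaussians, 0.1, 0.8)
    bump <- drop(atoms %*% amps)
    peak <- max(bump)
    # rescale the chromatic part so clipping never truncates the spectrum
    # (rescaling stays inside the dictionary span)
    if (base + peak > 0.95) {
      amps <- amps * (0.95 - base) / peak
      bump <- bump * (0.95 - base) / peak
    }
    # desaturate toward the neutral base until the rendered camera color is
    # inside the sRGB gamut (scaling amplitudes stays inside the span)
    lin_b <- base * lin_flat
    lin_d <- drop(lin_atoms %*% amps)
    t_ch <- ifelse(lin_d > 0, (0.97 - lin_b) / lin_d,
            ifelse(lin_d < 0, (0.01 - lin_b) / lin_d, 1))
    t_max <- min(1, t_ch)
    if (t_max < 1) bump <- bump * max(t_max, 0)
    s <- base + bump
    if (config$noise_sd > 0)
      s <- s + stats::rnorm(length(wl), 0, config$noise_sd)
    R[i, ] <- pmin(pmax(s, 0), 1)
  }
  for (i in 19:24) {
    s <- rep(CHECKER_GRAYS[i - 18], length(wl))
    if (config$noise_sd > 0)
      s <- s + stats::rnorm(length(wl), 0, config$noise_sd)
    R[i, ] <- pmin(pmax(s, 0), 1)
  }
  R
}

#' Synthetic broadband white-light illuminant
#'
#' A smooth, deterministic stand-in for an endoscopic white-light lamp: a
#' broad thermal-style envelope plus a mild blue LED-like bump, strictly
#' positive across 400-700 nm.
#'
#' @param grid A [wavelength_grid()].
#' @return An [spd()].
#' @export
generate_wli_illuminant <- function(grid = wavelength_grid()) {
  wl <- wavelengths(grid)
  # broad thermal-style envelope + blue pump, weighted so the lamp's
  # chromaticity sits on the D65 white point (a white-balanced camera):
  # a perfect reflector renders as linear (1,1,1) to within 3e-3
  power <- 0.50 +
    exp(-0.5 * ((wl - 554) / 115)^2) +
    0.555 * exp(-0.5 * ((wl - 450) / 51)^2)
  spd(grid, power)
}

#' Render checker patches to camera RGB
#'
#' Simulates the endoscope camera for calibration tests: integrate each
#' reflectance to XYZ under the illuminant, optionally distort XYZ with a
#' planted 3 x 3 matrix (mimicking filter cross-talk), encode to sRGB with
#' clipping, quantize to 8 bits.
#'
#' @param reflectances 24 x grid matrix from
#'   [generate_checker_reflectances()].
#' @param illuminant An [spd()].
#' @param planted_distortion Optional 3 x 3 matrix applied to XYZ before
#'   encoding; `NULL` means the identity (ideal camera).
#' @param config A [fixture_config()].
#' @return 24 x 3 integer matrix of 8-bit RGB; attribute `n_clipped` counts
#'   linear channel values clipped into gamut.
#' @export
render_camera_rgb <- function(reflectances, illuminant,
                              planted_distortion = NULL,
                              config = fixture_config()) {
  xyz <- spectrum_to_xyz(as.matrix(reflectances), illuminant,
                         cie1931_cmf(config$grid))
  if (!is.null(planted_distortion))
    xyz <- xyz %*% t(planted_distortion)
  lin <- (xyz / 100) %*% t(XYZ_TO_SRGB)
  n_clipped <- sum(lin < 0 | lin > 1)
  rgb8 <- round(255 * srgb_encode(pmin(pmax(lin, 0), 1)))
  storage.mode(rgb8) <- "integer"
  colnames(rgb8) <- c("R", "G", "B")
  attr(rgb8, "n_clipped") <- n_clipped
  rgb8
}

#' Synthetic NBI targets from a planted band model
#'
#' Renders every patch under the planted model; by construction
#' `objective_mean_de2000(planted, reflectances, targets)` is exactly zero.
#'
#' @param reflectances 24 x grid matrix.
#' @param planted_bands A [band_model()].
#' @param cmf Observer.
#' @return An [nbi_target_set()].
#' @export
generate_nbi_targets <- function(reflectances, planted_bands,
                                 cmf = cie1931_cmf()) {
  lab <- render_patch_color(as.matrix(reflectances), planted_bands, cmf)
  nbi_target_set(lab)
}

#' Render a checker mosaic image
#'
#' A 4-row x 6-column mosaic of uniform patches, row-major by patch_id.
#'
#' @param rgbs 24 x 3 matrix of 8-bit RGB (rows are patch_ids 1-24).
#' @param config A [fixture_config()]; `patch_pixels` sets patch size.
#' @return List: `image` (H x W x 3 encoded sRGB in [0,1]), `patch_id`
#'   (H x W integer matrix labelling each pixel's patch).
#' @export
generate_checker_image <- function(rgbs, config = fixture_config()) {
  rgbs <- as.matrix(rgbs)
  if (nrow(rgbs) != 24) stop("expected 24 patch colors")
  p <- config$patch_pixels
  h <- 4L * p; w <- 6L * p
  img <- array(0, dim = c(h, w, 3))
  ids <- matrix(0L, h, w)
  for (r in 1:4) for (cc in 1:6) {
    id <- (r - 1L) * 6L + cc
    rows <- ((r - 1L) * p + 1L):(r * p)
    cols <- ((cc - 1L) * p + 1L):(cc * p)
    for (ch in 1:3) img[rows, cols, ch] <- rgbs[id, ch] / 255
    ids[rows, cols] <- id
  }
  list(image = img, patch_id = ids)
}

#' Two-region lesion phantom
#'
#' A desk-scale analog of a mucosal lesion under white light: a spectrally
#' flat background and a central disk lesion whose reflectance is the
#' background multiplied by two Lorentzian absorption dips spanning roughly
#' 400-430 nm and 530-550 nm -- the hemoglobin absorption bands narrow-band
#' imaging exploits. Rendered under the [generate_wli_illuminant()] lamp.
#'
#' @param config A [fixture_config()]; image side is `8 * patch_pixels`.
#' @param dip_depths Fractional absorption at the 415 / 540 nm dip centers;
#'   defaults emulate strongly vascularized tissue.
#' @param dip_gammas HWHMs (nm) of the two dips.
#' @return List: `image` (encoded sRGB, [0,1]), `lesion_mask` (logical
#'   matrix), `background` and `lesion` reflectance spectra, `illuminant`.
#' @export
generate_lesion_phantom <- function(config = fixture_config(),
                                    dip_depths = c(0.70, 0.55),
                                    dip_gammas = c(15, 12)) {
  wl <- wavelengths(config$grid)
  illum <- generate_wli_illuminant(config$grid)
  background <- rep(0.55, length(wl))
  dip <- function(center, depth, g)
    1 - depth * g^2 / ((wl - center)^2 + g^2)
  lesion <- background * dip(415, dip_depths[1], dip_gammas[1]) *
                         dip(540, dip_depths[2], dip_gammas[2])
  side <- 8L * config$patch_pixels
  ctr <- (side + 1) / 2
  d2 <- outer(seq_len(side), seq_len(side),
              function(i, j) (i - ctr)^2 + (j - ctr)^2)
  lesion_mask <- d2 <= (side / 4)^2
  cmf <- cie1931_cmf(config$grid)
  cols <- xyz_to_srgb(spectrum_to_xyz(rbind(background, lesion), illum, cmf),
                      clip = TRUE)
  cols <- round(cols * 255) / 255
  img <- array(0, dim = c(side, side, 3))
  for (ch in 1:3) {
    plane <- matrix(cols[1, ch], side, side)
    plane[lesion_mask] <- cols[2, ch]
    img[, , ch] <- plane
  }
  list(image = img, lesion_mask = lesion_mask,
       background = background, lesion = lesion, illuminant = illum)
}
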