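#' Lorentzian illuminant band
#'
#' One Cauchy-Lorentz line: amplitude * gamma^2 / ((lambda - center)^2 +
#' gamma^2). Peak-normalized, so the maximum equals `amplitude` at the
#' center and the half-maximum sits at center +/- gamma (gamma is the HWHM).
#'
#' @param center_nm Band center (nm).
#' @param gamma_nm Half-width at half-maximum (nm), > 0.
#' @param amplitude Relative peak height, >= 0.
#' @return An object of class `lorentzian_band`.
#' @export
lorentzian_band <- function(center_nm, gamma_nm, amplitude = 1) {
  if (!is.finite(gamma_nm) || gamma_nm <= 0)
    stop("gamma_nm (HWHM) must be positive")
  if (!is.finite(amplitude) || amplitude < 0)
    stop("amplitude must be non-negative")
  structure(list(center_nm = center_nm, gamma_nm = gamma_nm,
                 amplitude = amplitude), class = "lorentzian_band")
}

#' @rdname lorentzian_band
#' @param lambda_nm Wavelength(s) at which to evaluate the band.
#' @param band A `lorentzian_band`.
#' @export
lorentzian_value <- function(lambda_nm, band) {
  g2 <- band$gamma_nm^2
  band$amplitude * g2 / ((lambda_nm - band$center_nm)^2 + g2)
}

#' Multi-band NBI illuminant model
#'
#' An ordered list of Lorentzian bands whose pointwise sum is the simulated
#' narrow-band illuminant SPD. The default centers \{415, 480, 540, 600,
#' 700, 780\} nm put the dominant power on the hemoglobin absorption peaks
#' (415, 540 nm) with weaker red/near-infrared bands carrying the brown
#' tones seen in reference NBI captures.
#'
#' @param bands List of [lorentzian_band()] objects (non-empty).
#' @return An object of class `band_model`.
#' @export
band_model <- function(bands = default_nbi_bands()) {
  if (length(bands) == 0) stop("band model needs at least one band")
  if (!all(vapply(bands, inherits, logical(1), "lorentzian_band")))
    stop("bands must be lorentzian_band objects")
  structure(list(bands = bands), class = "band_model")
}

#' @rdname band_model
#' @export
default_nbi_band_centers <- function() c(415, 480, 540, 600, 700, 780)

#' @rdname band_model
#' @export
default_nbi_bands <- function() {
  # 415 nm dominates (the Soret-band channel that darkens superficial
  # capillaries), 540 nm is the secondary vessel band, and the weak red
  # bands carry the brown tones of reference NBI captures; widths reflect
  # narrow filtered output
  centers <- default_nbi_band_centers()
  gammas  <- c(5, 8, 6, 10, 15, 20)
  amps    <- c(1.00, 0.02, 0.25, 0.08, 0.10, 0.02)
  band_model(Map(lorentzian_band, centers, gammas, amps))$bands
}

#' Evaluate a band model as an SPD
#'
#' @param model A [band_model()].
#' @param grid A [wavelength_grid()].
#' @return An [spd()] equal to the pointwise sum of the bands.
#' @export
band_model_spd <- function(model, grid = wavelength_grid()) {
  wl <- wavelengths(grid)
  power <- rowSums(vapply(model$bands, function(b) lorentzian_value(wl, b),
                          numeric(length(wl))))
  spd(grid, power)
}

#' Render a reflectance spectrum under a band-model illuminant
#'
#' Integrates the reflectance under [band_model_spd()] and converts to Lab
#' against D65. The luminance-ratio normalization makes a perfect reflector
#' render at L* = 100 under any non-degenerate model, so only the shape of
#' the band model matters, not its overall scale.
#'
#' @param reflectance Grid-length vector, or n x grid matrix of spectra.
#' @param model A [band_model()].
#' @param cmf Observer; default [cie1931_cmf()] on the default grid.
#' @return Lab vector (or n x 3 matrix).
#' @export
render_patch_color <- function(reflectance, model,
                               cmf = cie1931_cmf()) {
  illum <- band_model_spd(model, cmf$grid)
  xyz_to_lab(spectrum_to_xyz(reflectance, illum, cmf))
}

#' NBI target set
#'
#' Exactly 24 target patch colors in Lab (D65), keyed by patch_id 1-24.
#'
#' @param lab 24 x 3 matrix of Lab rows.
#' @param patch_id Integer labels; default 1:24.
#' @return A data.frame with columns patch_id, L, a, b, ordered by patch_id.
#' @export
nbi_target_set <- function(lab, patch_id = seq_len(nrow(lab))) {
  lab <- as.matrix(lab)
  if (nrow(lab) != 24) stop("an NBI target set has exactly 24 patches")
  if (anyDuplicated(patch_id) || !setequal(patch_id, 1:24))
    stop("patch_id must be a permutation of 1..24")
  d <- data.frame(patch_id = as.integer(patch_id),
                  L = lab[, 1], a = lab[, 2], b = lab[, 3])
  d[order(d$patch_id), , drop = FALSE]
}

#' Mean CIEDE2000 objective against NBI targets
#'
#' Renders each of the 24 patch reflectances under the band model and
#' averages the patch-wise CIEDE2000 difference to its target.
#'
#' @param model A [band_model()].
#' @param patches 24 x grid matrix of patch reflectances, row i being
#'   patch_id i.
#' @param targets An [nbi_target_set()].
#' @param cmf Observer.
#' @return Non-negative mean Delta-E 2000.
#' @export
objective_mean_de2000 <- function(model, patches, targets,
                                  cmf = cie1931_cmf()) {
  patches <- as.matrix(patches)
  if (nrow(patches) != 24) stop("expected 24 patch reflectances")
  if (!all(targets$patch_id == 1:24))
    stop("targets must cover patch_ids 1..24 exactly")
  rendered <- render_patch_color(patches, model, cmf)
  mean(delta_e(rendered, as.matrix(targets[, c("L", "a", "b")]),
               method = "DE2000"))
}
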