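#' Annealing configuration for band-model fitting
#'
#' Bounds and controls for [optimize_band_model()]. Band centers may move
#' within `center_window_nm` of their initial positions; widths and
#' amplitudes move within their stated ranges. The first band's amplitude
#' is pinned to 1, because the luminance normalization makes rendered
#' colors invariant to a global amplitude scale, so amplitudes are only
#' identifiable up to that scale.
#'
#' @param center_window_nm Half-width of the search window around each
#'   initial band center (nm).
#' @param gamma_range HWHM search range (nm).
#' @param amplitude_range Relative amplitude range for bands 2..n.
#' @param max_iterations Outer annealing iterations.
#' @param seed Integer seed controlling the whole run.
#' @param visiting_param,acceptance_param,initial_temperature Annealing
#'   shape controls (see [gsa_minimize()]).
#' @param local_polish Run bounded local search from incumbent bests?
#' @return An object of class `optimization_config`.
#' @export
optimization_config <- function(center_window_nm = 15,
                                gamma_range = c(1, 60),
                                amplitude_range = c(0, 1),
                                max_iterations = 150,
                                seed = 0L,
                                visiting_param = 2.62,
                                acceptance_param = -5.0,
                                initial_temperature = 5230,
                                local_polish = TRUE) {
  if (center_window_nm <= 0) stop("center_window_nm must be positive")
  if (gamma_range[1] <= 0 || gamma_range[1] >= gamma_range[2])
    stop("gamma_range must satisfy 0 < low < high")
  if (amplitude_range[1] < 0 || amplitude_range[1] >= amplitude_range[2])
    stop("amplitude_range must satisfy 0 <= low < high")
  if (max_iterations < 1) stop("max_iterations must be >= 1")
  structure(list(center_window_nm = center_window_nm,
                 gamma_range = gamma_range,
                 amplitude_range = amplitude_range,
                 max_iterations = as.integer(max_iterations),
                 seed = as.integer(seed),
                 visiting_param = visiting_param,
                 acceptance_param = acceptance_param,
                 initial_temperature = initial_temperature,
                 local_polish = isTRUE(local_polish)),
            class = "optimization_config")
}

band_par_pack <- function(model) {
  centers <- vapply(model$bands, `[[`, numeric(1), "center_nm")
  gammas <- vapply(model$bands, `[[`, numeric(1), "gamma_nm")
  amps <- vapply(model$bands, `[[`, numeric(1), "amplitude")
  list(par = c(centers, gammas, amps[-1]), n_bands = length(model$bands))
}

band_par_unpack <- function(par, n_bands) {
  centers <- par[seq_len(n_bands)]
  gammas <- par[n_bands + seq_len(n_bands)]
  amps <- c(1, par[2 * n_bands + seq_len(n_bands - 1)])
  band_model(Map(lorentzian_band, centers, gammas, amps))
}

band_par_bounds <- function(init_centers, config) {
  nb <- length(init_centers)
  list(
    lower = c(init_centers - config$center_window_nm,
              rep(config$gamma_range[1], nb),
              rep(config$amplitude_range[1], nb - 1)),
    upper = c(init_centers + config$center_window_nm,
              rep(config$gamma_range[2], nb),
              rep(config$amplitude_range[2], nb - 1))
  )
}

#' Fit the band model to reference NBI patch colors
#'
#' Minimizes the mean CIEDE2000 difference between the 24 patch colors
#' rendered under the Lorentzian band model and the 24 reference NBI
#' targets, by seeded generalized simulated annealing over band centers
#' (within a window around the initial centers), HWHMs and relative
#' amplitudes (first amplitude pinned to 1). Identical seed and inputs give
#' identical results; the final objective never exceeds the initial one.
#'
#' @param patches 24 x grid matrix of patch reflectances.
#' @param targets An [nbi_target_set()].
#' @param init Initial [band_model()]; must lie inside the bounds.
#' @param config An [optimization_config()].
#' @param cmf Observer.
#' @param nominal_centers Band centers (nm) anchoring the search windows;
#'   default the standard \{415, 480, 540, 600, 700, 780\} set.
#' @return List with `model` (fitted [band_model()]), `objective` (final
#'   mean Delta-E 2000), `initial_objective`, `trace` (data.frame
#'   iteration / best_objective), `n_eval`.
#' @export
optimize_band_model <- function(patches, targets,
                                init = band_model(),
                                config = optimization_config(),
                                cmf = cie1931_cmf(),
                                nominal_centers = default_nbi_band_centers()) {
  pk <- band_par_pack(init)
  if (length(nominal_centers) != pk$n_bands)
    stop("nominal_centers length must match the number of bands")
  bounds <- band_par_bounds(nominal_centers, config)
  if (any(pk$par < bounds$lower - 1e-12) ||
      any(pk$par > bounds$upper + 1e-12))
    stop("initial band model lies outside the search bounds")
  patches <- as.matrix(patches)
  f0 <- objective_mean_de2000(init, patches, targets, cmf)
  # hot-path objective: identical algebra to objective_mean_de2000 but
  # without per-call model construction or container validation
  wl <- wavelengths(cmf$grid)
  W <- cbind(cmf$xbar, cmf$ybar, cmf$zbar)
  target_lab <- as.matrix(targets[, c("L", "a", "b")])
  nb <- pk$n_bands
  obj <- function(par) {
    gg2 <- par[nb + seq_len(nb)]^2
    aa <- c(1, par[2 * nb + seq_len(nb - 1)])
    E <- numeric(length(wl))
    for (b in seq_len(nb))
      E <- E + aa[b] * gg2[b] / ((wl - par[b])^2 + gg2[b])
    xyz <- (patches %*% (E * W)) * (100 / sum(E * W[, 2]))
    mean(de2000(xyz_to_lab(xyz), target_lab))
  }
  set.seed(config$seed)
  res <- gsa_minimize(obj, bounds$lower, bounds$upper, x0 = pk$par,
                      maxiter = config$max_iterations,
                      qv = config$visiting_param,
                      qa = config$acceptance_param,
                      t0 = config$initial_temperature,
                      local_polish = config$local_polish)
  value <- res$value
  par <- res$par
  if (f0 < value) {           # never worse than the start point
    value <- f0
    par <- pk$par
  }
  model <- band_par_unpack(par, pk$n_bands)
  # report the objective through the reference implementation
  value <- min(value, objective_mean_de2000(model, patches, targets, cmf))
  list(model = model,
       objective = value,
       initial_objective = f0,
       trace = res$trace,
       n_eval = res$n_eval)
}

#' Simulate an NBI image from a white-light image
#'
#' The full enhancement path: reconstruct per-pixel reflectance spectra
#' from the white-light sRGB image, re-illuminate them under the Lorentzian
#' band model, and render back to 8-bit sRGB (out-of-gamut values clipped).
#'
#' @param image H x W x 3 encoded sRGB array ([0,1] or 0-255).
#' @param correction A `correction_model`.
#' @param basis A `pca_basis`.
#' @param conv A `conversion_model`.
#' @param bands A [band_model()].
#' @param cmf Observer on the model grid.
#' @return H x W x 3 array of encoded sRGB in [0,1], quantized to 8-bit
#'   levels (multiples of 1/255).
#' @export
convert_wli_to_save <- function(image, correction, basis, conv, bands,
                                cmf = cie1931_cmf(basis$grid)) {
  stop_if_grid_mismatch(basis$grid, cmf$grid, "basis and observer")
  cube <- image_to_cube(image, correction, basis, conv)
  h <- dim(cube$values)[1]; w <- dim(cube$values)[2]
  S <- matrix(cube$values, h * w, dim(cube$values)[3])
  illum <- band_model_spd(bands, basis$grid)
  rgb <- xyz_to_srgb(spectrum_to_xyz(S, illum, cmf), clip = TRUE)
  array(round(rgb * 255) / 255, dim = c(h, w, 3))
}
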