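#' Read and write checker measurement CSV
#'
#' Schema: columns `patch_id, R, G, B` followed by one reflectance column
#' per grid wavelength, named `refl_<nm>`. One row per patch; patch_ids
#' must be exactly 1..24.
#'
#' @param path File path.
#' @return `read_checker_csv`: list with `patch_id`, `rgb` (24 x 3 integer),
#'   `reflectance` (24 x grid matrix), `grid`.
#' @export
read_checker_csv <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE)
  need <- c("patch_id", "R", "G", "B")
  if (!all(need %in% names(d)))
    stop("checker CSV must start with columns patch_id, R, G, B")
  refl_cols <- grep("^refl_", names(d), value = TRUE)
  if (length(refl_cols) < 2)
    stop("checker CSV has no refl_<nm> reflectance columns")
  if (!setequal(d$patch_id, 1:24))
    stop(sprintf("checker CSV must contain patch_ids 1..24; missing: %s",
                 paste(setdiff(1:24, d$patch_id), collapse = ", ")))
  d <- d[order(d$patch_id), , drop = FALSE]
  wl <- as.numeric(sub("^refl_", "", refl_cols))
  grid <- grid_from_wavelengths(wl)
  refl <- as.matrix(d[, refl_cols])
  dimnames(refl) <- NULL
  if (any(!is.finite(refl)) || any(refl < 0) || any(refl > 1))
    stop("reflectance values must lie in [0, 1]")
  rgb <- as.matrix(d[, c("R", "G", "B")])
  list(patch_id = as.integer(d$patch_id), rgb = rgb,
       reflectance = refl, grid = grid)
}

#' @rdname read_checker_csv
#' @param rgb 24 x 3 matrix of 8-bit RGB.
#' @param reflectance 24 x grid matrix in [0,1].
#' @param grid The [wavelength_grid()].
#' @export
write_checker_csv <- function(rgb, reflectance, grid, path) {
  refl <- as.matrix(reflectance)
  d <- data.frame(patch_id = 1:24, R = rgb[, 1], G = rgb[, 2], B = rgb[, 3])
  refl_df <- as.data.frame(refl)
  names(refl_df) <- paste0("refl_", wavelengths(grid))
  utils::write.csv(cbind(d, refl_df), path, row.names = FALSE)
  invisible(path)
}

#' Read and write an SPD as CSV
#'
#' Two columns with a header: `wavelength_nm, power`.
#' @param path File path.
#' @return `read_spd_csv` returns an [spd()].
#' @export
read_spd_csv <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE)
  if (!all(c("wavelength_nm", "power") %in% names(d)))
    stop("SPD CSV must have columns wavelength_nm, power")
  spd(grid_from_wavelengths(d$wavelength_nm), d$power)
}

#' @rdname read_spd_csv
#' @param x An [spd()].
#' @export
write_spd_csv <- function(x, path) {
  utils::write.csv(data.frame(wavelength_nm = wavelengths(x$grid),
                              power = x$power),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read and write NBI target CSV
#'
#' Lab targets: columns `patch_id, L, a, b`. sRGB targets: columns
#' `patch_id, R, G, B` (8-bit), converted to Lab(D65) on read via the sRGB
#' pipeline -- the ingestion path for patch colors measured off a real NBI
#' photograph.
#'
#' @param path File path.
#' @param srgb Is the file in the sRGB layout?
#' @return An [nbi_target_set()].
#' @export
read_targets_csv <- function(path, srgb = FALSE) {
  d <- utils::read.csv(path, check.names = FALSE)
  if (srgb) {
    if (!all(c("patch_id", "R", "G", "B") %in% names(d)))
      stop("sRGB target CSV must have columns patch_id, R, G, B")
    lab <- xyz_to_lab(srgb_to_xyz(srgb_decode(
      as.matrix(d[, c("R", "G", "B")]) / 255)))
  } else {
    if (!all(c("patch_id", "L", "a", "b") %in% names(d)))
      stop("Lab target CSV must have columns patch_id, L, a, b")
    lab <- as.matrix(d[, c("L", "a", "b")])
  }
  nbi_target_set(lab, d$patch_id)
}

#' @rdname read_targets_csv
#' @param targets An [nbi_target_set()].
#' @export
write_targets_csv <- function(targets, path) {
  utils::write.csv(targets, path, row.names = FALSE)
  invisible(path)
}

grid_to_list <- function(grid)
  list(start_nm = grid$start_nm, stop_nm = grid$stop_nm,
       step_nm = grid$step_nm)

grid_from_list <- function(x)
  wavelength_grid(x$start_nm, x$stop_nm, x$step_nm)

#' Model serialization to JSON
#'
#' `correction_model`, the PCA basis + conversion model pair, and
#' `band_model` round-trip through plain JSON documents (matrices stored
#' row-major with explicit dimensions and grid headers).
#'
#' @param model,basis,conv,path Objects / file path.
#' @name model-json
#' @export
write_correction_json <- function(model, path) {
  jsonlite::write_json(list(
    type = "correction_model",
    expansion_terms = model$expansion$terms,
    C = model$C), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname model-json
#' @export
read_correction_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(x$type, "correction_model"))
    stop("not a correction_model JSON document")
  structure(list(expansion = variable_expansion(x$expansion_terms),
                 C = as.matrix(x$C)), class = "correction_model")
}

#' @rdname model-json
#' @export
write_reconstruction_json <- function(basis, conv, path) {
  jsonlite::write_json(list(
    type = "reconstruction_model",
    grid = grid_to_list(basis$grid),
    mean_spectrum = basis$mean_spectrum,
    components = basis$components,
    explained_variance_ratio = basis$explained_variance_ratio,
    expansion_terms = conv$expansion$terms,
    M = conv$M), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname model-json
#' @export
read_reconstruction_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(x$type, "reconstruction_model"))
    stop("not a reconstruction_model JSON document")
  basis <- structure(list(
    grid = grid_from_list(x$grid),
    mean_spectrum = as.numeric(x$mean_spectrum),
    components = as.matrix(x$components),
    explained_variance_ratio = as.numeric(x$explained_variance_ratio)),
    class = "pca_basis")
  conv <- structure(list(expansion = variable_expansion(x$expansion_terms),
                         M = as.matrix(x$M)), class = "conversion_model")
  list(basis = basis, conversion = conv)
}

#' @rdname model-json
#' @param bands A [band_model()].
#' @export
write_band_model_json <- function(bands, path) {
  jsonlite::write_json(list(
    type = "band_model",
    bands = lapply(bands$bands, function(b)
      list(center_nm = b$center_nm, gamma_nm = b$gamma_nm,
           amplitude = b$amplitude))),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname model-json
#' @export
read_band_model_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(x$type, "band_model"))
    stop("not a band_model JSON document")
  band_model(lapply(x$bands, function(b)
    lorentzian_band(b$center_nm, b$gamma_nm, b$amplitude)))
}

#' Read and write 8-bit RGB images
#'
#' PNG always; TIFF when the `tiff` package is available. Images are
#' H x W x 3 arrays of encoded sRGB in [0,1]; writing quantizes to 8 bits.
#'
#' @param path File path; format chosen by extension (.png / .tif(f)).
#' @return `read_image`: an H x W x 3 array in [0,1].
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("reading TIFF requires the 'tiff' package")
      tiff::readTIFF(path)
    },
    stop(sprintf("unsupported image extension '%s'", ext)))
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  if (dim(img)[3] > 3) img <- img[, , 1:3, drop = FALSE]  # drop alpha
  img
}

#' @rdname read_image
#' @param image H x W x 3 array in [0,1].
#' @export
write_image <- function(image, path) {
  img <- round(pmin(pmax(image, 0), 1) * 255) / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(img, path),
    tif = , tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("writing TIFF requires the 'tiff' package")
      tiff::writeTIFF(img, path, bits.per.sample = 8L)
    },
    stop(sprintf("unsupported image extension '%s'", ext)))
  invisible(path)
}

#' Read and write spectral cubes
#'
#' Cubes are stored as a compressed serialized archive holding the
#' wavelength vector (`wavelengths_nm`) alongside the reflectance array
#' (`reflectance`, row x column x wavelength).
#'
#' @param cube A `spectral_cube`.
#' @param path File path.
#' @export
write_cube <- function(cube, path) {
  saveRDS(list(wavelengths_nm = wavelengths(cube$grid),
               reflectance = cube$values),
          path, compress = "gzip")
  invisible(path)
}

#' @rdname write_cube
#' @export
read_cube <- function(path) {
  x <- readRDS(path)
  structure(list(grid = grid_from_wavelengths(x$wavelengths_nm),
                 values = x$reflectance), class = "spectral_cube")
}

#' Read and write optimizer traces
#'
#' Two-column CSV `iteration, best_objective`.
#' @param trace data.frame from [optimize_band_model()].
#' @param path File path.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(trace[, c("iteration", "best_objective")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  utils::read.csv(path)
}
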