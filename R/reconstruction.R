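#' Principal-component basis of checker reflectances
#'
#' Mean-centered PCA of the measured patch reflectance spectra. Components
#' are eigenvectors of the sample covariance ordered by decreasing
#' eigenvalue; each component's sign is fixed by making its
#' largest-magnitude coefficient positive, so the decomposition is
#' deterministic.
#'
#' @param spectra n x grid-length matrix of reflectance spectra (rows are
#'   patches).
#' @param n_pc Number of components to retain, in `1 .. min(n, grid) - 1`.
#'   The default 12 keeps ample variance for 24 smooth patches while the
#'   score regression stays over-determined.
#' @param grid The [wavelength_grid()] the spectra live on.
#' @return An object of class `pca_basis`: `grid`, `mean_spectrum`,
#'   `components` (n_pc x grid length, orthonormal rows),
#'   `explained_variance_ratio`.
#' @export
fit_pca <- function(spectra, n_pc = 12, grid = wavelength_grid()) {
  spectra <- as.matrix(spectra)
  n <- nrow(spectra)
  if (ncol(spectra) != grid_length(grid))
    stop("spectra width does not match the wavelength grid")
  max_pc <- min(n, ncol(spectra)) - 1L
  if (n_pc < 1 || n_pc > max_pc)
    stop(sprintf("n_pc must lie in 1..%d (got %d)", max_pc, n_pc))
  mu <- colMeans(spectra)
  Xc <- sweep(spectra, 2, mu)
  sv <- svd(Xc, nu = 0, nv = n_pc)
  ev <- sv$d^2 / (n - 1)
  total <- sum(ev)
  if (total < 1e-20)
    stop("degenerate variance: all spectra are identical")
  comp <- t(sv$v)                       # n_pc x grid
  for (i in seq_len(n_pc)) {            # deterministic sign convention
    j <- which.max(abs(comp[i, ]))
    if (comp[i, j] < 0) comp[i, ] <- -comp[i, ]
  }
  structure(list(
    grid = grid,
    mean_spectrum = mu,
    components = comp,
    explained_variance_ratio = ev[seq_len(n_pc)] / total
  ), class = "pca_basis")
}

#' Project spectra onto a PCA basis
#'
#' Scores are `components %*% (spectrum - mean_spectrum)`.
#'
#' @param basis A `pca_basis`.
#' @param spectrum Reflectance vector of grid length, or an n x grid matrix.
#' @return Score vector of length n_pc, or n x n_pc matrix.
#' @export
project_scores <- function(basis, spectrum) {
  S <- if (is.matrix(spectrum)) spectrum else matrix(spectrum, nrow = 1)
  if (ncol(S) != length(basis$mean_spectrum))
    stop("spectrum length does not match the basis grid")
  out <- sweep(S, 2, basis$mean_spectrum) %*% t(basis$components)
  if (is.matrix(spectrum)) out else drop(out)
}

#' Fit the conversion matrix M
#'
#' Least-squares regression of principal-component scores on the expanded
#' corrected XYZ: M minimizes ||PS - M V(XYZ_correct)||. Each row of M
#' (one score component) is solved independently by the same QR
#' decomposition.
#'
#' @param scores n x n_pc matrix of patch scores from [project_scores()].
#' @param corrected_xyz n x 3 matrix of corrected XYZ (0-100 scale).
#' @param expansion A [variable_expansion()]; by default the same 11-term
#'   set used for camera correction.
#' @return An object of class `conversion_model` with `expansion` and `M`
#'   (n_pc x n_terms).
#' @export
fit_conversion_matrix <- function(scores, corrected_xyz,
                                  expansion = variable_expansion()) {
  scores <- as.matrix(scores)
  corrected_xyz <- as.matrix(corrected_xyz)
  if (nrow(scores) != nrow(corrected_xyz))
    stop("scores and corrected XYZ must have the same number of patches")
  V <- expand_xyz(corrected_xyz, expansion)
  qrV <- qr(V)
  if (qrV$rank < n_terms(expansion)) {
    dropped <- setdiff(seq_len(n_terms(expansion)),
                       qrV$pivot[seq_len(qrV$rank)])
    stop(sprintf("design matrix is rank deficient; deficient columns: %s",
                 paste(dropped, collapse = ", ")))
  }
  M <- t(qr.coef(qrV, scores))          # n_pc x p
  structure(list(expansion = expansion, M = M), class = "conversion_model")
}

#' Reconstruct an analog reflectance spectrum from XYZ
#'
#' The analog spectrum is `mean_spectrum + t(components) %*% (M V(t))`:
#' score coefficients predicted from the expanded corrected tristimulus,
#' then expanded in the PCA basis with the mean added back. Output is
#' clipped to [0,1] unless `clip = FALSE` (diagnostics want raw residuals).
#'
#' @param basis A `pca_basis`.
#' @param model A `conversion_model`.
#' @param t Corrected XYZ: length-3 vector or n x 3 matrix (0-100 scale).
#' @param clip Clip reflectance into [0,1]?
#' @return Reflectance vector of grid length, or n x grid matrix.
#' @export
reconstruct_spectrum <- function(basis, model, t, clip = TRUE) {
  V <- expand_xyz(t, model$expansion)
  if (!is.matrix(V)) V <- matrix(V, nrow = 1)
  if (ncol(V) != ncol(model$M)) stop("expansion/model dimension mismatch")
  if (nrow(model$M) != nrow(basis$components))
    stop("conversion model and basis disagree on n_pc")
  scores <- V %*% t(model$M)                       # n x n_pc
  S <- sweep(scores %*% basis$components, 2, basis$mean_spectrum, "+")
  if (clip) S <- pmin(pmax(S, 0), 1)
  if (is.matrix(t)) S else drop(S)
}

#' Root-mean-square difference between two spectra
#'
#' @param a,b Reflectance vectors on one grid.
#' @return Non-negative scalar; 0 iff identical.
#' @export
spectrum_rmse <- function(a, b) {
  if (length(a) != length(b)) stop("spectra have different lengths")
  sqrt(mean((a - b)^2))
}

#' Convert an sRGB image to a spectral cube
#'
#' Per pixel: sRGB decode, XYZ, camera correction, spectrum reconstruction.
#' The implementation is vectorized over pixels but algebraically identical
#' to the scalar path. A uniform image yields a uniform cube.
#'
#' @param image H x W x 3 array of encoded sRGB in [0,1] (as returned by
#'   [read_image()]), or 8-bit integers 0-255.
#' @param correction A `correction_model`.
#' @param basis A `pca_basis`.
#' @param model A `conversion_model`.
#' @param clip Clip reflectance into [0,1] at materialization (default).
#' @return An object of class `spectral_cube`: `grid` plus `values`, an
#'   H x W x grid-length array (wavelength axis last).
#' @export
image_to_cube <- function(image, correction, basis, model, clip = TRUE) {
  img <- as_encoded_image(image)
  h <- dim(img)[1]; w <- dim(img)[2]
  rgb <- matrix(img, h * w, 3)
  xyz <- srgb_to_xyz(srgb_decode(rgb))
  xyzc <- apply_correction(correction, xyz)
  S <- reconstruct_spectrum(basis, model, xyzc, clip = clip)
  cube <- array(S, dim = c(h, w, ncol(S)))
  structure(list(grid = basis$grid, values = cube), class = "spectral_cube")
}

as_encoded_image <- function(image) {
  if (length(dim(image)) != 3 || dim(image)[3] != 3)
    stop("image must be an H x W x 3 array of RGB channels")
  img <- image
  if (max(img) > 1 + 1e-9) img <- img / 255
  if (any(img < -1e-9) || any(img > 1 + 1e-9))
    stop("image channels must lie in [0,1] or 0-255")
  pmin(pmax(img, 0), 1)
}

#' @export
print.spectral_cube <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<spectral_cube> %d x %d pixels, %d bands (%g-%g nm)\n",
              d[1], d[2], d[3], x$grid$start_nm, x$grid$stop_nm))
  invisible(x)
}
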