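#' Polynomial variable expansion of tristimulus values
#'
#' The camera correction and the spectrum conversion both regress against a
#' polynomial expansion V of XYZ. An expansion is an ordered list of
#' monomials given as exponent triples (a, b, c), meaning X^a * Y^b * Z^c;
#' the first term must be the constant (0, 0, 0). Monomials are evaluated on
#' XYZ/100 so the design matrix stays well-conditioned.
#'
#' The default is the 11-term second-order set
#' \{1, X, Y, Z, XY, XZ, YZ, X^2, Y^2, Z^2, XYZ\}, compact enough that 24
#' checker patches over-determine the fit while still absorbing channel
#' cross-talk, color shift and dark-current style offsets.
#'
#' @param terms Integer matrix, one row per monomial, columns = exponents of
#'   (X, Y, Z).
#' @return An object of class `variable_expansion`.
#' @export
variable_expansion <- function(terms = default_expansion_terms()) {
  terms <- as.matrix(terms)
  if (nrow(terms) == 0) stop("expansion needs at least one term")
  if (ncol(terms) != 3) stop("each term is an (X, Y, Z) exponent triple")
  if (any(terms[1, ] != 0)) stop("first term must be the constant (0,0,0)")
  if (anyDuplicated(apply(terms, 1, paste, collapse = ",")))
    stop("duplicate monomials in expansion")
  dimnames(terms) <- list(NULL, c("X", "Y", "Z"))
  structure(list(terms = terms), class = "variable_expansion")
}

#' @rdname variable_expansion
#' @export
default_expansion_terms <- function() {
  matrix(c(0, 0, 0,   # 1
           1, 0, 0,   # X
           0, 1, 0,   # Y
           0, 0, 1,   # Z
           1, 1, 0,   # XY
           1, 0, 1,   # XZ
           0, 1, 1,   # YZ
           2, 0, 0,   # X^2
           0, 2, 0,   # Y^2
           0, 0, 2,   # Z^2
           1, 1, 1),  # XYZ
         ncol = 3, byrow = TRUE)
}

n_terms <- function(expansion) nrow(expansion$terms)

#' Evaluate a variable expansion
#'
#' @param t Length-3 XYZ vector or n x 3 matrix on the 0-100 scale; values
#'   are divided by 100 before the monomials are evaluated.
#' @param expansion A [variable_expansion()].
#' @return Expanded vector of length `n_terms`, or an n x n_terms matrix.
#' @export
expand_xyz <- function(t, expansion = variable_expansion()) {
  m <- if (is.matrix(t)) t else matrix(t, ncol = 3)
  if (any(!is.finite(m))) stop("tristimulus values must be finite")
  s <- m / 100
  ex <- expansion$terms
  out <- matrix(1, nrow(s), nrow(ex))
  for (j in seq_len(nrow(ex))) {
    for (ch in 1:3) {
      e <- ex[j, ch]
      if (e != 0) out[, j] <- out[, j] * s[, ch]^e
    }
  }
  if (is.matrix(t)) out else drop(out)
}

#' Fit the camera correction matrix
#'
#' Ordinary least squares of spectrum-derived XYZ on the expanded camera
#' XYZ over the checker patches: C minimizes
#' ||XYZ_spectrum - C V(XYZ_camera)|| in the Frobenius norm. Both sides are
#' taken on the internal 0-1 scale (XYZ/100); [apply_correction()] restores
#' the 0-100 convention. The fit is deterministic (QR decomposition).
#'
#' @param camera_xyz n x 3 matrix of camera-derived XYZ (0-100 scale),
#'   typically from `srgb_to_xyz(srgb_decode(rgb/255))`.
#' @param spectrum_xyz n x 3 matrix of spectrometer-derived XYZ from
#'   [spectrum_to_xyz()] over the measured patch reflectances.
#' @param expansion A [variable_expansion()].
#' @return An object of class `correction_model` with elements `expansion`
#'   and `C` (3 x n_terms).
#' @export
fit_correction <- function(camera_xyz, spectrum_xyz,
                           expansion = variable_expansion()) {
  camera_xyz <- as.matrix(camera_xyz)
  spectrum_xyz <- as.matrix(spectrum_xyz)
  if (nrow(camera_xyz) != nrow(spectrum_xyz))
    stop("camera and spectrum XYZ must have the same number of patches")
  if (any(!is.finite(camera_xyz)) || any(!is.finite(spectrum_xyz)))
    stop("XYZ inputs must be finite")
  p <- n_terms(expansion)
  if (nrow(camera_xyz) < p)
    stop(sprintf(
      "rank deficiency: %d patches cannot determine %d expansion terms",
      nrow(camera_xyz), p))
  V <- expand_xyz(camera_xyz, expansion)
  qrV <- qr(V)
  if (qrV$rank < p)
    stop(sprintf("design matrix is rank deficient (rank %d < %d terms)",
                 qrV$rank, p))
  coef <- qr.coef(qrV, spectrum_xyz / 100)   # p x 3
  structure(list(expansion = expansion, C = t(coef)),
            class = "correction_model")
}

#' Apply a camera correction
#'
#' Returns `C V(t)` rescaled back to the 0-100 convention.
#'
#' @param model A `correction_model` from [fit_correction()].
#' @param t Length-3 XYZ vector or n x 3 matrix (0-100 scale).
#' @return Corrected XYZ, same shape as input.
#' @export
apply_correction <- function(model, t) {
  V <- expand_xyz(t, model$expansion)
  if (!is.matrix(V)) V <- matrix(V, nrow = 1)
  out <- 100 * (V %*% t(model$C))
  colnames(out) <- c("X", "Y", "Z")
  if (is.matrix(t)) out else drop(out)
}

#' Pooled root-mean-square XYZ error
#'
#' RMS over all 3n scalar components of n paired tristimulus values; this
#' pooling (rather than per-patch vector norms) is how the single
#' calibration error number is defined here.
#'
#' @param predicted,reference n x 3 matrices (or length-3 vectors).
#' @return Non-negative scalar; 0 iff the sets are identical.
#' @export
calibration_rmse <- function(predicted, reference) {
  p <- if (is.matrix(predicted)) predicted else matrix(predicted, ncol = 3)
  r <- if (is.matrix(reference)) reference else matrix(reference, ncol = 3)
  if (nrow(p) == 0) stop("calibration_rmse needs at least one pair")
  if (!all(dim(p) == dim(r))) stop("predicted and reference shapes differ")
  sqrt(mean((p - r)^2))
}
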