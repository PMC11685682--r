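#' Spectral power distribution
#'
#' Relative illuminant power per wavelength on a common grid. Power is
#' dimensionless and non-negative; only ratios matter, because every
#' colorimetric integration normalizes by the luminance ratio k (see
#' [spectrum_to_xyz()]).
#'
#' @param grid A [wavelength_grid()].
#' @param power Non-negative numeric vector of `grid_length(grid)` values.
#' @return An object of class `spd`.
#' @export
spd <- function(grid, power) {
  if (length(power) != grid_length(grid))
    stop(sprintf("SPD length %d does not match grid length %d",
                 length(power), grid_length(grid)))
  if (any(!is.finite(power)) || any(power < 0))
    stop("SPD power must be finite and non-negative")
  structure(list(grid = grid, power = power), class = "spd")
}

# --- sRGB transfer functions (IEC 61966-2-1) --------------------------------

#' sRGB transfer functions
#'
#' `srgb_decode` maps gamma-encoded sRGB channel values in [0,1] to linear
#' light; `srgb_encode` is its inverse. Both use the piecewise IEC 61966-2-1
#' curve (linear toe below 0.04045 / 0.0031308, power 2.4 above), applied
#' per channel, and are strictly monotone on [0,1].
#'
#' @param x Numeric vector/array of channel values in [0,1]. 8-bit values
#'   must be divided by 255 first.
#' @return Numeric object of the same shape.
#' @examples
#' srgb_decode(srgb_encode(0.25))  # 0.25
#' @export
srgb_decode <- function(x) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop("encoded sRGB channels must lie in [0, 1]; scale 8-bit values by 255")
  ifelse(x <= 0.04045, x / 12.92, ((x + 0.055) / 1.055)^2.4)
}

#' @rdname srgb_decode
#' @export
srgb_encode <- function(x) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop("linear sRGB channels must lie in [0, 1] before encoding")
  ifelse(x <= 0.0031308, 12.92 * x, 1.055 * x^(1 / 2.4) - 0.055)
}

# sRGB (D65) linear RGB -> XYZ, rows X, Y, Z; on the 0-1 luminance scale.
# Rescaled by the Y row sum so that linear white maps to Y = 1 exactly.
SRGB_TO_XYZ <- local({
  m <- matrix(c(
    0.4124564, 0.3575761, 0.1804375,
    0.2126729, 0.7151522, 0.0721750,
    0.0193339, 0.1191920, 0.9503041), nrow = 3, byrow = TRUE)
  m / sum(m[2, ])
})
XYZ_TO_SRGB <- solve(SRGB_TO_XYZ)

#' D65 reference white (0-100 scale)
#'
#' The white point used throughout for Lab conversion: the row sums of the
#' sRGB primaries matrix, so that linear RGB (1,1,1) maps exactly to it.
#' @export
d65_white <- function() 100 * rowSums(SRGB_TO_XYZ)

as_rgb_matrix <- function(c) {
  m <- if (is.matrix(c)) c else matrix(c, ncol = 3)
  if (ncol(m) != 3) stop("RGB input must have 3 channels")
  m
}

#' Linear sRGB to CIE 1931 XYZ
#'
#' Applies the standard sRGB(D65) primaries matrix and scales so linear
#' white (1,1,1) maps to the D65 white point on the 0-100 luminance scale.
#' Input must already be linear light (see [srgb_decode()]).
#'
#' @param c Length-3 vector or n x 3 matrix of linear channels in [0,1].
#' @return Tristimulus values: length-3 vector or n x 3 matrix (X, Y, Z).
#' @export
srgb_to_xyz <- function(c) {
  m <- as_rgb_matrix(c)
  if (any(!is.finite(m)) || any(m < 0) || any(m > 1))
    stop("srgb_to_xyz expects linear channels in [0, 1]; decode first")
  out <- 100 * (m %*% t(SRGB_TO_XYZ))
  colnames(out) <- c("X", "Y", "Z")
  if (is.matrix(c)) out else drop(out)
}

#' CIE XYZ to encoded sRGB
#'
#' Inverse primaries matrix, optional clipping of linear channels to [0,1],
#' then gamma encoding. With `clip = FALSE`, out-of-gamut tristimuli yield
#' out-of-range channels unchanged (and un-encoded outside [0,1] is an
#' error), so the default is to clip.
#'
#' @param t Length-3 vector or n x 3 matrix of XYZ on the 0-100 scale.
#' @param clip Clip linear channels into [0,1] before encoding?
#' @return Encoded sRGB channels in [0,1], same shape as input.
#' @export
xyz_to_srgb <- function(t, clip = TRUE) {
  m <- if (is.matrix(t)) t else matrix(t, ncol = 3)
  if (any(!is.finite(m))) stop("tristimulus values must be finite")
  lin <- (m / 100) %*% t(XYZ_TO_SRGB)
  if (clip) {
    lin <- pmin(pmax(lin, 0), 1)
    out <- srgb_encode(lin)
  } else {
    out <- lin
    inside <- lin >= 0 & lin <= 1
    out[inside] <- srgb_encode(lin[inside])
  }
  colnames(out) <- c("r", "g", "b")
  if (is.matrix(t)) out else drop(out)
}

# --- spectral integration ---------------------------------------------------

#' Reflectance spectrum to tristimulus values
#'
#' Riemann-sum integration of reflectance x illuminant against the observer,
#' normalized by the luminance ratio k = 100 / sum(E * ybar) so that a
#' perfect reflector has Y = 100 under any non-degenerate illuminant:
#' X = k * sum(R E xbar), and likewise Y, Z.
#'
#' @param reflectance Numeric vector of grid length in [0,1], or an
#'   n x grid-length matrix of spectra (one per row).
#' @param illuminant An [spd()].
#' @param cmf A `cmf`; default [cie1931_cmf()] on the illuminant grid.
#' @return Length-3 XYZ vector, or n x 3 matrix for matrix input.
#' @export
spectrum_to_xyz <- function(reflectance, illuminant,
                            cmf = cie1931_cmf(illuminant$grid)) {
  stop_if_grid_mismatch(illuminant$grid, cmf$grid, "illuminant and CMF")
  n <- grid_length(illuminant$grid)
  R <- if (is.matrix(reflectance)) reflectance else matrix(reflectance, nrow = 1)
  if (ncol(R) != n)
    stop(sprintf("reflectance length %d does not match grid length %d",
                 ncol(R), n))
  if (any(!is.finite(R))) stop("reflectance must be finite")
  denom <- sum(illuminant$power * cmf$ybar)
  if (denom <= 0)
    stop("degenerate illuminant: sum(E * ybar) is zero")
  k <- 100 / denom
  W <- illuminant$power * cbind(cmf$xbar, cmf$ybar, cmf$zbar)
  out <- k * (R %*% W)
  colnames(out) <- c("X", "Y", "Z")
  if (is.matrix(reflectance)) out else drop(out)
}

# --- Lab --------------------------------------------------------------------

lab_f <- function(t) {
  d <- 6 / 29
  ifelse(t > d^3, t^(1 / 3), t / (3 * d^2) + 4 / 29)
}

#' CIE XYZ to CIELAB
#'
#' Standard CIE L*a*b* against a reference white (default D65). The white
#' maps to (100, 0, 0).
#'
#' @param t Length-3 vector or n x 3 matrix of XYZ (0-100 scale).
#' @param white Reference white XYZ, strictly positive components.
#' @return Length-3 `(L, a, b)` vector or n x 3 matrix.
#' @export
xyz_to_lab <- function(t, white = d65_white()) {
  if (any(!is.finite(white)) || any(white <= 0))
    stop("reference white must have strictly positive components")
  m <- if (is.matrix(t)) t else matrix(t, ncol = 3)
  fx <- lab_f(m[, 1] / white[1])
  fy <- lab_f(m[, 2] / white[2])
  fz <- lab_f(m[, 3] / white[3])
  out <- cbind(L = 116 * fy - 16, a = 500 * (fx - fy), b = 200 * (fy - fz))
  if (is.matrix(t)) out else drop(out)
}

# --- color differences ------------------------------------------------------

#' Color difference between Lab pairs
#'
#' `method = "DE76"` is the Euclidean distance in Lab; `"DE94"` the CIE 1994
#' formula (graphic-arts weights, first argument as reference); `"DE2000"`
#' the full CIEDE2000 formula including the chroma-dependent G correction,
#' lightness/chroma/hue weighting functions and the blue-region hue-rotation
#' term.
#'
#' @param lab1,lab2 Length-3 Lab vectors or n x 3 matrices (paired by row).
#' @param method One of `"DE76"`, `"DE94"`, `"DE2000"`.
#' @return Non-negative difference(s).
#' @export
delta_e <- function(lab1, lab2, method = c("DE2000", "DE76", "DE94")) {
  method <- match.arg(method)
  a <- if (is.matrix(lab1)) lab1 else matrix(lab1, ncol = 3)
  b <- if (is.matrix(lab2)) lab2 else matrix(lab2, ncol = 3)
  if (nrow(a) != nrow(b)) stop("delta_e operands must pair row-by-row")
  out <- switch(method,
    DE76 = sqrt(rowSums((a - b)^2)),
    DE94 = de94(a, b),
    DE2000 = de2000(a, b))
  if (is.matrix(lab1) || is.matrix(lab2)) out else drop(out)
}

de94 <- function(a, b, kL = 1, kC = 1, kH = 1) {
  C1 <- sqrt(a[, 2]^2 + a[, 3]^2)
  C2 <- sqrt(b[, 2]^2 + b[, 3]^2)
  dL <- a[, 1] - b[, 1]
  dC <- C1 - C2
  dH2 <- pmax((a[, 2] - b[, 2])^2 + (a[, 3] - b[, 3])^2 - dC^2, 0)
  sC <- 1 + 0.045 * C1
  sH <- 1 + 0.015 * C1
  sqrt((dL / kL)^2 + (dC / (kC * sC))^2 + dH2 / (kH * sH)^2)
}

de2000 <- function(lab1, lab2, kL = 1, kC = 1, kH = 1) {
  deg <- pi / 180
  L1 <- lab1[, 1]; a1 <- lab1[, 2]; b1 <- lab1[, 3]
  L2 <- lab2[, 1]; a2 <- lab2[, 2]; b2 <- lab2[, 3]

  Cab1 <- sqrt(a1^2 + b1^2)
  Cab2 <- sqrt(a2^2 + b2^2)
  Cbar <- (Cab1 + Cab2) / 2
  G <- 0.5 * (1 - sqrt(Cbar^7 / (Cbar^7 + 25^7)))
  a1p <- (1 + G) * a1
  a2p <- (1 + G) * a2
  C1p <- sqrt(a1p^2 + b1^2)
  C2p <- sqrt(a2p^2 + b2^2)
  h1p <- ifelse(C1p == 0, 0, (atan2(b1, a1p) / deg) %% 360)
  h2p <- ifelse(C2p == 0, 0, (atan2(b2, a2p) / deg) %% 360)

  dLp <- L2 - L1
  dCp <- C2p - C1p
  dh <- h2p - h1p
  dhp <- ifelse(C1p * C2p == 0, 0,
         ifelse(dh > 180, dh - 360,
         ifelse(dh < -180, dh + 360, dh)))
  dHp <- 2 * sqrt(C1p * C2p) * sin(dhp * deg / 2)

  Lbp <- (L1 + L2) / 2
  Cbp <- (C1p + C2p) / 2
  hsum <- h1p + h2p
  habs <- abs(h1p - h2p)
  hbp <- ifelse(C1p * C2p == 0, hsum,
         ifelse(habs <= 180, hsum / 2,
         ifelse(hsum < 360, (hsum + 360) / 2, (hsum - 360) / 2)))

  T <- 1 - 0.17 * cos((hbp - 30) * deg) + 0.24 * cos(2 * hbp * deg) +
       0.32 * cos((3 * hbp + 6) * deg) - 0.20 * cos((4 * hbp - 63) * deg)
  dtheta <- 30 * exp(-((hbp - 275) / 25)^2)
  RC <- 2 * sqrt(Cbp^7 / (Cbp^7 + 25^7))
  SL <- 1 + 0.015 * (Lbp - 50)^2 / sqrt(20 + (Lbp - 50)^2)
  SC <- 1 + 0.045 * Cbp
  SH <- 1 + 0.015 * Cbp * T
  RT <- -sin(2 * dtheta * deg) * RC

  sqrt((dLp / (kL * SL))^2 + (dCp / (kC * SC))^2 + (dHp / (kH * SH))^2 +
       RT * (dCp / (kC * SC)) * (dHp / (kH * SH)))
}
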