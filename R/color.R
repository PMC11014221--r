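# RGB -> XYZ -> CIELAB conversion.
#
# The XYZ step is a fixed linear map applied directly to the R,G,B channels
# (no gamma linearisation by default); the LAB step uses the standard CIE
# companding function f and a D65-style white point.

# Coefficients as commonly printed for D65 RGB->XYZ. Note the (1,2) entry
# 0.35780: the first row then sums to 0.950676 rather than the white point's
# Xn = 0.950456 (a ~2e-4 truncation of the usual 0.357580). The truncated
# value is the package default; `strict_cie = TRUE` restores 0.357580 so
# that white maps exactly onto the white point.
.rgb2xyz_default <- matrix(c(
  0.412453, 0.35780,  0.180423,
  0.212671, 0.715160, 0.072169,
  0.019334, 0.119193, 0.950227), nrow = 3, byrow = TRUE)

.rgb2xyz_strict <- local({
  m <- .rgb2xyz_default
  m[1, 2] <- 0.357580
  m
})

#' Reference white point
#'
#' Tristimulus values of the reference white used by [xyz_to_lab()].
#' Defaults to the D65-style point (0.950456, 1.0, 1.088754).
#'
#' @param x,y,z Positive reals.
#' @return Named numeric vector of class `"white_point"`.
#' @export
white_point <- function(x = 0.950456, y = 1.0, z = 1.088754) {
  if (any(c(x, y, z) <= 0)) stop("white point components must be positive", call. = FALSE)
  structure(c(Xn = x, Yn = y, Zn = z), class = "white_point")
}

# CIE companding function: cube root above (6/29)^3, linear segment below.
f_cie <- function(t) {
  delta <- 6 / 29
  ifelse(t > delta^3, t^(1 / 3), t / (3 * delta^2) + 4 / 29)
}

# sRGB electro-optical transfer (gamma expansion), optional preprocessing.
srgb_linearize <- function(v) {
  ifelse(v <= 0.04045, v / 12.92, ((v + 0.055) / 1.055)^2.4)
}

#' Convert an RGB image to CIE XYZ
#'
#' Applies the fixed 3x3 conversion matrix per pixel. Channel values must be
#' in \[0, 1\] (8-bit images should be divided by 255 first, as
#' [read_image()] does).
#'
#' @param img H x W x 3 numeric array, channels R,G,B in \[0, 1\].
#' @param strict_cie Use 0.357580 instead of the truncated 0.35780 for the
#'   (1,2) matrix entry, making white map exactly to the white point.
#' @param linearize Apply sRGB gamma expansion before the linear map.
#'   Off by default: the conversion is defined directly on the stored
#'   channel values.
#' @return H x W x 3 numeric array, channels X,Y,Z.
#' @examples
#' px <- array(c(1, 0, 0), c(1, 1, 3))
#' rgb_to_xyz(px)[1, 1, ]  # first column of the conversion matrix
#' @export
rgb_to_xyz <- function(img, strict_cie = FALSE, linearize = FALSE) {
  assert_image(img, "RGB image")
  tol <- 1e-6
  rng <- range(img)
  if (rng[1] < -tol || rng[2] > 1 + tol)
    stop(sprintf("RGB channel values must lie in [0,1]; found range [%.4g, %.4g]",
                 rng[1], rng[2]), call. = FALSE)
  img[img < 0] <- 0
  img[img > 1] <- 1
  if (linearize) img[] <- srgb_linearize(img)
  m <- if (strict_cie) .rgb2xyz_strict else .rgb2xyz_default
  d <- dim(img)
  flat <- matrix(img, ncol = 3L)      # N x 3, columns R,G,B
  out <- flat %*% t(m)
  array(out, d)
}

#' Convert a CIE XYZ image to CIELAB
#'
#' L = 116 f(Y/Yn) - 16, a = 500 (f(X/Xn) - f(Y/Yn)),
#' b = 200 (f(Y/Yn) - f(Z/Zn)), with f the standard CIE companding function
#' (cube root above (6/29)^3, linear segment below).
#'
#' @param img H x W x 3 numeric array, channels X,Y,Z (nonnegative).
#' @param white A [white_point()].
#' @return H x W x 3 numeric array, channels L (0-100 for in-gamut input),
#'   a, b.
#' @examples
#' wp <- white_point()
#' xyz_to_lab(array(unclass(wp), c(1, 1, 3)))[1, 1, ]  # exactly (100, 0, 0)
#' @export
xyz_to_lab <- function(img, white = white_point()) {
  assert_image(img, "XYZ image")
  if (min(img) < -1e-9) stop("XYZ values must be nonnegative", call. = FALSE)
  fx <- f_cie(img[, , 1] / white[["Xn"]])
  fy <- f_cie(img[, , 2] / white[["Yn"]])
  fz <- f_cie(img[, , 3] / white[["Zn"]])
  out <- array(0, dim(img))
  out[, , 1] <- 116 * fy - 16
  out[, , 2] <- 500 * (fx - fy)
  out[, , 3] <- 200 * (fy - fz)
  out
}

#' Convert an RGB image to CIELAB
#'
#' Composition of [rgb_to_xyz()] and [xyz_to_lab()].
#'
#' @inheritParams rgb_to_xyz
#' @inheritParams xyz_to_lab
#' @return H x W x 3 numeric array, channels L, a, b.
#' @export
rgb_to_lab <- function(img, white = white_point(), strict_cie = FALSE,
                       linearize = FALSE) {
  xyz_to_lab(rgb_to_xyz(img, strict_cie = strict_cie, linearize = linearize),
             white = white)
}
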