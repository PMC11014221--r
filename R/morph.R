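# Binary morphology: erosion, dilation, hole filling and the refinement
# sequence that cleans a clustered fruit mask.
#
# Border policy: structuring-element cells that fall outside the raster are
# treated as background for both operations (pad-with-false). Erosion
# therefore eats the outermost rows/columns of a mask that touches the
# raster border; the pipeline accounts for this when cropping.

#' Binary erosion
#'
#' Output pixel is `TRUE` iff every `TRUE` cell of the translated element
#' lands on a `TRUE` mask pixel (the minimum value under the element's
#' footprint). Out-of-raster cells count as background.
#'
#' @param mask Logical matrix.
#' @param se A [structuring_element()]; default 3x3 square.
#' @return Logical matrix.
#' @examples
#' m <- matrix(TRUE, 5, 5)
#' sum(erode_mask(m))  # 9: only the 3x3 interior survives
#' @export
erode_mask <- function(mask, se = se_square(3)) {
  assert_mask(mask)
  offs <- se_offsets(se)
  out <- matrix(TRUE, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(offs)))
    out <- out & shift_mask(mask, -offs[i, 1], -offs[i, 2])
  out
}

#' Binary dilation
#'
#' Output pixel is `TRUE` iff the reflected, translated element hits at
#' least one `TRUE` mask pixel (the maximum value under the footprint);
#' the Minkowski sum of mask and element.
#'
#' @inheritParams erode_mask
#' @return Logical matrix.
#' @export
dilate_mask <- function(mask, se = se_square(3)) {
  assert_mask(mask)
  offs <- se_offsets(se)
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(offs)))
    out <- out | shift_mask(mask, offs[i, 1], offs[i, 2])
  out
}

#' Fill enclosed holes in a binary mask
#'
#' Background components with no 4-connected path to the raster border are
#' set to foreground; everything else is unchanged. Implemented as a
#' sweep-based reachability fill from the border.
#'
#' @param mask Logical matrix.
#' @return Logical matrix with holes filled.
#' @examples
#' donut <- matrix(FALSE, 7, 7); donut[2:6, 2:6] <- TRUE; donut[4, 4] <- FALSE
#' fill_holes(donut)[4, 4]  # TRUE
#' @export
fill_holes <- function(mask) {
  assert_mask(mask)
  H <- nrow(mask); W <- ncol(mask)
  bg <- !mask
  reach <- matrix(FALSE, H, W)
  reach[1, ] <- bg[1, ]; reach[H, ] <- reach[H, ] | bg[H, ]
  reach[, 1] <- reach[, 1] | bg[, 1]; reach[, W] <- reach[, W] | bg[, W]
  repeat {
    before <- reach
    if (H > 1L) for (i in 2:H)        reach[i, ] <- bg[i, ] & (reach[i, ] | reach[i - 1L, ])
    if (W > 1L) for (j in 2:W)        reach[, j] <- bg[, j] & (reach[, j] | reach[, j - 1L])
    if (H > 1L) for (i in (H - 1L):1) reach[i, ] <- bg[i, ] & (reach[i, ] | reach[i + 1L, ])
    if (W > 1L) for (j in (W - 1L):1) reach[, j] <- bg[, j] & (reach[, j] | reach[, j + 1L])
    if (identical(reach, before)) break
  }
  mask | (bg & !reach)
}

#' Refine a clustered fruit mask
#'
#' The cleanup sequence applied after K-means segmentation: fill enclosed
#' holes (voids from highlights or occluders), then erode `iterations`
#' times and dilate `iterations` times with the same element — an opening
#' that removes speckle noise while restoring the fruit body.
#'
#' @param mask Logical matrix.
#' @param iterations Number of erosion (then dilation) passes, >= 0;
#'   default 3.
#' @param se A [structuring_element()]; default 3x3 square.
#' @return Logical matrix. If erosion removes the mask entirely a warning
#'   signals over-erosion and the empty mask is returned.
#' @export
refine_mask <- function(mask, iterations = 3L, se = se_square(3)) {
  assert_mask(mask)
  iterations <- as.integer(iterations)
  if (is.na(iterations) || iterations < 0L)
    stop("iterations must be a nonnegative integer", call. = FALSE)
  out <- fill_holes(mask)
  if (iterations == 0L) return(out)
  for (i in seq_len(iterations)) out <- erode_mask(out, se)
  if (!any(out)) {
    warning("mask vanished after ", iterations, " erosion(s); returning empty mask")
    return(out)
  }
  for (i in seq_len(iterations)) out <- dilate_mask(out, se)
  out
}
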