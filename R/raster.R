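#' @keywords internal
"_PACKAGE"

# Shared raster conventions
#
# Images are H x W x 3 numeric arrays (channels R,G,B or L,a,b), masks and
# edge maps are H x W logical matrices. Pixel (1,1) is the top-left corner;
# row index = y, column index = x. Bounding boxes are 0-based and half-open,
# [x_min, x_max) x [y_min, y_max), the single convention used throughout.

assert_image <- function(img, what = "image") {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop(what, " must be an H x W x 3 numeric array", call. = FALSE)
  if (!is.numeric(img)) stop(what, " must be numeric", call. = FALSE)
  if (dim(img)[1] < 1L || dim(img)[2] < 1L)
    stop(what, " must have positive height and width", call. = FALSE)
  invisible(img)
}

assert_mask <- function(mask, what = "mask") {
  if (!is.matrix(mask) || !is.logical(mask))
    stop(what, " must be an H x W logical matrix", call. = FALSE)
  if (any(is.na(mask))) stop(what, " contains NA", call. = FALSE)
  invisible(mask)
}

# Translate a logical matrix by (dy, dx), padding with FALSE.
# shift_mask(m, dy, dx)[r, c] == m[r - dy, c - dx] where defined.
shift_mask <- function(m, dy, dx) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(FALSE, H, W)
  ys <- seq.int(max(1L, 1L + dy), min(H, H + dy))
  xs <- seq.int(max(1L, 1L + dx), min(W, W + dx))
  if (length(ys) && length(xs)) out[ys, xs] <- m[ys - dy, xs - dx]
  out
}

#' Structuring elements
#'
#' A structuring element (the rough-set literature's structural operator) is
#' a small logical template with a designated origin, slid over a binary
#' mask by [erode_mask()], [dilate_mask()] and the rough-set approximations.
#'
#' @param pixels Logical matrix; the template. Must contain at least one
#'   `TRUE` cell.
#' @param origin Integer `(row, col)` position of the reference point inside
#'   the template. Defaults to the centre cell.
#' @return An object of class `"structuring_element"`.
#' @examples
#' se_square(3)
#' @export
structuring_element <- function(pixels, origin = NULL) {
  if (!is.matrix(pixels) || !is.logical(pixels))
    stop("pixels must be a logical matrix", call. = FALSE)
  if (!any(pixels)) stop("structuring element must be nonempty", call. = FALSE)
  if (is.null(origin)) origin <- c((nrow(pixels) + 1L) %/% 2L, (ncol(pixels) + 1L) %/% 2L)
  origin <- as.integer(origin)
  if (length(origin) != 2L || origin[1] < 1L || origin[1] > nrow(pixels) ||
      origin[2] < 1L || origin[2] > ncol(pixels))
    stop("origin must lie inside the element", call. = FALSE)
  structure(list(pixels = pixels, origin = origin), class = "structuring_element")
}

#' @param size Odd or even positive integer side length.
#' @rdname structuring_element
#' @export
se_square <- function(size = 3L) {
  size <- as.integer(size)
  if (size < 1L) stop("size must be >= 1", call. = FALSE)
  structuring_element(matrix(TRUE, size, size))
}

#' @export
print.structuring_element <- function(x, ...) {
  cat(sprintf("structuring element %dx%d, origin (%d,%d)\n",
              nrow(x$pixels), ncol(x$pixels), x$origin[1], x$origin[2]))
  invisible(x)
}

# (dy, dx) offsets of the TRUE cells relative to the origin.
se_offsets <- function(se) {
  if (!inherits(se, "structuring_element"))
    stop("expected a structuring_element", call. = FALSE)
  w <- which(se$pixels, arr.ind = TRUE)
  cbind(w[, 1] - se$origin[1], w[, 2] - se$origin[2])
}

#' Reflect a structuring element through its origin
#'
#' @param se A [structuring_element()].
#' @return The point-reflected element (used by the erosion/dilation duality).
#' @export
reflect_se <- function(se) {
  p <- se$pixels[rev(seq_len(nrow(se$pixels))), rev(seq_len(ncol(se$pixels))), drop = FALSE]
  structuring_element(p, c(nrow(p) + 1L - se$origin[1], ncol(p) + 1L - se$origin[2]))
}

#' Label connected components of a binary mask
#'
#' Two foreground pixels belong to the same component when they are
#' 8-connected (default) or 4-connected. Labels are consecutive integers,
#' ordered by each component's first pixel in column-major scan order;
#' background is 0.
#'
#' @param mask Logical matrix.
#' @param connectivity 8 (default) or 4.
#' @return Integer matrix of labels, same shape as `mask`.
#' @export
label_components <- function(mask, connectivity = 8L) {
  assert_mask(mask)
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8", call. = FALSE)
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(Inf, H, W)
  lab[mask] <- which(mask)           # provisional label = linear index
  diag8 <- connectivity == 8L
  pmin_row <- function(prev) {
    cand <- prev
    if (diag8) {
      cand <- pmin(cand, c(Inf, prev[-W]), c(prev[-1], Inf))
    }
    cand
  }
  repeat {
    before <- lab
    if (H > 1L) for (i in 2:H) {      # downward
      cand <- pmin_row(lab[i - 1L, ])
      lab[i, ] <- ifelse(mask[i, ], pmin(lab[i, ], cand), Inf)
    }
    if (W > 1L) for (j in 2:W)        # rightward
      lab[, j] <- ifelse(mask[, j], pmin(lab[, j], lab[, j - 1L]), Inf)
    if (H > 1L) for (i in (H - 1L):1) { # upward
      cand <- pmin_row(lab[i + 1L, ])
      lab[i, ] <- ifelse(mask[i, ], pmin(lab[i, ], cand), Inf)
    }
    if (W > 1L) for (j in (W - 1L):1)  # leftward
      lab[, j] <- ifelse(mask[, j], pmin(lab[, j], lab[, j + 1L]), Inf)
    if (identical(lab, before)) break
  }
  out <- matrix(0L, H, W)
  if (any(mask)) {
    ids <- lab[mask]                 # component representative = min linear index
    out[mask] <- match(ids, sort(unique(ids)))
  }
  out
}

#' One-pixel contour of a binary mask
#'
#' Returns the mask pixels that have at least one 4-neighbour outside the
#' mask (the raster border counts as outside). This is the ground-truth edge
#' convention of the synthetic generator.
#'
#' @param mask Logical matrix.
#' @return Logical matrix marking contour pixels.
#' @export
mask_contour <- function(mask) {
  assert_mask(mask)
  interior <- shift_mask(mask, 1, 0) & shift_mask(mask, -1, 0) &
    shift_mask(mask, 0, 1) & shift_mask(mask, 0, -1)
  mask & !interior
}
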