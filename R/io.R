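# PNG raster input/output. PNG is the package's raster interchange format;
# masks and edge maps are stored as 8-bit grayscale PNGs (255 = foreground).

#' Read a PNG image as an RGB array
#'
#' 8-bit channels are scaled into \[0, 1\]. Grayscale images are replicated
#' to three channels; an alpha channel is dropped.
#'
#' @param path Path to a PNG file.
#' @return H x W x 3 numeric array in \[0, 1\].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("image not found: ", path, call. = FALSE)
  x <- png::readPNG(path)
  if (length(dim(x)) == 2L) x <- array(rep(x, 3), c(dim(x), 3L))
  if (dim(x)[3] > 3L) x <- x[, , 1:3, drop = FALSE]
  if (dim(x)[3] == 2L) x <- array(rep(x[, , 1], 3), c(dim(x)[1:2], 3L))
  x
}

#' Write a binary mask as an 8-bit PNG (255 = foreground)
#'
#' @param mask Logical matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  assert_mask(mask)
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' @rdname write_mask_png
#' @param edges Logical matrix of edge pixels (255 = edge, matching
#'   white-on-black edge figures).
#' @export
write_edges_png <- function(edges, path) write_mask_png(edges, path)

#' Read a mask/edge PNG back as a logical matrix
#'
#' Any pixel above 0.5 is foreground.
#'
#' @param path Path to an 8-bit PNG written by [write_mask_png()].
#' @return Logical matrix.
#' @export
read_mask_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) x <- x[, , 1]
  x > 0.5
}
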