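# Reassembly of per-fruit edge maps into one full-frame edge image.

#' Pair a crop-sized edge map with its full-frame placement
#'
#' @param edges Logical matrix of edges in crop coordinates.
#' @param box One-row box data frame giving the crop's position
#'   (0-based, half-open).
#' @return Object of class `"placed_edges"`.
#' @export
placed_edges <- function(edges, box) {
  assert_mask(edges, "edges")
  if (nrow(edges) != box$y_max - box$y_min || ncol(edges) != box$x_max - box$x_min)
    stop("edge map shape does not match its box", call. = FALSE)
  structure(list(edges = edges, box = box), class = "placed_edges")
}

#' Merge per-fruit edge maps into a full-frame edge image
#'
#' Each piece is pasted at its recorded box offset and combined with
#' logical OR, so the result is independent of piece order and overlapping
#' edge pixels are set once.
#'
#' @param pieces List of [placed_edges()] objects.
#' @param canvas_h,canvas_w Full-frame size in pixels.
#' @return Logical `canvas_h x canvas_w` edge matrix.
#' @export
merge_edges <- function(pieces, canvas_h, canvas_w) {
  canvas <- matrix(FALSE, canvas_h, canvas_w)
  for (i in seq_along(pieces)) {
    p <- pieces[[i]]
    if (!inherits(p, "placed_edges"))
      stop("piece ", i, " is not a placed_edges object", call. = FALSE)
    b <- p$box
    if (b$x_min < 0 || b$y_min < 0 || b$x_max > canvas_w || b$y_max > canvas_h)
      stop("piece ", i, ": box does not fit the canvas", call. = FALSE)
    rows <- (b$y_min + 1L):b$y_max
    cols <- (b$x_min + 1L):b$x_max
    canvas[rows, cols] <- canvas[rows, cols] | p$edges
  }
  canvas
}

#' Draw edge pixels over an RGB image
#'
#' Produces an overlay figure (white edges over the photograph by default).
#'
#' @param img H x W x 3 RGB array in \[0, 1\].
#' @param edges Logical H x W edge matrix.
#' @param color Length-3 RGB triple for the edge colour.
#' @return H x W x 3 RGB array.
#' @export
overlay_edges <- function(img, edges, color = c(1, 1, 1)) {
  assert_image(img)
  assert_mask(edges, "edges")
  if (!all(dim(edges) == dim(img)[1:2]))
    stop("edges and image shapes differ", call. = FALSE)
  out <- img
  for (ch in 1:3) {
    plane <- out[, , ch]
    plane[edges] <- color[ch]
    out[, , ch] <- plane
  }
  out
}
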