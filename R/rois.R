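# Per-fruit regions of interest: reading bounding boxes from a sidecar
# file (the interchange format with any external detector), cropping, and a
# naive colour-blob detector for fixture images.
#
# Box convention (used everywhere in the package): 0-based, half-open pixel
# coordinates [x_min, x_max) x [y_min, y_max) in the full frame.

box_columns <- c("x_min", "y_min", "x_max", "y_max", "score")

new_boxes <- function(x_min = integer(), y_min = integer(),
                      x_max = integer(), y_max = integer(),
                      score = numeric(), label = character()) {
  data.frame(x_min = as.integer(x_min), y_min = as.integer(y_min),
             x_max = as.integer(x_max), y_max = as.integer(y_max),
             score = as.numeric(if (length(score)) score else rep(1, length(x_min))),
             label = if (length(label)) label else rep("apple", length(x_min)),
             stringsAsFactors = FALSE)
}

#' Load fruit bounding boxes from a JSON or CSV sidecar file
#'
#' The schema shared with external detectors: JSON is a list of objects
#' `{"x_min":int, "y_min":int, "x_max":int, "y_max":int, "score":float}`;
#' CSV has the header `x_min,y_min,x_max,y_max,score`. `score` is optional
#' and defaults to 1.0. Coordinates are 0-based, half-open. Boxes are
#' clipped to the image bounds when `image_width`/`image_height` are given;
#' a record that is empty after validation (x_min >= x_max or
#' y_min >= y_max) raises a parse error naming the record.
#'
#' @param path Path to a `.json` or `.csv` box file.
#' @param image_width,image_height Optional frame size for clipping.
#' @return A data frame with columns `x_min`, `y_min`, `x_max`, `y_max`,
#'   `score`, `label`, in file order. An empty file yields zero rows.
#' @export
load_boxes <- function(path, image_width = NULL, image_height = NULL) {
  if (!file.exists(path)) stop("box file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "json") {
    x <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    if (length(x) == 0) data.frame() else as.data.frame(x)
  } else if (ext == "csv") {
    utils::read.csv(path, stringsAsFactors = FALSE)
  } else {
    stop("unsupported box file extension '", ext, "' (use .json or .csv)", call. = FALSE)
  }
  if (nrow(raw) == 0) return(new_boxes())
  needed <- c("x_min", "y_min", "x_max", "y_max")
  miss <- setdiff(needed, names(raw))
  if (length(miss))
    stop("box file ", path, " is missing field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (fld in needed)
    if (!is.numeric(raw[[fld]]))
      stop("box file ", path, ": field '", fld, "' is not numeric", call. = FALSE)
  score <- if ("score" %in% names(raw)) raw$score else rep(1, nrow(raw))
  score[is.na(score)] <- 1           # absent score defaults to certainty
  boxes <- new_boxes(raw$x_min, raw$y_min, raw$x_max, raw$y_max, score = score)
  validate_boxes(boxes, image_width, image_height, where = path)
}

validate_boxes <- function(boxes, image_width = NULL, image_height = NULL,
                           where = "boxes") {
  for (i in seq_len(nrow(boxes))) {
    b <- boxes[i, ]
    if (is.na(b$x_min) || is.na(b$y_min) || is.na(b$x_max) || is.na(b$y_max))
      stop(where, ", record ", i, ": missing coordinate", call. = FALSE)
    if (b$x_min >= b$x_max || b$y_min >= b$y_max)
      stop(where, ", record ", i, ": empty box (x_min >= x_max or y_min >= y_max)",
           call. = FALSE)
    if (!is.na(b$score) && (b$score < 0 || b$score > 1))
      stop(where, ", record ", i, ": score outside [0,1]", call. = FALSE)
  }
  if (!is.null(image_width) && !is.null(image_height)) {
    boxes$x_min <- pmax(boxes$x_min, 0L)
    boxes$y_min <- pmax(boxes$y_min, 0L)
    boxes$x_max <- pmin(boxes$x_max, as.integer(image_width))
    boxes$y_max <- pmin(boxes$y_max, as.integer(image_height))
    for (i in seq_len(nrow(boxes)))
      if (boxes$x_min[i] >= boxes$x_max[i] || boxes$y_min[i] >= boxes$y_max[i])
        stop(where, ", record ", i, ": box lies outside the image", call. = FALSE)
  }
  boxes
}

#' Write bounding boxes to a JSON sidecar file
#'
#' @param boxes Box data frame (see [load_boxes()]).
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
write_boxes <- function(boxes, path) {
  jsonlite::write_json(boxes[, c(box_columns, "label")], path,
                       auto_unbox = FALSE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Expand boxes by a relative margin
#'
#' Grows each box on every side by `margin` times its width/height (at
#' least `min_pad` pixels), then clips to the frame. The margin keeps fruit
#' edges away from the crop border, where the rough-set operator has no
#' support.
#'
#' @param boxes Box data frame.
#' @param margin Relative margin per side; default 0.05.
#' @param image_width,image_height Frame size for clipping.
#' @param min_pad Minimum padding in pixels; default 3.
#' @return Expanded box data frame.
#' @export
expand_boxes <- function(boxes, margin = 0.05, image_width, image_height,
                         min_pad = 3L) {
  if (margin < 0) stop("margin must be nonnegative", call. = FALSE)
  px <- pmax(as.integer(min_pad), ceiling(margin * (boxes$x_max - boxes$x_min)))
  py <- pmax(as.integer(min_pad), ceiling(margin * (boxes$y_max - boxes$y_min)))
  out <- boxes
  out$x_min <- pmax(0L, as.integer(boxes$x_min - px))
  out$y_min <- pmax(0L, as.integer(boxes$y_min - py))
  out$x_max <- pmin(as.integer(image_width), as.integer(boxes$x_max + px))
  out$y_max <- pmin(as.integer(image_height), as.integer(boxes$y_max + py))
  out
}

#' Crop an image or mask to a bounding box
#'
#' Pixel (1,1) of the crop is pixel (y_min+1, x_min+1) of the source (boxes
#' are 0-based, half-open).
#'
#' @param img H x W x 3 array or H x W matrix.
#' @param box One-row box data frame (or a list with the same fields).
#' @return The cropped array/matrix of shape
#'   `(y_max - y_min) x (x_max - x_min)`.
#' @export
crop <- function(img, box) {
  d <- dim(img)
  H <- d[1]; W <- d[2]
  if (box$x_min < 0 || box$y_min < 0 || box$x_max > W || box$y_max > H ||
      box$x_min >= box$x_max || box$y_min >= box$y_max)
    stop("box does not fit the image", call. = FALSE)
  rows <- (box$y_min + 1L):box$y_max
  cols <- (box$x_min + 1L):box$x_max
  if (length(d) == 3L) img[rows, cols, , drop = FALSE]
  else img[rows, cols, drop = FALSE]
}

#' Paste a crop-sized mask into a full-size canvas
#'
#' Inverse of [crop()] for masks: places `mask` at its box offset in an
#' all-background frame.
#'
#' @param mask Logical matrix of shape
#'   `(y_max - y_min) x (x_max - x_min)`.
#' @param box One-row box data frame.
#' @param canvas_h,canvas_w Frame size.
#' @return Logical `canvas_h x canvas_w` matrix.
#' @export
place_mask <- function(mask, box, canvas_h, canvas_w) {
  assert_mask(mask)
  if (nrow(mask) != box$y_max - box$y_min || ncol(mask) != box$x_max - box$x_min)
    stop("mask shape does not match box", call. = FALSE)
  out <- matrix(FALSE, canvas_h, canvas_w)
  out[(box$y_min + 1L):box$y_max, (box$x_min + 1L):box$x_max] <- mask
  out
}

#' Naive red-blob detector for fixture images
#'
#' Stands in for a trained fruit detector when exercising the pipeline on
#' synthetic scenes: thresholds the CIELAB a (green-red) channel, extracts
#' 8-connected components of sufficient area, and returns their tight
#' bounding boxes expanded by `margin`.
#'
#' @param img H x W x 3 RGB array in \[0, 1\].
#' @param min_area Minimum component area in pixels; default 25.
#' @param a_threshold Threshold on the a channel; default 20 (red apples
#'   sit far above it, foliage far below).
#' @param margin Relative expansion of each tight box; default 0.05.
#' @return Box data frame sorted by `(y_min, x_min)`; empty when no
#'   component qualifies.
#' @export
detect_blobs <- function(img, min_area = 25L, a_threshold = 20,
                         margin = 0.05) {
  assert_image(img)
  lab <- rgb_to_lab(img)
  m <- lab[, , 2] > a_threshold
  labs <- label_components(m, connectivity = 8L)
  n <- max(labs)
  if (n == 0L) return(new_boxes())
  keep <- which(tabulate(labs[labs > 0L], nbins = n) >= min_area)
  if (!length(keep)) return(new_boxes())
  H <- nrow(m); W <- ncol(m)
  rows <- lapply(keep, function(k) {
    w <- which(labs == k, arr.ind = TRUE)
    # tight box, 0-based half-open
    c(x_min = min(w[, 2]) - 1L, y_min = min(w[, 1]) - 1L,
      x_max = max(w[, 2]), y_max = max(w[, 1]))
  })
  b <- do.call(rbind, rows)
  boxes <- new_boxes(b[, "x_min"], b[, "y_min"], b[, "x_max"], b[, "y_max"])
  boxes <- expand_boxes(boxes, margin, W, H, min_pad = 2L)
  boxes <- boxes[order(boxes$y_min, boxes$x_min), , drop = FALSE]
  rownames(boxes) <- NULL
  boxes
}
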