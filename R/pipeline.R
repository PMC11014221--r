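# Full edge-detection pipeline: per-fruit ROI -> CIELAB -> K-means ->
# morphological refinement -> rough-set boundary -> full-frame merge.

#' Pipeline configuration
#'
#' All tunable knobs of the edge-detection pipeline, each overridable.
#'
#' @param k Number of K-means clusters; default 3 (fruit, background,
#'   noise such as highlights or foliage).
#' @param iterations Erosion/dilation passes in [refine_mask()]; default 3.
#' @param window Evaluation window for [windowed_confusion()]; default 3.
#' @param operator_size Side of the square rough-set structural operator;
#'   default 3.
#' @param margin Relative ROI expansion per side before cropping;
#'   default 0.05.
#' @param cluster_strategy `"center"` (default) or `"max_a"`; see
#'   [select_fruit_cluster()].
#' @param seed Base RNG seed; ROI i uses `seed + i - 1`.
#' @param strict_cie,gamma_linearize Colour-conversion flags; see
#'   [rgb_to_xyz()].
#' @param close_gaps Iterations of a void-sealing closing (dilate,
#'   fill holes, erode; 3x3 element) applied to the selected cluster mask
#'   before refinement. With the default 1 iteration, an interior void
#'   (e.g. a specular highlight clustered separately) that leaks to the
#'   background through a gap of up to two pixels is sealed and filled,
#'   while genuine occluder cuts of three or more pixels stay open and
#'   nearly-touching fruits are not welded together. 0 disables.
#' @param thin Thin the rough-set boundary band to a one-pixel contour
#'   (Zhang-Suen) before merging. Default `TRUE`: the raw band is about
#'   two pixels wide by construction, while evaluation compares against
#'   one-pixel ground-truth contours. Set `FALSE` to keep the raw band.
#' @param border_trim Width in pixels of the crop-border band in which
#'   detected edges are discarded (crop borders cut through neighbouring
#'   fruit and produce spurious edges there; the ROI margin guarantees the
#'   target fruit's own edge never lies in this band). Default
#'   `(operator_size - 1) / 2 + 1`.
#' @return List of class `"red_config"`.
#' @export
red_config <- function(k = 3L, iterations = 3L, window = 3L,
                       operator_size = 3L, margin = 0.05,
                       cluster_strategy = c("center", "max_a"), seed = 1L,
                       strict_cie = FALSE, gamma_linearize = FALSE,
                       close_gaps = 1L, thin = TRUE, border_trim = NULL) {
  cluster_strategy <- match.arg(cluster_strategy)
  operator_size <- as.integer(operator_size)
  if (is.null(border_trim)) border_trim <- (operator_size - 1L) %/% 2L + 1L
  cfg <- list(k = as.integer(k), iterations = as.integer(iterations),
              window = as.integer(window), operator_size = operator_size,
              margin = as.numeric(margin), cluster_strategy = cluster_strategy,
              seed = as.integer(seed), strict_cie = isTRUE(strict_cie),
              gamma_linearize = isTRUE(gamma_linearize),
              close_gaps = as.integer(close_gaps), thin = isTRUE(thin),
              border_trim = as.integer(border_trim))
  if (cfg$close_gaps < 0L) stop("close_gaps must be >= 0", call. = FALSE)
  if (cfg$k < 1L) stop("k must be >= 1", call. = FALSE)
  if (cfg$iterations < 0L || cfg$iterations > 10L)
    stop("iterations must be in 0..10", call. = FALSE)
  if (cfg$window < 1L || cfg$window %% 2L == 0L)
    stop("window must be odd and >= 1", call. = FALSE)
  if (cfg$operator_size < 1L) stop("operator_size must be >= 1", call. = FALSE)
  if (cfg$margin < 0) stop("margin must be >= 0", call. = FALSE)
  structure(cfg, class = "red_config")
}

#' @export
print.red_config <- function(x, ...) {
  cat("pipeline config:\n")
  for (nm in names(x)) cat(sprintf("  %-16s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

drop_border_edges <- function(edges, trim) {
  if (trim <= 0L) return(edges)
  H <- nrow(edges); W <- ncol(edges)
  t <- min(trim, (min(H, W) - 1L) %/% 2L)
  if (t < 1L) return(edges)
  edges[c(seq_len(t), (H - t + 1L):H), ] <- FALSE
  edges[, c(seq_len(t), (W - t + 1L):W)] <- FALSE
  edges
}

#' Run the full edge-detection pipeline
#'
#' For every fruit bounding box: expand by the margin, crop, convert to
#' CIELAB, segment by K-means, select the fruit cluster, seal hairline
#' gaps (light closing), refine the mask (fill voids, open), extract the
#' rough-set boundary, and discard edges in the crop-border band. The per-fruit edge maps are merged into one
#' full-frame edge image by logical OR.
#'
#' @param image RGB array in \[0, 1\], or a path to a PNG.
#' @param boxes Box data frame, or a path to a JSON/CSV box sidecar, or
#'   `NULL` with `detect = TRUE`.
#' @param config A [red_config()].
#' @param detect Use [detect_blobs()] instead of supplied boxes.
#' @param debug_dir If non-`NULL`, write per-ROI intermediates (cluster
#'   label map, refined mask, boundary) and the merged edge map as PNGs.
#' @return Object of class `"red_result"`: list with `edges` (full-frame
#'   logical matrix), `pieces` (list of [placed_edges()]), `masks` (refined
#'   crop masks), `boxes`, `boxes_expanded`, `config`. With zero boxes the
#'   edge canvas is empty and a warning is raised.
#' @export
run_red <- function(image, boxes = NULL, config = red_config(),
                    detect = FALSE, debug_dir = NULL) {
  if (is.character(image)) image <- read_image(image)
  assert_image(image)
  H <- dim(image)[1]; W <- dim(image)[2]
  if (detect) {
    boxes <- detect_blobs(image, margin = config$margin)
  } else if (is.character(boxes)) {
    boxes <- load_boxes(boxes, image_width = W, image_height = H)
  } else if (is.null(boxes)) {
    stop("supply boxes or set detect = TRUE", call. = FALSE)
  } else {
    boxes <- validate_boxes(boxes, W, H)
  }
  if (!is.null(debug_dir)) dir.create(debug_dir, showWarnings = FALSE, recursive = TRUE)
  if (nrow(boxes) == 0L) {
    warning("no fruit boxes: returning an empty edge map")
    return(structure(list(edges = matrix(FALSE, H, W), pieces = list(),
                          masks = list(), boxes = boxes,
                          boxes_expanded = boxes, config = config),
                     class = "red_result"))
  }
  exp_boxes <- expand_boxes(boxes, config$margin, W, H)
  op <- se_square(config$operator_size)
  pieces <- vector("list", nrow(boxes))
  masks <- vector("list", nrow(boxes))
  for (i in seq_len(nrow(boxes))) {
    res <- tryCatch({
      b <- exp_boxes[i, ]
      cr <- crop(image, b)
      lab <- rgb_to_lab(cr, strict_cie = config$strict_cie,
                        linearize = config$gamma_linearize)
      km <- kmeans_lab(lab, k = config$k, seed = config$seed + i - 1L)
      m <- select_fruit_cluster(km, config$cluster_strategy)
      if (config$close_gaps > 0L) {
        # seal hairline leaks, fill voids while sealed, then restore:
        # only voids whose leak the dilation pinches shut stay filled
        for (g in seq_len(config$close_gaps)) m <- dilate_mask(m, se_square(3))
        m <- fill_holes(m)
        for (g in seq_len(config$close_gaps)) m <- erode_mask(m, se_square(3))
      }
      m <- refine_mask(m, config$iterations, se_square(3))
      e <- boundary_region(m, op, thin = config$thin)
      e <- drop_border_edges(e, config$border_trim)
      if (!is.null(debug_dir)) {
        png::writePNG(km$label_map / km$k, file.path(debug_dir, sprintf("roi_%02d_clusters.png", i)))
        write_mask_png(m, file.path(debug_dir, sprintf("roi_%02d_mask.png", i)))
        write_edges_png(e, file.path(debug_dir, sprintf("roi_%02d_edges.png", i)))
      }
      list(piece = placed_edges(e, b), mask = m)
    }, error = function(err) {
      stop("ROI ", i, ": ", conditionMessage(err), call. = FALSE)
    })
    pieces[[i]] <- res$piece
    masks[[i]] <- res$mask
  }
  edges <- merge_edges(pieces, H, W)
  if (!is.null(debug_dir)) write_edges_png(edges, file.path(debug_dir, "edges.png"))
  structure(list(edges = edges, pieces = pieces, masks = masks, boxes = boxes,
                 boxes_expanded = exp_boxes, config = config),
            class = "red_result")
}

#' @export
print.red_result <- function(x, ...) {
  cat(sprintf("edge detection result: %dx%d frame, %d ROI(s), %d edge pixels\n",
              nrow(x$edges), ncol(x$edges), length(x$pieces), sum(x$edges)))
  invisible(x)
}

#' Full-frame instance masks of a pipeline result
#'
#' Places each refined crop mask at its box offset, for mask-level
#' evaluation. Scores are taken from the input boxes.
#'
#' @param result A [run_red()] result.
#' @return List of predictions (`mask`, `score`) as expected by
#'   [mask_average_precision()].
#' @export
result_masks <- function(result) {
  H <- nrow(result$edges); W <- ncol(result$edges)
  lapply(seq_along(result$masks), function(i)
    list(mask = place_mask(result$masks[[i]], result$boxes_expanded[i, ], H, W),
         score = result$boxes$score[i]))
}

#' Evaluate a pipeline result against scene ground truth
#'
#' @param result A [run_red()] result.
#' @param truth Ground truth as produced by [generate_scene()] (`edges`,
#'   `masks_visible`).
#' @param window Evaluation window; defaults to the pipeline config's.
#' @return A [edge_metrics()] report.
#' @export
evaluate_result <- function(result, truth, window = result$config$window) {
  edge_metrics(result$edges, truth$edges,
               truth_masks = truth$masks_visible,
               pred_masks = result_masks(result),
               window = window)
}
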