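# Deterministic synthetic-orchard generator.
#
# Scenes emulate the three conditions the pipeline is designed for:
# specular illumination highlights on the fruit, cluttered branch/leaf
# backgrounds, and dense mutually occluding fruits. Every scene carries
# exact ground truth: per-fruit visible and amodal masks, tight bounding
# boxes, and a one-pixel edge map (the 4-neighbour contour of the union of
# visible masks). All randomness flows from a single seed, so identical
# specs give byte-identical rasters.

#' Specification of a synthetic orchard scene
#'
#' @param canvas_h,canvas_w Canvas size in pixels.
#' @param n_fruits Number of fruits; 0 gives a pure background scene.
#' @param radius_range Length-2 vector, min/max fruit radius in pixels.
#' @param fruit_color,background_color RGB triples in \[0, 1\]. Defaults
#'   approximate a red apple over foliage green.
#' @param highlight_strength Specular highlight intensity in \[0, 1\];
#'   0 disables the highlight ellipse near the fruit top.
#' @param n_branches,n_leaves Number of dark branch segments and foliage
#'   leaf ellipses drawn over the scene (over the fruits).
#' @param occlusion Maximum allowed pairwise fruit overlap, as a fraction
#'   of the smaller fruit's area, enforced by rejection sampling.
#' @param noise_sigma Standard deviation of additive Gaussian pixel noise
#'   per channel; 0 disables.
#' @param shading Radial lightness falloff amplitude on the fruit body in
#'   \[0, 1\]; 0 gives a flat-colour fruit.
#' @param texture Amplitude of the smooth background luminance texture;
#'   0 gives a flat background.
#' @param dapple Strength of the dark-green foliage dapples in the
#'   background in \[0, 1\]; 0 disables. Dapples give every crop a natural
#'   third colour class alongside fruit and light background.
#' @param seed Integer seed; the single source of randomness.
#' @return List of class `"scene_spec"`.
#' @export
scene_spec <- function(canvas_h = 240L, canvas_w = 320L, n_fruits = 3L,
                       radius_range = c(24, 40),
                       fruit_color = c(0.80, 0.12, 0.10),
                       background_color = c(0.22, 0.45, 0.16),
                       highlight_strength = 0, n_branches = 0L, n_leaves = 0L,
                       occlusion = 0.15, noise_sigma = 0.01,
                       shading = 0.25, texture = 0.02, dapple = 0.5,
                       seed = 1L) {
  spec <- list(canvas_h = as.integer(canvas_h), canvas_w = as.integer(canvas_w),
               n_fruits = as.integer(n_fruits),
               radius_range = as.numeric(radius_range),
               fruit_color = as.numeric(fruit_color),
               background_color = as.numeric(background_color),
               highlight_strength = as.numeric(highlight_strength),
               n_branches = as.integer(n_branches), n_leaves = as.integer(n_leaves),
               occlusion = as.numeric(occlusion),
               noise_sigma = as.numeric(noise_sigma),
               shading = as.numeric(shading), texture = as.numeric(texture),
               dapple = as.numeric(dapple), seed = as.integer(seed))
  if (spec$canvas_h < 16L || spec$canvas_w < 16L)
    stop("canvas must be at least 16x16", call. = FALSE)
  if (spec$n_fruits < 0L) stop("n_fruits must be >= 0", call. = FALSE)
  if (length(spec$radius_range) != 2L || any(spec$radius_range <= 0) ||
      diff(spec$radius_range) < 0)
    stop("radius_range must be increasing and positive", call. = FALSE)
  if (2 * max(spec$radius_range) + 8 > min(spec$canvas_h, spec$canvas_w))
    stop("fruit radii do not fit the canvas", call. = FALSE)
  if (spec$occlusion < 0 || spec$occlusion > 1)
    stop("occlusion must be in [0,1]", call. = FALSE)
  if (spec$highlight_strength < 0 || spec$highlight_strength > 1)
    stop("highlight_strength must be in [0,1]", call. = FALSE)
  structure(spec, class = "scene_spec")
}

# Smooth value-noise field: bilinear interpolation of a coarse random grid.
value_noise <- function(H, W, cell = 24) {
  nh <- ceiling(H / cell) + 2L
  nw <- ceiling(W / cell) + 2L
  g <- matrix(stats::runif(nh * nw, -1, 1), nh, nw)
  y <- (seq_len(H) - 1) / cell
  x <- (seq_len(W) - 1) / cell
  y0 <- floor(y); fy <- y - y0
  x0 <- floor(x); fx <- x - x0
  Y0 <- matrix(y0 + 1L, H, W); X0 <- matrix(x0 + 1L, H, W, byrow = TRUE)
  FY <- matrix(fy, H, W);      FX <- matrix(fx, H, W, byrow = TRUE)
  v <- g[cbind(c(Y0), c(X0))] * (1 - c(FY)) * (1 - c(FX)) +
       g[cbind(c(Y0 + 1L), c(X0))] * c(FY) * (1 - c(FX)) +
       g[cbind(c(Y0), c(X0 + 1L))] * (1 - c(FY)) * c(FX) +
       g[cbind(c(Y0 + 1L), c(X0 + 1L))] * c(FY) * c(FX)
  matrix(v, H, W)
}

# Filled (optionally rotated) ellipse mask; coordinates in pixels.
ellipse_mask <- function(H, W, cy, cx, ry, rx, theta = 0) {
  Y <- matrix(seq_len(H), H, W) - cy
  X <- matrix(seq_len(W), H, W, byrow = TRUE) - cx
  if (theta != 0) {
    ct <- cos(theta); st <- sin(theta)
    Yr <- ct * Y + st * X
    Xr <- -st * Y + ct * X
    Y <- Yr; X <- Xr
  }
  (Y / ry)^2 + (X / rx)^2 <= 1
}

# Normalised squared elliptical radius (for radial shading), Inf outside.
ellipse_d2 <- function(H, W, cy, cx, ry, rx) {
  Y <- matrix(seq_len(H), H, W) - cy
  X <- matrix(seq_len(W), H, W, byrow = TRUE) - cx
  (Y / ry)^2 + (X / rx)^2
}

# Thick line segment mask: pixels within width/2 of the segment p1-p2.
segment_mask <- function(H, W, y1, x1, y2, x2, width) {
  Y <- matrix(seq_len(H), H, W)
  X <- matrix(seq_len(W), H, W, byrow = TRUE)
  vy <- y2 - y1; vx <- x2 - x1
  len2 <- vy^2 + vx^2
  t <- ((Y - y1) * vy + (X - x1) * vx) / max(len2, 1e-9)
  t <- pmin(pmax(t, 0), 1)
  dy <- Y - (y1 + t * vy); dx <- X - (x1 + t * vx)
  sqrt(dy^2 + dx^2) <= width / 2
}

set_color <- function(img, mask, color) {
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[mask] <- color[ch]
    img[, , ch] <- plane
  }
  img
}

#' Generate a synthetic orchard scene with exact ground truth
#'
#' Fruits are drawn as shaded ellipses (radial lightness falloff, optional
#' specular highlight near the top) over a textured, dappled green
#' background; branches (dark thick segments) and leaves (green ellipses)
#' are drawn over the fruits; finally additive Gaussian noise is applied.
#' Later-drawn fruits occlude earlier ones.
#'
#' @param spec A [scene_spec()].
#' @return List with `image` (H x W x 3 RGB array in \[0, 1\]) and `truth`:
#'   `boxes` (tight boxes of the visible masks, sorted by y then x),
#'   `masks_visible`, `masks_amodal` (lists of logical matrices, in box
#'   order), and `edges` (logical matrix; 4-neighbour contour of the union
#'   of visible masks). Fruits left without visible pixels are dropped
#'   from the ground truth.
#' @export
generate_scene <- function(spec) {
  if (!inherits(spec, "scene_spec")) stop("spec must be a scene_spec", call. = FALSE)
  with_seed(spec$seed, {
    H <- spec$canvas_h; W <- spec$canvas_w
    # --- background: green base, dark dapples, smooth luminance texture
    img <- array(rep(spec$background_color, each = H * W), c(H, W, 3))
    if (spec$dapple > 0) {
      dap <- value_noise(H, W, cell = 18) > 0.15
      dark <- spec$background_color * (1 - 0.55 * spec$dapple)
      img <- set_color(img, dap, dark)
    }
    if (spec$texture > 0) {
      tex <- value_noise(H, W, cell = 10) * spec$texture
      for (ch in 1:3) img[, , ch] <- img[, , ch] + tex
    }
    # --- fruit placement with pairwise overlap bound
    fruits <- list()
    margin <- 4
    for (i in seq_len(spec$n_fruits)) {
      placed <- FALSE
      for (try in seq_len(300L)) {
        r <- stats::runif(1, spec$radius_range[1], spec$radius_range[2])
        rx <- r
        ry <- r * stats::runif(1, 0.92, 1.08)
        cy <- stats::runif(1, ry + margin, H - ry - margin)
        cx <- stats::runif(1, rx + margin, W - rx - margin)
        cand <- ellipse_mask(H, W, cy, cx, ry, rx)
        ok <- TRUE
        for (f in fruits) {
          ov <- sum(cand & f$amodal) / min(sum(cand), sum(f$amodal))
          if (ov > spec$occlusion) { ok <- FALSE; break }
        }
        if (ok) {
          fruits[[i]] <- list(cy = cy, cx = cx, ry = ry, rx = rx, amodal = cand)
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("could not place ", spec$n_fruits, " fruits within the occlusion ",
             "bound; reduce n_fruits or enlarge the canvas", call. = FALSE)
    }
    # --- draw fruits (later fruits on top)
    for (i in seq_along(fruits)) {
      f <- fruits[[i]]
      jitter <- stats::runif(3, 0.92, 1.08)
      base <- pmin(pmax(spec$fruit_color * jitter, 0), 1)
      d2 <- ellipse_d2(H, W, f$cy, f$cx, f$ry, f$rx)
      shade <- (1 - spec$shading) + spec$shading * (1 - pmin(d2, 1))
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[f$amodal] <- (base[ch] * shade)[f$amodal]
        img[, , ch] <- plane
      }
      if (spec$highlight_strength > 0) {
        hl <- ellipse_mask(H, W, f$cy - 0.45 * f$ry, f$cx + 0.10 * f$rx,
                           0.28 * f$ry, 0.38 * f$rx) & f$amodal
        s <- spec$highlight_strength
        for (ch in 1:3) {
          plane <- img[, , ch]
          plane[hl] <- plane[hl] * (1 - s) + s
          img[, , ch] <- plane
        }
      }
    }
    # --- visible masks before occluders: subtract later-drawn fruits
    n <- length(fruits)
    visible <- lapply(seq_len(n), function(i) {
      v <- fruits[[i]]$amodal
      if (i < n) for (j in (i + 1L):n) v <- v & !fruits[[j]]$amodal
      v
    })
    # --- occluders drawn over everything
    occ <- matrix(FALSE, H, W)
    if (spec$n_branches > 0) {
      branch_col <- c(0.26, 0.17, 0.08)
      for (b in seq_len(spec$n_branches)) {
        side <- sample.int(2L, 1L)
        y1 <- stats::runif(1, 1, H); y2 <- stats::runif(1, 1, H)
        x1 <- if (side == 1L) 1 else stats::runif(1, 1, W)
        x2 <- if (side == 1L) W else stats::runif(1, 1, W)
        sm <- segment_mask(H, W, y1, x1, y2, x2, width = stats::runif(1, 2.5, 4.5))
        img <- set_color(img, sm, branch_col)
        occ <- occ | sm
      }
    }
    if (spec$n_leaves > 0) {
      for (l in seq_len(spec$n_leaves)) {
        leaf_col <- c(0.14, 0.40, 0.10) * stats::runif(1, 0.85, 1.15)
        lm <- ellipse_mask(H, W, stats::runif(1, 1, H), stats::runif(1, 1, W),
                           stats::runif(1, 6, 11), stats::runif(1, 10, 18),
                           theta = stats::runif(1, 0, pi))
        img <- set_color(img, lm, pmin(leaf_col, 1))
        occ <- occ | lm
      }
    }
    if (any(occ)) visible <- lapply(visible, function(v) v & !occ)
    # --- noise last (does not affect masks)
    if (spec$noise_sigma > 0)
      img <- img + array(stats::rnorm(length(img), 0, spec$noise_sigma), dim(img))
    img <- pmin(pmax(img, 0), 1)
    # --- ground truth
    keep <- which(vapply(visible, sum, numeric(1)) >= 30)
    visible <- visible[keep]
    amodal <- lapply(fruits[keep], `[[`, "amodal")
    boxes <- if (length(keep)) {
      b <- do.call(rbind, lapply(visible, function(v) {
        w <- which(v, arr.ind = TRUE)
        c(min(w[, 2]) - 1L, min(w[, 1]) - 1L, max(w[, 2]), max(w[, 1]))
      }))
      new_boxes(b[, 1], b[, 2], b[, 3], b[, 4])
    } else new_boxes()
    ord <- order(boxes$y_min, boxes$x_min)
    boxes <- boxes[ord, , drop = FALSE]
    rownames(boxes) <- NULL
    visible <- visible[ord]
    amodal <- amodal[ord]
    union_visible <- if (length(visible)) Reduce(`|`, visible)
                     else matrix(FALSE, H, W)
    list(image = img,
         truth = list(boxes = boxes,
                      masks_visible = visible,
                      masks_amodal = amodal,
                      edges = mask_contour(union_visible)),
         spec = spec)
  })
}

#' Scene specifications of the three study conditions
#'
#' The standard scene per condition: `illumination` (two large fruits with
#' a strong specular highlight), `complex_background` (three fruits behind
#' branches and leaves) and `dense_occlusion` (seven mutually occluding
#' fruits). Scene seeds are derived from `seed`.
#'
#' @param seed Integer base seed.
#' @return Named list of three [scene_spec()] objects.
#' @export
fixture_specs <- function(seed = 1L) {
  seed <- as.integer(seed)
  list(
    illumination = scene_spec(
      n_fruits = 2L, radius_range = c(30, 42), highlight_strength = 0.85,
      occlusion = 0.05, noise_sigma = 0.010, seed = seed),
    complex_background = scene_spec(
      n_fruits = 3L, radius_range = c(26, 36), highlight_strength = 0.2,
      n_branches = 2L, n_leaves = 5L, occlusion = 0.08, noise_sigma = 0.015,
      seed = seed + 1L),
    dense_occlusion = scene_spec(
      n_fruits = 7L, radius_range = c(18, 26), highlight_strength = 0.15,
      n_branches = 1L, n_leaves = 3L, occlusion = 0.30, noise_sigma = 0.012,
      seed = seed + 2L))
}

#' Write the standard three-scene fixture suite
#'
#' Generates one scene per study condition — `illumination` (few fruits,
#' strong specular highlight), `complex_background` (branches and leaves
#' over and around the fruits) and `dense_occlusion` (many mutually
#' occluding fruits) — and writes, per scene: the image PNG, the
#' ground-truth edge PNG, per-fruit visible-mask PNGs, a box JSON sidecar,
#' and a `manifest.json` listing files, specs and MD5 checksums.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed; scene seeds are derived from it.
#' @return The manifest, invisibly (also written as JSON).
#' @export
make_fixture_suite <- function(out_dir, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create ", out_dir, call. = FALSE)
  specs <- fixture_specs(seed)
  manifest <- list(seed = as.integer(seed), scenes = list())
  for (name in names(specs)) {
    sc <- generate_scene(specs[[name]])
    files <- list(image = file.path(out_dir, paste0(name, ".png")),
                  edges = file.path(out_dir, paste0(name, "_edges.png")),
                  boxes = file.path(out_dir, paste0(name, "_boxes.json")))
    png::writePNG(sc$image, files$image)
    write_edges_png(sc$truth$edges, files$edges)
    write_boxes(sc$truth$boxes, files$boxes)
    mask_files <- character(0)
    for (i in seq_along(sc$truth$masks_visible)) {
      mf <- file.path(out_dir, sprintf("%s_mask_%02d.png", name, i))
      write_mask_png(sc$truth$masks_visible[[i]], mf)
      mask_files <- c(mask_files, mf)
    }
    all_files <- c(unlist(files), mask_files)
    manifest$scenes[[name]] <- list(
      spec = unclass(specs[[name]]),
      n_fruits_visible = length(sc$truth$masks_visible),
      files = basename(all_files),
      md5 = unname(tools::md5sum(all_files)))
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
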