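test_that("identical spec and seed give byte-identical scenes", {
  sp <- scene_spec(n_fruits = 3L, n_branches = 1L, n_leaves = 2L,
                   highlight_strength = 0.5, seed = 77)
  a <- generate_scene(sp); b <- generate_scene(sp)
  expect_identical(a$image, b$image)
  expect_identical(a$truth, b$truth)
  # and the generator does not disturb the caller's RNG stream
  set.seed(1); x1 <- runif(1)
  set.seed(1); invisible(generate_scene(sp)); x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("a fruitless scene is pure background with empty ground truth", {
  sc <- generate_scene(scene_spec(n_fruits = 0L, seed = 2))
  expect_equal(nrow(sc$truth$boxes), 0)
  expect_length(sc$truth$masks_visible, 0)
  expect_false(any(sc$truth$edges))
})

test_that("an unocculted fruit has identical visible and amodal masks", {
  sc <- generate_scene(scene_spec(n_fruits = 1L, noise_sigma = 0,
                                  highlight_strength = 0.7, seed = 3))
  expect_equal(nrow(sc$truth$boxes), 1)
  expect_identical(sc$truth$masks_visible[[1]], sc$truth$masks_amodal[[1]])
})

test_that("visible masks are inside amodal masks and boxes are tight", {
  sc <- generate_scene(scene_spec(n_fruits = 5L, n_branches = 2L,
                                  n_leaves = 4L, occlusion = 0.25, seed = 4))
  for (i in seq_along(sc$truth$masks_visible)) {
    v <- sc$truth$masks_visible[[i]]
    expect_true(all(v <= sc$truth$masks_amodal[[i]]))
    w <- which(v, arr.ind = TRUE)
    b <- sc$truth$boxes[i, ]
    expect_equal(min(w[, 2]) - 1L, b$x_min)
    expect_equal(max(w[, 1]), b$y_max)
  }
})

test_that("ground-truth edges are the 4-neighbour contour of the visible union", {
  sc <- generate_scene(scene_spec(n_fruits = 4L, occlusion = 0.3, seed = 5))
  u <- Reduce(`|`, sc$truth$masks_visible)
  H <- nrow(u); W <- ncol(u)
  # independent double-loop contour oracle
  want <- matrix(FALSE, H, W)
  for (r in seq_len(H)) for (c in seq_len(W)) {
    if (!u[r, c]) next
    nb <- c(if (r > 1) u[r - 1, c] else FALSE,
            if (r < H) u[r + 1, c] else FALSE,
            if (c > 1) u[r, c - 1] else FALSE,
            if (c < W) u[r, c + 1] else FALSE)
    want[r, c] <- !all(nb)
  }
  expect_identical(sc$truth$edges, want)
})

test_that("pairwise fruit overlaps respect the occlusion bound", {
  sc <- generate_scene(scene_spec(n_fruits = 6L, radius_range = c(18, 26),
                                  occlusion = 0.3, seed = 6))
  am <- sc$truth$masks_amodal
  for (i in seq_along(am)) for (j in seq_along(am)) {
    if (i >= j) next
    ov <- sum(am[[i]] & am[[j]]) / min(sum(am[[i]]), sum(am[[j]]))
    expect_lte(ov, 0.3)
  }
})

test_that("adding occluders only shrinks the visible area", {
  base <- generate_scene(scene_spec(n_fruits = 3L, n_leaves = 0L, seed = 7))
  more <- generate_scene(scene_spec(n_fruits = 3L, n_leaves = 6L, seed = 7))
  area <- function(sc) sum(Reduce(`|`, c(sc$truth$masks_visible,
                                         list(matrix(FALSE, 240, 320)))))
  expect_lte(area(more), area(base))
})

test_that("impossible placements raise a helpful error", {
  expect_error(generate_scene(scene_spec(canvas_h = 64, canvas_w = 64,
                                         n_fruits = 12L, radius_range = c(20, 24),
                                         occlusion = 0, seed = 8)),
               "occlusion bound")
})

test_that("the fixture suite writes three reproducible scenes", {
  d1 <- file.path(tempdir(), "fix1"); d2 <- file.path(tempdir(), "fix2")
  unlink(c(d1, d2), recursive = TRUE)
  m1 <- make_fixture_suite(d1, seed = 9)
  m2 <- make_fixture_suite(d2, seed = 9)
  expect_named(m1$scenes, c("illumination", "complex_background", "dense_occlusion"))
  for (nm in names(m1$scenes)) {
    expect_identical(m1$scenes[[nm]]$md5, m2$scenes[[nm]]$md5)
    expect_true(all(file.exists(file.path(d1, m1$scenes[[nm]]$files))))
  }
  # dense scene really is dense; illumination scene really highlights
  expect_gte(m1$scenes$dense_occlusion$spec$n_fruits, 6)
  expect_gt(m1$scenes$illumination$spec$highlight_strength, 0.5)
  # the written artifacts round-trip
  sc <- generate_scene(do.call(scene_spec, m1$scenes$illumination$spec))
  img <- read_image(file.path(d1, "illumination.png"))
  expect_equal(dim(img), dim(sc$image))
  edges <- read_mask_png(file.path(d1, "illumination_edges.png"))
  expect_identical(edges, sc$truth$edges)
  boxes <- load_boxes(file.path(d1, "illumination_boxes.json"))
  expect_equal(nrow(boxes), nrow(sc$truth$boxes))
})
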