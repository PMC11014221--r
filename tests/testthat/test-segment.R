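lab_image <- function(colors, labels) {
  # build an H x W x 3 LAB array from a matrix of row indices into `colors`
  H <- nrow(labels); W <- ncol(labels)
  arr <- array(0, c(H, W, 3))
  for (ch in 1:3) arr[, , ch] <- matrix(colors[labels, ch], H, W)
  arr
}

test_that("a uniform image with k = 1 yields its own pixel as centroid", {
  img <- lab_image(matrix(c(50, 10, 20), 1), matrix(1L, 6, 7))
  km <- kmeans_lab(img, k = 1, seed = 1)
  expect_equal(unname(km$centroids[1, ]), c(50, 10, 20))
  expect_equal(km$inertia, 0)
  expect_true(all(km$label_map == 1L))
})

test_that("two distinct colors with k = 2 are separated exactly", {
  colors <- rbind(c(40, 45, 30), c(60, -35, 25))
  set.seed(21)
  for (rep in 1:5) {
    labels <- matrix(sample(1:2, 80, replace = TRUE), 8, 10)
    km <- kmeans_lab(lab_image(colors, labels), k = 2, seed = rep)
    expect_equal(km$inertia, 0)
    # partition matches the color partition (label ids may swap)
    m <- km$label_map == km$label_map[1, 1]
    expect_true(identical(m, labels == labels[1, 1]))
  }
})

test_that("inertia never increases with k", {
  set.seed(9)
  img <- array(rnorm(12 * 12 * 3, sd = 10), c(12, 12, 3))
  k1 <- kmeans_lab(img, k = 1, seed = 1)
  k2 <- kmeans_lab(img, k = 2, seed = 1)
  k3 <- kmeans_lab(img, k = 3, seed = 1)
  expect_lte(k2$inertia, k1$inertia)
  expect_lte(k3$inertia, k2$inertia)
})

test_that("k exceeding the number of distinct colours is reduced with a warning", {
  img <- lab_image(rbind(c(1, 2, 3), c(4, 5, 6)), matrix(c(1L, 2L), 4, 4))
  expect_warning(km <- kmeans_lab(img, k = 5, seed = 1), "distinct")
  expect_equal(km$k, 2)
  expect_equal(km$inertia, 0)
})

test_that("every pixel is assigned to its nearest centroid", {
  set.seed(13)
  img <- array(rnorm(10 * 10 * 3, sd = 8), c(10, 10, 3))
  km <- kmeans_lab(img, k = 3, seed = 2)
  x <- matrix(img, ncol = 3)
  d2 <- sapply(seq_len(km$k), function(j) rowSums(sweep(x, 2, km$centroids[j, ])^2))
  expect_equal(as.vector(km$label_map), max.col(-d2, ties.method = "first"))
})

test_that("the fitted inertia is comparable to stats::kmeans", {
  set.seed(17)
  img <- array(c(rnorm(150, 0, 3), rnorm(150, 20, 3)), c(10, 10, 3))
  ours <- kmeans_lab(img, k = 2, seed = 3)
  ref <- stats::kmeans(matrix(img, ncol = 3), centers = 2, nstart = 5)
  expect_lte(ours$inertia, ref$tot.withinss * 1.05)
})

test_that("select_fruit_cluster strategies pick the intended cluster", {
  # cluster 2 fills the center window, cluster 1 the frame
  labels <- matrix(1L, 12, 12); labels[4:9, 4:9] <- 2L
  colors <- rbind(c(55, -30, 25), c(45, 50, 30))
  km <- kmeans_lab(lab_image(colors, labels), k = 2, seed = 1)
  m_center <- select_fruit_cluster(km, "center")
  m_reddest <- select_fruit_cluster(km, "max_a")
  truth <- labels == 2L
  expect_identical(m_center, truth)
  expect_identical(m_reddest, truth)
  # k = 1: the whole crop is the mask
  km1 <- kmeans_lab(lab_image(colors, matrix(1L, 5, 5)), k = 1, seed = 1)
  expect_true(all(select_fruit_cluster(km1)))
})

test_that("noiseless two-colour crops are recovered pixel-perfectly", {
  for (s in 1:6) {
    sp <- scene_spec(n_fruits = 1L, shading = 0, texture = 0, dapple = 0,
                     noise_sigma = 0, highlight_strength = 0, seed = s)
    sc <- generate_scene(sp)
    H <- dim(sc$image)[1]; W <- dim(sc$image)[2]
    b <- expand_boxes(sc$truth$boxes, 0.05, W, H)[1, ]
    km <- kmeans_lab(rgb_to_lab(crop(sc$image, b)), k = 2, seed = s)
    for (strategy in c("center", "max_a")) {
      m <- select_fruit_cluster(km, strategy)
      expect_identical(m, crop(sc$truth$masks_visible[[1]], b))
    }
  }
})

test_that("the partition of well-separated colours is seed-invariant", {
  colors <- rbind(c(40, 45, 30), c(70, -35, 25))
  labels <- matrix(rep(1:2, length.out = 90), 9, 10)
  img <- lab_image(colors, labels)
  parts <- lapply(c(1, 99, 4242), function(s) {
    km <- kmeans_lab(img, k = 2, seed = s)
    km$label_map == km$label_map[1, 1]
  })
  expect_identical(parts[[1]], parts[[2]])
  expect_identical(parts[[1]], parts[[3]])
})
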