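# K-means segmentation of a fruit crop in CIELAB space.
#
# Each pixel contributes a three-dimensional feature (L, a, b); Lloyd
# iteration with k-means++ seeding partitions the crop, and one cluster is
# selected as the fruit mask.

# Evaluate code with a temporary RNG state seeded from `seed`, restoring
# the caller's state afterwards.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# k-means++ seeding: first centre uniform, subsequent centres sampled with
# probability proportional to squared distance from the nearest chosen one.
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(0, k, ncol(x))
  idx <- sample.int(n, 1L)
  centers[1L, ] <- x[idx, ]
  if (k > 1L) {
    d2 <- rowSums(sweep(x, 2, centers[1L, ])^2)
    for (j in 2:k) {
      if (all(d2 <= 0)) idx <- sample.int(n, 1L)
      else idx <- sample.int(n, 1L, prob = d2)
      centers[j, ] <- x[idx, ]
      d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j, ])^2))
    }
  }
  centers
}

#' K-means clustering of a CIELAB image
#'
#' Lloyd's algorithm on per-pixel (L, a, b) features with k-means++
#' seeding. Deterministic given `seed`. Convergence is declared when the
#' largest centroid movement falls below `tol` (in LAB units) or after
#' `max_iter` iterations. If the image has fewer distinct colours than
#' `k`, `k` is reduced with a warning.
#'
#' @param img H x W x 3 array, channels L, a, b (see [rgb_to_lab()]).
#' @param k Number of clusters, >= 1; default 3 (fruit, background, noise
#'   such as highlights or foliage).
#' @param seed Integer RNG seed; all `n_init` restarts draw from the
#'   stream it opens, so results are fully deterministic.
#' @param max_iter Maximum Lloyd iterations per restart; default 100.
#' @param tol Centroid-movement tolerance; default 1e-4.
#' @param n_init Number of k-means++ restarts; the fit with the lowest
#'   inertia wins. Default 4 — restarts guard against local optima that
#'   split one colour class in two.
#' @return Object of class `"lab_kmeans"`: list with `k`, `centroids`
#'   (k x 3, columns L,a,b), `label_map` (H x W integer matrix in 1..k),
#'   `inertia` (total within-cluster sum of squares), `iterations`, `seed`.
#' @export
kmeans_lab <- function(img, k = 3L, seed = 1L, max_iter = 100L, tol = 1e-4,
                       n_init = 4L) {
  assert_image(img, "LAB image")
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  x <- matrix(img, ncol = 3L)
  n_distinct <- nrow(unique(x))
  if (k > n_distinct) {
    warning("k = ", k, " exceeds the number of distinct colours (", n_distinct,
            "); reducing k")
    k <- n_distinct
  }
  best <- with_seed(seed, {
    fits <- lapply(seq_len(max(1L, as.integer(n_init))), function(j)
      lloyd_fit(x, kmeanspp_init(x, k), max_iter, tol))
    fits[[which.min(vapply(fits, `[[`, numeric(1), "inertia"))]]
  })
  structure(list(k = k,
                 centroids = `colnames<-`(best$centers, c("L", "a", "b")),
                 label_map = matrix(best$labels, dim(img)[1], dim(img)[2]),
                 inertia = best$inertia,
                 iterations = best$iterations,
                 seed = as.integer(seed)),
            class = "lab_kmeans")
}

# Lloyd iteration from given starting centres.
lloyd_fit <- function(x, centers, max_iter, tol) {
  n <- nrow(x)
  k <- nrow(centers)
  assign_d2 <- function(centers) {
    d2 <- vapply(seq_len(k),
                 function(j) rowSums(sweep(x, 2, centers[j, ])^2),
                 numeric(n))
    if (is.null(dim(d2))) d2 <- matrix(d2, nrow = n)
    d2
  }
  iter <- 0L
  repeat {
    iter <- iter + 1L
    d2 <- assign_d2(centers)
    lab <- max.col(-d2, ties.method = "first")
    newc <- centers
    for (j in seq_len(k)) {
      sel <- lab == j
      if (any(sel)) newc[j, ] <- colMeans(x[sel, , drop = FALSE])
      else {        # empty cluster: reseed at the farthest point
        far <- which.max(d2[cbind(seq_len(n), lab)])
        newc[j, ] <- x[far, ]
      }
    }
    movement <- sqrt(max(rowSums((newc - centers)^2)))
    centers <- newc
    if (movement < tol || iter >= max_iter) break
  }
  d2 <- assign_d2(centers)
  lab <- max.col(-d2, ties.method = "first")
  list(centers = centers, labels = as.integer(lab),
       inertia = sum(d2[cbind(seq_len(n), lab)]), iterations = iter)
}

#' @export
print.lab_kmeans <- function(x, ...) {
  cat(sprintf("lab_kmeans: k=%d, %dx%d pixels, inertia %.4g (%d iterations)\n",
              x$k, nrow(x$label_map), ncol(x$label_map), x$inertia, x$iterations))
  print(round(x$centroids, 2))
  invisible(x)
}

#' Select the fruit cluster of a segmentation
#'
#' Reduces a clustering of a fruit-centred crop to a binary fruit mask.
#' Strategy `"center"` (default) picks the cluster holding the majority of
#' pixels inside the central 50% x 50% window of the crop — the fruit is
#' centred by construction of the ROI. Strategy `"max_a"` picks the cluster
#' whose centroid has the largest a value (the reddest). Ties are broken in
#' favour of the larger cluster.
#'
#' @param model A [kmeans_lab()] result.
#' @param strategy `"center"` or `"max_a"`.
#' @return Logical matrix: the selected cluster's pixels.
#' @export
select_fruit_cluster <- function(model, strategy = c("center", "max_a")) {
  strategy <- match.arg(strategy)
  lm <- model$label_map
  sizes <- tabulate(lm, nbins = model$k)
  pick <- if (strategy == "center") {
    H <- nrow(lm); W <- ncol(lm)
    rows <- max(1L, floor(H / 4) + 1L):ceiling(3 * H / 4)
    cols <- max(1L, floor(W / 4) + 1L):ceiling(3 * W / 4)
    counts <- tabulate(lm[rows, cols], nbins = model$k)
    best <- which(counts == max(counts))
    best[which.max(sizes[best])]
  } else {
    best <- which(model$centroids[, "a"] == max(model$centroids[, "a"]))
    best[which.max(sizes[best])]
  }
  lm == pick
}
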