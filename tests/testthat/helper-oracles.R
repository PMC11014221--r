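# Brute-force oracles, independent of the package's vectorised
# implementations: straightforward double loops over pixels.

oracle_erode <- function(mask, se) {
  H <- nrow(mask); W <- ncol(mask)
  offs <- which(se$pixels, arr.ind = TRUE)
  offs <- cbind(offs[, 1] - se$origin[1], offs[, 2] - se$origin[2])
  out <- matrix(FALSE, H, W)
  for (r in seq_len(H)) for (c in seq_len(W)) {
    keep <- TRUE
    for (k in seq_len(nrow(offs))) {
      rr <- r + offs[k, 1]; cc <- c + offs[k, 2]
      inside <- rr >= 1 && rr <= H && cc >= 1 && cc <= W && mask[rr, cc]
      if (!inside) { keep <- FALSE; break }
    }
    out[r, c] <- keep
  }
  out
}

oracle_dilate <- function(mask, se) {
  H <- nrow(mask); W <- ncol(mask)
  offs <- which(se$pixels, arr.ind = TRUE)
  offs <- cbind(offs[, 1] - se$origin[1], offs[, 2] - se$origin[2])
  out <- matrix(FALSE, H, W)
  for (r in seq_len(H)) for (c in seq_len(W)) {
    hit <- FALSE
    for (k in seq_len(nrow(offs))) {
      rr <- r - offs[k, 1]; cc <- c - offs[k, 2]
      if (rr >= 1 && rr <= H && cc >= 1 && cc <= W && mask[rr, cc]) { hit <- TRUE; break }
    }
    out[r, c] <- hit
  }
  out
}

# Queue-based 4-connected flood fill of background from the border.
oracle_fill <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  bg <- !mask
  reach <- matrix(FALSE, H, W)
  queue <- which(bg & (row(bg) %in% c(1, H) | col(bg) %in% c(1, W)))
  reach[queue] <- TRUE
  while (length(queue)) {
    p <- queue[1]; queue <- queue[-1]
    r <- ((p - 1) %% H) + 1; c <- ((p - 1) %/% H) + 1
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      rr <- r + d[1]; cc <- c + d[2]
      if (rr >= 1 && rr <= H && cc >= 1 && cc <= W && bg[rr, cc] && !reach[rr, cc]) {
        reach[rr, cc] <- TRUE
        queue <- c(queue, (cc - 1) * H + rr)
      }
    }
  }
  mask | (bg & !reach)
}

# Windowed confusion tallies by direct enumeration of window contents.
oracle_confusion <- function(pred, truth, window) {
  H <- nrow(pred); W <- ncol(pred)
  h <- (window - 1) %/% 2
  tp <- fp <- fn <- tn <- 0L
  for (r in seq_len(H)) for (c in seq_len(W)) {
    rs <- max(1, r - h):min(H, r + h)
    cs <- max(1, c - h):min(W, c + h)
    dp <- any(pred[rs, cs]); dt <- any(truth[rs, cs])
    if (dp && dt) tp <- tp + 1L
    else if (dp) fp <- fp + 1L
    else if (dt) fn <- fn + 1L
    else tn <- tn + 1L
  }
  list(TP = tp, FP = fp, FN = fn, TN = tn)
}

random_mask <- function(H, W, p = 0.4) {
  matrix(stats::runif(H * W) < p, H, W)
}

disk_mask <- function(H, W, cy, cx, r) {
  outer(seq_len(H), seq_len(W), function(y, x) (y - cy)^2 + (x - cx)^2 <= r^2)
}

# Direct scalar CIELAB reference for one XYZ triple.
oracle_lab <- function(xyz, wp = c(0.950456, 1, 1.088754)) {
  f <- function(t) if (t > (6 / 29)^3) t^(1 / 3) else t / (3 * (6 / 29)^2) + 4 / 29
  fx <- f(xyz[1] / wp[1]); fy <- f(xyz[2] / wp[2]); fz <- f(xyz[3] / wp[3])
  c(116 * fy - 16, 500 * (fx - fy), 200 * (fy - fz))
}

px_image <- function(rgb) array(rgb, c(1, 1, 3))
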