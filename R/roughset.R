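# Rough-set approximation of a binary fruit mask.
#
# A rough set represents an uncertain region X by a lower approximation
# L(X) (pixels certainly inside) and an upper approximation U(X) (pixels
# possibly inside), induced here by sliding a structural operator over the
# mask: a window that fits entirely inside X joins L(X) (minimum value
# under the window), a window that merely touches X joins U(X) (maximum
# value). The boundary region Bn(X) = U(X) - L(X) is the extracted edge
# band, and Neg(X) = complement of U(X) is the certain background. With
# these max/min semantics the approximations coincide with dilation and
# erosion by the operator, and the boundary is the morphological gradient.

#' Upper approximation of a mask
#'
#' Pixels whose operator window touches the object: `dilate_mask(mask, op)`.
#'
#' @param mask Logical matrix; the (refined) fruit mask.
#' @param op A [structuring_element()]; the structural operator. Must
#'   contain its origin.
#' @return Logical matrix U(X).
#' @export
upper_approximation <- function(mask, op = se_square(3)) {
  check_operator(op)
  dilate_mask(mask, op)
}

#' Lower approximation of a mask
#'
#' Pixels whose operator window lies entirely inside the object:
#' `erode_mask(mask, op)`.
#'
#' @inheritParams upper_approximation
#' @return Logical matrix L(X).
#' @export
lower_approximation <- function(mask, op = se_square(3)) {
  check_operator(op)
  erode_mask(mask, op)
}

#' Rough-set boundary region (the extracted edge)
#'
#' Bn(X) = U(X) AND NOT L(X): the morphological gradient of the mask. For a
#' simply connected mask this is a closed band, roughly as wide as the
#' operator, straddling the true contour. `thin = TRUE` reduces the band to
#' a one-pixel edge curve: the object-side margin of the band (`Bn AND X`,
#' i.e. the mask pixels not in the lower approximation) is kept and then
#' thinned by Zhang-Suen (see [thin_edges()]), so the resulting curve lies
#' on object pixels, matching the usual convention that a contour belongs
#' to the object. The default keeps the raw band.
#'
#' @inheritParams upper_approximation
#' @param thin Thin the band to a 1-pixel object-side contour.
#'   Default `FALSE`.
#' @return Logical matrix Bn(X).
#' @examples
#' m <- matrix(FALSE, 10, 10); m[4:7, 4:7] <- TRUE
#' sum(boundary_region(m))  # 32 = 6x6 block minus 2x2 interior
#' @export
boundary_region <- function(mask, op = se_square(3), thin = FALSE) {
  up <- upper_approximation(mask, op)
  lo <- lower_approximation(mask, op)
  b <- up & !lo
  if (thin) b <- thin_edges(b & mask)
  b
}

#' Negative region
#'
#' Neg(X): pixels certainly outside the object, the complement of the upper
#' approximation.
#'
#' @inheritParams upper_approximation
#' @return Logical matrix Neg(X).
#' @export
negative_region <- function(mask, op = se_square(3)) {
  !upper_approximation(mask, op)
}

#' Full rough-set approximation of a mask
#'
#' Computes all four regions at once. They satisfy, pixelwise:
#' `lower <= mask <= upper`, `boundary == upper & !lower`,
#' `negative == !upper`, and upper is the disjoint union of lower and
#' boundary.
#'
#' @inheritParams upper_approximation
#' @return List of class `"rough_approx"` with elements `upper`, `lower`,
#'   `boundary`, `negative` (logical matrices) and `operator`.
#' @export
rough_approx <- function(mask, op = se_square(3)) {
  up <- upper_approximation(mask, op)
  lo <- lower_approximation(mask, op)
  structure(list(upper = up, lower = lo, boundary = up & !lo,
                 negative = !up, operator = op),
            class = "rough_approx")
}

#' @export
print.rough_approx <- function(x, ...) {
  cat(sprintf("rough approximation %dx%d: |L|=%d |U|=%d |Bn|=%d |Neg|=%d\n",
              nrow(x$upper), ncol(x$upper), sum(x$lower), sum(x$upper),
              sum(x$boundary), sum(x$negative)))
  invisible(x)
}

check_operator <- function(op) {
  if (!inherits(op, "structuring_element"))
    stop("op must be a structuring_element", call. = FALSE)
  if (!op$pixels[op$origin[1], op$origin[2]])
    stop("the structural operator must contain its origin", call. = FALSE)
  invisible(op)
}

#' Thin an edge band to a one-pixel contour
#'
#' Zhang-Suen iterative thinning: border pixels of the band are deleted in
#' two alternating subiterations while 8-connectivity and line ends are
#' preserved, until no pixel changes. Applied to the rough-set boundary
#' band it yields a single-pixel-wide edge curve.
#'
#' @param edges Logical matrix (an edge band).
#' @return Logical matrix of the thinned edges.
#' @export
thin_edges <- function(edges) {
  assert_mask(edges)
  m <- edges
  repeat {
    changed <- FALSE
    for (step in 0:1) {
      # 8-neighbourhood, clockwise from north (shift semantics: value of
      # the neighbour at that compass point).
      n2 <- shift_mask(m, 1, 0);  n3 <- shift_mask(m, 1, -1)
      n4 <- shift_mask(m, 0, -1); n5 <- shift_mask(m, -1, -1)
      n6 <- shift_mask(m, -1, 0); n7 <- shift_mask(m, -1, 1)
      n8 <- shift_mask(m, 0, 1);  n9 <- shift_mask(m, 1, 1)
      b <- n2 + n3 + n4 + n5 + n6 + n7 + n8 + n9
      ring <- list(n2, n3, n4, n5, n6, n7, n8, n9, n2)
      a <- matrix(0L, nrow(m), ncol(m))
      for (i in 1:8) a <- a + (!ring[[i]] & ring[[i + 1]])
      cond <- if (step == 0) !(n2 & n4 & n6) & !(n4 & n6 & n8)
              else           !(n2 & n4 & n8) & !(n2 & n6 & n8)
      del <- m & b >= 2 & b <= 6 & a == 1L & cond
      if (any(del)) {
        m <- m & !del
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}
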