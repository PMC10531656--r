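#' Convex hull volume of a point set
#'
#' Volume (area in 2D) of the convex hull of `points`. Duplicate points
#' are removed internally; point sets whose affine rank is below the
#' ambient dimension are degenerate and raise an error.
#'
#' @param points numeric matrix, one point per row, 1--6 columns.
#' @return A single non-negative volume.
#' @examples
#' sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
#' hull_volume(sq) # 1
#' @export
hull_volume <- function(points) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (anyNA(points)) stop("points must not contain missing values")
  v <- cpp_hull_volume(points)
  if (is.na(v)) {
    stop("degenerate point set: fewer than d+1 unique points or affine rank < ",
         ncol(points))
  }
  v
}

#' Volume of the intersection of two convex hulls
#'
#' Computes the volume of the intersection polytope of the convex hulls
#' of two point sets in the same (2--6 dimensional) space, by
#' intersecting the facet half-spaces of both hulls and enumerating the
#' vertices of the resulting polytope. Disjoint or lower-dimensional
#' intersections give 0.
#'
#' @param points_a,points_b numeric matrices of points (rows), equal
#'   column count; each must span its full dimension.
#' @return A single non-negative volume, 0 when the hulls do not overlap
#'   in full dimension.
#' @examples
#' sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
#' sq_shifted <- sweep(sq, 2, c(0.5, 0), "+")
#' hull_intersection_volume(sq, sq_shifted) # 0.5
#' @export
hull_intersection_volume <- function(points_a, points_b) {
  points_a <- as.matrix(points_a)
  points_b <- as.matrix(points_b)
  storage.mode(points_a) <- "double"
  storage.mode(points_b) <- "double"
  if (anyNA(points_a) || anyNA(points_b)) {
    stop("points must not contain missing values")
  }
  cpp_hull_intersection_volume(points_a, points_b)
}

# membership test against the hull of a reference point set (used by the
# Monte-Carlo oracles in the test suite as the shared primitive; the
# volume estimates themselves come from rejection sampling there)
#' Test points for membership in a convex hull
#'
#' @param hull_points matrix of points whose hull defines the region.
#' @param query matrix of query points (same column count).
#' @return Logical vector, one entry per query row.
#' @export
in_hull <- function(hull_points, query) {
  hull_points <- as.matrix(hull_points)
  query <- as.matrix(query)
  storage.mode(hull_points) <- "double"
  storage.mode(query) <- "double"
  cpp_in_hull(hull_points, query)
}
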