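#' Oriented plane in 3D
#'
#' A plane is stored as a point on the plane and a unit normal; the normal
#' defines the positive half-space. All anatomical cutting planes (Frankfurt,
#' C-plane, pole plane, mid-plane) are instances of this type.
#'
#' @param point numeric length-3 point on the plane (mm).
#' @param normal numeric length-3 normal (normalized on construction).
#' @return an object of class `plane`.
#' @export
plane <- function(point, normal) {
  point <- as.numeric(point); normal <- as.numeric(normal)
  if (length(point) != 3 || length(normal) != 3) stop("point and normal must be length 3")
  if (!all(is.finite(c(point, normal)))) stop("plane parameters must be finite")
  len <- sqrt(sum(normal^2))
  if (len < 1e-12) stop("plane normal must be non-zero")
  structure(list(point = point, normal = normal / len), class = "plane")
}

#' @export
print.plane <- function(x, ...) {
  cat(sprintf("plane: point (%.3f, %.3f, %.3f), normal (%.4f, %.4f, %.4f)\n",
              x$point[1], x$point[2], x$point[3],
              x$normal[1], x$normal[2], x$normal[3]))
  invisible(x)
}

#' Plane through three points
#'
#' @param a,b,c numeric length-3 points.
#' @param min_area reject near-collinear triples below this triangle area (mm^2).
#' @return a `plane` (normal from the right-handed cross product (b-a) x (c-a)).
#' @export
plane_from_points <- function(a, b, c, min_area = 1) {
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c)
  n <- cross3(b - a, c - a)
  area <- sqrt(sum(n^2)) / 2
  if (area < min_area)
    stop(sprintf("points are (near-)collinear: triangle area %.4g mm^2", area))
  plane(a, n)
}

#' Signed distances of points to a plane
#'
#' Positive on the side the normal points to.
#'
#' @param p a `plane`.
#' @param pts numeric length-3 vector or n x 3 matrix.
#' @return numeric vector of signed distances (mm).
#' @export
signed_distance <- function(p, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3)
  drop((pts[, 1] - p$point[1]) * p$normal[1] +
       (pts[, 2] - p$point[2]) * p$normal[2] +
       (pts[, 3] - p$point[3]) * p$normal[3])
}

#' Flip a plane's orientation
#' @param p a `plane`.
#' @return a `plane` with the normal negated.
#' @export
flip_plane <- function(p) plane(p$point, -p$normal)

# 3-vector cross product
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

unit3 <- function(v) {
  len <- sqrt(sum(v^2))
  if (len < 1e-12) stop("cannot normalize zero vector")
  v / len
}
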