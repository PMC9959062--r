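#' Rigid transform (rotation + translation)
#'
#' Maps a point v to `R v + t`. The rotation matrix is checked for
#' orthonormality and determinant +1 on construction.
#'
#' @param rotation 3 x 3 rotation matrix.
#' @param translation numeric length-3 translation (mm).
#' @return an object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  if (!all(dim(rotation) == c(3, 3))) stop("rotation must be 3 x 3")
  if (length(translation) != 3) stop("translation must be length 3")
  err <- max(abs(crossprod(rotation) - diag(3)))
  if (err > 1e-8) stop(sprintf("rotation not orthonormal (error %.3g)", err))
  if (det(rotation) < 0) stop("rotation has negative determinant (reflection)")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- rotation_angle(x$rotation)
  cat(sprintf("rigid_transform: rotation %.3f deg, translation (%.3f, %.3f, %.3f) mm\n",
              ang * 180 / pi, x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

#' Rotation matrix about an axis
#' @param axis length-3 axis (normalized internally).
#' @param angle_deg rotation angle in degrees (right-handed).
#' @return 3 x 3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle_deg) {
  u <- unit3(as.numeric(axis))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Rotation angle of a rotation matrix (radians)
#' @param R 3 x 3 rotation matrix.
#' @return angle in radians in [0, pi].
#' @export
rotation_angle <- function(R) {
  acos(max(-1, min(1, (sum(diag(R)) - 1) / 2)))
}

#' Compose two rigid transforms
#'
#' `compose_transform(a, b)` applies `b` first, then `a`.
#' @param a,b `rigid_transform` objects.
#' @return a `rigid_transform`.
#' @export
compose_transform <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' Invert a rigid transform
#' @param t a `rigid_transform`.
#' @return a `rigid_transform`.
#' @export
invert_transform <- function(t) {
  rigid_transform(t(t$rotation), -as.numeric(t(t$rotation) %*% t$translation))
}

#' Apply a rigid transform to points, a mesh, a plane, or landmarks
#'
#' @param x a `surface_mesh`, `plane`, `landmark_set`, or n x 3 point matrix.
#' @param t a `rigid_transform`.
#' @return the transformed object (frame tag of a mesh is preserved; callers
#'   that change frames set the tag explicitly).
#' @export
apply_transform <- function(x, t) {
  stopifnot(inherits(t, "rigid_transform"))
  if (inherits(x, "surface_mesh")) {
    x$vertices <- transform_points(x$vertices, t)
    return(x)
  }
  if (inherits(x, "plane")) {
    return(plane(as.numeric(t$rotation %*% x$point) + t$translation,
                 as.numeric(t$rotation %*% x$normal)))
  }
  if (inherits(x, "landmark_set")) {
    x$points <- transform_points(x$points, t)
    return(x)
  }
  transform_points(x, t)
}

transform_points <- function(pts, t) {
  single <- is.null(dim(pts))
  if (single) pts <- matrix(pts, ncol = 3)
  out <- pts %*% t(t$rotation)
  out[, 1] <- out[, 1] + t$translation[1]
  out[, 2] <- out[, 2] + t$translation[2]
  out[, 3] <- out[, 3] + t$translation[3]
  if (single) drop(out) else out
}

#' Serialize / read a rigid transform as a JSON 4 x 4 row-major matrix
#' @param t a `rigid_transform`.
#' @param path output / input file path.
#' @return `read_transform` returns a `rigid_transform`.
#' @export
write_transform <- function(t, path) {
  m <- rbind(cbind(t$rotation, t$translation), c(0, 0, 0, 1))
  jsonlite::write_json(list(matrix = m), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  m <- jsonlite::fromJSON(path)$matrix
  rigid_transform(m[1:3, 1:3], m[1:3, 4])
}

# project an approximate rotation back onto SO(3) via SVD
nearest_rotation <- function(M) {
  s <- svd(M)
  R <- s$u %*% t(s$v)
  if (det(R) < 0) {
    u <- s$u; u[, 3] <- -u[, 3]
    R <- u %*% t(s$v)
  }
  R
}
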