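#' Frankfurt horizontal plane from landmarks
#'
#' Plane through both porions and orbitale. The normal follows the
#' right-handed convention `(porion_right - porion_left) x (orbitale -
#' porion_left)`, which points superiorly for an upright subject; all
#' downstream constructions only use this orientation relative to the
#' landmarks, never world axes.
#'
#' @param landmarks a `landmark_set` with `porion_right`, `porion_left`,
#'   `orbitale`.
#' @return a `plane`.
#' @export
frankfurt_plane <- function(landmarks) {
  pr <- get_landmark(landmarks, "porion_right")
  pl <- get_landmark(landmarks, "porion_left")
  ob <- get_landmark(landmarks, "orbitale")
  if (sqrt(sum((pr - pl)^2)) < 1e-9) stop("porions are coincident")
  plane_from_points(pl, pr, ob, min_area = 1)
}

#' C-plane: the condylar isolation plane
#'
#' The plane parallel to the Frankfurt horizontal passing through the C-point
#' (deepest point of the mandibular notch); it separates the condylar process
#' from the ramus.
#'
#' @param c_point numeric length-3 C-point (mm).
#' @param fh the Frankfurt `plane`.
#' @return a `plane` with the Frankfurt normal through `c_point`.
#' @export
build_c_plane <- function(c_point, fh) {
  plane(as.numeric(c_point), fh$normal)
}

#' Sub-region cutting planes from the condylar poles
#'
#' Constructs the two dividers of the four-sub-region partition: the pole
#' plane through the lateral and medial condylar poles perpendicular to the
#' Frankfurt plane (normal oriented so the anterior reference lies on its
#' positive side), and the orthogonal mid-plane through the pole midpoint with
#' normal along the pole axis (positive side toward the lateral pole).
#'
#' @param landmarks a `landmark_set` with `lateral_pole`, `medial_pole` and
#'   `anterior_reference`.
#' @param fh the Frankfurt `plane`.
#' @return list with elements `pole_plane` and `mid_plane`.
#' @export
build_subregion_planes <- function(landmarks, fh) {
  lp <- get_landmark(landmarks, "lateral_pole")
  mp <- get_landmark(landmarks, "medial_pole")
  ar <- get_landmark(landmarks, "anterior_reference")
  axis <- lp - mp
  len <- sqrt(sum(axis^2))
  if (len < 1e-9) stop("condylar poles are coincident")
  u <- axis / len
  if (abs(sum(u * fh$normal)) > cos(5 * pi / 180))
    stop("pole axis within 5 degrees of the Frankfurt normal")
  n_pole <- unit3(cross3(u, fh$normal))
  pole_plane <- plane(lp, n_pole)
  if (signed_distance(pole_plane, ar) < 0) pole_plane <- flip_plane(pole_plane)
  mid_plane <- plane((lp + mp) / 2, u)
  if (signed_distance(mid_plane, lp) < 0) mid_plane <- flip_plane(mid_plane)
  list(pole_plane = pole_plane, mid_plane = mid_plane)
}

#' Full cutting-plane set for one joint side
#'
#' Bundles the Frankfurt plane, C-plane, pole plane, mid-plane and head/neck
#' divider, asserting the mutual parallelism/orthogonality invariants. The
#' head/neck divider defaults to the plane parallel to Frankfurt midway
#' between the C-point and the superior-most condylar vertex (the divider is a
#' convention of this package; override with `head_neck_plane`).
#'
#' @param landmarks a `landmark_set` (porions, orbitale, c_point, poles,
#'   anterior_reference).
#' @param ramus optional `surface_mesh` used to place the default head/neck
#'   divider.
#' @param head_neck_plane optional explicit `plane` override.
#' @return an object of class `cut_plane_set` with fields `frankfurt`,
#'   `c_plane`, `pole_plane`, `mid_plane`, `head_neck_plane`.
#' @export
cut_plane_set <- function(landmarks, ramus = NULL, head_neck_plane = NULL) {
  fh <- frankfurt_plane(landmarks)
  cpt <- get_landmark(landmarks, "c_point")
  cp <- build_c_plane(cpt, fh)
  sub <- build_subregion_planes(landmarks, fh)
  if (is.null(head_neck_plane)) {
    if (is.null(ramus))
      stop("provide a ramus mesh or an explicit head_neck_plane")
    smax <- max(signed_distance(cp, ramus$vertices))
    if (smax <= 0) stop("C-plane lies above the entire mesh")
    head_neck_plane <- plane(cp$point + 0.5 * smax * cp$normal, cp$normal)
  }
  ps <- structure(list(frankfurt = fh, c_plane = cp,
                       pole_plane = sub$pole_plane, mid_plane = sub$mid_plane,
                       head_neck_plane = head_neck_plane),
                  class = "cut_plane_set")
  validate_cut_planes(ps)
  ps
}

validate_cut_planes <- function(ps) {
  stopifnot(
    abs(abs(sum(ps$c_plane$normal * ps$frankfurt$normal)) - 1) < 1e-9,
    abs(sum(ps$pole_plane$normal * ps$frankfurt$normal)) < 1e-9,
    abs(sum(ps$mid_plane$normal * ps$pole_plane$normal)) < 1e-9)
  invisible(ps)
}

#' @export
print.cut_plane_set <- function(x, ...) {
  cat("cut_plane_set:\n")
  for (nm in names(x)) { cat(sprintf("  %-16s ", nm)); print(x[[nm]]) }
  invisible(x)
}

#' Isolate the condyle and split it into head and neck
#'
#' The condyle is the capped clip of the ramus above the C-plane; head and
#' neck are its capped sub-volumes above/below the head/neck divider. All
#' three are closed meshes suitable for volume computation.
#'
#' @param ramus a closed `surface_mesh` of the ramus including the condyle.
#' @param planes a `cut_plane_set`.
#' @return list with closed `surface_mesh` elements `condyle`, `head`, `neck`
#'   (`neck` may be empty when the dividers coincide).
#' @export
isolate_condyle <- function(ramus, planes) {
  if (max(signed_distance(planes$c_plane, ramus$vertices)) <= 0)
    stop("empty condyle: C-plane lies above the mesh")
  condyle <- suppressMessages(
    clip_by_plane(ramus, planes$c_plane, keep_side = "positive", cap = TRUE))
  if (n_faces(condyle) == 0) stop("empty condyle")
  head <- suppressMessages(
    clip_by_plane(condyle, planes$head_neck_plane, keep_side = "positive", cap = TRUE))
  neck <- suppressMessages(
    clip_by_plane(condyle, planes$head_neck_plane, keep_side = "negative", cap = TRUE))
  list(condyle = condyle, head = head, neck = neck)
}
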