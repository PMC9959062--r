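#' Signed surface-distance map
#'
#' For every vertex of the reference mesh, the unsigned distance to the
#' nearest point of the target surface, signed by the outward reference
#' normal: positive when the target lies outside the reference surface
#' (apposition / bone gain), negative when inside (resorption / bone loss).
#' Both meshes must carry the same frame tag — distances across registration
#' frames are meaningless and refused.
#'
#' @param reference a `surface_mesh` (the pre-operative structure by
#'   convention).
#' @param target a non-empty `surface_mesh` in the same frame.
#' @return an object of class `distance_map`: list with `values` (mm, one per
#'   reference vertex), `reference` (the mesh, with `scalars` set to the
#'   values), and `sign_convention`.
#' @export
distance_map <- function(reference, target) {
  check_same_frame(reference, target, "distance_map")
  if (n_faces(target) == 0) stop("distance_map: empty target mesh")
  res <- nearest_surface_point(reference$vertices, target)
  nrm <- vertex_normals(reference)
  disp <- res[, 2:4, drop = FALSE] - reference$vertices
  sgn <- sign(rowSums(nrm * disp))
  sgn[sgn == 0] <- 1
  vals <- sgn * res[, "distance"]
  reference$scalars <- vals
  structure(list(values = vals, reference = reference,
                 sign_convention = "positive = apposition (target outside reference)"),
            class = "distance_map")
}

#' @export
print.distance_map <- function(x, ...) {
  cat(sprintf("distance_map: %d vertices, mean %.4f mm, range [%.4f, %.4f] mm\n",
              length(x$values), mean(x$values), min(x$values), max(x$values)))
  cat(sprintf("  sign: %s\n", x$sign_convention))
  invisible(x)
}

resolve_region <- function(labels, region, n) {
  if (identical(region, "whole")) return(rep(TRUE, n))
  if (!region %in% region_levels())
    stop(sprintf("unknown region '%s'", region))
  if (is.null(labels)) stop("mesh has no region labels")
  as.character(labels) == region
}

#' Mean surface distance over a region
#'
#' Arithmetic mean of the signed (`mode = "signed"`) or absolute
#' (`mode = "absolute"`) distances over the vertices of one sub-region (or
#' `"whole"`). Headline tables use the absolute mode — sign cancellation would
#' understate remodeling — with the signed mean reported alongside.
#'
#' @param map a `distance_map`.
#' @param labels per-vertex region labels (defaults to the reference mesh's).
#' @param region `"whole"` or one of [region_levels()].
#' @param mode `"absolute"` or `"signed"`.
#' @return mean distance in mm, or `NA` (with a warning) for an empty region.
#' @export
region_mean_distance <- function(map, labels = NULL,
                                 region = "whole",
                                 mode = c("absolute", "signed")) {
  mode <- match.arg(mode)
  if (is.null(labels)) labels <- map$reference$labels
  sel <- resolve_region(labels, region, length(map$values))
  if (!any(sel)) {
    warning(sprintf("region '%s' is empty; returning NA", region))
    return(NA_real_)
  }
  v <- map$values[sel]
  if (mode == "absolute") mean(abs(v)) else mean(v)
}

#' RMS surface distance over a region
#'
#' Square root of the mean squared signed distance over the region's vertices
#' (the fossa headline metric).
#'
#' @inheritParams region_mean_distance
#' @return RMS distance in mm, or `NA` (with a warning) for an empty region.
#' @export
region_rms_distance <- function(map, labels = NULL, region = "whole") {
  if (is.null(labels)) labels <- map$reference$labels
  sel <- resolve_region(labels, region, length(map$values))
  if (!any(sel)) {
    warning(sprintf("region '%s' is empty; returning NA", region))
    return(NA_real_)
  }
  sqrt(mean(map$values[sel]^2))
}

#' Volumetric change in percent
#'
#' `100 * (V_post - V_pre) / V_pre` for two closed meshes in the same frame.
#'
#' @param pre,post closed `surface_mesh` objects (same frame).
#' @return percent change (negative = net volume loss).
#' @export
volumetric_change <- function(pre, post) {
  check_same_frame(pre, post, "volumetric_change")
  v_pre <- mesh_volume(pre)
  if (v_pre <= 0) stop("pre-operative volume must be positive")
  v_post <- mesh_volume(post)
  100 * (v_post - v_pre) / v_pre
}

# per-face region label by vertex majority (tie -> first vertex's label)
face_region <- function(mesh) {
  if (is.null(mesh$labels)) stop("mesh has no region labels")
  l <- as.character(mesh$labels)
  f <- mesh$faces
  l1 <- l[f[, 1]]; l2 <- l[f[, 2]]; l3 <- l[f[, 3]]
  out <- l1
  two23 <- l2 == l3 & l1 != l2
  out[two23] <- l2[two23]
  out
}

#' Minimum joint-space distance
#'
#' Minimum unsigned distance between the condylar surface and the glenoid
#' fossa, per sub-region: the minimum over condylar vertices carrying the
#' region label of the distance to the fossa faces carrying the same label
#' (region-restricted pairing, the default) or to the whole fossa
#' (`pairing = "whole"`). The whole-joint value is the minimum over all
#' regions. Both structures must be in the same (cranial) frame.
#'
#' @param condyle a labeled `surface_mesh`.
#' @param fossa a labeled `fossa_patch` (or labeled `surface_mesh`).
#' @param region `"whole"` or one of [region_levels()].
#' @param pairing `"region"` (default) or `"whole"` fossa target.
#' @return distance in mm, or `NA` (with a warning) when a region is empty on
#'   either side.
#' @export
min_joint_space <- function(condyle, fossa, region = "whole",
                            pairing = c("region", "whole")) {
  pairing <- match.arg(pairing)
  check_same_frame(condyle, fossa, "min_joint_space")
  if (identical(region, "whole")) {
    vals <- vapply(region_levels(), function(r)
      min_joint_space(condyle, fossa, r, pairing), numeric(1))
    return(min(vals, na.rm = TRUE))
  }
  sel_v <- resolve_region(condyle$labels, region, n_vertices(condyle))
  if (!any(sel_v)) {
    warning(sprintf("condylar region '%s' empty; returning NA", region))
    return(NA_real_)
  }
  if (pairing == "region") {
    fr <- face_region(fossa)
    fidx <- which(fr == region)
    if (!length(fidx)) {
      warning(sprintf("fossa region '%s' empty; returning NA", region))
      return(NA_real_)
    }
    target <- submesh(fossa, fidx)
  } else target <- fossa
  res <- nearest_surface_point(condyle$vertices[sel_v, , drop = FALSE], target)
  min(res[, "distance"])
}

#' Pre-to-post change in minimum joint-space distance
#'
#' `post - pre`; positive means the joint space widened.
#'
#' @param pre_mm,post_mm minimum joint-space distances (mm); `NA` propagates.
#' @return change in mm.
#' @export
joint_space_change <- function(pre_mm, post_mm) {
  if (is.na(pre_mm) || is.na(post_mm)) return(NA_real_)
  post_mm - pre_mm
}

#' Export a color-coded distance map as PLY
#'
#' Writes the reference mesh with per-vertex scalars and a diverging
#' blue-white-red colormap centered at zero (blue = resorption, red =
#' apposition), clamped at the scale bounds.
#'
#' @param map a `distance_map`.
#' @param scale numeric length-2 `(min, max)` in mm with `min < max` and the
#'   center color at 0.
#' @param path output PLY path.
#' @return the path, invisibly.
#' @export
export_colormap <- function(map, scale = c(-1, 1), path) {
  if (length(scale) != 2 || scale[1] >= scale[2])
    stop("scale must be (min, max) with min < max")
  v <- map$values
  pos_span <- max(scale[2], 1e-12)
  neg_span <- min(scale[1], -1e-12)
  s_pos <- pmin(pmax(v, 0) / pos_span, 1)
  s_neg <- pmin(pmax(-v, 0) / -neg_span, 1)
  r <- round(255 * (1 - s_neg))
  g <- round(255 * (1 - pmax(s_pos, s_neg)))
  b <- round(255 * (1 - s_pos))
  write_ply(map$reference, path, color = cbind(r, g, b))
  invisible(path)
}

check_same_frame <- function(a, b, what) {
  fa <- a$frame; fb <- b$frame
  if (!is.null(fa) && !is.null(fb) && !identical(fa, fb))
    stop(sprintf("%s: frame mismatch ('%s' vs '%s'); metrics must not mix registration frames",
                 what, fa, fb))
  invisible(TRUE)
}
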