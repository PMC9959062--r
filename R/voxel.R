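#' Voxel volume
#'
#' A 3D scalar grid with voxel spacing and world origin in mm. The world
#' position of voxel (i, j, k) (1-based array index) is
#' `origin + (c(i, j, k) - 1) * spacing`; axes follow the array axes (RAS-style
#' right-handed convention for phantoms; real data may use any frame since all
#' anatomical directions are landmark-derived).
#'
#' @param data 3D numeric array.
#' @param spacing numeric length-3 voxel spacing (mm), all > 0.
#' @param origin numeric length-3 world position of the first voxel center (mm).
#' @return an object of class `voxel_volume`.
#' @export
voxel_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(data)) != 3) stop("data must be a 3D array")
  if (any(dim(data) == 0)) stop("volume grid must be non-empty")
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  if (any(spacing <= 0)) stop("voxel spacing must be positive on all axes")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("voxel_volume: %d x %d x %d voxels, spacing (%.3g, %.3g, %.3g) mm, origin (%.3g, %.3g, %.3g)\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Read / write a volume as NIfTI (.nii / .nii.gz)
#'
#' @param path file path.
#' @param vol a `voxel_volume`.
#' @return `read_volume` returns a `voxel_volume`.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3]
  xf <- RNifti::xform(img)
  origin <- xf[1:3, 4]
  # honor axis flips in the stored orientation matrix; the package convention
  # keeps positive spacing and an origin at the first voxel center
  sgn <- sign(diag(xf[1:3, 1:3]))
  sgn[sgn == 0] <- 1
  a <- array(as.numeric(img), dim(img))
  d <- dim(a)
  for (ax in 1:3) if (sgn[ax] < 0) {
    a <- switch(ax,
                a[d[1]:1, , , drop = FALSE],
                a[, d[2]:1, , drop = FALSE],
                a[, , d[3]:1, drop = FALSE])
    origin[ax] <- origin[ax] - sp[ax] * (d[ax] - 1)
  }
  voxel_volume(a, spacing = abs(sp), origin = origin)
}

#' @rdname read_volume
#' @export
write_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing
  m <- diag(4)
  diag(m)[1:3] <- vol$spacing
  m[1:3, 4] <- vol$origin
  RNifti::qform(img) <- structure(m, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Extract an isosurface mesh from a volume
#'
#' Marching-tetrahedra isosurface (each grid cube split into six tetrahedra;
#' watertight by construction, triangles oriented outward from the
#' above-threshold side) in world coordinates honoring spacing and origin.
#' Only the largest connected component is retained, with a message, which
#' stands in for the interactive region-growing step of commercial
#' segmentation suites.
#'
#' @param vol a `voxel_volume`.
#' @param iso_threshold iso value; must lie within the volume's value range.
#' @param keep_all keep all components (default FALSE).
#' @return a `surface_mesh` (empty, with a warning, if the threshold isolates
#'   nothing).
#' @export
volume_to_mesh <- function(vol, iso_threshold, keep_all = FALSE) {
  rng <- range(vol$data)
  if (iso_threshold < rng[1] || iso_threshold > rng[2])
    stop(sprintf("iso threshold %.4g outside volume value range [%.4g, %.4g]",
                 iso_threshold, rng[1], rng[2]))
  d <- dim(vol$data)
  res <- cpp_marching_tets(as.numeric(vol$data), d[1], d[2], d[3],
                           iso_threshold, vol$spacing, vol$origin)
  if (nrow(res$faces) == 0) {
    warning("volume_to_mesh: threshold produced an empty surface")
    return(surface_mesh(matrix(numeric(0), 0, 3), matrix(integer(0), 0, 3),
                        clean = FALSE))
  }
  m <- surface_mesh(res$vertices, res$faces, clean = TRUE)
  if (!keep_all) m <- largest_component(m)
  m
}

#' Gaussian-smooth a volume (separable, sigma in mm)
#' @param vol a `voxel_volume`.
#' @param sigma_mm standard deviation in mm (scalar).
#' @return a `voxel_volume`.
#' @export
smooth_volume <- function(vol, sigma_mm) {
  d <- dim(vol$data)
  # isotropic sigma in voxels per axis, applied separably
  out <- vol$data
  sig_vox <- sigma_mm / mean(vol$spacing)
  sm <- cpp_blur3d(as.numeric(out), as.integer(d), sig_vox)
  voxel_volume(array(sm, d), vol$spacing, vol$origin)
}

#' Downsample a volume by integer factor (mean pooling)
#' @param vol a `voxel_volume`.
#' @param factor integer pooling factor per axis.
#' @return a `voxel_volume`.
#' @export
downsample_volume <- function(vol, factor = 2L) {
  factor <- as.integer(factor)
  if (factor <= 1L) return(vol)
  d <- dim(vol$data)
  nd <- pmax(1L, d %/% factor)
  a <- vol$data[seq_len(nd[1] * factor), seq_len(nd[2] * factor),
                seq_len(nd[3] * factor), drop = FALSE]
  dim(a) <- c(factor, nd[1], factor, nd[2], factor, nd[3])
  pooled <- apply(a, c(2, 4, 6), mean)
  voxel_volume(pooled, vol$spacing * factor,
               vol$origin + (factor - 1) / 2 * vol$spacing)
}

# world coordinates of all voxel centers satisfying a predicate mask
voxel_centers <- function(vol, mask = NULL) {
  d <- dim(vol$data)
  if (is.null(mask)) {
    idx <- which(array(TRUE, d))
  } else idx <- which(mask)
  ai <- arrayInd(idx, d)
  sweep(sweep(ai - 1, 2, vol$spacing, "*"), 2, vol$origin, "+")
}
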