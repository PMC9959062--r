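#' Triangle surface mesh
#'
#' The carrier of all anatomy in the package: an indexed triangle mesh with
#' coordinates in millimetres. Optional per-vertex scalars hold distance maps
#' and optional per-vertex labels hold anatomical sub-region assignments. A
#' `frame` tag records which registration frame ("ramus" for surface-based,
#' "cranial" for voxel-based, or any user tag) the coordinates live in;
#' morphometric operations refuse to mix frames.
#'
#' @param vertices numeric n x 3 matrix of vertex coordinates (mm).
#' @param faces integer m x 3 matrix of 1-based vertex indices.
#' @param scalars optional numeric vector of length n (per-vertex values).
#' @param labels optional character/factor vector of length n (region labels).
#' @param frame optional character frame tag.
#' @param clean drop zero-area faces and validate (default TRUE).
#' @return an object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces, scalars = NULL, labels = NULL,
                         frame = NULL, clean = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  if (nrow(faces) > 0 && ncol(faces) != 3L) stop("faces must be an m x 3 matrix")
  if (!all(is.finite(vertices))) stop("vertex coordinates must be finite")
  if (nrow(faces) > 0) {
    if (min(faces) < 1L || max(faces) > nrow(vertices))
      stop("face indices out of range")
  }
  m <- structure(list(vertices = vertices, faces = faces,
                      scalars = scalars, labels = labels, frame = frame),
                 class = "surface_mesh")
  if (clean && nrow(faces) > 0) m <- drop_degenerate_faces(m)
  if (!is.null(scalars) && length(scalars) != nrow(m$vertices))
    stop("scalars must have one value per vertex")
  if (!is.null(labels) && length(labels) != nrow(m$vertices))
    stop("labels must have one value per vertex")
  m
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: %d vertices, %d faces", nrow(x$vertices), nrow(x$faces)))
  if (!is.null(x$frame)) cat(sprintf(" [frame: %s]", x$frame))
  if (!is.null(x$scalars)) cat(" +scalars")
  if (!is.null(x$labels)) cat(" +labels")
  cat(if (is_closed_mesh(x)) " (closed)\n" else " (open)\n")
  invisible(x)
}

#' Number of vertices / faces
#' @param mesh a `surface_mesh`.
#' @return integer count.
#' @export
n_vertices <- function(mesh) nrow(mesh$vertices)

#' @rdname n_vertices
#' @export
n_faces <- function(mesh) nrow(mesh$faces)

# remove zero-area faces (degenerate after vertex merging or clipping)
drop_degenerate_faces <- function(mesh, tol = 1e-12) {
  a2 <- face_areas(mesh)
  dup <- mesh$faces[, 1] == mesh$faces[, 2] | mesh$faces[, 2] == mesh$faces[, 3] |
    mesh$faces[, 1] == mesh$faces[, 3]
  keep <- a2 > tol & !dup
  if (!all(keep)) mesh$faces <- mesh$faces[keep, , drop = FALSE]
  mesh
}

#' Merge coincident vertices
#'
#' Welds vertices closer than `tol` (rounded-coordinate hashing), re-indexes
#' faces and drops faces that become degenerate. Used after file import (STL
#' stores triangle soup) and after plane clipping.
#'
#' @param mesh a `surface_mesh`.
#' @param tol welding tolerance in mm.
#' @return a `surface_mesh`.
#' @export
merge_vertices <- function(mesh, tol = 1e-6) {
  v <- mesh$vertices
  key <- paste(round(v[, 1] / tol), round(v[, 2] / tol), round(v[, 3] / tol))
  first <- !duplicated(key)
  map <- match(key, key[first])
  newv <- v[first, , drop = FALSE]
  newf <- matrix(map[mesh$faces], ncol = 3)
  # drop only faces collapsed by the weld; area-based sliver removal would
  # open watertight clip results
  dup <- newf[, 1] == newf[, 2] | newf[, 2] == newf[, 3] | newf[, 1] == newf[, 3]
  surface_mesh(newv, newf[!dup, , drop = FALSE], frame = mesh$frame, clean = FALSE)
}

#' Per-face areas, normals, centroids
#' @param mesh a `surface_mesh`.
#' @return `face_areas`: numeric vector (mm^2); `face_normals`: m x 3 unit
#'   normals; `face_centroids`: m x 3 matrix.
#' @export
face_areas <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' @rdname face_areas
#' @export
face_normals <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

#' @rdname face_areas
#' @export
face_centroids <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  (v[f[, 1], , drop = FALSE] + v[f[, 2], , drop = FALSE] + v[f[, 3], , drop = FALSE]) / 3
}

#' Area-weighted per-vertex outward normals
#' @param mesh a `surface_mesh` with consistently oriented faces.
#' @return n x 3 matrix of unit normals.
#' @export
vertex_normals <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]) # area-weighted (x2)
  acc <- rowsum(rbind(fn, fn, fn), group = c(f[, 1], f[, 2], f[, 3]))
  n <- matrix(0, nrow(v), 3)
  n[as.integer(rownames(acc)), ] <- acc
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

#' Directed boundary edges of a mesh
#'
#' An edge is a boundary edge when it is used by exactly one face. A closed
#' (watertight) mesh has none.
#'
#' @param mesh a `surface_mesh`.
#' @return integer k x 2 matrix of directed vertex index pairs (possibly 0 rows).
#' @export
boundary_edges <- function(mesh) {
  f <- mesh$faces
  he <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(he[, 1], he[, 2]), pmax(he[, 1], he[, 2]))
  cnt <- table(key)
  bnd <- he[cnt[key] == 1L, , drop = FALSE]
  bnd
}

#' Is the mesh closed (watertight)?
#' @param mesh a `surface_mesh`.
#' @return logical.
#' @export
is_closed_mesh <- function(mesh) {
  if (nrow(mesh$faces) == 0) return(FALSE)
  nrow(boundary_edges(mesh)) == 0L
}

#' Enclosed volume of a closed mesh
#'
#' Signed divergence-theorem volume (sum of signed tetrahedra against the
#' origin). Positive for consistent outward orientation; if the signed volume
#' is negative the orientation is assumed inward, a warning is emitted, and the
#' absolute value is returned.
#'
#' @param mesh a closed, consistently oriented `surface_mesh`.
#' @return volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  nb <- nrow(boundary_edges(mesh))
  if (nb > 0)
    stop(sprintf("open mesh: %d boundary edges; volume undefined", nb))
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c <- v[f[, 3], , drop = FALSE]
  vol <- sum(a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) +
             a[, 2] * (b[, 3] * c[, 1] - b[, 1] * c[, 3]) +
             a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])) / 6
  if (vol < 0) {
    warning("mesh oriented inward; returning |volume|")
    vol <- -vol
  }
  vol
}

#' Total surface area
#' @param mesh a `surface_mesh`.
#' @return area in mm^2.
#' @export
mesh_area <- function(mesh) sum(face_areas(mesh))

#' Extract the sub-mesh spanned by a set of faces
#'
#' @param mesh a `surface_mesh`.
#' @param face_idx integer vector of face indices to keep.
#' @param drop_unused drop vertices no longer referenced (default TRUE).
#' @return a `surface_mesh` inheriting scalars/labels/frame.
#' @export
submesh <- function(mesh, face_idx, drop_unused = TRUE) {
  f <- mesh$faces[face_idx, , drop = FALSE]
  if (drop_unused) {
    used <- sort(unique(as.vector(f)))
    map <- integer(nrow(mesh$vertices))
    map[used] <- seq_along(used)
    out <- surface_mesh(mesh$vertices[used, , drop = FALSE],
                        matrix(map[f], ncol = 3),
                        scalars = mesh$scalars[used],
                        labels = mesh$labels[used],
                        frame = mesh$frame, clean = FALSE)
  } else {
    out <- surface_mesh(mesh$vertices, f, scalars = mesh$scalars,
                        labels = mesh$labels, frame = mesh$frame, clean = FALSE)
  }
  out
}

#' Drop vertices not referenced by any face
#' @param mesh a `surface_mesh`.
#' @return a `surface_mesh` with faces re-indexed.
#' @export
drop_unreferenced <- function(mesh) {
  if (nrow(mesh$faces) == 0)
    return(surface_mesh(matrix(numeric(0), 0, 3), mesh$faces,
                        frame = mesh$frame, clean = FALSE))
  submesh(mesh, seq_len(nrow(mesh$faces)))
}

#' Keep only the largest connected component
#'
#' Components are computed on the vertex adjacency induced by shared face
#' edges. Used after isosurface extraction where speckle components occur.
#'
#' @param mesh a `surface_mesh`.
#' @param quiet suppress the message when components are dropped.
#' @return a `surface_mesh`.
#' @export
largest_component <- function(mesh, quiet = FALSE) {
  f <- mesh$faces
  if (nrow(f) == 0) return(mesh)
  g <- igraph::graph_from_edgelist(
    rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)]), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, nrow(mesh$vertices) - igraph::vcount(g)))
  comp <- igraph::components(g)
  if (comp$no <= 1) return(mesh)
  big <- which.max(comp$csize)
  keep_v <- comp$membership == big
  keep_f <- keep_v[f[, 1]] & keep_v[f[, 2]] & keep_v[f[, 3]]
  if (!quiet)
    message(sprintf("largest_component: kept %d of %d faces (%d components)",
                    sum(keep_f), nrow(f), comp$no))
  submesh(mesh, which(keep_f))
}
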