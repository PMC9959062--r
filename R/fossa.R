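#' Attach a traced curve to a mesh surface
#'
#' Emulates the semi-automatic fossa tracing step: each hand-traced 3D point
#' is snapped to its nearest point on the surface (then to the nearest mesh
#' vertex), and consecutive snapped vertices are joined by shortest paths
#' along the mesh edge graph (discrete Dijkstra, deterministic). The result is
#' a closed, non-self-intersecting loop of mesh vertices.
#'
#' @param curve n x 3 matrix of traced points (n >= 3), mm.
#' @param surface a `surface_mesh`.
#' @param capture_distance maximum snap distance (mm, default 10); points
#'   farther away raise an error listing their indices.
#' @return an object of class `surface_loop`: list with `vertex_idx` (cyclic,
#'   first not repeated), `points` (their coordinates) and `length_mm`.
#' @export
attach_curve_to_surface <- function(curve, surface, capture_distance = 10) {
  curve <- as.matrix(curve)
  if (nrow(curve) < 3) stop("a traced curve needs at least 3 points")
  near <- nearest_surface_point(curve, surface)
  far <- which(near[, "distance"] > capture_distance)
  if (length(far))
    stop(sprintf("curve points beyond capture distance (%g mm): indices %s",
                 capture_distance, paste(far, collapse = ", ")))
  # snap to the nearest vertex of the closest face
  snapv <- integer(nrow(curve))
  for (i in seq_len(nrow(curve))) {
    tri <- surface$faces[near[i, "face"], ]
    dv <- colSums((t(surface$vertices[tri, , drop = FALSE]) - near[i, 2:4])^2)
    snapv[i] <- tri[which.min(dv)]
  }
  snapv <- snapv[c(TRUE, diff(snapv) != 0)]
  if (length(snapv) >= 2 && snapv[length(snapv)] == snapv[1])
    snapv <- snapv[-length(snapv)]
  if (length(snapv) < 3) stop("curve collapses to fewer than 3 surface vertices")
  g <- mesh_edge_graph(surface)
  path <- integer(0)
  for (i in seq_along(snapv)) {
    from <- snapv[i]
    to <- snapv[if (i == length(snapv)) 1 else i + 1]
    sp <- igraph::shortest_paths(g, from, to, weights = igraph::E(g)$weight,
                                 output = "vpath")$vpath[[1]]
    sp <- as.integer(sp)
    path <- c(path, sp[-length(sp)])
  }
  # prune revisits so the loop is simple
  repeat {
    dup <- path[duplicated(path)]
    if (!length(dup)) break
    v <- dup[1]
    pos <- which(path == v)
    path <- path[-((pos[1] + 1):pos[2])]
  }
  if (length(path) < 3) stop("attached loop degenerates to fewer than 3 vertices")
  pts <- surface$vertices[path, , drop = FALSE]
  seg <- pts[c(seq_len(nrow(pts))[-1], 1), , drop = FALSE] - pts
  structure(list(vertex_idx = path, points = pts,
                 length_mm = sum(sqrt(rowSums(seg^2)))),
            class = "surface_loop")
}

#' @export
print.surface_loop <- function(x, ...) {
  cat(sprintf("surface_loop: %d vertices, length %.2f mm (closed)\n",
              length(x$vertex_idx), x$length_mm))
  invisible(x)
}

# undirected weighted edge graph of a mesh
mesh_edge_graph <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- unique(e)
  w <- sqrt(rowSums((mesh$vertices[e[, 1], , drop = FALSE] -
                     mesh$vertices[e[, 2], , drop = FALSE])^2))
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, nrow(mesh$vertices) - igraph::vcount(g)))
  igraph::E(g)$weight <- w
  g
}

#' Extract the fossa patch enclosed by a surface loop
#'
#' Cuts the skull surface along the loop edges and returns the connected set
#' of faces on the seed's side. The patch is an open sub-mesh whose boundary
#' lies on the skull surface.
#'
#' @param skull a `surface_mesh`.
#' @param loop a `surface_loop` from [attach_curve_to_surface()] (or an
#'   integer vector of cyclically ordered mesh vertex indices).
#' @param seed numeric length-3 point near the intended patch (the fossa roof).
#' @return an object of class `c("fossa_patch", "surface_mesh")`.
#' @export
extract_fossa_patch <- function(skull, loop, seed) {
  vidx <- if (inherits(loop, "surface_loop")) loop$vertex_idx else as.integer(loop)
  if (length(vidx) < 3 || vidx[1] == vidx[length(vidx)] && length(unique(vidx)) < 3)
    stop("loop must be a closed cycle of at least 3 vertices")
  f <- skull$faces
  nf <- nrow(f)
  # blocked undirected edges = consecutive loop vertex pairs
  nxt <- c(vidx[-1], vidx[1])
  blocked <- paste(pmin(vidx, nxt), pmax(vidx, nxt))
  # face adjacency across shared, non-blocked edges
  he <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  hekey <- paste(pmin(he[, 1], he[, 2]), pmax(he[, 1], he[, 2]))
  face_of <- rep(seq_len(nf), 3)
  keep <- !(hekey %in% blocked)
  sp <- split(face_of[keep], hekey[keep])
  sp <- sp[lengths(sp) == 2]
  if (length(sp)) {
    adj <- do.call(rbind, sp)
    g <- igraph::graph_from_edgelist(adj, directed = FALSE)
    g <- igraph::add_vertices(g, max(0, nf - igraph::vcount(g)))
  } else {
    g <- igraph::make_empty_graph(nf, directed = FALSE)
  }
  comp <- igraph::components(g)
  seed_face <- nearest_surface_point(as.numeric(seed), skull)$face
  patch_faces <- which(comp$membership == comp$membership[seed_face])
  if (length(patch_faces) == nf)
    stop("loop does not separate the surface; patch would be the whole mesh")
  patch <- submesh(skull, patch_faces)
  class(patch) <- c("fossa_patch", "surface_mesh")
  patch
}

#' Partition a fossa patch into the four sub-regions
#'
#' Applies [label_by_planes()] with the same sign and tie conventions as the
#' condylar partition, so condyle and fossa sub-regions correspond by name.
#'
#' @param patch a `fossa_patch`.
#' @param pole_plane,mid_plane the joint side's cutting planes.
#' @return the patch with per-vertex `labels`.
#' @export
partition_fossa <- function(patch, pole_plane, mid_plane) {
  out <- label_by_planes(patch, pole_plane, mid_plane)
  class(out) <- class(patch)
  out
}
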