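#' Clip a mesh by a plane
#'
#' Returns the part of the mesh on the requested side of the plane. Triangles
#' crossing the plane are re-triangulated at the intersection; with
#' `cap = TRUE` the planar cross-section is triangulated (fan per boundary
#' loop) so that a closed input yields a closed output. Vertices lying exactly
#' on the plane (|signed distance| < 1e-9 mm) belong to the positive side —
#' the deterministic tie rule used throughout the package.
#'
#' @param mesh a `surface_mesh`.
#' @param p a `plane`.
#' @param keep_side "positive" (default) or "negative".
#' @param cap close the planar cross-section (default FALSE).
#' @return a `surface_mesh` (possibly empty; a plane missing the mesh entirely
#'   returns the whole mesh or an empty mesh, with a message).
#' @export
clip_by_plane <- function(mesh, p, keep_side = c("positive", "negative"),
                          cap = FALSE) {
  keep_side <- match.arg(keep_side)
  tie <- 1e-9
  d <- signed_distance(p, mesh$vertices)
  keep_v <- if (keep_side == "positive") d >= -tie else d < -tie
  f <- mesh$faces
  nk <- keep_v[f[, 1]] + keep_v[f[, 2]] + keep_v[f[, 3]]
  if (all(nk == 3L)) {
    message("clip_by_plane: plane misses the mesh; returning whole mesh")
    return(mesh)
  }
  if (all(nk == 0L)) {
    message("clip_by_plane: plane misses the mesh; returning empty mesh")
    return(surface_mesh(matrix(numeric(0), 0, 3), matrix(integer(0), 0, 3),
                        frame = mesh$frame, clean = FALSE))
  }
  v <- mesh$vertices
  keep_faces <- f[nk == 3L, , drop = FALSE]
  cross_idx <- which(nk == 1L | nk == 2L)

  new_v <- list()         # appended intersection vertices
  edge_cache <- new.env(hash = TRUE, parent = emptyenv())
  nv0 <- nrow(v)
  edge_vertex <- function(i, j) {
    key <- if (i < j) paste(i, j) else paste(j, i)
    hit <- edge_cache[[key]]
    if (!is.null(hit)) return(hit)
    # canonical order so adjacent faces share the bit-identical point
    a <- min(i, j); b <- max(i, j)
    t <- d[a] / (d[a] - d[b])
    pt <- v[a, ] + t * (v[b, ] - v[a, ])
    new_v[[length(new_v) + 1]] <<- pt
    id <- nv0 + length(new_v)
    edge_cache[[key]] <- id
    id
  }

  new_f <- list()
  for (fi in cross_idx) {
    tri <- f[fi, ]
    kf <- keep_v[tri]
    # Sutherland-Hodgman: walk the triangle boundary, emit kept vertices and
    # edge intersections, preserving winding
    poly <- integer(0)
    for (c in 1:3) {
      i <- tri[c]; j <- tri[if (c == 3) 1 else c + 1]
      if (kf[c]) poly <- c(poly, i)
      if (kf[c] != keep_v[j]) poly <- c(poly, edge_vertex(i, j))
    }
    if (length(poly) >= 3)
      for (k in 2:(length(poly) - 1))
        new_f[[length(new_f) + 1]] <- c(poly[1], poly[k], poly[k + 1])
  }
  allv <- rbind(v, do.call(rbind, new_v))
  allf <- rbind(keep_faces, do.call(rbind, new_f))
  out <- surface_mesh(allv, allf, frame = mesh$frame, clean = FALSE)

  if (cap) {
    bnd <- boundary_edges(out)
    # cap only boundary edges on the cutting plane (input may itself be open)
    if (nrow(bnd) > 0) {
      on_pl <- abs(signed_distance(p, allv[bnd[, 1], , drop = FALSE])) < 1e-6 &
        abs(signed_distance(p, allv[bnd[, 2], , drop = FALSE])) < 1e-6
      loops <- link_loops(bnd[on_pl, , drop = FALSE])
      for (loop in loops) {
        cen <- colMeans(allv[loop, , drop = FALSE])
        allv <- rbind(allv, cen)
        ci <- nrow(allv)
        nl <- length(loop)
        nxt <- c(loop[-1], loop[1])
        # reversed orientation closes the mesh consistently
        capf <- cbind(nxt, loop, ci)
        allf <- rbind(allf, capf)
      }
      out <- surface_mesh(allv, allf, frame = mesh$frame, clean = FALSE)
    }
  }
  out <- drop_unreferenced(merge_vertices(out, tol = 1e-9))
  out$frame <- mesh$frame
  out
}

# link directed boundary edges into closed loops (list of vertex index vectors)
link_loops <- function(bnd) {
  if (nrow(bnd) == 0) return(list())
  nxt <- split(bnd[, 2], bnd[, 1])
  used <- rep(FALSE, nrow(bnd))
  starts <- bnd[, 1]
  loops <- list()
  remaining <- rep(TRUE, nrow(bnd))
  edge_from <- split(seq_len(nrow(bnd)), bnd[, 1])
  while (any(remaining)) {
    e0 <- which(remaining)[1]
    loop <- bnd[e0, 1]
    cur <- bnd[e0, 2]
    remaining[e0] <- FALSE
    guard <- 0
    while (cur != loop[1] && guard < nrow(bnd) + 1) {
      loop <- c(loop, cur)
      cand <- edge_from[[as.character(cur)]]
      cand <- cand[remaining[cand]]
      if (length(cand) == 0) break # open chain; drop it
      e <- cand[1]
      remaining[e] <- FALSE
      cur <- bnd[e, 2]
      guard <- guard + 1
    }
    if (cur == loop[1] && length(loop) >= 3)
      loops[[length(loops) + 1]] <- loop
  }
  loops
}

#' Nearest point on a mesh surface
#'
#' Exact minimum point-to-triangle distance over all faces, accelerated by a
#' uniform spatial grid (identical result to the brute-force scan).
#'
#' @param query numeric length-3 point, or n x 3 matrix of query points.
#' @param target a non-empty `surface_mesh`.
#' @param brute force the O(n m) all-faces scan (reference path).
#' @return for a single query, a list with `distance` (mm), `point` (length-3)
#'   and `face` (index); for a matrix of queries, an n x 5 matrix with columns
#'   distance, x, y, z, face.
#' @export
nearest_surface_point <- function(query, target, brute = FALSE) {
  if (n_faces(target) == 0) stop("nearest_surface_point: empty target mesh")
  single <- is.null(dim(query))
  q <- if (single) matrix(as.numeric(query), ncol = 3) else as.matrix(query)
  storage.mode(q) <- "double"
  res <- if (brute) cpp_closest_points_brute(q, target$vertices, target$faces)
         else cpp_closest_points(q, target$vertices, target$faces)
  colnames(res) <- c("distance", "x", "y", "z", "face")
  if (single)
    list(distance = unname(res[1, 1]), point = unname(res[1, 2:4]),
         face = as.integer(res[1, 5]))
  else res
}

#' Label vertices by two cutting planes
#'
#' Assigns each vertex one of the four sub-region labels from the sign of its
#' distance to the anterior/posterior divider (`plane_ap`, normal pointing
#' anterior) and the lateral/medial divider (`plane_lm`, normal pointing
#' lateral). Vertices on a plane (|distance| < 1e-9 mm) take the anterior /
#' lateral side (tie rule).
#'
#' @param mesh a `surface_mesh`.
#' @param plane_ap `plane` whose positive side is anterior.
#' @param plane_lm `plane` whose positive side is lateral.
#' @return the mesh with `labels` set to the four `region_levels()` values.
#' @export
label_by_planes <- function(mesh, plane_ap, plane_lm) {
  ang <- acos(min(1, abs(sum(plane_ap$normal * plane_lm$normal)))) * 180 / pi
  if (ang < 10)
    stop(sprintf("cutting planes are near-parallel (%.2f deg apart)", ang))
  tie <- 1e-9
  ant <- signed_distance(plane_ap, mesh$vertices) > -tie
  lat <- signed_distance(plane_lm, mesh$vertices) > -tie
  mesh$labels <- paste(ifelse(ant, "anterior", "posterior"),
                       ifelse(lat, "lateral", "medial"), sep = "-")
  mesh
}
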