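# Shared fixtures: analytic meshes built in code.

# UV sphere; odd n_rings places a ring exactly on the equator
uv_sphere <- function(r = 10, n = 33, ctr = c(0, 0, 0), ang_offset = 0) {
  phi <- seq(0.999 * pi, 0.001 * pi, length.out = n)
  rings <- lapply(phi, function(p) {
    ang <- 2 * pi * (0:(n - 1)) / n + ang_offset
    cbind(ctr[1] + r * sin(p) * cos(ang),
          ctr[2] + r * sin(p) * sin(ang),
          ctr[3] + r * cos(p))
  })
  tmjmorph:::lathe_mesh(rings, ctr + c(0, 0, -r), ctr + c(0, 0, r))
}

# ASCII STL of a unit tetrahedron (4 faces, 4 unique vertices after welding)
write_tetra_stl <- function(path) {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  f <- rbind(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4), c(1, 4, 3))
  lines <- c("solid tetra")
  for (i in seq_len(nrow(f))) {
    lines <- c(lines, " facet normal 0 0 0", "  outer loop",
               sprintf("   vertex %g %g %g",
                       v[f[i, ], 1], v[f[i, ], 2], v[f[i, ], 3]),
               "  endloop", " endfacet")
  }
  writeLines(c(lines, "endsolid tetra"), path)
  path
}

# O(V^2) Dijkstra on a mesh edge graph, independent of the igraph-backed path
dijkstra_path_length <- function(mesh, from, to) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- unique(cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  w <- sqrt(rowSums((mesh$vertices[e[, 1], , drop = FALSE] -
                     mesh$vertices[e[, 2], , drop = FALSE])^2))
  n <- nrow(mesh$vertices)
  adj <- vector("list", n)
  for (k in seq_len(nrow(e))) {
    adj[[e[k, 1]]] <- rbind(adj[[e[k, 1]]], c(e[k, 2], w[k]))
    adj[[e[k, 2]]] <- rbind(adj[[e[k, 2]]], c(e[k, 1], w[k]))
  }
  dist <- rep(Inf, n); dist[from] <- 0
  done <- rep(FALSE, n)
  repeat {
    u <- which.min(ifelse(done, Inf, dist))
    if (done[u] || !is.finite(dist[u])) break
    if (u == to) break
    done[u] <- TRUE
    for (k in seq_len(NROW(adj[[u]]))) {
      v <- adj[[u]][k, 1]; d2 <- dist[u] + adj[[u]][k, 2]
      if (d2 < dist[v]) dist[v] <- d2
    }
  }
  dist[to]
}

# recover the SBR alignment of a phantom's post ramus (coarse + cropped refine)
sbr_align <- function(ph, planes = NULL) {
  pre <- ph$pre$ramus
  if (is.null(planes)) planes <- cut_plane_set(ph$pre$landmarks, ramus = pre)
  coarse <- icp_register(ph$post$ramus, pre)
  post_c <- apply_transform(ph$post$ramus, coarse$transform)
  ref_pre <- crop_reference_region(pre, list(planes$c_plane))
  ref_post <- crop_reference_region(post_c, list(planes$c_plane))
  fine <- icp_register(ref_post, ref_pre, init = rigid_transform())
  list(transform = compose_transform(fine$transform, coarse$transform),
       fine = fine, coarse = coarse, planes = planes)
}
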