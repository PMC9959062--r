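test_that("mesh construction enforces invariants", {
  expect_error(surface_mesh(matrix(1, 2, 2), matrix(1L, 1, 3)), "n x 3")
  expect_error(surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                            rbind(c(1, 2, 4))), "out of range")
  expect_error(surface_mesh(rbind(c(0, 0, NA), c(1, 0, 0), c(0, 1, 0)),
                            rbind(c(1, 2, 3))), "finite")
  # degenerate (repeated-index) faces are cleaned on construction
  m <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                    rbind(c(1, 2, 3), c(1, 1, 2)))
  expect_equal(n_faces(m), 1L)
})

test_that("mesh volume matches analytic values and flags open meshes", {
  cube <- box_mesh(c(0, 0, 0), c(1, 1, 1))
  expect_true(is_closed_mesh(cube))
  expect_identical(mesh_volume(cube), 1)

  s <- uv_sphere(10, 49)
  expect_lt(abs(mesh_volume(s) / (4 / 3 * pi * 1000) - 1), 0.01)

  open_cube <- submesh(cube, 1:10) # two faces removed
  expect_error(mesh_volume(open_cube), "open mesh")
  expect_error(mesh_volume(open_cube), "boundary edges")
})

test_that("mesh volume is rigid-motion invariant", {
  s <- uv_sphere(6, 25)
  v0 <- mesh_volume(s)
  tr <- rigid_transform(rotation_about_axis(c(1, 2, 3), 37), c(12, -7, 5))
  expect_lt(abs(mesh_volume(apply_transform(s, tr)) / v0 - 1), 1e-9)
})

test_that("plane clipping: analytic hemisphere, additivity, degenerate cases", {
  s <- uv_sphere(10, 65)
  eq <- plane(c(0, 0, 0), c(0, 0, 1))
  hemi <- clip_by_plane(s, eq, "positive", cap = TRUE)
  expect_true(is_closed_mesh(hemi))
  expect_lt(abs(mesh_volume(hemi) / (2 / 3 * pi * 1000) - 1), 0.01)

  # volume additivity across arbitrary planes
  for (p in list(plane(c(1, 2, 3), c(1, 1, 1)), plane(c(0, 0, -4), c(0.3, -1, 2)))) {
    a <- clip_by_plane(s, p, "positive", cap = TRUE)
    b <- clip_by_plane(s, p, "negative", cap = TRUE)
    expect_lt(abs((mesh_volume(a) + mesh_volume(b)) / mesh_volume(s) - 1), 1e-6)
  }

  # plane missing the mesh: whole or empty result, not an error
  expect_message(whole <- clip_by_plane(s, plane(c(0, 0, -20), c(0, 0, 1)), "positive"),
                 "whole mesh")
  expect_identical(whole$vertices, s$vertices)
  expect_message(none <- clip_by_plane(s, plane(c(0, 0, -20), c(0, 0, 1)), "negative"),
                 "empty mesh")
  expect_identical(n_faces(none), 0L)

  # cap = FALSE leaves an open boundary loop lying on the plane
  ho <- clip_by_plane(s, eq, "positive", cap = FALSE)
  bnd <- boundary_edges(ho)
  expect_gt(nrow(bnd), 0)
  expect_lt(max(abs(ho$vertices[unique(as.vector(bnd)), 3])), 1e-6)
})

test_that("nearest_surface_point is exact against brute force", {
  s <- uv_sphere(10, 29)
  # a vertex of the target itself
  expect_equal(nearest_surface_point(s$vertices[5, ], s)$distance, 0)
  # analytic distance from outside the sphere
  expect_lt(abs(nearest_surface_point(c(0, 0, 11), s)$distance - 1), 0.02)
  expect_error(nearest_surface_point(c(0, 0, 0),
                                     surface_mesh(matrix(numeric(0), 0, 3),
                                                  matrix(integer(0), 0, 3),
                                                  clean = FALSE)), "empty")
  # property: grid-accelerated result equals the all-faces scan
  set.seed(11)
  q <- matrix(rnorm(300, sd = 12), ncol = 3)
  fast <- nearest_surface_point(q, s)
  slow <- nearest_surface_point(q, s, brute = TRUE)
  expect_lt(max(abs(fast[, "distance"] - slow[, "distance"])), 1e-9)
  expect_lt(max(abs(fast[, 2:4] - slow[, 2:4])), 1e-9)
})

test_that("label_by_planes partitions vertices with the anterior/lateral tie rule", {
  s <- uv_sphere(10, 48, ang_offset = 0.03)
  ap <- plane(c(0, 0, 0), c(0, 1, 0))
  lm <- plane(c(0, 0, 0), c(1, 0, 0))
  sl <- label_by_planes(s, ap, lm)
  tab <- table(sl$labels) / n_vertices(sl)
  expect_setequal(names(tab), region_levels())
  expect_true(all(abs(tab - 0.25) < 0.02))
  expect_identical(sum(table(sl$labels)), n_vertices(sl)) # partition

  # flipping a plane swaps the corresponding label pair exactly (off-plane
  # vertices; on-plane vertices follow the tie rule in both labelings)
  fl <- label_by_planes(s, flip_plane(ap), lm)
  swapped <- c("anterior-lateral" = "posterior-lateral",
               "anterior-medial" = "posterior-medial",
               "posterior-lateral" = "anterior-lateral",
               "posterior-medial" = "anterior-medial")
  off <- abs(signed_distance(ap, s$vertices)) > 1e-9
  expect_identical(unname(swapped[sl$labels[off]]), fl$labels[off])

  # all vertices strictly anterior-lateral
  one <- label_by_planes(s, plane(c(0, -20, 0), c(0, 1, 0)),
                         plane(c(-20, 0, 0), c(1, 0, 0)))
  expect_identical(unique(one$labels), "anterior-lateral")

  # vertex exactly on both planes takes the anterior-lateral side
  tri <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 1), c(0, 1, 1)), rbind(c(1, 2, 3)))
  tl <- label_by_planes(tri, ap, lm)
  expect_identical(tl$labels[1], "anterior-lateral")

  expect_error(label_by_planes(s, ap, plane(c(0, 0, 0), c(0.01, 1, 0))),
               "near-parallel")
})

test_that("mesh file formats round-trip (STL, PLY, OBJ)", {
  td <- withr::local_tempdir()
  sq <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)),
                     rbind(c(1, 2, 3), c(1, 3, 4)))
  for (fmt in c("ply", "obj")) {
    f <- file.path(td, paste0("sq.", fmt))
    write_mesh(sq, f)
    back <- read_mesh(f)
    expect_equal(back$vertices, sq$vertices, tolerance = 1e-12)
    expect_identical(back$faces, sq$faces)
  }
  # STL is float32 triangle soup: vertices welded back, coordinates to 1e-6
  s <- uv_sphere(10, 17)
  f <- file.path(td, "s.stl")
  write_mesh(s, f)
  back <- read_mesh(f)
  expect_identical(n_vertices(back), n_vertices(s))
  expect_lt(abs(mesh_volume(back) - mesh_volume(s)), 1e-3)
  write_mesh(s, file.path(td, "sa.stl"), binary = FALSE)
  expect_identical(n_vertices(read_mesh(file.path(td, "sa.stl"))), n_vertices(s))

  # hand-written ASCII STL of a unit tetrahedron: 4 faces, 4 welded vertices
  ft <- write_tetra_stl(file.path(td, "tet.stl"))
  tet <- read_mesh(ft)
  expect_identical(n_faces(tet), 4L)
  expect_identical(n_vertices(tet), 4L)
  expect_lt(abs(mesh_volume(tet) - 1 / 6), 1e-9)

  # PLY carries distance scalars and region labels
  s$scalars <- s$vertices[, 3]
  s <- label_by_planes(s, plane(c(0, 0, 0), c(0, 1, 0)), plane(c(0, 0, 0), c(1, 0, 0)))
  fp <- file.path(td, "sc.ply")
  write_mesh(s, fp)
  back <- read_mesh(fp)
  expect_equal(back$scalars, s$scalars, tolerance = 1e-9)
  expect_identical(back$labels, s$labels)

  # degenerate inputs
  empty <- file.path(td, "empty.stl"); file.create(empty)
  expect_error(read_mesh(empty), "empty file")
  expect_error(read_mesh(file.path(td, "nope.stl")), "no such file")
})

test_that("volume_to_mesh extracts the isosurface in world coordinates", {
  s <- uv_sphere(8, 49)
  vol <- rasterize(s, spacing = 0.3, padding = 2)
  m <- volume_to_mesh(vol, 0.5)
  expect_true(is_closed_mesh(m))
  expect_lt(abs(mesh_volume(m) / (4 / 3 * pi * 512) - 1), 0.05)
  # world coordinates honor origin and spacing
  expect_lt(max(abs(colMeans(m$vertices))), 0.1)

  expect_error(volume_to_mesh(vol, 2), "outside volume value range")

  # two disjoint spheres: only the larger component is retained
  s_small <- uv_sphere(4, 25, ctr = c(25, 0, 0))
  vol2 <- rasterize(list(s, s_small), spacing = 0.4, padding = 2)
  expect_message(m2 <- volume_to_mesh(vol2, 0.5), "components")
  expect_lt(abs(mesh_volume(m2) / (4 / 3 * pi * 512) - 1), 0.05)
  expect_gt(min(sqrt(rowSums(sweep(m2$vertices, 2, c(25, 0, 0))^2))), 10)
})

test_that("voxel volumes round-trip through NIfTI", {
  td <- withr::local_tempdir()
  set.seed(3)
  v <- voxel_volume(array(rnorm(5 * 6 * 7), c(5, 6, 7)),
                    spacing = c(0.3, 0.3, 0.3), origin = c(-1, 2, 0.5))
  f <- file.path(td, "v.nii.gz")
  write_volume(v, f)
  back <- read_volume(f)
  expect_equal(back$data, v$data, tolerance = 1e-6)
  expect_equal(back$spacing, v$spacing, tolerance = 1e-6)
  expect_equal(back$origin, v$origin, tolerance = 1e-6)
  expect_error(voxel_volume(array(1, c(2, 2, 2)), spacing = c(0, 1, 1)),
               "positive")
})
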