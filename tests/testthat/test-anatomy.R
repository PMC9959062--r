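test_that("Frankfurt plane from porions and orbitale", {
  lm <- landmark_set(porion_right = c(40, 0, 0), porion_left = c(-40, 0, 0),
                     orbitale = c(0, 60, 0))
  fh <- frankfurt_plane(lm)
  expect_equal(fh$normal, c(0, 0, 1), tolerance = 1e-12)

  lm2 <- landmark_set(porion_right = c(40, 0, 0), porion_left = c(-40, 0, 0),
                      orbitale = c(0, 0, 0))
  expect_error(frankfurt_plane(lm2), "collinear")

  # three generic points all lie on the fitted plane
  set.seed(21)
  pts <- matrix(rnorm(9, sd = 30), 3, 3)
  lm3 <- landmark_set(porion_right = pts[1, ], porion_left = pts[2, ],
                      orbitale = pts[3, ])
  fh3 <- frankfurt_plane(lm3)
  expect_lt(max(abs(signed_distance(fh3, pts))), 1e-9)
})

test_that("C-plane is the Frankfurt-parallel plane through the C-point", {
  fh <- plane(c(0, 0, 0), c(0, 0, 1))
  cp <- build_c_plane(c(10, 5, 30), fh)
  expect_equal(cp$normal, fh$normal)
  expect_equal(signed_distance(cp, c(10, 5, 30)), 0)
  expect_equal(signed_distance(cp, c(0, 0, 30)), 0) # plane z = 30
  # C-point on the Frankfurt plane: C-plane coincides with it
  cp0 <- build_c_plane(c(3, 4, 0), fh)
  expect_equal(signed_distance(cp0, c(0, 0, 0)), 0)
})

test_that("sub-region planes honor pole and orientation conventions", {
  lm <- landmark_set(porion_right = c(40, 0, 30), porion_left = c(-40, 0, 30),
                     orbitale = c(0, 60, 30),
                     lateral_pole = c(10, 0, 30), medial_pole = c(-10, 0, 30),
                     anterior_reference = c(0, 50, 30))
  fh <- frankfurt_plane(lm)
  sub <- build_subregion_planes(lm, fh)
  expect_equal(sub$pole_plane$normal, c(0, 1, 0), tolerance = 1e-12)
  expect_equal(sub$mid_plane$normal, c(1, 0, 0), tolerance = 1e-12)
  expect_equal(sub$mid_plane$point, c(0, 0, 30))
  # both poles lie on the pole plane
  expect_lt(abs(signed_distance(sub$pole_plane, c(10, 0, 30))), 1e-9)
  expect_lt(abs(signed_distance(sub$pole_plane, c(-10, 0, 30))), 1e-9)
  # orthogonality invariants
  expect_lt(abs(sum(sub$pole_plane$normal * fh$normal)), 1e-9)
  expect_lt(abs(sum(sub$mid_plane$normal * sub$pole_plane$normal)), 1e-9)

  lm_bad <- landmark_set(porion_right = c(40, 0, 30), porion_left = c(-40, 0, 30),
                         orbitale = c(0, 60, 30),
                         lateral_pole = c(0.1, 0, 40), medial_pole = c(-0.1, 0, 20),
                         anterior_reference = c(0, 50, 30))
  expect_error(build_subregion_planes(lm_bad, fh), "5 degrees")
  lm_co <- lm; lm_co$points["medial_pole", ] <- lm$points["lateral_pole", ]
  expect_error(build_subregion_planes(lm_co, fh), "coincident")
})

test_that("cut_plane_set satisfies its parallelism/orthogonality invariants", {
  ph <- make_tmj_phantom(tmj_phantom_spec(), make_volumes = FALSE)
  ps <- cut_plane_set(ph$pre$landmarks, ramus = ph$pre$ramus)
  expect_lt(abs(abs(sum(ps$c_plane$normal * ps$frankfurt$normal)) - 1), 1e-9)
  expect_lt(abs(sum(ps$pole_plane$normal * ps$frankfurt$normal)), 1e-9)
  expect_lt(abs(sum(ps$mid_plane$normal * ps$pole_plane$normal)), 1e-9)
  # default head/neck divider sits midway between C-point and the condylar top
  smax <- max(signed_distance(ps$c_plane, ph$pre$ramus$vertices))
  expect_equal(signed_distance(ps$c_plane, ps$head_neck_plane$point), smax / 2,
               tolerance = 1e-9)
})

test_that("condylar isolation matches the analytic cap volume and is additive", {
  ph <- make_tmj_phantom(tmj_phantom_spec(), make_volumes = FALSE)
  planes <- cut_plane_set(ph$pre$landmarks, ramus = ph$pre$ramus)
  iso <- isolate_condyle(ph$pre$ramus, planes)
  expect_true(is_closed_mesh(iso$condyle))
  expect_lt(abs(mesh_volume(iso$condyle) / ph$truth$condyle_volume_analytic - 1),
            0.01)
  v_sum <- mesh_volume(iso$head) + mesh_volume(iso$neck)
  expect_lt(abs(v_sum / mesh_volume(iso$condyle) - 1), 0.005)

  # degenerate split: divider at the C-plane leaves an empty neck
  planes2 <- planes
  planes2$head_neck_plane <- planes$c_plane
  iso2 <- isolate_condyle(ph$pre$ramus, planes2)
  expect_identical(n_faces(iso2$neck), 0L)
  expect_equal(mesh_volume(iso2$head), mesh_volume(iso2$condyle), tolerance = 1e-9)

  above <- plane(c(0, 0, 100), c(0, 0, 1))
  planes3 <- planes
  planes3$c_plane <- above
  expect_error(isolate_condyle(ph$pre$ramus, planes3), "empty condyle")
})

test_that("sub-region labeling is equivariant under rigid motion", {
  ph <- make_tmj_phantom(tmj_phantom_spec(), make_volumes = FALSE)
  planes <- cut_plane_set(ph$pre$landmarks, ramus = ph$pre$ramus)
  iso <- isolate_condyle(ph$pre$ramus, planes)
  lab0 <- label_by_planes(iso$condyle, planes$pole_plane, planes$mid_plane)$labels

  g <- rigid_transform(rotation_about_axis(c(2, -1, 1), 25), c(7, 3, -4))
  lm_g <- apply_transform(ph$pre$landmarks, g)
  ramus_g <- apply_transform(ph$pre$ramus, g)
  planes_g <- cut_plane_set(lm_g, ramus = ramus_g)
  iso_g <- isolate_condyle(ramus_g, planes_g)
  lab_g <- label_by_planes(iso_g$condyle, planes_g$pole_plane,
                           planes_g$mid_plane)$labels
  expect_identical(lab0, lab_g)
})

test_that("curve attachment snaps to the surface and follows edge paths", {
  s <- uv_sphere(10, 33)
  # idempotence: a curve sampled at mesh vertices snaps onto itself
  idx <- seq(1, n_vertices(s), by = 37)[1:6]
  lp <- attach_curve_to_surface(s$vertices[idx, ], s)
  expect_true(all(idx %in% lp$vertex_idx))
  expect_lt(max(nearest_surface_point(lp$points, s)[, "distance"]), 1e-9)

  # hovering circle: snapped loop length agrees with an independent Dijkstra
  ang <- 2 * pi * (0:11) / 12
  crv <- cbind(10.8 * cos(ang), 10.8 * sin(ang), 0)
  loop <- attach_curve_to_surface(crv, s)
  oracle <- 0
  vs <- loop$vertex_idx
  snapped <- vapply(seq_len(nrow(crv)), function(i) {
    near <- nearest_surface_point(crv[i, ], s)
    tri <- s$faces[near$face, ]
    tri[which.min(colSums((t(s$vertices[tri, ]) - near$point)^2))]
  }, integer(1))
  snapped <- unique(snapped)
  for (i in seq_along(snapped))
    oracle <- oracle + dijkstra_path_length(
      s, snapped[i], snapped[if (i == length(snapped)) 1 else i + 1])
  expect_lt(abs(loop$length_mm / oracle - 1), 0.05)

  expect_error(attach_curve_to_surface(crv[1:2, ], s), "at least 3")
  expect_error(attach_curve_to_surface(crv + 50, s), "capture distance")
})

test_that("fossa patch extraction separates the surface at the loop", {
  s <- uv_sphere(10, 49, ang_offset = 0.02)
  ang <- 2 * pi * (0:15) / 16
  crv <- cbind(10.5 * cos(ang), 10.5 * sin(ang), 0)
  loop <- attach_curve_to_surface(crv, s)
  patch <- extract_fossa_patch(s, loop, c(0, 0, 10.2))
  # equatorial loop, polar seed: patch is a hemisphere (2 pi r^2)
  expect_lt(abs(mesh_area(patch) / (2 * pi * 100) - 1), 0.02)
  # seed on the other side gives the complement
  patch2 <- extract_fossa_patch(s, loop, c(0, 0, -10.2))
  expect_equal(mesh_area(patch) + mesh_area(patch2), mesh_area(s),
               tolerance = 1e-9)
  # a cycle that does not separate the surface is rejected
  expect_error(extract_fossa_patch(s, c(1L, 2L, 3L), c(0, 0, 10)), "separate")
})

test_that("fossa partition uses the condylar label conventions", {
  s <- uv_sphere(10, 49, ang_offset = 0.02)
  ang <- 2 * pi * (0:15) / 16
  loop <- attach_curve_to_surface(cbind(10.5 * cos(ang), 10.5 * sin(ang), 0), s)
  patch <- extract_fossa_patch(s, loop, c(0, 0, 10.2))
  pf <- partition_fossa(patch, plane(c(0, 0, 0), c(0, 1, 0)),
                        plane(c(0, 0, 0), c(1, 0, 0)))
  expect_setequal(unique(pf$labels), region_levels())
  tab <- table(pf$labels) / n_vertices(pf)
  expect_true(all(abs(tab - 0.25) < 0.03))
  # a patch entirely in one quadrant keeps a single label
  one <- partition_fossa(patch, plane(c(0, -20, 0), c(0, 1, 0)),
                         plane(c(-20, 0, 0), c(1, 0, 0)))
  expect_identical(unique(one$labels), "anterior-lateral")
})
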