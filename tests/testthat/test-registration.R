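test_that("rigid transforms compose, invert and apply correctly", {
  expect_error(rigid_transform(matrix(1, 3, 3)), "orthonormal")
  refl <- diag(c(-1, 1, 1))
  expect_error(rigid_transform(refl), "reflection")

  tr <- rigid_transform(rotation_about_axis(c(0, 0, 1), 90), c(0, 0, 0))
  expect_equal(apply_transform(c(1, 0, 0), tr), c(0, 1, 0), tolerance = 1e-12)

  set.seed(7)
  m <- surface_mesh(matrix(rnorm(3000), ncol = 3),
                    matrix(sample(1000, 300, replace = TRUE), ncol = 3),
                    clean = FALSE)
  t1 <- rigid_transform(rotation_about_axis(c(1, -2, 0.5), 63), c(4, -1, 9))
  back <- apply_transform(apply_transform(m, t1), invert_transform(t1))
  expect_lt(max(abs(back$vertices - m$vertices)), 1e-9)

  # composition against sequential application
  t2 <- rigid_transform(rotation_about_axis(c(0, 1, 0), -20), c(-2, 0, 1))
  p <- c(1.5, -2, 3)
  expect_equal(apply_transform(p, compose_transform(t2, t1)),
               apply_transform(apply_transform(p, t1), t2), tolerance = 1e-12)

  td <- withr::local_tempdir()
  f <- file.path(td, "t.json")
  write_transform(t1, f)
  t1b <- read_transform(f)
  expect_equal(t1b$rotation, t1$rotation, tolerance = 1e-12)
  expect_equal(t1b$translation, t1$translation, tolerance = 1e-12)
})

test_that("ICP recovers a known rigid perturbation of the phantom ramus", {
  spec <- tmj_phantom_spec(skull_rotation_deg = 10,
                          skull_rotation_axis = c(0, 0, 1),
                          skull_translation = c(3, 2, 1))
  ph <- make_tmj_phantom(spec, make_volumes = FALSE)
  res <- icp_register(ph$post$ramus, ph$pre$ramus)
  expect_true(res$converged)
  expect_lt(res$rms, 0.05)
  # residual trace is non-increasing
  expect_true(all(diff(res$trace) <= 1e-12))
  # the recovered transform undoes the ground-truth motion
  err <- compose_transform(res$transform, ph$truth$mandible_transform)
  expect_lt(rotation_angle(err$rotation) * 180 / pi, 0.5)
  p0 <- c(0, 0, 60)
  expect_lt(sqrt(sum((apply_transform(p0, err) - p0)^2)), 0.05)
})

test_that("ICP identity and degenerate-overlap behavior", {
  s <- uv_sphere(10, 25)
  res <- icp_register(s, s, init = rigid_transform())
  expect_lt(res$rms, 1e-9)
  expect_lt(rotation_angle(res$transform$rotation), 1e-9)

  far <- uv_sphere(10, 25, ctr = c(100, 0, 0))
  expect_error(icp_register(far, s, init = rigid_transform(),
                            params = icp_params(cutoff = 1)),
               "insufficient overlap")
  expect_error(icp_params(trim = 0.6), "trim")
})

test_that("ICP residual is equivariant under a common rigid transform", {
  ph <- make_tmj_phantom(tmj_phantom_spec(skull_rotation_deg = 4,
                                          skull_translation = c(1, 2, -1)),
                         make_volumes = FALSE)
  r1 <- icp_register(ph$post$ramus, ph$pre$ramus)
  g <- rigid_transform(rotation_about_axis(c(1, 1, 0), 30), c(5, -3, 2))
  r2 <- icp_register(apply_transform(ph$post$ramus, g),
                     apply_transform(ph$pre$ramus, g))
  expect_lt(abs(r1$rms - r2$rms), 1e-6)
})

test_that("crop_reference_region removes excluded half-spaces", {
  ph <- make_tmj_phantom(tmj_phantom_spec(), make_volumes = FALSE)
  ramus <- ph$pre$ramus
  planes <- cut_plane_set(ph$pre$landmarks, ramus = ramus)
  ref <- crop_reference_region(ramus, list(planes$c_plane))
  # output vertices are strictly below the C-plane (welding may add cut points)
  expect_lt(max(signed_distance(planes$c_plane, ref$vertices)), 1e-6)
  n_below <- sum(signed_distance(planes$c_plane, ramus$vertices) < -1e-9)
  expect_gte(n_vertices(ref), n_below)

  # plane excluding nothing leaves the mesh unchanged
  low <- plane(c(0, 0, -5), c(0, 0, -1))
  expect_identical(suppressMessages(crop_reference_region(ramus, list(low)))$vertices,
                   ramus$vertices)
  # excluding everything is an error
  high <- plane(c(0, 0, -5), c(0, 0, 1))
  expect_error(suppressMessages(crop_reference_region(ramus, list(high))),
               "removed")
})

test_that("voxel registration recovers translations within half a voxel", {
  sp <- 0.6
  spec <- tmj_phantom_spec(skull_translation = c(2, -1, 3) * sp,
                          voxel_spacing = sp, seed = 5)
  ph <- make_tmj_phantom(spec)
  res <- voxel_register(ph$volumes$post, ph$volumes$pre, ph$volumes$mask)
  err <- compose_transform(res$transform, ph$truth$skull_transform)
  p0 <- c(0, 0, 60)
  shift <- apply_transform(p0, err) - p0
  expect_lt(max(abs(shift)) / sp, 0.5)

  # moving == fixed recovers the identity to a small fraction of a voxel
  res0 <- voxel_register(ph$volumes$pre, ph$volumes$pre, ph$volumes$mask)
  expect_lt(sqrt(sum((apply_transform(p0, res0$transform) - p0)^2)) / sp, 0.1)

  zero_mask <- voxel_volume(array(0, dim(ph$volumes$mask$data)),
                            ph$volumes$mask$spacing, ph$volumes$mask$origin)
  expect_error(voxel_register(ph$volumes$post, ph$volumes$pre, zero_mask),
               "empty mask")
})
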