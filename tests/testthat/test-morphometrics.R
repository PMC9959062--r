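test_that("distance maps are zero on identity and analytic on nested spheres", {
  s <- uv_sphere(10, 41)
  dm0 <- distance_map(s, s)
  expect_lt(max(abs(dm0$values)), 1e-9)

  outer <- uv_sphere(11, 41)
  dm_out <- distance_map(s, outer)
  expect_true(all(dm_out$values > 0)) # apposition positive
  expect_lt(max(abs(dm_out$values - 1)), 0.05)

  inner <- uv_sphere(9, 41)
  dm_in <- distance_map(s, inner)
  expect_true(all(dm_in$values < 0)) # resorption negative
  expect_lt(max(abs(dm_in$values + 1)), 0.05)

  # anti-symmetry at matched scale for nested spheres
  dm_rev <- distance_map(outer, s)
  expect_lt(abs(mean(dm_out$values) + mean(dm_rev$values)), 0.02)

  a <- s; a$frame <- "ramus"
  b <- outer; b$frame <- "cranial"
  expect_error(distance_map(a, b), "frame mismatch")
})

test_that("regional summaries: mean, RMS, and empty-region handling", {
  s <- uv_sphere(5, 21)
  dm <- distance_map(s, s)
  expect_equal(region_mean_distance(dm, labels = NULL, region = "whole"), 0)
  # sign cancellation on a (+1, -1) two-vertex region
  n <- length(dm$values)
  dm$values <- rep(0, n); dm$values[1:2] <- c(1, -1)
  labs <- rep("posterior-medial", n); labs[1:2] <- "anterior-lateral"
  expect_equal(region_mean_distance(dm, labs, "anterior-lateral", "signed"), 0)
  expect_equal(region_mean_distance(dm, labs, "anterior-lateral", "absolute"), 1)
  two <- dm; two$values <- c(3, 4)
  lab2 <- c("anterior-lateral", "anterior-lateral")
  expect_equal(region_rms_distance(two, labels = lab2, region = "anterior-lateral"),
               sqrt(12.5))

  labs <- rep("anterior-lateral", length(dm$values))
  expect_warning(out <- region_mean_distance(dm, labs, region = "posterior-medial"),
                 "empty")
  expect_true(is.na(out))

  # Jensen: RMS >= |signed mean| on random maps
  set.seed(5)
  for (i in 1:50) {
    vals <- rnorm(200, mean = runif(1, -1, 1))
    m <- list(values = vals, reference = NULL)
    class(m) <- "distance_map"
    labs <- rep("anterior-lateral", 200)
    expect_gte(region_rms_distance(m, labs, "anterior-lateral") + 1e-12,
               abs(region_mean_distance(m, labs, "anterior-lateral", "signed")))
  }
})

test_that("whole-structure mean lies between regional means", {
  s <- uv_sphere(10, 41, ang_offset = 0.02)
  s <- label_by_planes(s, plane(c(0, 0, 0), c(0, 1, 0)), plane(c(0, 0, 0), c(1, 0, 0)))
  set.seed(9)
  dm <- distance_map(s, s)
  dm$values <- rnorm(length(dm$values), 0.3, 0.4)
  dm$reference <- s
  regional <- vapply(region_levels(), function(r)
    region_mean_distance(dm, s$labels, r), numeric(1))
  whole <- region_mean_distance(dm, s$labels, "whole")
  expect_gte(whole, min(regional))
  expect_lte(whole, max(regional))
})

test_that("volumetric change is exact arithmetic on mesh volumes", {
  s <- uv_sphere(10, 33)
  expect_equal(volumetric_change(s, s), 0)
  shrunk <- s
  shrunk$vertices <- s$vertices * (0.95)^(1 / 3)
  expect_equal(volumetric_change(s, shrunk), -5, tolerance = 1e-9)
})

test_that("carved indentation volume is recovered as volumetric change", {
  # dent of analytic surface-integral volume on a phantom condylar head
  site <- list(structure = "head", region = "anterior-lateral",
               depth = 0.5, sigma = 2)
  ph <- make_tmj_phantom(tmj_phantom_spec(sites = list(site)),
                         make_volumes = FALSE)
  planes <- cut_plane_set(ph$pre$landmarks, ramus = ph$pre$ramus)
  pre <- isolate_condyle(ph$pre$ramus, planes)$condyle
  post <- isolate_condyle(ph$post$ramus, planes)$condyle
  carved_meas <- mesh_volume(pre) - mesh_volume(post)
  carved_truth <- ph$truth$carved_mm3[["head anterior-lateral"]]
  expect_lt(abs(carved_meas / carved_truth - 1), 0.1)
  expect_equal(volumetric_change(pre, post),
               -100 * carved_meas / mesh_volume(pre), tolerance = 1e-9)
})

test_that("minimum joint space matches the concentric phantom gap", {
  ph <- make_tmj_phantom(tmj_phantom_spec(gap = 3), make_volumes = FALSE)
  planes <- cut_plane_set(ph$pre$landmarks, ramus = ph$pre$ramus)
  cond <- label_by_planes(isolate_condyle(ph$pre$ramus, planes)$condyle,
                          planes$pole_plane, planes$mid_plane)
  cond$frame <- "cranial"
  skull <- ph$pre$skull; skull$frame <- "cranial"
  loop <- attach_curve_to_surface(ph$pre$curve, skull)
  patch <- extract_fossa_patch(skull, loop, ph$pre$seed_point)
  patch <- partition_fossa(patch, planes$pole_plane, planes$mid_plane)

  regional <- vapply(region_levels(), function(r)
    min_joint_space(cond, patch, r), numeric(1))
  expect_true(all(abs(regional - 3) < 0.1))
  # whole-joint value is the minimum over the four regions
  expect_equal(min_joint_space(cond, patch, "whole"), min(regional))
  # touching surfaces give zero
  expect_equal(min_joint_space(cond, cond, "whole", pairing = "whole"), 0)

  other <- cond; other$frame <- "ramus"
  expect_error(min_joint_space(other, patch, "whole"), "frame mismatch")
})

test_that("joint space change is post minus pre with NA propagation", {
  expect_equal(joint_space_change(2, 2), 0)
  expect_equal(joint_space_change(2, 1.5), -0.5)
  expect_true(is.na(joint_space_change(NA_real_, 2)))
})

test_that("colormap export encodes the diverging scale and round-trips", {
  s <- uv_sphere(5, 21)
  dm <- distance_map(s, s)
  dm$values <- seq(-2, 2, length.out = length(dm$values))
  dm$reference$scalars <- dm$values
  td <- withr::local_tempdir()
  f <- file.path(td, "cm.ply")
  export_colormap(dm, c(-1, 1), f)
  lines <- readLines(f)
  nv <- length(dm$values)
  body <- read.table(text = lines[(which(lines == "end_header") + 1):(which(lines == "end_header") + nv)])
  rgb <- as.matrix(body[, 5:7])
  zero_idx <- which.min(abs(dm$values))
  expect_true(all(rgb[zero_idx, ] >= 250)) # center is white
  expect_equal(unname(rgb[which.max(dm$values), ]), c(255, 0, 0)) # saturated red
  expect_equal(unname(rgb[which.min(dm$values), ]), c(0, 0, 255)) # saturated blue
  back <- read_mesh(f)
  expect_equal(back$scalars, dm$values, tolerance = 1e-9)
  expect_error(export_colormap(dm, c(1, -1), file.path(td, "x.ply")), "min < max")
})

test_that("morphometrics are invariant under a common rigid transform", {
  site <- list(structure = "head", region = "posterior-medial",
               depth = 0.4, sigma = 2)
  ph <- make_tmj_phantom(tmj_phantom_spec(sites = list(site)),
                         make_volumes = FALSE)
  planes <- cut_plane_set(ph$pre$landmarks, ramus = ph$pre$ramus)
  pre <- isolate_condyle(ph$pre$ramus, planes)$condyle
  post <- isolate_condyle(ph$post$ramus, planes)$condyle
  vc0 <- volumetric_change(pre, post)
  d0 <- mean(abs(distance_map(pre, post)$values))

  g <- rigid_transform(rotation_about_axis(c(0.3, 1, -2), 41), c(-6, 2, 8))
  vc1 <- volumetric_change(apply_transform(pre, g), apply_transform(post, g))
  d1 <- mean(abs(distance_map(apply_transform(pre, g), apply_transform(post, g))$values))
  expect_lt(abs(vc1 - vc0), 1e-6)
  expect_lt(abs(d1 - d0), 1e-6)
})
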