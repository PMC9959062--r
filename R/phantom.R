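#' Synthetic TMJ phantom specification
#'
#' Defines an idealized temporomandibular joint with analytic ground truth:
#' a spherical condylar head (radius `head_radius`, so cap volumes and the
#' concentric joint gap are exact), a tapered elliptic ramus shaft (the
#' ellipticity makes axial rotation observable to surface registration), a
#' cranial plate carrying a concentric spherical fossa socket at gap `gap`,
#' and a separate forehead block that gives the cranial volume full 3D
#' structure for voxel registration. Post-operative anatomy is the
#' pre-operative anatomy with smooth Gaussian remodeling indentations applied
#' at named sub-regions, optionally displaced within the fossa
#' (`condylar_displacement`, cranial frame) and moved by a rigid scan-pose
#' perturbation. Every stochastic choice (volume noise) is fixed by `seed`.
#'
#' @param head_radius condylar head radius (mm).
#' @param head_center condylar head center (mm).
#' @param neck_radius condylar neck radius (mm).
#' @param c_point_z height of the mandibular-notch C-point (mm).
#' @param shaft_radius ramus shaft base radius (mm).
#' @param gap condyle-to-fossa joint space (mm).
#' @param sites list of remodeling sites: each
#'   `list(structure = "head"|"neck"|"fossa", region = <region name or NA>,
#'   depth = mm, sigma = mm)`.
#' @param skull_rotation_deg,skull_rotation_axis,skull_translation rigid
#'   scan-pose perturbation applied to all post-operative anatomy.
#' @param condylar_displacement extra displacement (mm) of the mandible within
#'   the fossa (positive z = toward the fossa roof).
#' @param voxel_spacing rasterization spacing (mm) for the cranial volumes.
#' @param noise_sd additive Gaussian intensity noise for pseudo-CT volumes.
#' @param n_theta circumferential mesh resolution.
#' @param seed integer seed fixing all stochastic choices.
#' @return an object of class `tmj_phantom_spec`.
#' @export
tmj_phantom_spec <- function(head_radius = 7, head_center = c(0, 0, 60),
                             neck_radius = 4, c_point_z = 55,
                             shaft_radius = 8, gap = 3, sites = list(),
                             skull_rotation_deg = 0,
                             skull_rotation_axis = c(0, 0, 1),
                             skull_translation = c(0, 0, 0),
                             condylar_displacement = c(0, 0, 0),
                             voxel_spacing = 0.6, noise_sd = 10,
                             n_theta = 72L, seed = 1L) {
  if (gap <= 0) stop("joint gap must be positive")
  for (s in sites) {
    if (s$depth < 0) stop("remodeling depths must be >= 0")
    if (s$sigma > head_radius)
      stop("remodeling radius larger than the region extent")
  }
  structure(list(head_radius = head_radius, head_center = head_center,
                 neck_radius = neck_radius, c_point_z = c_point_z,
                 shaft_radius = shaft_radius, gap = gap, sites = sites,
                 skull_rotation_deg = skull_rotation_deg,
                 skull_rotation_axis = skull_rotation_axis,
                 skull_translation = skull_translation,
                 condylar_displacement = condylar_displacement,
                 voxel_spacing = voxel_spacing, noise_sd = noise_sd,
                 n_theta = as.integer(n_theta), seed = as.integer(seed)),
            class = "tmj_phantom_spec")
}

#' Analytic spherical cap volume
#' @param r sphere radius (mm).
#' @param h cap height (mm), 0 <= h <= 2r.
#' @return volume in mm^3.
#' @export
spherical_cap_volume <- function(r, h) pi * h^2 * (3 * r - h) / 3

# run expr with a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else on.exit(rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# --- lathe-style closed mesh from stacked cross-section rings ---------------

# rings: list of n_theta x 3 matrices, ascending along the axis; closed by
# apex fans at both ends
lathe_mesh <- function(rings, bottom_apex, top_apex) {
  nt <- nrow(rings[[1]])
  nr <- length(rings)
  v <- do.call(rbind, rings)
  idx <- function(r, j) (r - 1L) * nt + ((j - 1L) %% nt) + 1L
  faces <- vector("list", nr + 1)
  for (r in seq_len(nr - 1)) {
    j <- seq_len(nt)
    a <- idx(r, j); b <- idx(r, j + 1)
    cc <- idx(r + 1, j + 1); d <- idx(r + 1, j)
    faces[[r]] <- rbind(cbind(a, b, cc), cbind(a, cc, d))
  }
  v <- rbind(v, bottom_apex, top_apex)
  bi <- nr * nt + 1L; ti <- nr * nt + 2L
  j <- seq_len(nt)
  faces[[nr]] <- cbind(bi, idx(1, j + 1), idx(1, j))
  faces[[nr + 1]] <- cbind(ti, idx(nr, j), idx(nr, j + 1))
  surface_mesh(v, do.call(rbind, faces), clean = TRUE)
}

# condyle-bearing ramus: elliptic tapered shaft blending into a spherical head
make_ramus_mesh <- function(spec) {
  rh <- spec$head_radius; C <- spec$head_center
  nr <- spec$neck_radius
  z_attach <- C[3] - sqrt(rh^2 - nr^2)
  nt <- spec$n_theta
  ang <- 2 * pi * (seq_len(nt) - 1) / nt
  ring_at <- function(rx, ry, z, cx = C[1], cy = C[2])
    cbind(cx + rx * cos(ang), cy + ry * sin(ang), z)
  rings <- list()
  # shaft: base radius tapers to the neck by z = 50, elliptic at the base
  zs <- seq(0, 50, by = 1.25)
  for (z in zs) {
    t <- z / 50
    rho <- nr + (spec$shaft_radius - nr) * (1 - t)^1.5
    sx <- 1 + 0.30 * (1 - t)
    sy <- 1 - 0.20 * (1 - t)
    rings[[length(rings) + 1]] <- ring_at(rho * sx, rho * sy, z)
  }
  # straight neck up to the sphere attachment
  for (z in seq(50 + 0.85, z_attach - 0.2, by = 0.85))
    rings[[length(rings) + 1]] <- ring_at(nr, nr, z)
  # spherical head: polar-angle rings from the attachment to near the apex
  phi_attach <- acos((z_attach - C[3]) / rh)
  for (phi in seq(phi_attach, 0.06, length.out = 40)) {
    rho <- rh * sin(phi)
    rings[[length(rings) + 1]] <- ring_at(rho, rho, C[3] + rh * cos(phi))
  }
  lathe_mesh(rings, bottom_apex = c(C[1], C[2], 0),
             top_apex = c(C[1], C[2], C[3] + rh))
}

# cranial plate with a concentric spherical fossa socket; bottom heightfield
make_skull_mesh <- function(spec, grid_step = 0.8) {
  C <- spec$head_center
  Ri <- spec$head_radius + spec$gap
  rho_rim <- 0.8 * Ri
  z_plate <- C[3] + sqrt(Ri^2 - rho_rim^2)
  z_top <- C[3] + Ri + 2.5
  half <- 25
  xs <- seq(C[1] - half, C[1] + half, by = grid_step)
  ys <- seq(C[2] - half, C[2] + half, by = grid_step)
  nx <- length(xs); ny <- length(ys)
  gx <- matrix(xs, nx, ny)
  gy <- matrix(ys, nx, ny, byrow = TRUE)
  rho <- sqrt((gx - C[1])^2 + (gy - C[2])^2)
  zb <- matrix(z_plate, nx, ny)
  inb <- rho < rho_rim
  zb[inb] <- C[3] + sqrt(Ri^2 - rho[inb]^2)
  vid <- function(i, j) (j - 1L) * nx + i
  vb <- cbind(as.vector(gx), as.vector(gy), as.vector(zb))
  vt <- cbind(as.vector(gx), as.vector(gy), z_top)
  nb <- nrow(vb)
  faces <- list()
  for (j in seq_len(ny - 1)) {
    i <- seq_len(nx - 1)
    p11 <- vid(i, j); p21 <- vid(i + 1, j)
    p12 <- vid(i, j + 1); p22 <- vid(i + 1, j + 1)
    faces[[length(faces) + 1]] <- rbind(
      cbind(p11, p12, p22), cbind(p11, p22, p21),          # bottom, normals down
      cbind(nb + p11, nb + p21, nb + p22),                 # top, normals up
      cbind(nb + p11, nb + p22, nb + p12))
  }
  # walls along the CCW bottom boundary
  bnd <- c(vid(seq_len(nx), 1), vid(nx, seq(2, ny)),
           vid(seq(nx - 1, 1), ny), vid(1, seq(ny - 1, 2)))
  bnxt <- c(bnd[-1], bnd[1])
  faces[[length(faces) + 1]] <- rbind(cbind(bnd, bnxt, nb + bnxt),
                                      cbind(bnd, nb + bnxt, nb + bnd))
  surface_mesh(rbind(vb, vt), do.call(rbind, faces), clean = TRUE)
}

make_forehead_block <- function(spec) {
  C <- spec$head_center
  Ri <- spec$head_radius + spec$gap
  z_top <- C[3] + Ri + 2.5
  box_mesh(c(C[1] - 18, C[2] + 12, z_top), c(C[1] + 18, C[2] + 24, z_top + 10))
}

#' Axis-aligned closed box mesh (12 triangles)
#' @param lo,hi numeric length-3 opposite corners (mm).
#' @return a `surface_mesh` with outward orientation.
#' @export
box_mesh <- function(lo, hi) {
  v <- as.matrix(expand.grid(x = c(lo[1], hi[1]), y = c(lo[2], hi[2]),
                             z = c(lo[3], hi[3])))
  # corner index: 1 + (x==hi) + 2*(y==hi) + 4*(z==hi)
  f <- rbind(c(1, 3, 4), c(1, 4, 2),   # bottom (z = lo), normal -z
             c(5, 6, 8), c(5, 8, 7),   # top +z
             c(1, 2, 6), c(1, 6, 5),   # front -y
             c(3, 7, 8), c(3, 8, 4),   # back +y
             c(1, 5, 7), c(1, 7, 3),   # left -x
             c(2, 4, 8), c(2, 8, 6))   # right +x
  surface_mesh(v, f, clean = TRUE)
}

# site center directions: anterior = +y, lateral = +x, elevation inside the
# condylar head cap (or the fossa socket)
site_direction <- function(structure, region) {
  if (structure == "neck") return(unit3(c(0, -1, -0.5)))
  s <- switch(region,
              "anterior-lateral" = c(1, 1), "anterior-medial" = c(-1, 1),
              "posterior-lateral" = c(1, -1), "posterior-medial" = c(-1, -1),
              stop(sprintf("unknown region '%s'", region)))
  if (structure == "fossa") unit3(c(0.6 * s[1], 0.6 * s[2], 1))
  else unit3(c(s[1], s[2], 1.1))
}

# Gaussian indentation depths (mm) at points pts for a site on a sphere of
# radius r about center C
site_depths <- function(pts, C, r, u, depth, sigma) {
  p_site <- C + r * u
  d2 <- (pts[, 1] - p_site[1])^2 + (pts[, 2] - p_site[2])^2 + (pts[, 3] - p_site[3])^2
  depth * exp(-d2 / (2 * sigma^2))
}

#' Generate a synthetic TMJ phantom
#'
#' Builds the pre-operative anatomy (ramus + condyle mesh, cranial mesh,
#' landmark set, traced fossa curve), the post-operative anatomy (remodeled,
#' displaced, rigidly perturbed), optional pseudo-CT volumes with a
#' registration mask, and a ground-truth record. Deterministic per seed.
#'
#' @param spec a `tmj_phantom_spec`.
#' @param make_volumes rasterize cranial volumes for voxel registration
#'   (default TRUE).
#' @return list with elements `pre` (ramus, skull, landmarks, curve, seed
#'   point), `post` (ramus, skull), `volumes` (pre, post, mask or NULL) and
#'   `truth` (transforms, analytic volumes, carved volumes per structure and
#'   region, joint gap and displacement).
#' @export
make_tmj_phantom <- function(spec = tmj_phantom_spec(), make_volumes = TRUE) {
  rh <- spec$head_radius; C <- spec$head_center
  Ri <- rh + spec$gap
  pre_ramus <- make_ramus_mesh(spec)
  pre_skull <- make_skull_mesh(spec)
  block <- make_forehead_block(spec)

  z_attach <- C[3] - sqrt(rh^2 - spec$neck_radius^2)
  lm <- landmark_set(
    porion_right = c(C[1] + 40, C[2], C[3]),
    porion_left = c(C[1] - 40, C[2], C[3]),
    orbitale = c(C[1], C[2] + 60, C[3]),
    c_point = c(C[1], C[2] + sqrt(rh^2 - (spec$c_point_z - C[3])^2),
                spec$c_point_z),
    lateral_pole = c(C[1] + rh, C[2], C[3]),
    medial_pole = c(C[1] - rh, C[2], C[3]),
    anterior_reference = c(C[1], C[2] + 30, C[3]))

  rho_rim <- 0.8 * Ri
  rho_c <- 0.9 * rho_rim
  tt <- 2 * pi * (0:15) / 16
  curve <- cbind(C[1] + rho_c * cos(tt), C[2] + rho_c * sin(tt),
                 C[3] + sqrt(Ri^2 - rho_c^2) - 0.8)
  seed_point <- c(C[1], C[2], C[3] + Ri - 0.2)

  # --- remodeling on the post anatomy (pre frame), with carved-volume truth
  post_ramus <- pre_ramus
  post_skull <- pre_skull
  carved <- list()
  vertex_area <- function(mesh) {
    fa <- face_areas(mesh)
    acc <- rowsum(rep(fa / 3, 3), group = as.vector(mesh$faces))
    out <- numeric(n_vertices(mesh))
    out[as.integer(rownames(acc))] <- acc
    out
  }
  for (s in spec$sites) {
    u <- site_direction(s$structure, s$region)
    key <- paste(s$structure, if (is.null(s$region)) "" else s$region)
    if (s$structure %in% c("head", "neck")) {
      v <- post_ramus$vertices
      on_sphere <- v[, 3] > z_attach + 0.15
      dep <- site_depths(v, C, rh, u, s$depth, s$sigma)
      dep[!on_sphere] <- 0
      nrm <- sweep(v, 2, C)
      nrm <- nrm / sqrt(rowSums(nrm^2))
      post_ramus$vertices <- v - dep * nrm
      carved[[key]] <- sum(dep * vertex_area(pre_ramus))
    } else if (s$structure == "fossa") {
      v <- post_skull$vertices
      on_bowl <- abs(sqrt(rowSums(sweep(v, 2, C)^2)) - Ri) < 0.05
      dep <- site_depths(v, C, Ri, u, s$depth, s$sigma)
      dep[!on_bowl] <- 0
      nrm <- sweep(v, 2, C)
      nrm <- nrm / sqrt(rowSums(nrm^2))
      post_skull$vertices <- v + dep * nrm # socket deepens away from the condyle
      carved[[key]] <- sum(dep * vertex_area(pre_skull))
    }
  }

  Ts <- rigid_transform(rotation_about_axis(spec$skull_rotation_axis,
                                            spec$skull_rotation_deg),
                        spec$skull_translation)
  Td <- rigid_transform(diag(3), spec$condylar_displacement)
  Tm <- compose_transform(Ts, Td)
  post_ramus <- apply_transform(post_ramus, Tm)
  post_skull_moved <- apply_transform(post_skull, Ts)
  post_block <- apply_transform(block, Ts)

  volumes <- NULL
  if (make_volumes) {
    volumes <- with_seed(spec$seed, {
      pre_vol <- rasterize(list(pre_skull, block), spacing = spec$voxel_spacing,
                           padding = 3, fill = 1200, background = 80,
                           smooth_sigma = 0.7, noise_sd = spec$noise_sd)
      post_vol <- rasterize(list(post_skull_moved, post_block),
                            spacing = spec$voxel_spacing,
                            padding = 3, fill = 1200, background = 80,
                            smooth_sigma = 0.7, noise_sd = spec$noise_sd)
      occ <- rasterize(list(pre_skull, block), spacing = spec$voxel_spacing,
                       padding = 3, fill = 1, background = 0, smooth_sigma = 1.2)
      mask_arr <- (occ$data > 0.05) * 1.0
      ys <- occ$origin[2] + (seq_len(dim(occ$data)[2]) - 1) * occ$spacing[2]
      mask_arr[, ys < C[2] + 5, ] <- 0
      list(pre = pre_vol, post = post_vol,
           mask = voxel_volume(mask_arr, occ$spacing, occ$origin))
    })
  }

  h_cap <- rh - (spec$c_point_z - C[3])
  truth <- list(
    skull_transform = Ts, mandible_transform = Tm,
    condylar_displacement = spec$condylar_displacement,
    condyle_volume_analytic = spherical_cap_volume(rh, h_cap),
    carved_mm3 = carved,
    sites = spec$sites,
    gap = spec$gap)
  list(pre = list(ramus = pre_ramus, skull = pre_skull, landmarks = lm,
                  curve = curve, seed_point = seed_point),
       post = list(ramus = post_ramus, skull = post_skull_moved),
       volumes = volumes, truth = truth, spec = spec)
}

#' Rasterize meshes into a pseudo-CT voxel volume
#'
#' Solid voxelization (parity ray casting through voxel centers) of one or
#' more closed meshes onto a common grid, with optional Gaussian smoothing
#' to pseudo-CT intensities and additive Gaussian noise (caller controls the
#' RNG seed).
#'
#' @param mesh a closed `surface_mesh` or list of them.
#' @param spacing isotropic voxel spacing (mm).
#' @param padding empty margin around the joint bounding box (mm).
#' @param fill,background interior / exterior intensity.
#' @param smooth_sigma Gaussian smoothing sigma (mm; 0 = none).
#' @param noise_sd additive Gaussian noise SD (0 = none).
#' @param origin,dims optional explicit grid (otherwise fitted to the meshes).
#' @return a `voxel_volume`.
#' @export
rasterize <- function(mesh, spacing = 0.3, padding = 2, fill = 1,
                      background = 0, smooth_sigma = 0, noise_sd = 0,
                      origin = NULL, dims = NULL) {
  meshes <- if (inherits(mesh, "surface_mesh")) list(mesh) else mesh
  if (!length(meshes) || any(!vapply(meshes, function(m) n_faces(m) > 0, logical(1))))
    stop("rasterize: empty mesh")
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  if (any(spacing <= 0)) stop("spacing must be positive")
  allv <- do.call(rbind, lapply(meshes, function(m) m$vertices))
  if (is.null(origin) || is.null(dims)) {
    lo <- apply(allv, 2, min) - padding
    hi <- apply(allv, 2, max) + padding
    if (any(hi - lo < spacing)) stop("spacing larger than mesh extent")
    dims <- as.integer(ceiling((hi - lo) / spacing)) + 1L
    origin <- lo
  }
  occ <- rep(0L, prod(dims))
  for (m in meshes) {
    o <- cpp_voxelize(m$vertices, m$faces, origin, spacing, as.integer(dims))
    occ <- pmax(occ, o)
  }
  arr <- array(background + (fill - background) * as.numeric(occ), dims)
  vol <- voxel_volume(arr, spacing, origin)
  if (smooth_sigma > 0) vol <- smooth_volume(vol, smooth_sigma)
  if (noise_sd > 0)
    vol$data <- vol$data + array(stats::rnorm(length(vol$data), 0, noise_sd),
                                 dim(vol$data))
  vol
}

#' Simulate a two-observer (k-rater) ratings table
#'
#' Subject effects ~ Normal(0, between_sd^2) are added to the true values and
#' independent rater errors ~ Normal(0, error_sd^2) to every cell. The
#' implied intraclass correlation `between_sd^2 / (between_sd^2 + error_sd^2)`
#' is recorded as attribute `true_icc`.
#'
#' @param true_values numeric vector of per-subject true values.
#' @param between_sd between-subject SD.
#' @param error_sd rater error SD.
#' @param k number of raters (>= 2).
#' @param seed RNG seed (NULL = use current RNG state).
#' @return n x k matrix with attribute `true_icc`.
#' @export
simulate_observer_ratings <- function(true_values, between_sd, error_sd,
                                      k = 2L, seed = NULL) {
  if (between_sd < 0 || error_sd < 0) stop("SDs must be >= 0")
  if (k < 2) stop("need k >= 2 raters")
  gen <- function() {
    n <- length(true_values)
    subj <- true_values + stats::rnorm(n, 0, between_sd)
    tab <- matrix(subj, n, k) + matrix(stats::rnorm(n * k, 0, error_sd), n, k)
    attr(tab, "true_icc") <- between_sd^2 / (between_sd^2 + error_sd^2)
    tab
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' Generate a cohort of varied TMJ phantoms for reliability studies
#'
#' Each joint draws per-region remodeling depths (uniform 0.15-1.0 mm on the
#' four condylar-head regions, one posterior neck site and the four fossa
#' regions), a joint gap (uniform 2.5-3.5 mm), a vertical condylar
#' displacement (uniform -0.5 to 0.3 mm) and a small rigid scan-pose
#' perturbation — the between-subject variation a clinical sample would show.
#'
#' @param n number of joints.
#' @param seed cohort seed.
#' @param voxel_spacing rasterization spacing for the cranial volumes (mm).
#' @return list of `tmj_phantom_spec` objects.
#' @export
tmj_phantom_cohort <- function(n = 20L, seed = 1L, voxel_spacing = 1.0) {
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      sites <- list()
      for (r in region_levels())
        sites[[length(sites) + 1]] <- list(structure = "head", region = r,
                                           depth = stats::runif(1, 0.15, 1.0),
                                           sigma = 2.0)
      sites[[length(sites) + 1]] <- list(structure = "neck",
                                         region = NA_character_,
                                         depth = stats::runif(1, 0.15, 0.8),
                                         sigma = 1.5)
      for (r in region_levels())
        sites[[length(sites) + 1]] <- list(structure = "fossa", region = r,
                                           depth = stats::runif(1, 0.1, 0.6),
                                           sigma = 2.0)
      tmj_phantom_spec(
        gap = stats::runif(1, 2.5, 3.5),
        sites = sites,
        skull_rotation_deg = stats::runif(1, -2, 2),
        skull_rotation_axis = c(0, 0, 1),
        skull_translation = stats::runif(3, -1.5, 1.5),
        condylar_displacement = c(0, 0, stats::runif(1, -0.5, 0.3)),
        voxel_spacing = voxel_spacing,
        seed = sample.int(1e6, 1))
    })
  })
}

#' Write a generated phantom to disk
#'
#' Emits STL meshes (pre/post ramus and skull), NIfTI volumes and mask (when
#' present), JSON landmark and curve files, and `truth.json` with the
#' ground-truth record.
#'
#' @param phantom result of [make_tmj_phantom()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_mesh(phantom$pre$ramus, file.path(dir, "pre_ramus.stl"))
  write_mesh(phantom$post$ramus, file.path(dir, "post_ramus.stl"))
  write_mesh(phantom$pre$skull, file.path(dir, "pre_skull.stl"))
  write_mesh(phantom$post$skull, file.path(dir, "post_skull.stl"))
  write_landmarks(phantom$pre$landmarks, file.path(dir, "landmarks.json"))
  write_curve(phantom$pre$curve, file.path(dir, "curve.json"))
  if (!is.null(phantom$volumes)) {
    write_volume(phantom$volumes$pre, file.path(dir, "pre.nii.gz"))
    write_volume(phantom$volumes$post, file.path(dir, "post.nii.gz"))
    write_volume(phantom$volumes$mask, file.path(dir, "mask.nii.gz"))
  }
  tr <- phantom$truth
  tr$skull_transform <- rbind(cbind(tr$skull_transform$rotation,
                                    tr$skull_transform$translation), c(0, 0, 0, 1))
  tr$mandible_transform <- rbind(cbind(tr$mandible_transform$rotation,
                                       tr$mandible_transform$translation),
                                 c(0, 0, 0, 1))
  tr$seed_point <- phantom$pre$seed_point
  jsonlite::write_json(tr, file.path(dir, "truth.json"), digits = NA,
                       auto_unbox = TRUE)
  invisible(dir)
}
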