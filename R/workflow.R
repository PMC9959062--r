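#' Holistic TMJ assessment of one joint side
#'
#' Runs the full dual-frame pipeline on in-memory objects:
#' \enumerate{
#'   \item Cranial frame: masked voxel-based registration (VBR) of the
#'     post-operative onto the pre-operative volume; the traced curve is
#'     attached to both skull surfaces, the glenoid fossa patch extracted and
#'     partitioned, and fossa RMS surface distances computed.
#'   \item Ramus frame: surface-based registration (SBR) of the post onto the
#'     pre ramus — a coarse whole-ramus pass followed by a refinement on the
#'     stable reference region below the C-plane — then condylar isolation,
#'     head/neck split, four-sub-region partition, volumetric change and
#'     mean surface distances.
#'   \item Joint space: minimum condyle-to-fossa distances per sub-region,
#'     pre and post, in the cranial frame; change = post - pre.
#' }
#' Frame tags are attached to every mesh and checked by each metric, so
#' cross-frame computation is impossible by construction.
#'
#' @param pre_ramus,post_ramus closed ramus+condyle `surface_mesh` objects.
#' @param pre_skull,post_skull cranial `surface_mesh` objects.
#' @param landmarks a `landmark_set` (porions, orbitale, c_point, poles,
#'   anterior_reference), defined on the pre-operative anatomy.
#' @param curve n x 3 traced curve engulfing the pre-operative fossa.
#' @param seed_point 3D point near the fossa roof selecting the patch side.
#' @param pre_volume,post_volume,mask `voxel_volume`s for VBR (may be omitted
#'   when `vbr` is supplied).
#' @param vbr optional precomputed VBR `registration_result` (its transform
#'   maps post-volume space onto the pre-volume space).
#' @param icp `icp_params` for the SBR passes.
#' @param vbr_metric "ncc" (default) or "nmi".
#' @param pairing joint-space fossa pairing, "region" or "whole".
#' @param subject,side identifiers copied into the report.
#' @param output_dir optional directory: writes report.csv/report.json,
#'   transform JSONs, colormap PLYs and a parameter log.
#' @return object of class `tmj_assessment`: list with `report` (data.frame:
#'   subject, side, structure, region, metric, value, frame), `transforms`,
#'   `maps`, and the labeled structures.
#' @export
assess_tmj <- function(pre_ramus, post_ramus, pre_skull, post_skull,
                       landmarks, curve, seed_point,
                       pre_volume = NULL, post_volume = NULL, mask = NULL,
                       vbr = NULL, icp = icp_params(), vbr_metric = "ncc",
                       pairing = "region", subject = "case", side = "right",
                       output_dir = NULL) {
  # --- cranial frame -------------------------------------------------------
  if (is.null(vbr)) {
    if (is.null(pre_volume) || is.null(post_volume) || is.null(mask))
      stop("assess_tmj: provide volumes + mask, or a precomputed vbr result")
    vbr <- voxel_register(post_volume, pre_volume, mask, metric = vbr_metric)
  }
  t_vbr <- vbr$transform
  pre_skull$frame <- "cranial"
  post_skull_c <- apply_transform(post_skull, t_vbr)
  post_skull_c$frame <- "cranial"

  planes <- cut_plane_set(landmarks, ramus = pre_ramus)

  loop_pre <- attach_curve_to_surface(curve, pre_skull)
  fossa_pre <- extract_fossa_patch(pre_skull, loop_pre, seed_point)
  fossa_pre <- partition_fossa(fossa_pre, planes$pole_plane, planes$mid_plane)
  loop_post <- attach_curve_to_surface(curve, post_skull_c)
  fossa_post <- extract_fossa_patch(post_skull_c, loop_post, seed_point)
  fossa_post <- partition_fossa(fossa_post, planes$pole_plane, planes$mid_plane)

  dm_fossa <- distance_map(fossa_pre, post_skull_c)
  # --- ramus frame ---------------------------------------------------------
  pre_ramus$frame <- "ramus"
  coarse <- icp_register(post_ramus, pre_ramus, params = icp)
  post_coarse <- apply_transform(post_ramus, coarse$transform)
  ref_pre <- crop_reference_region(pre_ramus, list(planes$c_plane))
  ref_post <- crop_reference_region(post_coarse, list(planes$c_plane))
  fine <- icp_register(ref_post, ref_pre, init = rigid_transform(), params = icp)
  t_sbr <- compose_transform(fine$transform, coarse$transform)
  post_ramus_s <- apply_transform(post_ramus, t_sbr)
  post_ramus_s$frame <- "ramus"

  iso_pre <- isolate_condyle(pre_ramus, planes)
  iso_post <- isolate_condyle(post_ramus_s, planes)
  cond_pre <- label_by_planes(iso_pre$condyle, planes$pole_plane, planes$mid_plane)
  dm_cond <- distance_map(cond_pre, iso_post$condyle)

  rows <- list()
  add <- function(structure, region, metric, value, frame)
    rows[[length(rows) + 1]] <<- data.frame(
      subject = subject, side = side, structure = structure, region = region,
      metric = metric, value = value, frame = frame, stringsAsFactors = FALSE)

  # volumetric change: condyle, head, neck, and the four head sub-regions
  add("condyle", "whole", "volumetric_change_pct",
      volumetric_change(iso_pre$condyle, iso_post$condyle), "ramus")
  add("head", "whole", "volumetric_change_pct",
      volumetric_change(iso_pre$head, iso_post$head), "ramus")
  if (n_faces(iso_pre$neck) > 0 && n_faces(iso_post$neck) > 0)
    add("neck", "whole", "volumetric_change_pct",
        volumetric_change(iso_pre$neck, iso_post$neck), "ramus")
  quad_pre <- region_solids(iso_pre$head, planes$pole_plane, planes$mid_plane)
  quad_post <- region_solids(iso_post$head, planes$pole_plane, planes$mid_plane)
  for (r in region_levels())
    if (!is.null(quad_pre[[r]]) && !is.null(quad_post[[r]]))
      add("head", r, "volumetric_change_pct",
          volumetric_change(quad_pre[[r]], quad_post[[r]]), "ramus")

  # mean surface distances on the condyle (head/neck by the divider plane)
  is_head <- signed_distance(planes$head_neck_plane, cond_pre$vertices) > -1e-9
  struct_sets <- list(condyle = rep(TRUE, n_vertices(cond_pre)),
                      head = is_head, neck = !is_head)
  for (s in names(struct_sets)) {
    sel <- struct_sets[[s]]
    if (!any(sel)) next
    add(s, "whole", "mean_abs_distance_mm", mean(abs(dm_cond$values[sel])), "ramus")
    add(s, "whole", "mean_signed_distance_mm", mean(dm_cond$values[sel]), "ramus")
  }
  for (r in region_levels()) {
    sel <- is_head & cond_pre$labels == r
    if (!any(sel)) next
    add("head", r, "mean_abs_distance_mm", mean(abs(dm_cond$values[sel])), "ramus")
    add("head", r, "mean_signed_distance_mm", mean(dm_cond$values[sel]), "ramus")
  }

  # fossa RMS distances
  add("fossa", "whole", "rms_distance_mm", region_rms_distance(dm_fossa), "cranial")
  for (r in region_levels())
    add("fossa", r, "rms_distance_mm",
        region_rms_distance(dm_fossa, region = r), "cranial")

  # joint space (cranial frame): post condyle via the VBR alignment
  post_ramus_c <- apply_transform(post_ramus, t_vbr)
  cond_pre_c <- cond_pre; cond_pre_c$frame <- "cranial"
  iso_post_c <- isolate_condyle(post_ramus_c, planes)
  cond_post_c <- label_by_planes(iso_post_c$condyle, planes$pole_plane,
                                 planes$mid_plane)
  cond_post_c$frame <- "cranial"
  for (r in c("whole", region_levels())) {
    js_pre <- min_joint_space(cond_pre_c, fossa_pre, r, pairing = pairing)
    js_post <- min_joint_space(cond_post_c, fossa_post, r, pairing = pairing)
    add("joint_space", r, "min_distance_pre_mm", js_pre, "cranial")
    add("joint_space", r, "min_distance_post_mm", js_post, "cranial")
    add("joint_space", r, "joint_space_change_mm",
        joint_space_change(js_pre, js_post), "cranial")
  }

  out <- structure(list(report = do.call(rbind, rows),
                        transforms = list(sbr = t_sbr, vbr = t_vbr),
                        registrations = list(sbr_coarse = coarse, sbr_fine = fine,
                                             vbr = vbr),
                        maps = list(condyle = dm_cond, fossa = dm_fossa),
                        planes = planes,
                        structures = list(condyle_pre = cond_pre,
                                          condyle_post = iso_post$condyle,
                                          fossa_pre = fossa_pre,
                                          fossa_post = fossa_post)),
                   class = "tmj_assessment")
  if (!is.null(output_dir)) write_assessment(out, output_dir)
  out
}

#' @export
print.tmj_assessment <- function(x, ...) {
  cat("tmj_assessment\n")
  cat(sprintf("  SBR residual: %.4f mm; VBR converged: %s\n",
              x$registrations$sbr_fine$rms, x$registrations$vbr$converged))
  print(utils::head(x$report, 12))
  cat(sprintf("  ... %d report rows\n", nrow(x$report)))
  invisible(x)
}

# split a closed structure into the four capped sub-region solids
region_solids <- function(mesh, pole_plane, mid_plane) {
  out <- list()
  halves <- list(
    anterior = suppressMessages(clip_by_plane(mesh, pole_plane, "positive", cap = TRUE)),
    posterior = suppressMessages(clip_by_plane(mesh, pole_plane, "negative", cap = TRUE)))
  for (ap in names(halves)) {
    h <- halves[[ap]]
    if (n_faces(h) == 0) next
    for (lm in c("lateral", "medial")) {
      q <- suppressMessages(clip_by_plane(
        h, mid_plane, if (lm == "lateral") "positive" else "negative", cap = TRUE))
      if (n_faces(q) > 0) out[[paste(ap, lm, sep = "-")]] <- q
    }
  }
  out
}

#' Write assessment artifacts to a directory
#'
#' Emits `report.csv`, `report.json`, `transforms/sbr.json`,
#' `transforms/vbr.json`, colormap PLYs for the condylar and fossa distance
#' maps, and `log.yaml` echoing the decision parameters.
#'
#' @param assessment a `tmj_assessment`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_assessment <- function(assessment, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "transforms"), showWarnings = FALSE)
  rep <- assessment$report
  utils::write.csv(rep, file.path(dir, "report.csv"), row.names = FALSE)
  jsonlite::write_json(rep, file.path(dir, "report.json"), digits = NA,
                       dataframe = "rows")
  write_transform(assessment$transforms$sbr, file.path(dir, "transforms", "sbr.json"))
  write_transform(assessment$transforms$vbr, file.path(dir, "transforms", "vbr.json"))
  tr <- rbind(
    data.frame(stage = "sbr_coarse",
               iteration = seq_along(assessment$registrations$sbr_coarse$trace) - 1L,
               rms_mm = assessment$registrations$sbr_coarse$trace),
    data.frame(stage = "sbr_fine",
               iteration = seq_along(assessment$registrations$sbr_fine$trace) - 1L,
               rms_mm = assessment$registrations$sbr_fine$trace))
  utils::write.csv(tr, file.path(dir, "transforms", "icp_trace.csv"),
                   row.names = FALSE)
  rng <- max(abs(assessment$maps$condyle$values), 0.5)
  export_colormap(assessment$maps$condyle, c(-rng, rng),
                  file.path(dir, "condyle_distance_map.ply"))
  rngf <- max(abs(assessment$maps$fossa$values), 0.5)
  export_colormap(assessment$maps$fossa, c(-rngf, rngf),
                  file.path(dir, "fossa_distance_map.ply"))
  yaml::write_yaml(list(
    sign_convention = assessment$maps$condyle$sign_convention,
    frames = list(condylar_metrics = "ramus (SBR)",
                  fossa_and_joint_space = "cranial (VBR)")),
    file.path(dir, "log.yaml"))
  invisible(dir)
}

#' Assess a case described by a YAML config file
#'
#' The config lists, per side, the pre/post ramus and skull meshes
#' (STL/PLY/OBJ), pre/post volumes and mask (NIfTI), landmark and curve JSON
#' files, plus a `seed_point`; optional `params` override registration
#' settings, and `segmentation_threshold` builds skull meshes from the
#' volumes when explicit meshes are not given.
#'
#' @param config path to a YAML file or an equivalent nested list.
#' @return named list of `tmj_assessment` objects, one per declared side.
#' @export
assess_case <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (is.null(cfg$sides) || !length(cfg$sides)) stop("config declares no sides")
  params <- cfg$params %||% list()
  icp <- do.call(icp_params, params$icp %||% list())
  out <- list()
  for (side in names(cfg$sides)) {
    sc <- cfg$sides[[side]]
    need <- function(field) {
      p <- sc[[field]]
      if (is.null(p)) stop(sprintf("side '%s': missing '%s'", side, field))
      if (!file.exists(p)) stop(sprintf("side '%s': file not found: %s", side, p))
      p
    }
    pre_vol <- read_volume(need("pre_volume"))
    post_vol <- read_volume(need("post_volume"))
    mask <- read_volume(need("mask"))
    thr <- params$segmentation_threshold
    pre_skull <- if (!is.null(sc$pre_skull)) read_mesh(need("pre_skull"))
                 else volume_to_mesh(pre_vol, thr)
    post_skull <- if (!is.null(sc$post_skull)) read_mesh(need("post_skull"))
                  else volume_to_mesh(post_vol, thr)
    out[[side]] <- assess_tmj(
      pre_ramus = read_mesh(need("pre_ramus")),
      post_ramus = read_mesh(need("post_ramus")),
      pre_skull = pre_skull, post_skull = post_skull,
      landmarks = read_landmarks(need("landmarks")),
      curve = read_curve(need("curve")),
      seed_point = as.numeric(sc$seed_point),
      pre_volume = pre_vol, post_volume = post_vol, mask = mask,
      icp = icp, vbr_metric = params$vbr_metric %||% "ncc",
      pairing = params$pairing %||% "region",
      subject = cfg$subject %||% "case", side = side,
      output_dir = if (!is.null(cfg$output_dir))
        file.path(cfg$output_dir, side) else NULL)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Two-observer reliability run over stacked assessment reports
#'
#' Convenience wrapper around [reliability_study()] that also writes the
#' reliability table as CSV and one Bland-Altman plot per headline metric
#' when `output_dir` is given.
#'
#' @param reports_obs1,reports_obs2 stacked [assess_tmj()] report data.frames
#'   (rows matched on subject, structure, region, metric).
#' @param output_dir optional output directory.
#' @return a `reliability_report` data.frame.
#' @export
run_reliability <- function(reports_obs1, reports_obs2, output_dir = NULL) {
  rel <- reliability_study(reports_obs1, reports_obs2)
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(rel, file.path(output_dir, "reliability.csv"),
                     row.names = FALSE)
    key <- function(d) paste(d$subject, d$structure, d$region, d$metric, sep = "|")
    m <- match(key(reports_obs1), key(reports_obs2))
    for (met in unique(rel$metric)) {
      sel <- reports_obs1$metric == met & !is.na(reports_obs1$value)
      x <- reports_obs1$value[sel]
      y <- reports_obs2$value[m][sel]
      ok <- !is.na(y)
      if (sum(ok) < 3) next
      grDevices::png(file.path(output_dir, sprintf("bland_altman_%s.png", met)),
                     width = 640, height = 480)
      plot(bland_altman(x[ok], y[ok]), main = met)
      grDevices::dev.off()
    }
  }
  rel
}

#' End-to-end phantom reliability study
#'
#' Generates a cohort of varied TMJ phantoms, simulates two observers whose
#' only difference is independent Gaussian jitter on the landmark points and
#' the traced curve (the manual steps of the protocol), runs the full
#' assessment pipeline per observer, and summarizes inter-observer agreement.
#' Voxel registration, which takes no manual input, is computed once per
#' joint and shared between observers.
#'
#' @param n number of joints.
#' @param seed study seed (drives cohort generation and observer jitter).
#' @param jitter_sd observer jitter SD in mm (default 0.3).
#' @param voxel_spacing phantom volume spacing (mm).
#' @param output_dir optional artifact directory (see [run_reliability()]).
#' @param headline_only keep only the headline metrics (absolute-mean /
#'   volumetric / RMS / joint-space change), mirroring the clinical table
#'   layout.
#' @return list with `reliability` (the `reliability_report`), `reports`
#'   (both observers' stacked reports) and `n`.
#' @export
phantom_reliability_study <- function(n = 20L, seed = 1L, jitter_sd = 0.3,
                                      voxel_spacing = 1.0, output_dir = NULL,
                                      headline_only = TRUE) {
  specs <- tmj_phantom_cohort(n = n, seed = seed, voxel_spacing = voxel_spacing)
  rep1 <- list(); rep2 <- list()
  for (i in seq_along(specs)) {
    ph <- make_tmj_phantom(specs[[i]], make_volumes = TRUE)
    vbr <- voxel_register(ph$volumes$post, ph$volumes$pre, ph$volumes$mask)
    for (obs in 1:2) {
      lm <- with_seed(seed * 10000L + i * 10L + obs,
                      jitter_landmarks(ph$pre$landmarks, jitter_sd))
      crv <- with_seed(seed * 20000L + i * 10L + obs,
                       ph$pre$curve + matrix(stats::rnorm(length(ph$pre$curve),
                                                          0, jitter_sd),
                                             nrow(ph$pre$curve), 3))
      a <- assess_tmj(ph$pre$ramus, ph$post$ramus, ph$pre$skull, ph$post$skull,
                      landmarks = lm, curve = crv,
                      seed_point = ph$pre$seed_point, vbr = vbr,
                      subject = sprintf("joint%02d", i))
      if (obs == 1) rep1[[i]] <- a$report else rep2[[i]] <- a$report
    }
  }
  r1 <- do.call(rbind, rep1); r2 <- do.call(rbind, rep2)
  if (headline_only) {
    keep <- c("volumetric_change_pct", "mean_abs_distance_mm",
              "rms_distance_mm", "joint_space_change_mm")
    r1 <- r1[r1$metric %in% keep, ]
    r2 <- r2[r2$metric %in% keep, ]
  }
  rel <- run_reliability(r1, r2, output_dir = output_dir)
  list(reliability = rel, reports = list(obs1 = r1, obs2 = r2), n = n)
}
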