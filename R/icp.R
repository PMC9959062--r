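#' ICP parameter set
#'
#' Parameters for trimmed point-to-plane iterative-closest-point surface
#' registration. Defaults: 200 iterations max, convergence when the trimmed
#' RMS residual changes by less than 1e-5 mm, correspondences farther than
#' 10 mm discarded, worst 10% of correspondences trimmed each iteration.
#'
#' @param max_iter maximum iterations.
#' @param tol convergence tolerance on RMS change (mm).
#' @param cutoff correspondence distance cutoff (mm).
#' @param trim fraction of worst correspondences discarded (0 <= trim < 0.5).
#' @param max_points deterministic subsample size of the moving vertex set.
#' @return an object of class `icp_params`.
#' @export
icp_params <- function(max_iter = 200L, tol = 1e-5, cutoff = 10, trim = 0.1,
                       max_points = 3000L) {
  if (trim < 0 || trim >= 0.5) stop("trim fraction must be in [0, 0.5)")
  if (tol <= 0) stop("tolerance must be positive")
  structure(list(max_iter = as.integer(max_iter), tol = tol, cutoff = cutoff,
                 trim = trim, max_points = as.integer(max_points)),
            class = "icp_params")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("registration_result: RMS %.6f mm after %d iterations (%s)\n",
              x$rms, x$iterations, if (x$converged) "converged" else "not converged"))
  print(x$transform)
  invisible(x)
}

registration_result <- function(transform, rms, iterations, converged, trace = NULL) {
  structure(list(transform = transform, rms = rms, iterations = iterations,
                 converged = converged, trace = trace),
            class = "registration_result")
}

#' Surface-based rigid registration (trimmed point-to-plane ICP)
#'
#' Aligns `moving` onto `fixed` by iterating nearest-surface correspondences
#' and a linearized point-to-plane update. Fully deterministic: the moving
#' vertex set is subsampled on a fixed stride, correspondences use exact
#' nearest-triangle queries, and no randomness enters. The returned transform
#' maps moving-frame points onto the fixed frame. The RMS trace is
#' non-increasing: an update that would worsen the trimmed RMS falls back to a
#' point-to-point (Kabsch) step and, failing that, terminates.
#'
#' @param moving,fixed non-empty `surface_mesh` objects.
#' @param init optional initial `rigid_transform` (default: centroid alignment).
#' @param params an `icp_params`.
#' @return a `registration_result` (fields: transform, rms, iterations,
#'   converged, trace of per-iteration RMS).
#' @export
icp_register <- function(moving, fixed, init = NULL, params = icp_params()) {
  if (n_vertices(moving) == 0 || n_faces(fixed) == 0)
    stop("icp_register: both meshes must be non-empty")
  pts_all <- moving$vertices
  if (nrow(pts_all) > params$max_points) {
    idx <- unique(round(seq(1, nrow(pts_all), length.out = params$max_points)))
    pts <- pts_all[idx, , drop = FALSE]
  } else pts <- pts_all
  if (is.null(init)) {
    init <- rigid_transform(diag(3), colMeans(fixed$vertices) - colMeans(pts))
  }
  fn <- face_normals(fixed)
  Tcur <- init

  eval_res <- function(Tr) {
    p <- transform_points(pts, Tr)
    res <- cpp_closest_points(p, fixed$vertices, fixed$faces)
    sel <- which(res[, 1] <= params$cutoff)
    if (length(sel) < 6)
      stop("insufficient overlap: no correspondences within cutoff")
    keep_n <- max(6L, floor(length(sel) * (1 - params$trim)))
    sel <- sel[order(res[sel, 1])[seq_len(keep_n)]]
    list(p = p[sel, , drop = FALSE], q = res[sel, 2:4, drop = FALSE],
         n = fn[res[sel, 5], , drop = FALSE],
         rms = sqrt(mean(res[sel, 1]^2)))
  }

  cur <- eval_res(Tcur)
  trace <- cur$rms
  converged <- FALSE
  it <- 0L
  while (it < params$max_iter) {
    it <- it + 1L
    # linearized point-to-plane step
    p <- cur$p; q <- cur$q; nn <- cur$n
    cxn <- cbind(p[, 2] * nn[, 3] - p[, 3] * nn[, 2],
                 p[, 3] * nn[, 1] - p[, 1] * nn[, 3],
                 p[, 1] * nn[, 2] - p[, 2] * nn[, 1])
    A <- cbind(cxn, nn)
    b <- -rowSums(nn * (p - q))
    x <- tryCatch(qr.solve(crossprod(A), crossprod(A, b)),
                  error = function(e) rep(0, 6))
    r <- x[1:3]; tr <- x[4:6]
    K <- matrix(c(0, r[3], -r[2], -r[3], 0, r[1], r[2], -r[1], 0), 3, 3)
    dT <- rigid_transform(nearest_rotation(diag(3) + K), tr)
    Tnew <- compose_transform(dT, Tcur)
    nxt <- eval_res(Tnew)
    if (nxt$rms > cur$rms + 1e-12) {
      # fall back to a point-to-point Kabsch step on the same correspondences
      pc <- colMeans(p); qc <- colMeans(q)
      H <- crossprod(sweep(p, 2, pc), sweep(q, 2, qc))
      Rk <- nearest_rotation(t(H))
      dT <- rigid_transform(Rk, qc - as.numeric(Rk %*% pc))
      Tnew <- compose_transform(dT, Tcur)
      nxt <- eval_res(Tnew)
      if (nxt$rms > cur$rms + 1e-12) break
    }
    delta <- cur$rms - nxt$rms
    Tcur <- Tnew
    cur <- nxt
    trace <- c(trace, cur$rms)
    if (abs(delta) < params$tol) { converged <- TRUE; break }
  }
  registration_result(Tcur, cur$rms, it, converged, trace)
}

#' Crop the stable reference region used for ramus alignment
#'
#' Removes the positive half-space of every exclusion plane (the C-plane,
#' excluding the remodeling condylar head, is the mandatory default in the
#' assessment workflow; an osteotomy-exclusion plane may be added). The
#' remainder is the stable reference structure fed to [icp_register()] so that
#' remodeling regions do not bias the alignment.
#'
#' @param ramus a `surface_mesh`.
#' @param excluded_planes list of `plane` objects; the positive side of each is
#'   excluded.
#' @return a `surface_mesh` (open; used as a point/surface set).
#' @export
crop_reference_region <- function(ramus, excluded_planes) {
  if (!length(excluded_planes)) stop("at least one exclusion plane required")
  if (inherits(excluded_planes, "plane")) excluded_planes <- list(excluded_planes)
  n0 <- n_vertices(ramus)
  out <- ramus
  for (p in excluded_planes)
    out <- suppressMessages(clip_by_plane(out, p, keep_side = "negative", cap = FALSE))
  if (n_vertices(out) < 0.05 * n0)
    stop(sprintf("reference-region crop removed %.1f%% of vertices",
                 100 * (1 - n_vertices(out) / n0)))
  out
}
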