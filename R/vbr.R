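#' Voxel-based rigid registration on a masked region
#'
#' Rigid alignment of a moving volume onto a fixed volume by maximizing a
#' masked intensity-similarity metric — normalized cross-correlation
#' (default) or normalized mutual information with partial-volume binning —
#' with a multi-resolution (mean-pooled pyramid) Nelder-Mead descent over the six
#' rigid parameters (rotations in degrees about the mask centroid,
#' translations in mm). The procedure is fully deterministic: every voxel
#' under the mask is used (no stochastic sampling).
#'
#' The returned transform maps moving-frame points onto the fixed frame, i.e.
#' applying it to a mesh segmented from the moving volume aligns that mesh
#' with the fixed volume's anatomy.
#'
#' @param moving,fixed `voxel_volume` objects with comparable value semantics.
#' @param mask binary `voxel_volume` on the fixed grid selecting the stable
#'   region (anterior cranial base, zygomatic arches, forehead in the TMJ
#'   workflow).
#' @param levels pyramid levels (default 3: pooling factors 4, 2, 1).
#' @param metric "ncc" (masked normalized cross-correlation, default) or "nmi".
#' @param bins histogram bins for NMI.
#' @param init optional initial parameter vector (rx, ry, rz deg, tx, ty, tz mm).
#' @param maxit Nelder-Mead iteration cap per level (coarsest gets 3x).
#' @return a `registration_result`; `converged` reflects optimizer status and
#'   diagnostics are kept in `trace` (per-level similarity).
#' @export
voxel_register <- function(moving, fixed, mask, levels = 3L,
                           metric = c("ncc", "nmi"), bins = 32L,
                           init = NULL, maxit = 150L) {
  metric <- match.arg(metric)
  if (!all(dim(mask$data) == dim(fixed$data)))
    stop("mask must be aligned to the fixed grid")
  if (sum(mask$data > 0.5) == 0) stop("voxel_register: empty mask")
  d_mask <- mask$data > 0.5
  cen <- colMeans(voxel_centers(fixed, d_mask))

  rot_from_par <- function(p) {
    rotation_about_axis(c(0, 0, 1), p[3]) %*%
      rotation_about_axis(c(0, 1, 0), p[2]) %*%
      rotation_about_axis(c(1, 0, 0), p[1])
  }
  # A(y) = R (y - cen) + cen + t : fixed-frame point -> moving-frame sample point
  par_to_A <- function(p) {
    R <- rot_from_par(p)
    rigid_transform(R, cen - as.numeric(R %*% cen) + p[4:6])
  }

  mrange <- range(moving$data)
  frange <- range(fixed$data)
  p <- if (is.null(init)) rep(0, 6) else as.numeric(init)
  trace <- list()
  conv <- TRUE
  factors <- 2^((levels:1) - 1)
  for (li in seq_along(factors)) {
    f <- factors[li]
    fx <- if (f > 1) downsample_volume(fixed, f) else fixed
    mv <- if (f > 1) downsample_volume(moving, f) else moving
    mk <- if (f > 1) downsample_volume(mask, f) else mask
    sel <- mk$data > 0.25
    if (sum(sel) < 32) next
    ctr <- voxel_centers(fx, sel)
    fvals <- fx$data[sel]
    dims_m <- dim(mv$data)
    # coarser levels carry fewer samples; shrink the histogram accordingly
    bins_l <- max(8L, as.integer(bins / f))
    cost <- function(pp) {
      A <- par_to_A(pp)
      s <- transform_points(ctr, A)
      idx <- sweep(sweep(s, 2, mv$origin, "-"), 2, mv$spacing, "/")
      vals <- cpp_trilinear(as.numeric(mv$data), as.integer(dims_m), idx)
      ok <- !is.na(vals)
      if (sum(ok) < 0.5 * length(vals)) return(1e6)
      a <- fvals[ok]; b <- vals[ok]
      if (metric == "ncc") {
        if (stats::sd(a) == 0 || stats::sd(b) == 0) return(1e6)
        return(-stats::cor(a, b))
      }
      # normalized mutual information with partial-volume (linear) binning on
      # fixed global ranges, so the cost is continuous in the parameters
      soft_bins <- function(v, rng) {
        u <- (v - rng[1]) / (rng[2] - rng[1]) * bins_l - 0.5
        i0 <- pmin(pmax(floor(u), 0), bins_l - 1)
        w1 <- pmin(pmax(u - i0, 0), 1)
        list(i0 = as.integer(i0), i1 = as.integer(pmin(i0 + 1, bins_l - 1)),
             w0 = 1 - w1, w1 = w1)
      }
      sa <- soft_bins(a, frange); sb <- soft_bins(b, mrange)
      ij <- c(sa$i0 * bins_l + sb$i0, sa$i0 * bins_l + sb$i1,
              sa$i1 * bins_l + sb$i0, sa$i1 * bins_l + sb$i1) + 1L
      wj <- c(sa$w0 * sb$w0, sa$w0 * sb$w1, sa$w1 * sb$w0, sa$w1 * sb$w1)
      jo <- as.numeric(rowsum(wj, ij, reorder = FALSE)) / length(a)
      pa <- as.numeric(rowsum(c(sa$w0, sa$w1), c(sa$i0, sa$i1),
                              reorder = FALSE)) / length(a)
      pb <- as.numeric(rowsum(c(sb$w0, sb$w1), c(sb$i0, sb$i1),
                              reorder = FALSE)) / length(a)
      ha <- -sum(pa[pa > 0] * log(pa[pa > 0]))
      hb <- -sum(pb[pb > 0] * log(pb[pb > 0]))
      hab <- -sum(jo[jo > 0] * log(jo[jo > 0]))
      if (hab <= 0) return(1e6)
      -(ha + hb) / hab
    }
    it <- if (li == 1) 5L * maxit else maxit
    opt <- stats::optim(p, cost, method = "Nelder-Mead",
                        control = list(maxit = it, reltol = 1e-10))
    # converged when the optimizer met its tolerance or the level barely
    # refined the parameters (the pyramid start was already at the optimum)
    conv <- (opt$convergence == 0) || max(abs(opt$par - p)) < 0.05
    p <- opt$par
    trace[[li]] <- c(level = f, value = opt$value, evals = opt$counts[1])
  }
  A <- par_to_A(p)
  res_t <- invert_transform(A)
  registration_result(res_t, rms = NA_real_, iterations = length(factors),
                      converged = conv, trace = trace)
}
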