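#' Anatomical landmark set
#'
#' Named 3D points in mm driving all plane constructions: `porion_right`,
#' `porion_left`, `orbitale` (Frankfurt horizontal), `c_point` (deepest point
#' of the mandibular notch), `lateral_pole`, `medial_pole` (condylar poles) and
#' an optional `anterior_reference` fixing the anterior direction.
#'
#' @param ... named length-3 numeric points, or a single named list of them.
#' @return an object of class `landmark_set` with a `points` matrix (rownames =
#'   landmark names).
#' @export
landmark_set <- function(...) {
  args <- list(...)
  if (length(args) == 1 && is.list(args[[1]]) && is.null(names(args)[1]))
    args <- args[[1]]
  if (is.null(names(args)) || any(names(args) == ""))
    stop("all landmarks must be named")
  pts <- do.call(rbind, lapply(args, function(p) {
    p <- as.numeric(p)
    if (length(p) != 3 || !all(is.finite(p))) stop("each landmark must be a finite 3D point")
    p
  }))
  rownames(pts) <- names(args)
  structure(list(points = pts), class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat("landmark_set:\n")
  for (nm in rownames(x$points))
    cat(sprintf("  %-18s (%8.3f, %8.3f, %8.3f)\n", nm,
                x$points[nm, 1], x$points[nm, 2], x$points[nm, 3]))
  invisible(x)
}

#' Fetch a landmark by name
#' @param lm a `landmark_set`.
#' @param name landmark name.
#' @param required error (TRUE) or return NULL (FALSE) when absent.
#' @return numeric length-3 point.
#' @export
get_landmark <- function(lm, name, required = TRUE) {
  if (!name %in% rownames(lm$points)) {
    if (required) stop(sprintf("required landmark '%s' missing", name))
    return(NULL)
  }
  as.numeric(lm$points[name, ])
}

#' Read / write landmarks as JSON (`{"porion_right": [x,y,z], ...}`, mm)
#' @param path file path.
#' @param lm a `landmark_set`.
#' @return `read_landmarks` returns a `landmark_set`.
#' @export
read_landmarks <- function(path) {
  obj <- jsonlite::fromJSON(path)
  landmark_set(obj)
}

#' @rdname read_landmarks
#' @export
write_landmarks <- function(lm, path) {
  obj <- stats::setNames(
    lapply(seq_len(nrow(lm$points)), function(i) as.numeric(lm$points[i, ])),
    rownames(lm$points))
  jsonlite::write_json(obj, path, digits = NA)
  invisible(path)
}

#' Read / write a traced curve as a JSON array of [x,y,z] points (mm)
#' @param path file path.
#' @param curve n x 3 matrix of points.
#' @return `read_curve` returns an n x 3 matrix.
#' @export
read_curve <- function(path) {
  m <- jsonlite::fromJSON(path)
  m <- as.matrix(m)
  if (ncol(m) != 3) stop("curve file must contain [x,y,z] triples")
  storage.mode(m) <- "double"
  m
}

#' @rdname read_curve
#' @export
write_curve <- function(curve, path) {
  jsonlite::write_json(curve, path, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' Add independent Gaussian jitter to landmarks (observer simulation)
#' @param lm a `landmark_set`.
#' @param sd per-coordinate standard deviation (mm).
#' @return a `landmark_set`.
#' @export
jitter_landmarks <- function(lm, sd = 0.3) {
  lm$points <- lm$points + matrix(stats::rnorm(length(lm$points), 0, sd),
                                  nrow(lm$points), 3)
  lm
}
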