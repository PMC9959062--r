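#' Read a triangle mesh from STL, PLY or OBJ
#'
#' Coordinates are taken to be millimetres (the package-wide unit contract;
#' mesh files carry no unit metadata). STL files (ASCII or binary,
#' auto-detected) are triangle soup, so coincident vertices are welded after
#' reading. PLY reading is ASCII and recovers per-vertex `distance` scalars,
#' `region` labels and RGB colors when present. OBJ reads `v`/`f` records and
#' triangulates polygonal faces by fanning.
#'
#' @param path file path.
#' @param format "stl", "ply" or "obj"; inferred from the extension by default.
#' @return a `surface_mesh`.
#' @export
read_mesh <- function(path, format = NULL) {
  if (!file.exists(path)) stop(sprintf("cannot read mesh: no such file '%s'", path))
  if (file.size(path) == 0) stop(sprintf("cannot read mesh: empty file '%s'", path))
  if (is.null(format))
    format <- tolower(tools::file_ext(path))
  switch(format,
         stl = read_stl(path),
         ply = read_ply(path),
         obj = read_obj(path),
         stop(sprintf("unsupported mesh format '%s'", format)))
}

#' Write a triangle mesh to STL, PLY or OBJ
#'
#' @param mesh a `surface_mesh`.
#' @param path output path.
#' @param format "stl", "ply" or "obj"; inferred from the extension by default.
#' @param binary write binary STL (default TRUE; ignored for PLY/OBJ, which are
#'   written ASCII).
#' @param color optional n x 3 integer matrix (0-255) of per-vertex RGB for PLY.
#' @return the path, invisibly.
#' @export
write_mesh <- function(mesh, path, format = NULL, binary = TRUE, color = NULL) {
  if (is.null(format))
    format <- tolower(tools::file_ext(path))
  switch(format,
         stl = write_stl(mesh, path, binary = binary),
         ply = write_ply(mesh, path, color = color),
         obj = write_obj(mesh, path),
         stop(sprintf("unsupported mesh format '%s'", format)))
  invisible(path)
}

# --- STL -------------------------------------------------------------------

is_binary_stl <- function(path) {
  sz <- file.size(path)
  if (sz < 84) return(FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  invisible(readBin(con, "raw", 80))
  n <- readBin(con, "integer", 1, size = 4, endian = "little")
  !is.na(n) && n >= 0 && sz == 84 + 50 * as.double(n)
}

read_stl <- function(path) {
  if (is_binary_stl(path)) {
    con <- file(path, "rb")
    on.exit(close(con))
    invisible(readBin(con, "raw", 80))
    n <- readBin(con, "integer", 1, size = 4, endian = "little")
    raw <- readBin(con, "raw", 50 * n)
    m <- matrix(raw, nrow = 50)
    tri <- matrix(readBin(as.vector(m[1:48, ]), "numeric", size = 4, n = 12 * n,
                          endian = "little"), nrow = 12)
    vs <- matrix(as.vector(tri[4:12, ]), ncol = 3, byrow = TRUE)
  } else {
    lines <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
    if (length(vl) == 0) stop(sprintf("no vertices found in STL '%s'", path))
    toks <- strsplit(trimws(vl), "\\s+")
    vs <- t(vapply(toks, function(t) as.numeric(t[2:4]), numeric(3)))
  }
  if (nrow(vs) %% 3 != 0) stop("malformed STL: vertex count not a multiple of 3")
  faces <- matrix(seq_len(nrow(vs)), ncol = 3, byrow = TRUE)
  merge_vertices(surface_mesh(vs, faces, clean = TRUE))
}

write_stl <- function(mesh, path, binary = TRUE) {
  v <- mesh$vertices; f <- mesh$faces
  n <- nrow(f)
  fn <- face_normals(mesh)
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.raw(rep(0, 80)), con)
    writeBin(as.integer(n), con, size = 4, endian = "little")
    # 12 floats + attribute count per facet
    block <- rbind(t(fn), t(v[f[, 1], , drop = FALSE]),
                   t(v[f[, 2], , drop = FALSE]), t(v[f[, 3], , drop = FALSE]))
    for (i in seq_len(n)) {
      writeBin(block[, i], con, size = 4, endian = "little")
      writeBin(as.raw(c(0, 0)), con)
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid mesh", con)
    for (i in seq_len(n)) {
      writeLines(sprintf("  facet normal %.9g %.9g %.9g", fn[i, 1], fn[i, 2], fn[i, 3]), con)
      writeLines("    outer loop", con)
      for (c in 1:3) {
        p <- v[f[i, c], ]
        writeLines(sprintf("      vertex %.9g %.9g %.9g", p[1], p[2], p[3]), con)
      }
      writeLines("    endloop", con)
      writeLines("  endfacet", con)
    }
    writeLines("endsolid mesh", con)
  }
  invisible(path)
}

# --- PLY (ASCII) -----------------------------------------------------------

read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || lines[1] != "ply") stop("not a PLY file")
  endh <- which(lines == "end_header")[1]
  if (is.na(endh)) stop("malformed PLY: no end_header")
  header <- lines[1:endh]
  if (!any(grepl("^format ascii", header)))
    stop("only ASCII PLY supported")
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex ", header, value = TRUE)[1]))
  nf <- as.integer(sub("element face ", "", grep("^element face ", header, value = TRUE)[1]))
  if (is.na(nf)) nf <- 0L
  # vertex property names in declaration order
  vstart <- grep("^element vertex ", header)[1]
  vend <- grep("^element ", header)
  vend <- c(vend[vend > vstart], endh)[1]
  props <- header[(vstart + 1):(vend - 1)]
  props <- grep("^property ", props, value = TRUE)
  pnames <- vapply(strsplit(props, "\\s+"), function(t) t[length(t)], character(1))
  body <- lines[(endh + 1):length(lines)]
  vdat <- utils::read.table(text = body[seq_len(nv)], col.names = pnames)
  verts <- as.matrix(vdat[, c("x", "y", "z")])
  scal <- if ("distance" %in% pnames) vdat$distance else NULL
  labs <- if ("region" %in% pnames) vdat$region else NULL
  faces <- NULL
  if (nf > 0) {
    ftoks <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
    faces <- t(vapply(ftoks, function(t) as.integer(t[2:4]) + 1L, integer(3)))
  } else faces <- matrix(integer(0), 0, 3)
  m <- surface_mesh(verts, faces, scalars = scal, clean = FALSE)
  if (!is.null(labs)) m$labels <- region_levels()[labs + 1L]
  m
}

write_ply <- function(mesh, path, color = NULL) {
  v <- mesh$vertices; f <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  has_s <- !is.null(mesh$scalars)
  has_l <- !is.null(mesh$labels)
  has_c <- !is.null(color)
  hdr <- c("ply", "format ascii 1.0",
           sprintf("element vertex %d", nrow(v)),
           "property double x", "property double y", "property double z")
  if (has_s) hdr <- c(hdr, "property double distance")
  if (has_l) hdr <- c(hdr, "property int region")
  if (has_c) hdr <- c(hdr, "property uchar red", "property uchar green", "property uchar blue")
  hdr <- c(hdr, sprintf("element face %d", nrow(f)),
           "property list uchar int vertex_indices", "end_header")
  writeLines(hdr, con)
  cols <- list(sprintf("%.12g", v[, 1]), sprintf("%.12g", v[, 2]), sprintf("%.12g", v[, 3]))
  if (has_s) cols <- c(cols, list(sprintf("%.12g", mesh$scalars)))
  if (has_l) {
    lab_idx <- match(as.character(mesh$labels), region_levels()) - 1L
    lab_idx[is.na(lab_idx)] <- -1L
    cols <- c(cols, list(sprintf("%d", lab_idx)))
  }
  if (has_c) cols <- c(cols, list(sprintf("%d", color[, 1]), sprintf("%d", color[, 2]),
                                  sprintf("%d", color[, 3])))
  writeLines(do.call(paste, cols), con)
  writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  invisible(path)
}

# --- OBJ -------------------------------------------------------------------

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^v\\s", lines, value = TRUE)
  fl <- grep("^f\\s", lines, value = TRUE)
  if (length(vl) == 0) stop(sprintf("no vertices found in OBJ '%s'", path))
  verts <- t(vapply(strsplit(trimws(vl), "\\s+"),
                    function(t) as.numeric(t[2:4]), numeric(3)))
  faces <- list()
  for (ln in fl) {
    toks <- strsplit(trimws(ln), "\\s+")[[1]][-1]
    idx <- as.integer(vapply(strsplit(toks, "/"), `[`, character(1), 1))
    # fan-triangulate polygons
    if (length(idx) >= 3)
      for (k in 2:(length(idx) - 1))
        faces[[length(faces) + 1]] <- c(idx[1], idx[k], idx[k + 1])
  }
  faces <- if (length(faces)) do.call(rbind, faces) else matrix(integer(0), 0, 3)
  surface_mesh(verts, faces, clean = TRUE)
}

write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  v <- mesh$vertices; f <- mesh$faces
  writeLines(sprintf("v %.12g %.12g %.12g", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3]), con)
  invisible(path)
}

#' Canonical sub-region label set
#'
#' The four condylar/fossa sub-regions in fixed order, shared by every labeled
#' structure so that condyle and fossa regions correspond.
#' @return character vector of the four region names.
#' @export
region_levels <- function() {
  c("anterior-lateral", "anterior-medial", "posterior-lateral", "posterior-medial")
}
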