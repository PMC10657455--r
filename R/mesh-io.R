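#' @include AllClasses.R
NULL

#' Read a triangle mesh from STL, PLY or OBJ
#'
#' The format is inferred from the file extension. Coordinates are assumed to
#' be in nanometres; meshes exported in other units (voxels, micrometres,
#' depending on the segmentation tool) can be rescaled on load with
#' \code{unitScale}. STL files (triangle soup) have coincident vertices
#' welded; binary and ASCII STL are auto-detected.
#'
#' @param path file path ending in \code{.stl}, \code{.ply} or \code{.obj}.
#' @param unitScale multiplicative factor applied to coordinates on load
#'   (default 1; e.g. 1000 for a mesh stored in micrometres).
#' @param name organelle label; defaults to the file base name.
#' @return A [TriMesh-class].
#' @export
readMesh <- function(path, unitScale = 1, name = NULL) {
  if (!file.exists(path)) stop("cannot read mesh file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (is.null(name)) name <- tools::file_path_sans_ext(basename(path))
  mesh <- switch(ext,
    stl = .readSTL(path),
    ply = .readPLY(path),
    obj = .readOBJ(path),
    stop("unsupported mesh format: .", ext, " (expected .stl, .ply or .obj)")
  )
  if (nrow(mesh$vertices) == 0L || nrow(mesh$faces) == 0L)
    stop("empty mesh in ", path)
  TriMesh(mesh$vertices * unitScale, mesh$faces, name = name)
}

#' Write a triangle mesh to STL, PLY or OBJ
#'
#' @param mesh a [TriMesh-class].
#' @param path output path; the extension selects the format. STL and PLY are
#'   written in ASCII.
#' @param faceScalar optional numeric vector (one per face) written as an
#'   extra \code{quality} property (PLY only), e.g. a proximity flag.
#' @param vertexScalar optional numeric vector (one per vertex) written as an
#'   extra \code{quality} property (PLY only), e.g. mean curvature.
#' @return the path, invisibly.
#' @export
writeMesh <- function(mesh, path, faceScalar = NULL, vertexScalar = NULL) {
  stopifnot(is(mesh, "TriMesh"))
  validObject(mesh)
  if (nrow(mesh@vertices) == 0L || nrow(mesh@faces) == 0L)
    stop("refusing to write an empty mesh")
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    stl = .writeSTL(mesh, path),
    ply = .writePLY(mesh, path, faceScalar, vertexScalar),
    obj = .writeOBJ(mesh, path),
    stop("unsupported mesh format: .", ext)
  )
  invisible(path)
}

# --- STL ---------------------------------------------------------------------

.isBinarySTL <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  head <- readBin(con, "raw", 512L)
  txt <- rawToChar(head[head != as.raw(0)][seq_len(min(80, sum(head != 0)))])
  if (!grepl("^\\s*solid", txt)) return(TRUE)
  # some binary files start with "solid" too; check size consistency
  if (length(head) >= 84) {
    n <- readBin(head[81:84], "integer", 1L, size = 4L, endian = "little")
    expect <- 84 + as.numeric(n) * 50
    if (!is.na(n) && n >= 0 && file.size(path) == expect) return(TRUE)
  }
  FALSE
}

.weldVertices <- function(vraw, faces) {
  key <- apply(vraw, 1L, paste, collapse = "\r")
  idx <- match(key, unique(key))
  keep <- !duplicated(idx)
  v <- vraw[keep, , drop = FALSE]
  f <- matrix(idx[faces], ncol = 3L)
  list(vertices = v, faces = f)
}

.readSTL <- function(path) {
  if (.isBinarySTL(path)) {
    con <- file(path, "rb")
    on.exit(close(con))
    readBin(con, "raw", 80L)
    n <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (is.na(n) || n <= 0) stop("empty binary STL")
    blob <- readBin(con, "raw", n * 50L)  # 12 float32 + uint16 attr per facet
    m <- matrix(blob, nrow = 50L)
    tri <- vapply(seq_len(n), function(i)
      readBin(m[1:48, i], "numeric", 12L, size = 4L, endian = "little"),
      numeric(12L))
    tri <- t(tri)  # n x 12: normal, v1, v2, v3
    vraw <- rbind(tri[, 4:6, drop = FALSE], tri[, 7:9, drop = FALSE],
                  tri[, 10:12, drop = FALSE])
    ord <- as.vector(t(cbind(seq_len(n), n + seq_len(n), 2L * n + seq_len(n))))
    vraw <- vraw[ord, , drop = FALSE]
  } else {
    lines <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
    if (!length(vl)) stop("no vertices found in ASCII STL")
    nums <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(x)
      as.numeric(x[2:4])))
    vraw <- nums
  }
  nf <- nrow(vraw) / 3L
  if (nf != floor(nf)) stop("malformed STL: vertex count not a multiple of 3")
  faces <- matrix(seq_len(nrow(vraw)), ncol = 3L, byrow = TRUE)
  .weldVertices(vraw, faces)
}

.writeSTL <- function(mesh, path) {
  v <- mesh@vertices; f <- mesh@faces
  n <- faceNormals(mesh)
  con <- file(path, "w")
  on.exit(close(con))
  nm <- if (nzchar(mesh@name)) mesh@name else "mesh"
  writeLines(paste("solid", nm), con)
  fmt <- paste0(
    "facet normal %.9g %.9g %.9g\n outer loop\n",
    "  vertex %.9g %.9g %.9g\n  vertex %.9g %.9g %.9g\n  vertex %.9g %.9g %.9g\n",
    " endloop\nendfacet")
  body <- sprintf(fmt, n[, 1], n[, 2], n[, 3],
                  v[f[, 1], 1], v[f[, 1], 2], v[f[, 1], 3],
                  v[f[, 2], 1], v[f[, 2], 2], v[f[, 2], 3],
                  v[f[, 3], 1], v[f[, 3], 2], v[f[, 3], 3])
  writeLines(body, con)
  writeLines(paste("endsolid", nm), con)
}

# --- PLY (ASCII) -------------------------------------------------------------

.readPLY <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || trimws(lines[1]) != "ply") stop("not a PLY file")
  endHdr <- match("end_header", trimws(lines))
  if (is.na(endHdr)) stop("malformed PLY: no end_header")
  hdr <- trimws(lines[seq_len(endHdr)])
  if (any(grepl("^format\\s+binary", hdr)))
    stop("binary PLY is not supported; export as ASCII PLY")
  els <- grep("^element\\s", hdr)
  counts <- list()
  props <- list()
  for (i in seq_along(els)) {
    tok <- strsplit(hdr[els[i]], "\\s+")[[1]]
    nxt <- if (i < length(els)) els[i + 1] - 1L else endHdr - 1L
    counts[[tok[2]]] <- as.integer(tok[3])
    pl <- hdr[(els[i] + 1L):nxt]
    props[[tok[2]]] <- pl[grepl("^property\\s", pl)]
  }
  if (is.null(counts$vertex) || is.null(counts$face))
    stop("PLY must declare vertex and face elements")
  body <- lines[(endHdr + 1L):length(lines)]
  body <- body[nzchar(trimws(body))]
  nV <- counts$vertex; nF <- counts$face
  vlines <- strsplit(trimws(body[seq_len(nV)]), "\\s+")
  pnames <- vapply(strsplit(props$vertex, "\\s+"), function(x) x[length(x)], "")
  xyz <- match(c("x", "y", "z"), pnames)
  if (anyNA(xyz)) stop("PLY vertex element lacks x/y/z properties")
  v <- t(vapply(vlines, function(x) as.numeric(x[xyz]), numeric(3L)))
  flines <- strsplit(trimws(body[nV + seq_len(nF)]), "\\s+")
  f <- t(vapply(flines, function(x) {
    k <- as.integer(x[1])
    if (k != 3L) stop("only triangular PLY faces are supported")
    as.integer(x[2:4]) + 1L
  }, integer(3L)))
  list(vertices = v, faces = f)
}

.writePLY <- function(mesh, path, faceScalar = NULL, vertexScalar = NULL) {
  v <- mesh@vertices; f <- mesh@faces
  if (!is.null(faceScalar) && length(faceScalar) != nrow(f))
    stop("faceScalar must have one value per face")
  if (!is.null(vertexScalar) && length(vertexScalar) != nrow(v))
    stop("vertexScalar must have one value per vertex")
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- c("ply", "format ascii 1.0",
           paste("comment", if (nzchar(mesh@name)) mesh@name else "mesh"),
           paste("element vertex", nrow(v)),
           "property double x", "property double y", "property double z",
           if (!is.null(vertexScalar)) "property double quality",
           paste("element face", nrow(f)),
           "property list uchar int vertex_indices",
           if (!is.null(faceScalar)) "property double quality",
           "end_header")
  writeLines(hdr, con)
  if (is.null(vertexScalar)) {
    writeLines(sprintf("%.10g %.10g %.10g", v[, 1], v[, 2], v[, 3]), con)
  } else {
    writeLines(sprintf("%.10g %.10g %.10g %.10g", v[, 1], v[, 2], v[, 3],
                       vertexScalar), con)
  }
  if (is.null(faceScalar)) {
    writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  } else {
    writeLines(sprintf("3 %d %d %d %.10g", f[, 1] - 1L, f[, 2] - 1L,
                       f[, 3] - 1L, faceScalar), con)
  }
}

# --- OBJ ---------------------------------------------------------------------

.readOBJ <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^v\\s", lines, value = TRUE)
  fl <- grep("^f\\s", lines, value = TRUE)
  v <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(x)
    as.numeric(x[2:4])))
  f <- do.call(rbind, lapply(strsplit(trimws(fl), "\\s+"), function(x) {
    idx <- as.integer(sub("/.*$", "", x[-1]))
    if (length(idx) != 3L) stop("only triangular OBJ faces are supported")
    idx
  }))
  list(vertices = v, faces = f)
}

.writeOBJ <- function(mesh, path) {
  v <- mesh@vertices; f <- mesh@faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("o", if (nzchar(mesh@name)) mesh@name else "mesh"), con)
  writeLines(sprintf("v %.10g %.10g %.10g", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3]), con)
}
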