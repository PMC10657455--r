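#' @include AllGenerics.R
NULL

.crossProd <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Per-face triangle areas
#' @param mesh a [TriMesh-class].
#' @return numeric vector of face areas in nm^2.
#' @export
faceAreas <- function(mesh) {
  v <- mesh@vertices; f <- mesh@faces
  if (nrow(f) == 0L) return(numeric())
  a <- v[f[, 1], , drop = FALSE]
  ab <- v[f[, 2], , drop = FALSE] - a
  ac <- v[f[, 3], , drop = FALSE] - a
  cr <- .crossProd(ab, ac)
  0.5 * sqrt(rowSums(cr^2))
}

#' Per-face unit normals (outward for an outward-oriented mesh)
#' @param mesh a [TriMesh-class].
#' @return numeric matrix, faces x 3.
#' @export
faceNormals <- function(mesh) {
  v <- mesh@vertices; f <- mesh@faces
  a <- v[f[, 1], , drop = FALSE]
  cr <- .crossProd(v[f[, 2], , drop = FALSE] - a, v[f[, 3], , drop = FALSE] - a)
  n <- sqrt(rowSums(cr^2))
  n[n == 0] <- 1
  cr / n
}

.checkNonEmpty <- function(mesh) {
  if (nrow(mesh@vertices) == 0L || nrow(mesh@faces) == 0L)
    stop("mesh is empty")
  invisible(TRUE)
}

#' @rdname surfaceArea
#' @export
setMethod("surfaceArea", "TriMesh", function(x, units = c("nm2", "um2"), ...) {
  .checkNonEmpty(x)
  units <- match.arg(units)
  a <- sum(faceAreas(x))
  if (units == "um2") a / 1e6 else a
})

#' @rdname enclosedVolume
#' @export
setMethod("enclosedVolume", "TriMesh", function(x, units = c("nm3", "um3"),
                                                force = FALSE,
                                                fixOrientation = FALSE, ...) {
  .checkNonEmpty(x)
  units <- match.arg(units)
  if (!force) {
    rep <- validateMesh(x)
    if (!rep@watertight)
      stop("mesh is not watertight (", .watertightDefect(x),
           "); signed-tetrahedron volume undefined. Use force = TRUE for an ",
           "approximate value.")
    if (!rep@oriented)
      stop("mesh faces are not consistently oriented; fix winding before ",
           "computing the enclosed volume")
  }
  v <- x@vertices; f <- x@faces
  ref <- colMeans(v)  # interior-ish reference for numerical stability
  a <- sweep(v[f[, 1], , drop = FALSE], 2L, ref)
  b <- sweep(v[f[, 2], , drop = FALSE], 2L, ref)
  cc <- sweep(v[f[, 3], , drop = FALSE], 2L, ref)
  vol <- sum(rowSums(a * .crossProd(b, cc))) / 6
  if (vol < 0) {
    if (fixOrientation) {
      warning("mesh appears inward-oriented; returning |signed volume|")
      vol <- -vol
    } else if (!force) {
      stop("signed volume is negative: mesh orientation is inward. ",
           "Set fixOrientation = TRUE to sign-correct.")
    }
  }
  if (units == "um3") vol / 1e9 else vol
})

# one-line description of why a mesh fails the watertight test
.watertightDefect <- function(mesh) {
  ec <- .edgeCounts(mesh)
  nb <- sum(ec$count == 1L)
  nm <- sum(ec$count > 2L)
  paste0(nb, " boundary edge(s), ", nm, " non-manifold edge(s)")
}

#' Rigid / affine helpers for meshes
#'
#' @param mesh a [TriMesh-class].
#' @param offset numeric 3-vector (nm).
#' @return transformed [TriMesh-class].
#' @export
translateMesh <- function(mesh, offset) {
  mesh@vertices <- sweep(mesh@vertices, 2L, as.numeric(offset), "+")
  mesh
}

#' @rdname translateMesh
#' @param s scalar scale factor.
#' @export
scaleMesh <- function(mesh, s) {
  mesh@vertices <- mesh@vertices * s
  mesh
}

#' @rdname translateMesh
#' @param R 3 x 3 rotation matrix.
#' @export
rotateMesh <- function(mesh, R) {
  mesh@vertices <- mesh@vertices %*% t(R)
  mesh
}
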