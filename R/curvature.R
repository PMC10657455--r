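#' @include AllClasses.R
NULL

# angle-weighted vertex normals (outward for an outward-oriented mesh)
.vertexNormals <- function(mesh) {
  v <- mesh@vertices; f <- mesh@faces
  nv <- nrow(v)
  fn <- faceNormals(mesh)
  n <- matrix(0, nv, 3L)
  for (corner in 1:3) {
    idx <- f[, corner]
    prev <- f[, c(3, 1, 2)[corner]]
    nxt <- f[, c(2, 3, 1)[corner]]
    e1 <- v[nxt, , drop = FALSE] - v[idx, , drop = FALSE]
    e2 <- v[prev, , drop = FALSE] - v[idx, , drop = FALSE]
    cosang <- rowSums(e1 * e2) /
      pmax(sqrt(rowSums(e1^2) * rowSums(e2^2)), .Machine$double.eps)
    ang <- acos(pmin(pmax(cosang, -1), 1))
    s <- rowsum(fn * ang, idx)
    rid <- as.integer(rownames(s))
    n[rid, ] <- n[rid, ] + s
  }
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

#' Discrete mean curvature per vertex
#'
#' Cotangent Laplace-Beltrami estimate with Meyer mixed-Voronoi vertex
#' areas. The sign convention makes convex regions of an outward-oriented
#' closed surface positive: a sphere of radius \eqn{r} gives \eqn{+1/r}
#' everywhere.
#'
#' @param mesh a watertight, outward-oriented [TriMesh-class].
#' @return numeric vector of mean curvature, 1/nm, one entry per vertex.
#' @examples
#' range(vertexMeanCurvature(makeIcosphere(10, 4))) * 10  # ~1
#' @export
vertexMeanCurvature <- function(mesh) {
  .checkNonEmpty(mesh)
  v <- mesh@vertices; f <- mesh@faces
  nv <- nrow(v); nf <- nrow(f)
  areas <- faceAreas(mesh)
  if (any(areas <= 0)) stop("degenerate faces present; validate the mesh first")

  i1 <- f[, 1]; i2 <- f[, 2]; i3 <- f[, 3]
  p1 <- v[i1, , drop = FALSE]; p2 <- v[i2, , drop = FALSE]; p3 <- v[i3, , drop = FALSE]
  # cotangent of the angle at each corner: cot = dot / (2 * area)
  cot1 <- rowSums((p2 - p1) * (p3 - p1)) / (2 * areas)
  cot2 <- rowSums((p1 - p2) * (p3 - p2)) / (2 * areas)
  cot3 <- rowSums((p1 - p3) * (p2 - p3)) / (2 * areas)

  # cotangent Laplacian: L x at vertex i = sum_j (cot a + cot b)(x_j - x_i)
  ii <- c(i1, i2, i2, i3, i3, i1)
  jj <- c(i2, i1, i3, i2, i1, i3)
  ww <- c(cot3, cot3, cot1, cot1, cot2, cot2)
  W <- Matrix::sparseMatrix(i = ii, j = jj, x = ww, dims = c(nv, nv))
  wsum <- Matrix::rowSums(W)
  Lx <- as.matrix(W %*% v) - wsum * v

  # Meyer mixed Voronoi areas
  Amix <- numeric(nv)
  obtuse1 <- cot1 < 0; obtuse2 <- cot2 < 0; obtuse3 <- cot3 < 0
  anyObt <- obtuse1 | obtuse2 | obtuse3
  l12 <- rowSums((p2 - p1)^2); l23 <- rowSums((p3 - p2)^2); l31 <- rowSums((p1 - p3)^2)
  # non-obtuse: Voronoi corner areas
  vor1 <- (l12 * cot3 + l31 * cot2) / 8
  vor2 <- (l12 * cot3 + l23 * cot1) / 8
  vor3 <- (l31 * cot2 + l23 * cot1) / 8
  a1 <- ifelse(anyObt, ifelse(obtuse1, areas / 2, areas / 4), vor1)
  a2 <- ifelse(anyObt, ifelse(obtuse2, areas / 2, areas / 4), vor2)
  a3 <- ifelse(anyObt, ifelse(obtuse3, areas / 2, areas / 4), vor3)
  add <- function(acc, idx, val) {
    s <- rowsum(val, idx)
    acc[as.integer(rownames(s))] <- acc[as.integer(rownames(s))] + s[, 1]
    acc
  }
  Amix <- add(Amix, i1, a1)
  Amix <- add(Amix, i2, a2)
  Amix <- add(Amix, i3, a3)
  if (any(Amix <= 0)) stop("vertex with non-positive mixed area (isolated vertex?)")

  K <- -Lx / (2 * Amix)         # mean curvature normal (outward where convex)
  H <- sqrt(rowSums(K^2)) / 2   # |K| = 2H
  n <- .vertexNormals(mesh)
  s <- sign(rowSums(K * n))
  s[s == 0] <- 1
  H * s
}
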