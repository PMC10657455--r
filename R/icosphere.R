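#' @include AllClasses.R
NULL

# Unit icosahedron (circumradius 1), consistently outward-oriented.
.icosahedron <- function() {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  t, 0), c(1,  t, 0), c(-1, -t, 0), c(1, -t, 0),
    c(0, -1,  t), c(0, 1,  t), c(0, -1, -t), c(0, 1, -t),
    c( t, 0, -1), c(t, 0,  1), c(-t, 0, -1), c(-t, 0,  1)
  )
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  list(vertices = v, faces = f)
}

# One 4-to-1 subdivision step with midpoints projected to the unit sphere.
# Fully vectorised (edge deduplication via match on composite keys) so deep
# subdivision levels stay fast in R.
.subdivideSphere <- function(v, f) {
  nv <- nrow(v)
  e1 <- cbind(f[, 1], f[, 2])
  e2 <- cbind(f[, 2], f[, 3])
  e3 <- cbind(f[, 3], f[, 1])
  edges <- rbind(e1, e2, e3)
  key <- pmin(edges[, 1], edges[, 2]) * (nv + 1) + pmax(edges[, 1], edges[, 2])
  ukey <- unique(key)
  idx <- match(key, ukey)
  first <- match(ukey, key)
  mid <- (v[edges[first, 1], , drop = FALSE] + v[edges[first, 2], , drop = FALSE]) / 2
  mid <- mid / sqrt(rowSums(mid^2))
  m <- nv + idx  # midpoint vertex index per (face, edge)
  nf <- nrow(f)
  mab <- m[seq_len(nf)]
  mbc <- m[nf + seq_len(nf)]
  mca <- m[2L * nf + seq_len(nf)]
  fnew <- rbind(
    cbind(f[, 1], mab, mca),
    cbind(f[, 2], mbc, mab),
    cbind(f[, 3], mca, mbc),
    cbind(mab, mbc, mca)
  )
  list(vertices = rbind(v, mid), faces = fnew)
}

#' Geodesic icosphere mesh
#'
#' Builds a watertight, consistently outward-oriented icosphere by repeated
#' 4-to-1 subdivision of an icosahedron with projection to the sphere.
#' Subdivision level \eqn{s} gives \eqn{20 \cdot 4^s} faces.
#'
#' @param radius sphere radius in nm.
#' @param subdivisions integer in \code{0:9}.
#' @param center optional 3-vector, sphere centre in nm.
#' @param name organelle label for the resulting mesh.
#' @return A [TriMesh-class].
#' @examples
#' s <- makeIcosphere(1, 4)
#' surfaceArea(s) / (4 * pi)     # ~1 (within 0.5%)
#' enclosedVolume(s) / (4 * pi / 3)
#' @export
makeIcosphere <- function(radius, subdivisions = 3L, center = c(0, 0, 0),
                          name = "") {
  stopifnot(is.numeric(radius), length(radius) == 1L, radius > 0)
  subdivisions <- as.integer(subdivisions)
  if (subdivisions < 0L || subdivisions > 9L)
    stop("subdivisions must be in 0..9")
  m <- .icosahedron()
  s <- subdivisions
  while (s > 0L) {
    m <- .subdivideSphere(m$vertices, m$faces)
    s <- s - 1L
  }
  v <- m$vertices * radius
  v <- sweep(v, 2L, as.numeric(center), "+")
  TriMesh(v, m$faces, name = name)
}

#' Sphere-or-ellipsoid mesh by anisotropic scaling of an icosphere
#'
#' @param semiAxes numeric 3-vector of semi-axis lengths (nm).
#' @param subdivisions icosphere subdivision level.
#' @param center centre in nm.
#' @param axes optional 3 x 3 rotation matrix whose columns are the ellipsoid
#'   axes directions.
#' @param name organelle label.
#' @return A [TriMesh-class].
#' @export
makeEllipsoid <- function(semiAxes, subdivisions = 3L, center = c(0, 0, 0),
                          axes = diag(3), name = "") {
  stopifnot(length(semiAxes) == 3L, all(semiAxes > 0))
  s <- makeIcosphere(1, subdivisions)
  v <- sweep(s@vertices, 2L, as.numeric(semiAxes), "*") %*% t(axes)
  v <- sweep(v, 2L, as.numeric(center), "+")
  TriMesh(v, s@faces, name = name)
}
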