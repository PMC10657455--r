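#' @include AllClasses.R
NULL

#' Minimum distance from each source vertex to a target surface
#'
#' For every vertex of \code{source}, the exact minimum point-to-triangle
#' distance over all faces of \code{target}, computed with an axis-aligned
#' bounding-box tree over the target triangles. Distances are unsigned;
#' overlapping surfaces yield zeros.
#'
#' @param source,target [TriMesh-class] objects in the same (nm) frame.
#' @return numeric vector, nm, one entry per source vertex.
#' @seealso [bruteForceDistances()] for the exhaustive reference used in
#'   tests, [proximityMap()] for thresholded area fractions.
#' @export
vertexToSurfaceDistances <- function(source, target) {
  .checkNonEmpty(source); .checkNonEmpty(target)
  cpp_surface_distances(source@vertices, target@vertices, target@faces)
}

# closed-form point-to-triangle distances for one point against all faces,
# via barycentric region classification (vectorised over faces)
.pointTriDistOne <- function(p, A, B, C) {
  ab <- B - A; ac <- C - A
  ap <- sweep(-A, 2L, p, "+")
  d1 <- rowSums(ab * ap); d2 <- rowSums(ac * ap)
  bp <- sweep(-B, 2L, p, "+")
  d3 <- rowSums(ab * bp); d4 <- rowSums(ac * bp)
  cp <- sweep(-C, 2L, p, "+")
  d5 <- rowSums(ab * cp); d6 <- rowSums(ac * cp)
  vc <- d1 * d4 - d3 * d2
  vb <- d5 * d2 - d1 * d6
  va <- d3 * d6 - d5 * d4
  n <- nrow(A)
  Q <- matrix(NA_real_, n, 3L)
  done <- rep(FALSE, n)
  setQ <- function(idx, pts) {
    Q[idx, ] <<- pts
    done[idx] <<- TRUE
  }
  r <- !done & d1 <= 0 & d2 <= 0
  if (any(r)) setQ(r, A[r, , drop = FALSE])
  r <- !done & d3 >= 0 & d4 <= d3
  if (any(r)) setQ(r, B[r, , drop = FALSE])
  r <- !done & vc <= 0 & d1 >= 0 & d3 <= 0
  if (any(r)) {
    t <- d1[r] / (d1[r] - d3[r])
    setQ(r, A[r, , drop = FALSE] + ab[r, , drop = FALSE] * t)
  }
  r <- !done & d6 >= 0 & d5 <= d6
  if (any(r)) setQ(r, C[r, , drop = FALSE])
  r <- !done & vb <= 0 & d2 >= 0 & d6 <= 0
  if (any(r)) {
    t <- d2[r] / (d2[r] - d6[r])
    setQ(r, A[r, , drop = FALSE] + ac[r, , drop = FALSE] * t)
  }
  r <- !done & va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0
  if (any(r)) {
    t <- (d4[r] - d3[r]) / ((d4[r] - d3[r]) + (d5[r] - d6[r]))
    setQ(r, B[r, , drop = FALSE] + (C[r, , drop = FALSE] - B[r, , drop = FALSE]) * t)
  }
  r <- !done
  if (any(r)) {
    denom <- 1 / (va[r] + vb[r] + vc[r])
    v <- vb[r] * denom; w <- vc[r] * denom
    setQ(r, A[r, , drop = FALSE] + ab[r, , drop = FALSE] * v +
           ac[r, , drop = FALSE] * w)
  }
  dif <- sweep(-Q, 2L, p, "+")
  min(sqrt(rowSums(dif^2)))
}

#' Exhaustive point-to-triangle distances (test oracle)
#'
#' Same quantity as [vertexToSurfaceDistances()], computed without any
#' acceleration structure. Intended for validation on small meshes; guarded
#' against accidental use on large inputs.
#'
#' @param source,target [TriMesh-class] objects.
#' @param force lift the \code{nV * nF <= 1e7} size guard.
#' @return numeric vector, nm, one entry per source vertex.
#' @export
bruteForceDistances <- function(source, target, force = FALSE) {
  .checkNonEmpty(source); .checkNonEmpty(target)
  nV <- nrow(source@vertices); nF <- nrow(target@faces)
  if (!force && as.numeric(nV) * nF > 1e7)
    stop("brute-force distance size guard exceeded (", nV, " x ", nF,
         "); use vertexToSurfaceDistances() or force = TRUE")
  tv <- target@vertices; tf <- target@faces
  A <- tv[tf[, 1], , drop = FALSE]
  B <- tv[tf[, 2], , drop = FALSE]
  C <- tv[tf[, 3], , drop = FALSE]
  apply(source@vertices, 1L, .pointTriDistOne, A = A, B = B, C = C)
}

#' Thresholded proximity-area mapping between two organelle surfaces
#'
#' Computes per-vertex minimum distances from \code{source} to
#' \code{target}, flags a source face as proximal at threshold \eqn{t} when
#' the minimum of its three vertex distances is \eqn{\le t} (inclusive), and
#' reports the fraction of total source surface area that is proximal at each
#' threshold. The result is asymmetric in (source, target) by construction:
#' the chloroplast-to-mitochondria fraction differs from the
#' mitochondria-to-chloroplast fraction because the two surfaces differ.
#'
#' Default thresholds are 100 nm (organelle vicinity) and 24 nm (putative
#' membrane contact sites). Fractions are inclusive (the 24 nm set is a
#' subset of the 100 nm set); the exclusive band fractions are reported
#' alongside.
#'
#' @param source,target [TriMesh-class] objects.
#' @param thresholds positive distances in nm; sorted decreasing internally.
#' @return A [ProximityResult-class].
#' @examples
#' sc <- makeTwoSphereScene(1, 1, 3, subdivisions = 3)
#' pr <- proximityMap(sceneMeshes(sc)$A, sceneMeshes(sc)$B, thresholds = 1.2)
#' areaFractions(pr)  # ~0.07, the spherical-cap fraction
#' @export
proximityMap <- function(source, target, thresholds = c(100, 24)) {
  .checkNonEmpty(source); .checkNonEmpty(target)
  if (length(thresholds) == 0L) stop("at least one threshold is required")
  if (any(thresholds <= 0)) stop("thresholds must be positive")
  thresholds <- sort(unique(as.numeric(thresholds)), decreasing = TRUE)
  d <- vertexToSurfaceDistances(source, target)
  # unsigned distances carry no interior-negative convention: source vertices
  # lying inside the target volume are in contact and clamp to zero
  inside <- cpp_points_in_mesh(source@vertices, target@vertices, target@faces)
  if (any(inside)) {
    warning(sum(inside), " source vertex/vertices inside the target mesh: ",
            "surfaces overlap; contact distances clamped to 0")
    d[inside] <- 0
  }
  f <- source@faces
  faceMin <- pmin(d[f[, 1]], d[f[, 2]], d[f[, 3]])
  areas <- faceAreas(source)
  total <- sum(areas)
  flags <- vapply(thresholds, function(t) faceMin <= t,
                  logical(nrow(f)))
  flags <- matrix(flags, nrow = nrow(f))
  fr <- colSums(areas * flags) / total
  excl <- if (length(fr) > 1L) c(fr[-length(fr)] - fr[-1L], fr[length(fr)]) else fr
  new("ProximityResult",
      source = source@name, target = target@name,
      vertexDistances = d, thresholds = thresholds,
      faceFlags = flags, areaFractions = as.numeric(fr),
      exclusiveFractions = as.numeric(excl),
      minDistance = min(d), maxDistance = max(d))
}

#' Distance extrema between two organelle surfaces
#'
#' Minimum and maximum over the per-vertex minimum distances of
#' \code{source} to \code{target} (e.g. the mitochondria-to-starch distance
#' range of a cyst reconstruction).
#'
#' @param source,target [TriMesh-class] objects.
#' @return named numeric vector \code{c(min = , max = )}, nm.
#' @export
distanceExtrema <- function(source, target) {
  d <- vertexToSurfaceDistances(source, target)
  c(min = min(d), max = max(d))
}

#' Export a proximity result
#'
#' Writes the per-vertex distances as CSV, a JSON summary (inclusive and
#' exclusive area fractions, extrema), and optionally a PLY of the source
#' mesh with the strictest-threshold face flag as a quality channel (the
#' "dark spots" rendering of proximity surfaces).
#'
#' @param pr a [ProximityResult-class].
#' @param source the source [TriMesh-class] (needed for PLY export).
#' @param prefix output path prefix.
#' @param writePLY also write \code{<prefix>_proximity.ply}.
#' @return character vector of written paths, invisibly.
#' @export
writeProximityResult <- function(pr, source = NULL, prefix = "proximity",
                                 writePLY = FALSE) {
  csv <- paste0(prefix, "_vertex_distances.csv")
  utils::write.csv(data.frame(vertex = seq_along(pr@vertexDistances),
                              distance_nm = pr@vertexDistances),
                   csv, row.names = FALSE)
  js <- paste0(prefix, "_summary.json")
  writeLines(jsonlite::toJSON(list(
    source = pr@source, target = pr@target,
    thresholds_nm = pr@thresholds,
    area_fractions = pr@areaFractions,
    exclusive_band_fractions = pr@exclusiveFractions,
    min_distance_nm = pr@minDistance,
    max_distance_nm = pr@maxDistance), auto_unbox = TRUE, pretty = TRUE,
    digits = NA), js)
  out <- c(csv, js)
  if (writePLY) {
    if (is.null(source)) stop("source mesh required for PLY export")
    ply <- paste0(prefix, "_proximity.ply")
    writeMesh(source, ply,
              faceScalar = as.numeric(pr@faceFlags[, ncol(pr@faceFlags)]))
    out <- c(out, ply)
  }
  invisible(out)
}
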