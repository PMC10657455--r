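#' @include AllClasses.R
NULL

#' HC Laplacian smoothing parameters
#'
#' Controls for [hcLaplacianSmooth()]. \code{alpha} blends the push-back
#' reference between the original positions (1) and the previous iterate (0);
#' \code{beta} sets how much of a vertex's own deviation (versus its
#' neighbours' mean deviation) is pushed back. Defaults \code{alpha = 0},
#' \code{beta = 0.5} follow the algorithm's original publication; three
#' iterations suffice to remove sub-resolution surface relief while the
#' push-back step counteracts the global shrinkage of plain Laplacian
#' smoothing.
#'
#' @param iterations non-negative iteration count (default 3).
#' @param alpha weight in \code{[0, 1]} (default 0).
#' @param beta weight in \code{[0, 1]} (default 0.5).
#' @return A \code{SmoothingParams} object.
#' @export
SmoothingParams <- function(iterations = 3L, alpha = 0, beta = 0.5) {
  iterations <- as.integer(iterations)
  if (is.na(iterations) || iterations < 0L) stop("iterations must be >= 0")
  if (alpha < 0 || alpha > 1 || beta < 0 || beta > 1)
    stop("alpha and beta must lie in [0, 1]")
  structure(list(iterations = iterations, alpha = alpha, beta = beta),
            class = "SmoothingParams")
}

# row-normalised uniform 1-ring adjacency operator
.uniformAdjacency <- function(mesh) {
  f <- mesh@faces
  nv <- nrow(mesh@vertices)
  i <- c(f[, 1], f[, 2], f[, 2], f[, 3], f[, 3], f[, 1])
  j <- c(f[, 2], f[, 1], f[, 3], f[, 2], f[, 1], f[, 3])
  W <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(nv, nv))
  W@x[W@x > 0] <- 1  # collapse duplicated edge entries to unit weight
  deg <- Matrix::rowSums(W)
  if (any(deg == 0))
    stop(sum(deg == 0), " isolated vertex/vertices (no 1-ring neighbourhood)")
  Matrix::Diagonal(x = 1 / deg) %*% W
}

#' HC Laplacian smoothing
#'
#' Smooths a mesh by uniform 1-ring Laplacian averaging followed by the HC
#' push-back correction that counteracts shrinkage: after each averaging
#' step, every vertex is moved back by a blend of its own deviation from the
#' pre-smoothing position and the mean deviation of its neighbours.
#' Connectivity is never changed; \code{iterations = 0} returns the input
#' unchanged.
#'
#' @param mesh a [TriMesh-class] (validated, no isolated vertices).
#' @param params a [SmoothingParams()] object.
#' @return the smoothed [TriMesh-class].
#' @examples
#' w <- makeIcosphere(1, 3)
#' s <- hcLaplacianSmooth(w, SmoothingParams(iterations = 3))
#' surfaceArea(s) / surfaceArea(w)  # ~1: a smooth sphere is near a fixed point
#' @export
hcLaplacianSmooth <- function(mesh, params = SmoothingParams()) {
  stopifnot(is(mesh, "TriMesh"), inherits(params, "SmoothingParams"))
  if (params$iterations == 0L) return(mesh)
  W <- .uniformAdjacency(mesh)
  o <- mesh@vertices
  q <- o
  for (it in seq_len(params$iterations)) {
    p <- as.matrix(W %*% q)
    b <- p - (params$alpha * o + (1 - params$alpha) * q)
    p <- p - (params$beta * b + (1 - params$beta) * as.matrix(W %*% b))
    q <- p
  }
  mesh@vertices <- q
  mesh
}

#' Plain Laplacian smoothing (uniform weights, no shrinkage correction)
#'
#' Reference smoother used to demonstrate the shrinkage the HC push-back
#' avoids.
#'
#' @inheritParams hcLaplacianSmooth
#' @param iterations iteration count.
#' @return the smoothed [TriMesh-class].
#' @export
laplacianSmooth <- function(mesh, iterations = 3L) {
  stopifnot(is(mesh, "TriMesh"))
  iterations <- as.integer(iterations)
  if (iterations == 0L) return(mesh)
  W <- .uniformAdjacency(mesh)
  q <- mesh@vertices
  for (it in seq_len(iterations)) q <- as.matrix(W %*% q)
  mesh@vertices <- q
  mesh
}

#' Percent surface area gained by membrane wrinkles
#'
#' \code{100 * (area(native) - area(smoothed)) / area(smoothed)}: the
#' relative area excess of the native (wrinkled) surface over its smoothed
#' counterpart. Accepts either two meshes or two precomputed areas (any
#' consistent unit).
#'
#' @param native wrinkled-surface [TriMesh-class], or its area.
#' @param smoothed smoothed-surface [TriMesh-class], or its area.
#' @return percent gain (numeric scalar); negative values (native smaller
#'   than smoothed) are returned with a warning.
#' @examples
#' wrinkleAreaGain(825.5, 736)  # 12.16% on a cyst plasma membrane
#' @export
wrinkleAreaGain <- function(native, smoothed) {
  an <- if (is(native, "TriMesh")) surfaceArea(native) else as.numeric(native)
  as_ <- if (is(smoothed, "TriMesh")) surfaceArea(smoothed) else as.numeric(smoothed)
  if (as_ <= 0) stop("smoothed area must be positive")
  gain <- 100 * (an - as_) / as_
  if (gain < 0) warning("native area is smaller than smoothed area: negative gain")
  gain
}
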