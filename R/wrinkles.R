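#' @include AllClasses.R
NULL

.emptyWrinkleStats <- function() {
  new("WrinkleStats",
      components = data.frame(id = integer(), n_vertices = integer(),
                              n_faces = integer(), length = numeric(),
                              width = numeric(), area = numeric()),
      faceIds = list(),
      meanLength = NA_real_, sdLength = NA_real_,
      meanWidth = NA_real_, sdWidth = NA_real_,
      nComponents = 0L)
}

#' Detect membrane wrinkles by curvature thresholding
#'
#' Selects vertices whose mean curvature exceeds
#' \code{mean(H) + curvatureSdFactor * sd(H)}, groups them into connected
#' components over the mesh edge graph, and measures each component's length
#' and width as the extents of its member vertices along the first and
#' second principal axes. Because a component samples the underlying ridge
#' at mesh resolution, each raw extent underestimates the true extent by
#' about one edge length (half an edge at either end); the component's mean
#' incident edge length is added as a sampling-bias correction. Components
#' spanning fewer than \code{minComponentFaces} faces (faces with all three
#' vertices selected) are dropped. A surface with no super-threshold
#' vertices yields an empty result, not an error.
#'
#' @param mesh a watertight [TriMesh-class].
#' @param curvatureSdFactor threshold in SD units above the mean curvature
#'   (default 1.0).
#' @param minComponentFaces minimum member-face count (default 10).
#' @param curvature optional precomputed per-vertex curvature (skips the
#'   cotangent-Laplacian pass).
#' @return A [WrinkleStats-class].
#' @export
detectWrinkles <- function(mesh, curvatureSdFactor = 1.0,
                           minComponentFaces = 10L, curvature = NULL) {
  .checkNonEmpty(mesh)
  H <- if (is.null(curvature)) vertexMeanCurvature(mesh) else curvature
  thr <- mean(H) + curvatureSdFactor * stats::sd(H)
  sel <- which(H > thr)
  if (length(sel) == 0L) return(.emptyWrinkleStats())

  v <- mesh@vertices; f <- mesh@faces
  inSel <- logical(nrow(v))
  inSel[sel] <- TRUE
  # edges with both endpoints selected
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  keep <- inSel[e[, 1]] & inSel[e[, 2]]
  e <- e[keep, , drop = FALSE]
  g <- igraph::graph_from_edgelist(
    matrix(match(e, sel), ncol = 2L), directed = FALSE)
  g <- igraph::simplify(g)
  miss <- length(sel) - igraph::vcount(g)
  if (miss > 0) g <- igraph::add_vertices(g, miss)
  comp <- igraph::components(g)$membership
  edgeLen <- sqrt(rowSums((v[e[, 1], , drop = FALSE] -
                           v[e[, 2], , drop = FALSE])^2))

  faceAll <- inSel[f[, 1]] & inSel[f[, 2]] & inSel[f[, 3]]
  faceComp <- rep(NA_integer_, nrow(f))
  faceComp[faceAll] <- comp[match(f[faceAll, 1], sel)]
  areas <- faceAreas(mesh)

  rows <- list(); faceIds <- list(); kept <- 0L
  for (ci in seq_len(max(comp))) {
    members <- sel[comp == ci]
    fidx <- which(!is.na(faceComp) & faceComp == ci)
    if (length(fidx) < minComponentFaces) next
    coords <- v[members, , drop = FALSE]
    pc <- stats::prcomp(coords, center = TRUE, rank. = 2L)
    ext <- apply(pc$x, 2L, function(s) diff(range(s)))
    # sampling-bias correction: half an edge missed at each extremity
    ecorr <- mean(edgeLen[comp[match(e[, 1], sel)] == ci], na.rm = TRUE)
    if (!is.finite(ecorr)) ecorr <- 0
    ext <- sort(ext + ecorr, decreasing = TRUE)
    kept <- kept + 1L
    rows[[kept]] <- data.frame(id = kept, n_vertices = length(members),
                               n_faces = length(fidx),
                               length = ext[1], width = ext[2],
                               area = sum(areas[fidx]))
    faceIds[[kept]] <- fidx
  }
  if (kept == 0L) return(.emptyWrinkleStats())
  components <- do.call(rbind, rows)
  new("WrinkleStats",
      components = components, faceIds = faceIds,
      meanLength = mean(components$length),
      sdLength = if (kept > 1L) stats::sd(components$length) else NA_real_,
      meanWidth = mean(components$width),
      sdWidth = if (kept > 1L) stats::sd(components$width) else NA_real_,
      nComponents = kept)
}

#' Serialize wrinkle statistics to JSON
#' @param stats a [WrinkleStats-class].
#' @param path optional output path.
#' @return path (invisibly) or JSON string.
#' @export
wrinkleStatsJSON <- function(stats, path = NULL) {
  x <- list(n_components = stats@nComponents,
            mean_length_nm = stats@meanLength, sd_length_nm = stats@sdLength,
            mean_width_nm = stats@meanWidth, sd_width_nm = stats@sdWidth,
            components = stats@components)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         dataframe = "rows")
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}
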