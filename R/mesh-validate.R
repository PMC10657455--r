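#' @include AllGenerics.R
NULL

# undirected edge table with incidence counts and directed-edge repetition
.edgeCounts <- function(mesh) {
  f <- mesh@faces
  nv <- nrow(mesh@vertices)
  dir1 <- rbind(f[, 1:2, drop = FALSE], f[, 2:3, drop = FALSE],
                f[, c(3, 1), drop = FALSE])
  key <- pmin(dir1[, 1], dir1[, 2]) * (nv + 1) + pmax(dir1[, 1], dir1[, 2])
  dirkey <- dir1[, 1] * (nv + 1) + dir1[, 2]
  ukey <- unique(key)
  tab <- tabulate(match(key, ukey), nbins = length(ukey))
  list(count = tab,
       nEdges = length(ukey),
       directedDuplicated = anyDuplicated(dirkey) > 0L)
}

#' @rdname validateMesh
#' @param dropDegenerate remove faces with area below \code{degenerateTol}
#'   (with a warning) before reporting; the cleaned mesh is available via
#'   \code{attr(report, "mesh")}.
#' @param degenerateTol area threshold in nm^2 below which a face counts as
#'   degenerate (default \code{1e-6}).
#' @export
setMethod("validateMesh", "TriMesh", function(x, dropDegenerate = TRUE,
                                              degenerateTol = 1e-6, ...) {
  .checkNonEmpty(x)
  areas <- faceAreas(x)
  degen <- which(areas < degenerateTol)
  mesh <- x
  if (length(degen) && dropDegenerate) {
    warning(length(degen), " degenerate face(s) (area < ", degenerateTol,
            " nm^2) removed during validation")
    mesh@faces <- mesh@faces[-degen, , drop = FALSE]
  }
  ec <- .edgeCounts(mesh)
  watertight <- all(ec$count == 2L)
  oriented <- !ec$directedDuplicated
  ndup <- nrow(mesh@vertices) - nrow(unique(mesh@vertices))
  euler <- nrow(mesh@vertices) - ec$nEdges + nrow(mesh@faces)
  rep <- new("ValidationReport",
             watertight = watertight, oriented = oriented,
             nDuplicateVertices = as.integer(ndup),
             nDegenerateFaces = as.integer(length(degen)),
             eulerCharacteristic = as.integer(euler))
  attr(rep, "mesh") <- mesh
  rep
})

#' Serialize a validation report to JSON
#' @param report a [ValidationReport-class].
#' @param path optional output path; when NULL, the JSON string is returned.
#' @return path (invisibly) or JSON string.
#' @export
validationReportJSON <- function(report, path = NULL) {
  x <- list(watertight = report@watertight, oriented = report@oriented,
            n_duplicate_vertices = report@nDuplicateVertices,
            n_degenerate_faces = report@nDegenerateFaces,
            euler_characteristic = report@eulerCharacteristic)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}
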