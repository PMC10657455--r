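#' @include AllClasses.R
NULL

#' Write / read an organelle scene directory
#'
#' A scene directory holds one ASCII PLY per mesh (\code{<name>.ply}, plus
#' \code{cell.ply} for the boundary), a \code{ground_truth.csv} when the
#' scene carries a generator ground-truth table, and a \code{scene.json}
#' with the remaining metadata.
#'
#' @param scene an [OrganelleScene-class].
#' @param dir directory path (created if needed).
#' @return the directory, invisibly.
#' @export
writeScene <- function(scene, dir) {
  stopifnot(is(scene, "OrganelleScene"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(scene@meshes))
    writeMesh(scene@meshes[[nm]], file.path(dir, paste0(nm, ".ply")))
  if (!is.null(scene@cellBoundary))
    writeMesh(scene@cellBoundary, file.path(dir, "cell.ply"))
  meta <- scene@metadata
  if (!is.null(meta$groundTruth)) {
    utils::write.csv(meta$groundTruth, file.path(dir, "ground_truth.csv"),
                     row.names = FALSE)
    meta$groundTruth <- NULL
  }
  meta$has_cell_boundary <- !is.null(scene@cellBoundary)
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA, null = "null"),
             file.path(dir, "scene.json"))
  invisible(dir)
}

#' @rdname writeScene
#' @export
readScene <- function(dir) {
  if (!dir.exists(dir)) stop("scene directory not found: ", dir)
  metaPath <- file.path(dir, "scene.json")
  meta <- if (file.exists(metaPath))
    jsonlite::fromJSON(metaPath, simplifyVector = TRUE) else list()
  gtPath <- file.path(dir, "ground_truth.csv")
  if (file.exists(gtPath)) meta$groundTruth <- utils::read.csv(gtPath)
  plys <- sort(list.files(dir, pattern = "\\.ply$", full.names = TRUE))
  if (!length(plys)) stop("no PLY meshes in scene directory: ", dir)
  hasCell <- isTRUE(meta$has_cell_boundary)
  meta$has_cell_boundary <- NULL
  meshes <- list()
  cellMesh <- NULL
  for (p in plys) {
    nm <- tools::file_path_sans_ext(basename(p))
    m <- readMesh(p, name = nm)
    if (hasCell && nm == "cell") cellMesh <- m else meshes[[nm]] <- m
  }
  OrganelleScene(meshes, cellBoundary = cellMesh, metadata = meta)
}
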