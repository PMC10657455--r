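#' @include AllGenerics.R
NULL

#' @rdname meshVertices
#' @export
setMethod("meshVertices", "TriMesh", function(x) x@vertices)

#' @rdname meshFaces
#' @export
setMethod("meshFaces", "TriMesh", function(x) x@faces)

#' @rdname meshName
#' @export
setMethod("meshName", "TriMesh", function(x) x@name)

#' @rdname sceneMeshes
#' @export
setMethod("sceneMeshes", "OrganelleScene", function(x) x@meshes)

#' @rdname cellBoundary
#' @export
setMethod("cellBoundary", "OrganelleScene", function(x) x@cellBoundary)

#' @rdname areaFractions
#' @export
setMethod("areaFractions", "ProximityResult", function(x)
  stats::setNames(x@areaFractions, paste0("le_", format(x@thresholds, trim = TRUE), "nm")))

setMethod("show", "TriMesh", function(object) {
  cat(sprintf("TriMesh %s: %d vertices, %d faces\n",
              if (nzchar(object@name)) sQuote(object@name) else "(unnamed)",
              nrow(object@vertices), nrow(object@faces)))
  if (nrow(object@vertices)) {
    rng <- apply(object@vertices, 2L, range)
    cat(sprintf("  extent (nm): x [%.1f, %.1f]  y [%.1f, %.1f]  z [%.1f, %.1f]\n",
                rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2], rng[1, 3], rng[2, 3]))
  }
  invisible(object)
})

setMethod("show", "LabelVolume", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("LabelVolume: %d x %d x %d voxels (z,y,x) at %.3g nm\n",
              d[1], d[2], d[3], object@voxelSize))
  if (length(object@labelMap))
    cat("  labels:", paste(sprintf("%s=%d", names(object@labelMap),
                                   object@labelMap), collapse = ", "), "\n")
  invisible(object)
})

setMethod("show", "OrganelleScene", function(object) {
  cat(sprintf("OrganelleScene: %d meshes%s\n", length(object@meshes),
              if (is.null(object@cellBoundary)) "" else " + cell boundary"))
  if (length(object@meshes))
    cat("  ", paste(names(object@meshes), collapse = ", "), "\n", sep = "")
  invisible(object)
})

setMethod("show", "ValidationReport", function(object) {
  cat(sprintf(paste0("ValidationReport: watertight=%s oriented=%s ",
                     "duplicates=%d degenerate=%d Euler=%d\n"),
              object@watertight, object@oriented, object@nDuplicateVertices,
              object@nDegenerateFaces, object@eulerCharacteristic))
  invisible(object)
})

setMethod("show", "ProximityResult", function(object) {
  cat(sprintf("ProximityResult %s -> %s\n", object@source, object@target))
  cat(sprintf("  distance range: [%.2f, %.2f] nm\n",
              object@minDistance, object@maxDistance))
  for (i in seq_along(object@thresholds))
    cat(sprintf("  area fraction <= %g nm: %.4f\n", object@thresholds[i],
                object@areaFractions[i]))
  invisible(object)
})

setMethod("show", "WrinkleStats", function(object) {
  cat(sprintf("WrinkleStats: %d ridge components\n", object@nComponents))
  if (object@nComponents > 0)
    cat(sprintf("  length %.1f +/- %.1f nm, width %.1f +/- %.1f nm\n",
                object@meanLength, object@sdLength,
                object@meanWidth, object@sdWidth))
  invisible(object)
})

setMethod("show", "MorphometryReport", function(object) {
  cat("MorphometryReport\n")
  if (nrow(object@perOrganelle)) {
    cat("  per-organelle:\n")
    print(object@perOrganelle, row.names = FALSE)
  }
  if (nrow(object@ratios)) {
    cat("  ratios:\n")
    print(object@ratios, row.names = FALSE)
  }
  if (length(object@proximity))
    cat("  proximity pairs:", paste(names(object@proximity), collapse = ", "), "\n")
  invisible(object)
})
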