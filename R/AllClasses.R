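#' @import methods
NULL

#' Triangle surface mesh of an organelle
#'
#' An oriented triangle mesh in nanometre coordinates: the fundamental
#' container of the morphometry pipeline. Vertices are stored as an
#' \code{n x 3} numeric matrix (x, y, z in nm) and faces as an \code{m x 3}
#' integer matrix of 1-based vertex indices, wound so that face normals point
#' outward for a closed surface.
#'
#' @slot vertices numeric matrix, \code{n x 3}, coordinates in nm.
#' @slot faces integer matrix, \code{m x 3}, 1-based vertex indices.
#' @slot name character scalar, organelle label (may be \code{""}).
#'
#' @seealso [surfaceArea()], [enclosedVolume()], [validateMesh()]
#' @export
setClass("TriMesh",
  representation(vertices = "matrix", faces = "matrix", name = "character"),
  prototype(vertices = matrix(numeric(), 0L, 3L),
            faces = matrix(integer(), 0L, 3L), name = "")
)

setValidity("TriMesh", function(object) {
  msg <- character()
  v <- object@vertices; f <- object@faces
  if (!is.numeric(v) || ncol(v) != 3L) msg <- c(msg, "vertices must be an n x 3 numeric matrix")
  if (ncol(f) != 3L) msg <- c(msg, "faces must be an m x 3 index matrix")
  if (nrow(f) > 0L) {
    if (anyNA(f) || any(f < 1L) || any(f > nrow(v)))
      msg <- c(msg, "face indices must lie in [1, nrow(vertices)]")
  }
  if (anyNA(v)) msg <- c(msg, "vertex coordinates contain NA")
  if (length(object@name) != 1L) msg <- c(msg, "name must be a single string")
  if (length(msg)) msg else TRUE
})

#' Construct a TriMesh
#'
#' @param vertices numeric \code{n x 3} matrix of coordinates in nm.
#' @param faces integer \code{m x 3} matrix of 1-based vertex indices.
#' @param name organelle label.
#' @return A [TriMesh-class] object.
#' @examples
#' m <- TriMesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)), rbind(c(1L, 2L, 3L)))
#' surfaceArea(m)
#' @export
TriMesh <- function(vertices, faces, name = "") {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  new("TriMesh", vertices = vertices, faces = faces, name = as.character(name))
}

#' Labelled voxel volume
#'
#' A 3D integer label image with isotropic voxel size, as produced by manual
#' or automatic segmentation of a FIB-SEM stack. Voxels are stored in
#' \code{(z, y, x)} order (an R array with \code{dim = c(nz, ny, nx)}); label
#' 0 is reserved for background.
#'
#' @slot voxels integer 3D array, \code{(z, y, x)} order.
#' @slot voxelSize numeric scalar, isotropic voxel edge length in nm.
#' @slot labelMap named integer vector mapping organelle names to labels.
#' @export
setClass("LabelVolume",
  representation(voxels = "array", voxelSize = "numeric", labelMap = "integer")
)

setValidity("LabelVolume", function(object) {
  msg <- character()
  if (length(dim(object@voxels)) != 3L) msg <- c(msg, "voxels must be a 3D array")
  if (length(object@voxelSize) != 1L || !is.finite(object@voxelSize) ||
      object@voxelSize <= 0) msg <- c(msg, "voxelSize must be a positive scalar (nm)")
  if (any(object@labelMap == 0L)) msg <- c(msg, "label 0 is reserved for background")
  present <- setdiff(unique(as.integer(object@voxels)), 0L)
  if (length(object@labelMap) && !all(present %in% object@labelMap))
    msg <- c(msg, "voxel labels present that are absent from labelMap")
  if (length(msg)) msg else TRUE
})

#' Construct a LabelVolume
#'
#' @param voxels integer 3D array in \code{(z, y, x)} order.
#' @param voxelSize isotropic voxel size in nm.
#' @param labelMap named integer vector (organelle name -> label). When
#'   empty, labels are named \code{"label_<k>"} on demand.
#' @return A [LabelVolume-class] object.
#' @export
LabelVolume <- function(voxels, voxelSize, labelMap = integer()) {
  storage.mode(voxels) <- "integer"
  labelMap <- as.integer(labelMap) |> stats::setNames(names(labelMap))
  new("LabelVolume", voxels = voxels, voxelSize = as.numeric(voxelSize),
      labelMap = labelMap)
}

#' A scene of organelle meshes
#'
#' A named collection of [TriMesh-class] objects in a common nm coordinate
#' frame, with an optional cell-boundary (plasma membrane) mesh enclosing the
#' others. Multi-component organelle classes (mitochondria, lipid droplets,
#' starch grains) are represented as multiple meshes sharing a class prefix,
#' e.g. \code{"mitochondrion_1"}.
#'
#' @slot meshes named list of [TriMesh-class].
#' @slot cellBoundary a [TriMesh-class] or \code{NULL}.
#' @slot metadata list of free-form provenance (seeds, generator parameters,
#'   ground-truth tables).
#' @export
setClass("OrganelleScene",
  representation(meshes = "list", cellBoundary = "ANY", metadata = "list"),
  prototype(meshes = list(), cellBoundary = NULL, metadata = list())
)

setValidity("OrganelleScene", function(object) {
  msg <- character()
  if (length(object@meshes)) {
    if (is.null(names(object@meshes)) || anyDuplicated(names(object@meshes)))
      msg <- c(msg, "meshes must be uniquely named")
    if (!all(vapply(object@meshes, is, logical(1), "TriMesh")))
      msg <- c(msg, "all scene members must be TriMesh objects")
  }
  if (!is.null(object@cellBoundary) && !is(object@cellBoundary, "TriMesh"))
    msg <- c(msg, "cellBoundary must be a TriMesh or NULL")
  if (length(msg)) msg else TRUE
})

#' Construct an OrganelleScene
#' @param meshes named list of [TriMesh-class] objects.
#' @param cellBoundary optional enclosing [TriMesh-class] (plasma membrane).
#' @param metadata list of provenance entries.
#' @return An [OrganelleScene-class] object.
#' @export
OrganelleScene <- function(meshes = list(), cellBoundary = NULL, metadata = list()) {
  new("OrganelleScene", meshes = meshes, cellBoundary = cellBoundary,
      metadata = metadata)
}

#' Mesh validation report
#'
#' Summary of the structural checks required before metric computations:
#' watertightness (every edge shared by exactly two faces), orientation
#' consistency (no directed edge repeated), duplicate-vertex and
#' degenerate-face counts, and the Euler characteristic V - E + F.
#'
#' @slot watertight logical.
#' @slot oriented logical.
#' @slot nDuplicateVertices integer.
#' @slot nDegenerateFaces integer.
#' @slot eulerCharacteristic integer.
#' @export
setClass("ValidationReport",
  representation(watertight = "logical", oriented = "logical",
                 nDuplicateVertices = "integer", nDegenerateFaces = "integer",
                 eulerCharacteristic = "integer")
)

#' Inter-organelle proximity result
#'
#' Per-vertex minimum distances from a source mesh to a target surface, plus
#' face-level proximity flags and the fraction of source surface area within
#' each distance threshold.
#'
#' @slot source,target organelle names.
#' @slot vertexDistances numeric, nm, one entry per source vertex.
#' @slot thresholds numeric, nm, sorted decreasing.
#' @slot faceFlags logical matrix, faces x thresholds.
#' @slot areaFractions numeric in [0, 1], one per threshold.
#' @slot exclusiveFractions numeric, fraction in each exclusive distance band
#'   (threshold k but not threshold k+1).
#' @slot minDistance,maxDistance numeric, nm.
#' @export
setClass("ProximityResult",
  representation(source = "character", target = "character",
                 vertexDistances = "numeric", thresholds = "numeric",
                 faceFlags = "matrix", areaFractions = "numeric",
                 exclusiveFractions = "numeric",
                 minDistance = "numeric", maxDistance = "numeric")
)

setValidity("ProximityResult", function(object) {
  msg <- character()
  if (any(object@vertexDistances < 0)) msg <- c(msg, "distances must be >= 0")
  if (is.unsorted(rev(object@thresholds))) msg <- c(msg, "thresholds must be sorted decreasing")
  fr <- object@areaFractions
  if (any(fr < -1e-12 | fr > 1 + 1e-12)) msg <- c(msg, "area fractions must lie in [0, 1]")
  if (length(fr) > 1L && any(diff(fr) > 1e-12))
    msg <- c(msg, "area fractions must be non-increasing as the threshold decreases")
  if (length(object@minDistance) && length(object@maxDistance) &&
      object@minDistance > object@maxDistance)
    msg <- c(msg, "minDistance must not exceed maxDistance")
  if (length(msg)) msg else TRUE
})

#' Membrane wrinkle statistics
#'
#' Ridge components detected on a surface by curvature thresholding, each
#' with its length and width (extents along the first two principal axes of
#' the member vertices, in nm) and summary means/SDs.
#'
#' @slot components data.frame with columns \code{id}, \code{n_vertices},
#'   \code{n_faces}, \code{length}, \code{width}, \code{area}.
#' @slot faceIds list of integer vectors, member faces per component.
#' @slot meanLength,sdLength,meanWidth,sdWidth numeric, nm.
#' @slot nComponents integer.
#' @export
setClass("WrinkleStats",
  representation(components = "data.frame", faceIds = "list",
                 meanLength = "numeric", sdLength = "numeric",
                 meanWidth = "numeric", sdWidth = "numeric",
                 nComponents = "integer")
)

setValidity("WrinkleStats", function(object) {
  msg <- character()
  if (object@nComponents != nrow(object@components))
    msg <- c(msg, "nComponents must equal nrow(components)")
  if (nrow(object@components) &&
      any(object@components$length + 1e-9 < object@components$width))
    msg <- c(msg, "component length must be >= width")
  if (length(msg)) msg else TRUE
})

#' Scene-level morphometry report
#'
#' Aggregated per-organelle volumes, areas and cell-volume occupancies,
#' pairwise volume/area ratios, and proximity summaries, with provenance.
#'
#' @slot perOrganelle data.frame: \code{name}, \code{volume_um3},
#'   \code{area_um2}, \code{occupancy} (fraction of cell volume).
#' @slot ratios data.frame: \code{a}, \code{b}, \code{volume_ratio},
#'   \code{area_ratio}.
#' @slot proximity named list of [ProximityResult-class] summaries.
#' @slot provenance list (voxel size, package version, seed, config hash).
#' @export
setClass("MorphometryReport",
  representation(perOrganelle = "data.frame", ratios = "data.frame",
                 proximity = "list", provenance = "list")
)
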