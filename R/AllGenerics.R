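#' @include AllClasses.R
NULL

#' Total surface area of a mesh
#'
#' Sum of triangle areas, in nm^2. Invariant under rigid motion; scales as
#' \eqn{s^2} under uniform scaling by \eqn{s}.
#'
#' @param x a [TriMesh-class] (or object with a mesh representation).
#' @param units \code{"nm2"} (default) or \code{"um2"}.
#' @param ... further arguments for methods.
#' @return numeric scalar area.
#' @export
setGeneric("surfaceArea", function(x, ...) standardGeneric("surfaceArea"))

#' Volume enclosed by a watertight mesh
#'
#' Sum of signed tetrahedron volumes, one tetrahedron per face against a
#' fixed interior reference point. Requires a watertight, consistently
#' oriented mesh; positive for outward orientation.
#'
#' @param x a [TriMesh-class].
#' @param units \code{"nm3"} (default) or \code{"um3"}.
#' @param force compute even for a non-watertight mesh (result approximate).
#' @param fixOrientation if the signed volume comes out negative (inward
#'   orientation), return the absolute value with a warning instead of
#'   erroring.
#' @param ... further arguments for methods.
#' @return numeric scalar volume.
#' @export
setGeneric("enclosedVolume", function(x, ...) standardGeneric("enclosedVolume"))

#' Structural validation of a mesh
#'
#' @param x a [TriMesh-class].
#' @param ... further arguments for methods.
#' @return a [ValidationReport-class].
#' @export
setGeneric("validateMesh", function(x, ...) standardGeneric("validateMesh"))

#' Mesh vertices accessor
#' @param x a [TriMesh-class].
#' @return numeric matrix of vertex coordinates (nm).
#' @export
setGeneric("meshVertices", function(x) standardGeneric("meshVertices"))

#' Mesh faces accessor
#' @param x a [TriMesh-class].
#' @return integer matrix of 1-based face indices.
#' @export
setGeneric("meshFaces", function(x) standardGeneric("meshFaces"))

#' Organelle name accessor
#' @param x a [TriMesh-class].
#' @return character scalar.
#' @export
setGeneric("meshName", function(x) standardGeneric("meshName"))

#' Scene meshes accessor
#' @param x an [OrganelleScene-class].
#' @return named list of [TriMesh-class].
#' @export
setGeneric("sceneMeshes", function(x) standardGeneric("sceneMeshes"))

#' Cell boundary accessor
#' @param x an [OrganelleScene-class].
#' @return a [TriMesh-class] or NULL.
#' @export
setGeneric("cellBoundary", function(x) standardGeneric("cellBoundary"))

#' Proximity area fractions accessor
#' @param x a [ProximityResult-class].
#' @return named numeric vector, one fraction per threshold.
#' @export
setGeneric("areaFractions", function(x) standardGeneric("areaFractions"))
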