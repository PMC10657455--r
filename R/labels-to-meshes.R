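#' @include AllClasses.R
NULL

.labelName <- function(volume, label) {
  nm <- names(volume@labelMap)[match(label, volume@labelMap)]
  if (is.na(nm) || is.null(nm)) sprintf("label_%d", label) else nm
}

#' Extract organelle surface meshes from a label volume
#'
#' Each requested label is binarised and its 0.5-level isosurface extracted
#' by marching tetrahedra on the voxel-corner sample grid (vertex coordinates
#' are sample index times \code{voxelSize}). The mask is padded by one
#' background voxel on every side, so labels touching the volume boundary
#' still yield closed surfaces. The resulting meshes are watertight and
#' outward-oriented. Optional light HC Laplacian smoothing can be applied;
#' the iteration count is recorded in the scene metadata.
#'
#' @param volume a [LabelVolume-class].
#' @param labels integer labels to extract; default: all labels in
#'   \code{labelMap}, or all non-background labels present.
#' @param smoothingIterations HC smoothing iterations per mesh (default 0).
#' @return An [OrganelleScene-class] with one mesh per label.
#' @export
labelsToMeshes <- function(volume, labels = NULL, smoothingIterations = 0L) {
  stopifnot(is(volume, "LabelVolume"))
  vox <- volume@voxels
  present <- setdiff(sort(unique(as.integer(vox))), 0L)
  if (is.null(labels)) {
    labels <- if (length(volume@labelMap)) as.integer(volume@labelMap) else present
  }
  missing <- setdiff(labels, present)
  if (length(missing))
    stop("label(s) absent from volume: ", paste(missing, collapse = ", "))
  h <- volume@voxelSize
  d <- dim(vox)
  meshes <- list()
  for (lab in labels) {
    mask <- array(0L, dim = d + 2L)
    mask[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- (vox == lab) * 1L
    res <- cpp_marching_tets(as.integer(mask), d[1] + 2L, d[2] + 2L,
                             d[3] + 2L, h)
    v <- res$vertices - h  # undo the one-voxel padding offset
    mesh <- TriMesh(v, res$faces, name = .labelName(volume, lab))
    if (smoothingIterations > 0L)
      mesh <- hcLaplacianSmooth(mesh,
                                SmoothingParams(iterations = smoothingIterations))
    meshes[[mesh@name]] <- mesh
  }
  OrganelleScene(meshes,
                 metadata = list(voxel_size_nm = h,
                                 smoothing_iterations = as.integer(smoothingIterations),
                                 source = "labelsToMeshes"))
}

#' Voxel-count volume of a label
#'
#' The independent volume oracle for [enclosedVolume()]: number of voxels
#' carrying the label times \code{voxelSize^3}.
#'
#' @param volume a [LabelVolume-class].
#' @param label integer label (non-zero).
#' @return volume in nm^3.
#' @export
voxelLabelVolume <- function(volume, label) {
  stopifnot(is(volume, "LabelVolume"), length(label) == 1L)
  n <- sum(volume@voxels == as.integer(label))
  if (n == 0L) stop("label ", label, " not present in volume")
  n * volume@voxelSize^3
}
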