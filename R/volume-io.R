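#' @include AllClasses.R
NULL

#' Read a segmented label volume from a multi-page TIFF or NRRD file
#'
#' TIFF stacks are read page-by-page (page = z slice, matrix rows = y,
#' columns = x); TIFF carries no voxel-size metadata, so \code{voxelSize}
#' must be supplied. NRRD files carry their own \code{sizes}, \code{type},
#' \code{encoding} (\code{ascii} or little-endian \code{raw}) and
#' \code{spacings}; the first NRRD axis is the fastest-varying and maps to z.
#'
#' @param path file ending in \code{.tif}, \code{.tiff} or \code{.nrrd}.
#' @param voxelSize isotropic voxel size in nm (required for TIFF; for NRRD
#'   it overrides the header spacing when given).
#' @param labelMap optional named integer vector naming the labels.
#' @return A [LabelVolume-class].
#' @export
readLabelVolume <- function(path, voxelSize = NULL, labelMap = integer()) {
  if (!file.exists(path)) stop("cannot read label volume: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    if (is.null(voxelSize))
      stop("voxelSize (nm) is required when reading TIFF label stacks")
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    d <- dim(pages[[1]])
    vox <- array(0L, dim = c(length(pages), d[1], d[2]))
    for (z in seq_along(pages)) vox[z, , ] <- as.integer(pages[[z]])
    return(LabelVolume(vox, voxelSize, labelMap))
  }
  if (ext == "nrrd") {
    nr <- .readNRRD(path)
    vs <- if (!is.null(voxelSize)) voxelSize else nr$spacing
    if (is.null(vs)) stop("NRRD has no spacings; supply voxelSize")
    return(LabelVolume(nr$data, vs, labelMap))
  }
  stop("unsupported label-volume format: .", ext)
}

#' Write a label volume to multi-page TIFF or NRRD
#'
#' TIFF output is 16-bit (labels must fit in 0..65535); NRRD output is
#' written with \code{encoding: ascii} and \code{type: int32}, carrying the
#' voxel spacing in the header.
#'
#' @param volume a [LabelVolume-class].
#' @param path output path (\code{.tif}/\code{.tiff} or \code{.nrrd}).
#' @return the path, invisibly.
#' @export
writeLabelVolume <- function(volume, path) {
  stopifnot(is(volume, "LabelVolume"))
  ext <- tolower(tools::file_ext(path))
  vox <- volume@voxels
  if (ext %in% c("tif", "tiff")) {
    if (max(vox) > 65535L) stop("labels exceed 16-bit TIFF range")
    pages <- lapply(seq_len(dim(vox)[1]), function(z)
      matrix(vox[z, , ] / 65535, nrow = dim(vox)[2]))
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  } else if (ext == "nrrd") {
    .writeNRRD(volume, path)
  } else {
    stop("unsupported label-volume format: .", ext)
  }
  invisible(path)
}

# Minimal NRRD reader: attached data, encodings ascii / raw(little-endian),
# integer types.
.readNRRD <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, 1L)
  if (!grepl("^NRRD", magic)) stop("not a NRRD file")
  fields <- list()
  repeat {
    ln <- readLines(con, 1L)
    if (length(ln) == 0L) stop("malformed NRRD: no blank line before data")
    if (!nzchar(ln)) break
    if (grepl("^#", ln)) next
    kv <- strsplit(ln, ":\\s*")[[1]]
    fields[[tolower(kv[1])]] <- paste(kv[-1], collapse = ":")
  }
  sizes <- as.integer(strsplit(trimws(fields$sizes), "\\s+")[[1]])
  if (length(sizes) != 3L) stop("only 3-D NRRD volumes are supported")
  n <- prod(sizes)
  type <- tolower(fields$type)
  enc <- tolower(fields$encoding)
  if (enc %in% c("ascii", "text", "txt")) {
    txt <- readLines(con)
    vals <- as.integer(strsplit(paste(txt, collapse = " "), "\\s+")[[1]] |>
                         (\(x) x[nzchar(x)])())
  } else if (enc == "raw") {
    sz <- switch(type,
                 "uint8" = 1L, "int8" = 1L, "uint16" = 2L, "int16" = 2L,
                 "uint32" = 4L, "int32" = 4L, "int" = 4L,
                 stop("unsupported NRRD type: ", type))
    signed <- !startsWith(type, "uint") || sz == 4L
    vals <- readBin(con, "integer", n, size = sz, signed = signed,
                    endian = "little")
  } else stop("unsupported NRRD encoding: ", enc)
  if (length(vals) != n) stop("NRRD data length mismatch")
  spacing <- NULL
  if (!is.null(fields$spacings)) {
    sp <- as.numeric(strsplit(trimws(fields$spacings), "\\s+")[[1]])
    if (length(unique(round(sp, 9))) != 1L)
      stop("anisotropic NRRD spacings are not supported")
    spacing <- sp[1]
  }
  list(data = array(vals, dim = sizes), spacing = spacing)
}

.writeNRRD <- function(volume, path) {
  vox <- volume@voxels
  con <- file(path, "wb")
  on.exit(close(con))
  h <- volume@voxelSize
  hdr <- c("NRRD0004",
           "# label volume written by cystmorph",
           "type: int32",
           "dimension: 3",
           paste("sizes:", paste(dim(vox), collapse = " ")),
           sprintf("spacings: %.10g %.10g %.10g", h, h, h),
           "encoding: ascii",
           "")
  writChar <- paste0(paste(hdr, collapse = "\n"), "\n")
  writeChar(writChar, con, eos = NULL)
  vals <- as.integer(vox)
  rows <- split(vals, ceiling(seq_along(vals) / 16))
  writeChar(paste0(vapply(rows, paste, "", collapse = " "), "\n",
                   collapse = ""), con, eos = NULL)
}
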