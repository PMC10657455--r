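#' @include AllClasses.R
NULL

# group multi-component organelles (mitochondrion_3, LD_17, starch_2 ...)
# into classes by stripping a trailing _<number>
.organelleClass <- function(name) sub("_[0-9]+$", "", name)

.classMeshes <- function(scene, class) {
  nm <- names(scene@meshes)
  scene@meshes[.organelleClass(nm) == class]
}

.classVolume <- function(scene, class, ...) {
  ms <- .classMeshes(scene, class)
  if (!length(ms)) stop("organelle class '", class, "' absent from scene")
  sum(vapply(ms, enclosedVolume, numeric(1), ...))
}

.classArea <- function(scene, class) {
  ms <- .classMeshes(scene, class)
  if (!length(ms)) stop("organelle class '", class, "' absent from scene")
  sum(vapply(ms, surfaceArea, numeric(1)))
}

#' Per-organelle volumes, areas and cell-volume occupancies
#'
#' Sums volumes and areas per organelle class (multi-component classes such
#' as mitochondria or lipid droplets are aggregated over their meshes) and
#' divides by the cell-boundary (plasma membrane) volume to obtain occupancy
#' fractions.
#'
#' @param scene an [OrganelleScene-class] with a watertight cell boundary.
#' @return a [MorphometryReport-class] with the per-organelle table filled.
#' @export
occupancyReport <- function(scene) {
  stopifnot(is(scene, "OrganelleScene"))
  if (is.null(scene@cellBoundary))
    stop("scene lacks a cell boundary; occupancies are undefined")
  Vcell <- enclosedVolume(scene@cellBoundary)
  classes <- unique(.organelleClass(names(scene@meshes)))
  rows <- lapply(classes, function(cl) {
    vol <- .classVolume(scene, cl)
    if (vol > Vcell)
      stop("inconsistent scene: '", cl, "' volume exceeds the cell volume")
    data.frame(name = cl,
               n_components = length(.classMeshes(scene, cl)),
               volume_um3 = vol / 1e9,
               area_um2 = .classArea(scene, cl) / 1e6,
               occupancy = vol / Vcell)
  })
  per <- if (length(rows)) do.call(rbind, rows) else
    data.frame(name = character(), n_components = integer(),
               volume_um3 = numeric(), area_um2 = numeric(),
               occupancy = numeric())
  new("MorphometryReport",
      perOrganelle = per,
      ratios = data.frame(a = character(), b = character(),
                          volume_ratio = numeric(), area_ratio = numeric()),
      proximity = list(),
      provenance = list(cell_volume_um3 = Vcell / 1e9))
}

#' Pairwise organelle volume and surface-area ratios
#'
#' Ratio of summed volumes and summed areas of two organelle classes, e.g.
#' the plastid/mitochondria volume and area ratios of a cyst.
#'
#' @param scene an [OrganelleScene-class].
#' @param a,b organelle class names (numerator, denominator).
#' @return named list with \code{volume_ratio} and \code{area_ratio}.
#' @export
organelleRatios <- function(scene, a, b) {
  va <- .classVolume(scene, a); vb <- .classVolume(scene, b)
  aa <- .classArea(scene, a); ab <- .classArea(scene, b)
  if (vb == 0 || ab == 0) stop("zero denominator for organelle '", b, "'")
  list(volume_ratio = va / vb, area_ratio = aa / ab)
}

# merge all meshes of a class into one TriMesh (disjoint union) so proximity
# queries see the whole class surface
.mergeClass <- function(scene, class) {
  ms <- .classMeshes(scene, class)
  if (!length(ms)) return(NULL)
  if (length(ms) == 1L) {
    m <- ms[[1L]]
    m@name <- class
    return(m)
  }
  vs <- lapply(ms, meshVertices)
  fs <- lapply(ms, meshFaces)
  off <- cumsum(c(0L, vapply(vs, nrow, integer(1))))
  f <- do.call(rbind, Map(function(fm, o) fm + o, fs, off[-length(off)]))
  TriMesh(do.call(rbind, vs), f, name = class)
}

#' Assemble the full scene morphometry report
#'
#' Runs the occupancy table, the configured organelle ratio pairs and the
#' configured proximity pairs (inclusive area fractions at the given
#' thresholds, plus distance extrema), and collects provenance. Pairs whose
#' organelles are absent from the scene are skipped with a warning rather
#' than failing the whole report.
#'
#' @param scene an [OrganelleScene-class].
#' @param ratioPairs list of 2-element character vectors (default:
#'   chloroplast/mitochondrion).
#' @param proximityPairs list of 2-element character vectors, source then
#'   target (defaults: chloroplast-mitochondrion both ways,
#'   chloroplast-LD, mitochondrion-LD, mitochondrion-starch).
#' @param thresholds proximity thresholds in nm (default \code{c(100, 24)}).
#' @param seed integer recorded in provenance (the report itself is
#'   deterministic).
#' @return a [MorphometryReport-class].
#' @export
assembleReport <- function(scene,
                           ratioPairs = list(c("chloroplast", "mitochondrion")),
                           proximityPairs = list(
                             c("chloroplast", "mitochondrion"),
                             c("mitochondrion", "chloroplast"),
                             c("chloroplast", "LD"),
                             c("mitochondrion", "LD"),
                             c("mitochondrion", "starch")),
                           thresholds = c(100, 24),
                           seed = NA_integer_) {
  # a mesh named "cell" doubles as the boundary when none is set (e.g. scenes
  # extracted straight from a label volume)
  if (is.null(scene@cellBoundary) && !is.null(scene@meshes$cell)) {
    scene@cellBoundary <- scene@meshes$cell
    scene@meshes$cell <- NULL
  }
  rep <- if (!is.null(scene@cellBoundary)) {
    tryCatch(occupancyReport(scene),
             error = function(e) stop("occupancy stage failed: ",
                                      conditionMessage(e)))
  } else {
    warning("scene has no cell boundary: occupancies reported as NA")
    classes <- unique(.organelleClass(names(scene@meshes)))
    per <- do.call(rbind, lapply(classes, function(cl)
      data.frame(name = cl,
                 n_components = length(.classMeshes(scene, cl)),
                 volume_um3 = .classVolume(scene, cl) / 1e9,
                 area_um2 = .classArea(scene, cl) / 1e6,
                 occupancy = NA_real_)))
    new("MorphometryReport", perOrganelle = per,
        ratios = data.frame(a = character(), b = character(),
                            volume_ratio = numeric(), area_ratio = numeric()),
        proximity = list(), provenance = list())
  }
  classes <- unique(.organelleClass(names(scene@meshes)))
  ratios <- list()
  for (pr in ratioPairs) {
    if (!all(pr %in% classes)) {
      warning("ratio pair ", paste(pr, collapse = "/"),
              " skipped: organelle absent")
      next
    }
    rr <- tryCatch(organelleRatios(scene, pr[1], pr[2]),
                   error = function(e) stop("ratio stage failed for ",
                                            paste(pr, collapse = "/"), ": ",
                                            conditionMessage(e)))
    ratios[[length(ratios) + 1L]] <-
      data.frame(a = pr[1], b = pr[2],
                 volume_ratio = rr$volume_ratio, area_ratio = rr$area_ratio)
  }
  rep@ratios <- if (length(ratios)) do.call(rbind, ratios) else rep@ratios

  prox <- list()
  for (pr in proximityPairs) {
    if (!all(pr %in% classes)) {
      warning("proximity pair ", paste(pr, collapse = "->"),
              " skipped: organelle absent")
      next
    }
    src <- .mergeClass(scene, pr[1])
    tgt <- .mergeClass(scene, pr[2])
    res <- tryCatch(proximityMap(src, tgt, thresholds = thresholds),
                    error = function(e) stop("proximity stage failed for ",
                                             paste(pr, collapse = "->"), ": ",
                                             conditionMessage(e)))
    prox[[paste(pr, collapse = "->")]] <- res
  }
  rep@proximity <- prox
  rep@provenance <- c(rep@provenance, list(
    package = "cystmorph",
    version = as.character(utils::packageVersion("cystmorph")),
    thresholds_nm = thresholds,
    seed = seed,
    scene_metadata = scene@metadata[setdiff(names(scene@metadata),
                                            "groundTruth")]))
  rep
}

#' Serialize a morphometry report to JSON (+ optional CSV tables)
#'
#' Percentages and ratios are written at full precision; the JSON is
#' byte-stable for identical inputs, so repeated runs of the same scene and
#' configuration produce identical files.
#'
#' @param report a [MorphometryReport-class].
#' @param path JSON output path, or NULL to return the JSON string.
#' @param csvPrefix when non-NULL, also write
#'   \code{<csvPrefix>_organelles.csv} and \code{<csvPrefix>_ratios.csv}.
#' @return path or JSON string.
#' @export
reportJSON <- function(report, path = NULL, csvPrefix = NULL) {
  prox <- lapply(report@proximity, function(p) list(
    source = p@source, target = p@target,
    thresholds_nm = p@thresholds,
    area_fractions = p@areaFractions,
    exclusive_band_fractions = p@exclusiveFractions,
    min_distance_nm = p@minDistance, max_distance_nm = p@maxDistance))
  x <- list(schema = "cystmorph-report/1",
            per_organelle = report@perOrganelle,
            ratios = report@ratios,
            proximity = prox,
            provenance = report@provenance)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         dataframe = "rows")
  if (!is.null(csvPrefix)) {
    utils::write.csv(report@perOrganelle,
                     paste0(csvPrefix, "_organelles.csv"), row.names = FALSE)
    utils::write.csv(report@ratios, paste0(csvPrefix, "_ratios.csv"),
                     row.names = FALSE)
  }
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(path)
}
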