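#' @include icosphere.R
NULL

# --- direction / rotation helpers -------------------------------------------

.fibonacciDirections <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

.randomRotation <- function() {
  m <- matrix(stats::rnorm(9), 3L)
  qr_ <- qr(m)
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

.anyTangent <- function(u) {
  a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  t1 <- a - sum(a * u) * u
  t1 / sqrt(sum(t1^2))
}

# normal truncated at +/- 2 SD and at zero
.truncNorm <- function(n, mean, sd) {
  lo <- max(mean - 2 * sd, .Machine$double.eps)
  hi <- mean + 2 * sd
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(2L * n, mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

# --- wrinkled sphere ---------------------------------------------------------

#' Parameters for the wrinkled-sphere generator
#'
#' Defaults reproduce the ridge-dimension statistics measured on the cyst
#' plasma membrane: length 406 +/- 90.9 nm, width 140.6 +/- 44.2 nm,
#' Gaussian-sampled and truncated at 2 SD. The ridge relief height is not a
#' measured quantity; the 80 nm default gives sub-resolution relief of the
#' same order as the ridge width.
#'
#' @param nRidges number of ridges to place.
#' @param lengthMean,lengthSd ridge length distribution, nm.
#' @param widthMean,widthSd ridge width distribution, nm.
#' @param height ridge relief height, nm.
#' @param seed integer RNG seed.
#' @return a \code{WrinkleGenParams} list.
#' @export
WrinkleGenParams <- function(nRidges = 60L, lengthMean = 406, lengthSd = 90.9,
                             widthMean = 140.6, widthSd = 44.2,
                             height = 80, seed = 42L) {
  stopifnot(nRidges >= 0, lengthMean > 0, widthMean > 0, height > 0,
            lengthSd >= 0, widthSd >= 0)
  structure(list(nRidges = as.integer(nRidges), lengthMean = lengthMean,
                 lengthSd = lengthSd, widthMean = widthMean,
                 widthSd = widthSd, height = height, seed = as.integer(seed)),
            class = "WrinkleGenParams")
}

#' Synthetic wrinkled sphere with ground-truth ridge table
#'
#' Stamps \code{nRidges} non-intersecting elliptic-paraboloid ridges
#' (radial displacement \eqn{h (1 - q^2)} inside an elliptical footprint of
#' full axes length x width) onto an icosphere, at rejection-sampled
#' locations with random in-plane orientations. Ridge dimensions are drawn
#' from the configured Gaussians truncated at 2 SD. The ground-truth table
#' (one row per ridge: centre, axis, length, width) is attached as
#' \code{attr(mesh, "groundTruth")}, and the un-wrinkled base sphere area as
#' \code{attr(mesh, "baseArea")}.
#'
#' @param radius sphere radius, nm.
#' @param params a [WrinkleGenParams()] list.
#' @param subdivisions icosphere subdivision level, or \code{NULL} (default)
#'   to pick the smallest level whose mean edge length is at most a quarter
#'   of the mean ridge width (so a ridge spans at least 4 edges across,
#'   keeping the narrow ridge dimension resolvable).
#' @param maxTries placement attempts per ridge before giving up.
#' @return a [TriMesh-class] with ground-truth attributes.
#' @export
makeWrinkledSphere <- function(radius, params = WrinkleGenParams(),
                               subdivisions = NULL, maxTries = 2000L) {
  stopifnot(radius > 0, inherits(params, "WrinkleGenParams"))
  if (is.null(subdivisions)) {
    need <- 16 * pi * radius^2 * 16 / (sqrt(3) * 20 * params$widthMean^2)
    subdivisions <- min(9L, max(0L, ceiling(log(need, base = 4))))
  }
  mesh <- makeIcosphere(radius, subdivisions, name = "wrinkled_sphere")
  baseArea <- surfaceArea(mesh)
  meanEdge <- sqrt(4 * baseArea / (nrow(mesh@faces) * sqrt(3)))
  if (params$nRidges > 0 && meanEdge > params$widthMean / 2)
    warning(sprintf(paste0("mesh edge length (%.0f nm) exceeds half the mean ",
                           "ridge width (%.0f nm); ridges are under-resolved"),
                    meanEdge, params$widthMean))
  gt <- data.frame()
  if (params$nRidges > 0) {
    set.seed(params$seed)
    L <- .truncNorm(params$nRidges, params$lengthMean, params$lengthSd)
    W <- pmin(.truncNorm(params$nRidges, params$widthMean, params$widthSd), L)
    centers <- matrix(NA_real_, params$nRidges, 3L)
    axes <- matrix(NA_real_, params$nRidges, 3L)
    placed <- 0L
    tries <- 0L
    while (placed < params$nRidges) {
      tries <- tries + 1L
      if (tries > maxTries * params$nRidges)
        stop("could not place ", params$nRidges,
             " non-intersecting ridges; reduce nRidges or ridge size")
      u <- stats::rnorm(3L)
      u <- u / sqrt(sum(u^2))
      ok <- TRUE
      if (placed > 0L) {
        cosSep <- centers[seq_len(placed), , drop = FALSE] %*% u
        sep <- acos(pmin(pmax(cosSep, -1), 1)) * radius
        minSep <- (L[seq_len(placed)] + L[placed + 1L]) / 2 + params$widthMean
        ok <- all(sep > minSep)
      }
      if (!ok) next
      placed <- placed + 1L
      centers[placed, ] <- u
      t1 <- .anyTangent(u)
      th <- stats::runif(1L, 0, pi)
      t2 <- c(u[2] * t1[3] - u[3] * t1[2],
              u[3] * t1[1] - u[1] * t1[3],
              u[1] * t1[2] - u[2] * t1[1])
      axes[placed, ] <- cos(th) * t1 + sin(th) * t2
    }
    v <- mesh@vertices
    vhat <- v / sqrt(rowSums(v^2))
    for (k in seq_len(params$nRidges)) {
      u <- centers[k, ]
      a1 <- axes[k, ]
      a2 <- c(u[2] * a1[3] - u[3] * a1[2],
              u[3] * a1[1] - u[1] * a1[3],
              u[1] * a1[2] - u[2] * a1[1])
      cosCut <- cos(0.75 * L[k] / radius)
      cand <- which(vhat %*% u > cosCut)
      if (!length(cand)) next
      rel <- sweep(v[cand, , drop = FALSE], 2L, radius * u)
      uu <- rel %*% a1
      ww <- rel %*% a2
      q2 <- (2 * uu / L[k])^2 + (2 * ww / W[k])^2
      inside <- q2 < 1
      if (!any(inside)) next
      d <- params$height * (1 - q2[inside])
      idx <- cand[inside]
      v[idx, ] <- v[idx, ] + vhat[idx, , drop = FALSE] * d
    }
    mesh@vertices <- v
    gt <- data.frame(ridge = seq_len(params$nRidges),
                     cx = centers[, 1] * radius, cy = centers[, 2] * radius,
                     cz = centers[, 3] * radius,
                     ax = axes[, 1], ay = axes[, 2], az = axes[, 3],
                     length = L, width = W, height = params$height)
  }
  attr(mesh, "groundTruth") <- gt
  attr(mesh, "baseArea") <- baseArea
  attr(mesh, "subdivisions") <- subdivisions
  mesh
}

# --- two-sphere analytic fixture --------------------------------------------

#' Two-sphere proximity fixture
#'
#' Two icospheres named \code{A} and \code{B} with centres \code{d} apart
#' along x: the analytic test scene for proximity mapping (the proximal area
#' fraction of A at threshold t has a spherical-cap closed form).
#'
#' @param rA,rB sphere radii, nm.
#' @param d centre separation, nm.
#' @param subdivisions icosphere subdivision level.
#' @return an [OrganelleScene-class]; overlapping configurations
#'   (\code{d < rA + rB}) are flagged in \code{metadata$overlapping}.
#' @export
makeTwoSphereScene <- function(rA, rB, d, subdivisions = 4L) {
  stopifnot(rA > 0, rB > 0, d > 0)
  A <- makeIcosphere(rA, subdivisions, center = c(0, 0, 0), name = "A")
  B <- makeIcosphere(rB, subdivisions, center = c(d, 0, 0), name = "B")
  OrganelleScene(list(A = A, B = B),
                 metadata = list(rA = rA, rB = rB, d = d,
                                 subdivisions = as.integer(subdivisions),
                                 overlapping = d < rA + rB))
}

#' Spherical-cap closed form for two-sphere proximity fractions
#'
#' For spheres of radii \code{rA}, \code{rB} with centres \code{d} apart
#' (\code{d > rA + rB}), the fraction of sphere A's surface within distance
#' \code{t} of sphere B is the normalised spherical-cap area
#' \eqn{(1 - \cos\theta^*)/2} with
#' \eqn{\cos\theta^* = (rA^2 + d^2 - (rB + t)^2) / (2 rA d)}; 0 when no
#' point qualifies, 1 when all do.
#'
#' @param rA,rB,d geometry, nm.
#' @param t distance threshold, nm.
#' @return fraction in [0, 1].
#' @export
sphereCapFraction <- function(rA, rB, d, t) {
  ct <- (rA^2 + d^2 - (rB + t)^2) / (2 * rA * d)
  if (ct >= 1) return(0)
  if (ct <= -1) return(1)
  (1 - ct) / 2
}

# --- toy cyst ----------------------------------------------------------------

#' Configuration for the toy cyst scene
#'
#' Defaults emulate the reconstructed cyst architecture: an 18.8 um diameter
#' cell (radius 9400 nm), a central chloroplast occupying ~29% of the cell
#' volume with radial protrusions tipped by starch grains, a pyrenoid at 5%
#' of the chloroplast volume, a peripheral flattened nucleus, peripheral
#' mitochondria (a subset parked at the configured gap from the protrusion
#' tips), and many cytosolic lipid droplets. Fractions are cell-volume
#' fractions; the droplet fraction sits below the reported range because a
#' sphere-packed cytosolic shell saturates earlier than the real, highly
#' non-convex cytosol.
#'
#' @param cellRadius nm (default 9400).
#' @param chloroplastFraction,LDFraction,nucleusFraction,mitoFraction
#'   cell-volume fractions (defaults 0.29, 0.08, 0.023, 0.02).
#' @param pyrenoidOfChloroplastFraction pyrenoid / chloroplast volume ratio
#'   (default 0.05).
#' @param nMitochondria,nLDs,nProtrusions counts (defaults 36, 400, 6).
#' @param proximityOffset target surface gap between protrusion-tip
#'   mitochondria and the chloroplast/starch tip, nm (default 50).
#' @param protrusionHeight,protrusionAngle bump height (nm) and angular
#'   footprint radius (rad) of each protrusion.
#' @param starchRadius starch grain radius, nm.
#' @param seed integer RNG seed.
#' @return a \code{ToyCystConfig} list.
#' @export
ToyCystConfig <- function(cellRadius = 9400,
                          chloroplastFraction = 0.29,
                          LDFraction = 0.08,
                          nucleusFraction = 0.023,
                          mitoFraction = 0.02,
                          pyrenoidOfChloroplastFraction = 0.05,
                          nMitochondria = 36L, nLDs = 400L,
                          nProtrusions = 6L,
                          proximityOffset = 50,
                          protrusionHeight = 1200,
                          protrusionAngle = 0.28,
                          starchRadius = 400,
                          seed = 1L) {
  fr <- c(chloroplastFraction, LDFraction, nucleusFraction, mitoFraction)
  if (any(fr <= 0) || any(fr >= 1) || sum(fr) >= 1)
    stop("organelle volume fractions must lie in (0,1) and sum below 1")
  if (proximityOffset < 0) stop("proximityOffset must be >= 0")
  structure(list(cellRadius = cellRadius,
                 chloroplastFraction = chloroplastFraction,
                 LDFraction = LDFraction, nucleusFraction = nucleusFraction,
                 mitoFraction = mitoFraction,
                 pyrenoidOfChloroplastFraction = pyrenoidOfChloroplastFraction,
                 nMitochondria = as.integer(nMitochondria),
                 nLDs = as.integer(nLDs),
                 nProtrusions = as.integer(nProtrusions),
                 proximityOffset = proximityOffset,
                 protrusionHeight = protrusionHeight,
                 protrusionAngle = protrusionAngle,
                 starchRadius = starchRadius,
                 seed = as.integer(seed)),
            class = "ToyCystConfig")
}

# quadrature oracles for the protruded chloroplast (radial graph surface
# r(gamma) = rc + h cos^2(pi gamma / (2 thetap)) inside each bump)
.protrusionVolumeGain <- function(rc, h, thetap) {
  f <- function(g) {
    prof <- cos(pi * g / (2 * thetap))^2
    ((rc + h * prof)^3 - rc^3) / 3 * sin(g) * 2 * pi
  }
  stats::integrate(f, 0, thetap, rel.tol = 1e-10)$value
}

.protrusionAreaGain <- function(rc, h, thetap) {
  r <- function(g) rc + h * cos(pi * g / (2 * thetap))^2
  dr <- function(g) -h * pi / thetap * cos(pi * g / (2 * thetap)) *
    sin(pi * g / (2 * thetap))
  f <- function(g) 2 * pi * sin(g) * r(g) * sqrt(r(g)^2 + dr(g)^2)
  cap <- stats::integrate(f, 0, thetap, rel.tol = 1e-10)$value
  capSphere <- 2 * pi * rc^2 * (1 - cos(thetap))
  cap - capSphere
}

# stamp azimuthally symmetric radial bumps on a sphere mesh
.stampProtrusions <- function(mesh, dirs, h, thetap) {
  v <- mesh@vertices
  vhat <- v / sqrt(rowSums(v^2))
  for (k in seq_len(nrow(dirs))) {
    u <- dirs[k, ]
    cosg <- pmin(pmax(vhat %*% u, -1), 1)
    g <- acos(cosg)
    inside <- which(g < thetap)
    if (!length(inside)) next
    prof <- cos(pi * g[inside] / (2 * thetap))^2
    v[inside, ] <- v[inside, ] + vhat[inside, , drop = FALSE] * (h * prof)
  }
  mesh@vertices <- v
  mesh
}

#' Synthetic cyst scene with analytic ground truth
#'
#' Builds a deterministic (seeded) organelle scene emulating the cyst
#' architecture (see [ToyCystConfig()]) and records, for every organelle,
#' the generator's reference volume and area (exact formulas for spheres and
#' ellipsoids; adaptive quadrature of the radial bump profile for the
#' protruded chloroplast) together with the nominal mitochondrion-tip gap.
#' The ground-truth table is stored in \code{metadata$groundTruth}; the
#' scene's meshes are all watertight and outward-oriented.
#'
#' Placement uses random sequential addition with rejection: protrusions sit
#' on octahedral axes (randomly rotated); the nucleus takes the direction
#' clearest of protrusions; mitochondria and droplets are parked in the
#' cytosolic shell with pairwise overlap rejection. Each placement stage
#' draws from its own seeded substream, so e.g. adding droplets does not
#' perturb mitochondrion positions.
#'
#' @param config a [ToyCystConfig()] list.
#' @param maxTries placement attempts per object.
#' @return an [OrganelleScene-class].
#' @export
makeToyCyst <- function(config = ToyCystConfig(), maxTries = 20000L) {
  stopifnot(inherits(config, "ToyCystConfig"))
  R <- config$cellRadius
  Vcell <- 4 / 3 * pi * R^3
  rc <- R * config$chloroplastFraction^(1 / 3)
  h <- config$protrusionHeight
  thetap <- config$protrusionAngle
  gap <- config$proximityOffset
  margin <- 50  # generic clearance, nm

  gt <- list()
  addGT <- function(name, class, volume, area, note = "") {
    gt[[length(gt) + 1L]] <<- data.frame(name = name, class = class,
                                         volume_nm3 = volume, area_nm2 = area,
                                         note = note)
  }

  # cell boundary
  cell <- makeIcosphere(R, 4L, name = "cell")
  addGT("cell", "cell", Vcell, 4 * pi * R^2)

  # chloroplast with protrusions on (rotated) octahedral axes
  set.seed(config$seed + 11L)
  rot <- .randomRotation()
  dirs <- if (config$nProtrusions == 6L) {
    rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0), c(0, 0, 1),
          c(0, 0, -1)) %*% t(rot)
  } else {
    .fibonacciDirections(config$nProtrusions) %*% t(rot)
  }
  chl <- makeIcosphere(rc, 5L, name = "chloroplast")
  chl <- .stampProtrusions(chl, dirs, h, thetap)
  Vchl <- 4 / 3 * pi * rc^3 +
    config$nProtrusions * .protrusionVolumeGain(rc, h, thetap)
  Achl <- 4 * pi * rc^2 + config$nProtrusions * .protrusionAreaGain(rc, h, thetap)
  addGT("chloroplast", "chloroplast", Vchl, Achl,
        sprintf("%d protrusions, quadrature reference", config$nProtrusions))

  # pyrenoid: central sphere at the configured chloroplast-volume fraction
  rp <- (3 * config$pyrenoidOfChloroplastFraction * Vchl / (4 * pi))^(1 / 3)
  pyr <- makeIcosphere(rp, 4L, name = "pyrenoid")
  addGT("pyrenoid", "pyrenoid", 4 / 3 * pi * rp^3, 4 * pi * rp^2,
        sprintf("%.3g of chloroplast volume",
                config$pyrenoidOfChloroplastFraction))

  meshes <- list(chloroplast = chl, pyrenoid = pyr)

  # starch grains tangent to each protrusion tip from inside
  rs <- config$starchRadius
  for (k in seq_len(config$nProtrusions)) {
    cs <- (rc + h - rs) * dirs[k, ]
    st <- makeIcosphere(rs, 3L, center = cs, name = sprintf("starch_%d", k))
    meshes[[st@name]] <- st
    addGT(st@name, "starch", 4 / 3 * pi * rs^3, 4 * pi * rs^2)
  }

  # nucleus: oblate ellipsoid (flat axis radial) in the clearest direction
  set.seed(config$seed + 13L)
  Vn <- config$nucleusFraction * Vcell
  cn <- 0.38 * (R - rc)
  an <- sqrt(3 * Vn / (4 * pi * cn))
  cand <- .fibonacciDirections(512L)
  clearance <- apply(cand, 1L, function(u)
    min(acos(pmin(pmax(dirs %*% u, -1), 1))))
  un <- cand[which.max(clearance), ]
  r0 <- rc + cn + 2 * margin
  t1 <- .anyTangent(un)
  t2 <- c(un[2] * t1[3] - un[3] * t1[2], un[3] * t1[1] - un[1] * t1[3],
          un[1] * t1[2] - un[2] * t1[1])
  nucAxes <- cbind(t1, t2, un)
  nuc <- makeEllipsoid(c(an, an, cn), 4L, center = r0 * un, axes = nucAxes,
                       name = "nucleus")
  if (max(sqrt(rowSums(nuc@vertices^2))) > R - margin ||
      min(sqrt(rowSums(nuc@vertices^2))) < rc + margin / 2)
    stop("nucleus does not fit in the cytosolic shell; ",
         "reduce nucleusFraction or chloroplastFraction")
  meshes$nucleus <- nuc
  addGT("nucleus", "nucleus", Vn, NA_real_, "oblate ellipsoid; area from mesh")

  # mitochondria: prolate 2:1 ellipsoids, long axis tangential; the first
  # nProtrusions sit at `gap` from the protrusion tips
  set.seed(config$seed + 17L)
  nm <- config$nMitochondria
  Vm <- config$mitoFraction * Vcell / nm
  sm <- (3 * Vm / (8 * pi))^(1 / 3)   # semi-axes (2 sm, sm, sm)
  mitoCenters <- matrix(NA_real_, nm, 3L)
  mitoLong <- matrix(NA_real_, nm, 3L)
  placedPts <- list()  # (center, radius) spheres for cheap overlap rejection
  rejectOverlap <- function(c0, rad) {
    if (!length(placedPts)) return(FALSE)
    for (p in placedPts)
      if (sqrt(sum((c0 - p$c)^2)) < rad + p$r + margin / 2) return(TRUE)
    FALSE
  }
  nTip <- min(nm, config$nProtrusions)
  for (k in seq_len(nTip)) {
    u <- dirs[k, ]
    c0 <- (rc + h + gap + sm) * u
    a1 <- .anyTangent(u)
    mitoCenters[k, ] <- c0
    mitoLong[k, ] <- a1
    placedPts[[length(placedPts) + 1L]] <- list(c = c0, r = 2 * sm)
  }
  if (nm > nTip) {
    bandLo <- rc + margin + sm
    bandHi <- R - margin - sm
    coneGuard <- thetap + atan(2 * sm / bandLo) + 0.05
    nucGuard <- atan(an / r0) + atan(2 * sm / bandLo) + 0.05
    placed <- nTip
    tries <- 0L
    while (placed < nm) {
      tries <- tries + 1L
      if (tries > maxTries)
        stop("could not place mitochondria; lower mitoFraction or counts")
      u <- stats::rnorm(3L); u <- u / sqrt(sum(u^2))
      if (min(acos(pmin(pmax(dirs %*% u, -1), 1))) < coneGuard) next
      if (acos(min(max(sum(un * u), -1), 1)) < nucGuard) next
      rr <- stats::runif(1L, bandLo, bandHi)
      c0 <- rr * u
      if (rejectOverlap(c0, 2 * sm)) next
      placed <- placed + 1L
      mitoCenters[placed, ] <- c0
      mitoLong[placed, ] <- .anyTangent(u)
      placedPts[[length(placedPts) + 1L]] <- list(c = c0, r = 2 * sm)
    }
  }
  for (k in seq_len(nm)) {
    u <- mitoCenters[k, ] / sqrt(sum(mitoCenters[k, ]^2))
    a1 <- mitoLong[k, ]
    a2 <- c(u[2] * a1[3] - u[3] * a1[2], u[3] * a1[1] - u[1] * a1[3],
            u[1] * a1[2] - u[2] * a1[1])
    mt <- makeEllipsoid(c(2 * sm, sm, sm), 3L, center = mitoCenters[k, ],
                        axes = cbind(a1, a2, u),
                        name = sprintf("mitochondrion_%d", k))
    meshes[[mt@name]] <- mt
    addGT(mt@name, "mitochondria", Vm, NA_real_,
          if (k <= nTip) sprintf("tip-parked, nominal gap %g nm", gap) else "")
  }

  # lipid droplets: random sequential addition in the cytosolic shell
  set.seed(config$seed + 19L)
  nl <- config$nLDs
  Vl <- config$LDFraction * Vcell / nl
  rl <- (3 * Vl / (4 * pi))^(1 / 3)
  bandLo <- rc + margin + rl
  bandHi <- R - margin - rl
  if (bandLo >= bandHi)
    stop("lipid droplets too large for the cytosolic shell; raise nLDs")
  coneGuard <- thetap + atan(rl / bandLo) + 0.03
  nucGuard <- atan(an / r0) + atan(rl / bandLo) + 0.03
  ldTemplate <- makeIcosphere(rl, 3L)
  placed <- 0L
  tries <- 0L
  while (placed < nl) {
    tries <- tries + 1L
    if (tries > maxTries * 10L)
      stop("could not pack ", nl, " lipid droplets; lower LDFraction")
    u <- stats::rnorm(3L); u <- u / sqrt(sum(u^2))
    if (min(acos(pmin(pmax(dirs %*% u, -1), 1))) < coneGuard) next
    if (acos(min(max(sum(un * u), -1), 1)) < nucGuard) next
    rr <- (stats::runif(1L, bandLo^3, bandHi^3))^(1 / 3)
    c0 <- rr * u
    if (rejectOverlap(c0, rl)) next
    placed <- placed + 1L
    ld <- ldTemplate
    ld@vertices <- sweep(ld@vertices, 2L, c0, "+")
    ld@name <- sprintf("LD_%d", placed)
    meshes[[ld@name]] <- ld
    placedPts[[length(placedPts) + 1L]] <- list(c = c0, r = rl)
    addGT(ld@name, "LD", Vl, 4 * pi * rl^2)
  }

  gtTab <- do.call(rbind, gt)
  # fill mesh-derived areas where no closed form is recorded
  for (i in which(is.na(gtTab$area_nm2))) {
    nm_i <- gtTab$name[i]
    if (!is.null(meshes[[nm_i]]))
      gtTab$area_nm2[i] <- surfaceArea(meshes[[nm_i]])
  }
  OrganelleScene(meshes, cellBoundary = cell,
                 metadata = list(config = unclass(config),
                                 groundTruth = gtTab,
                                 proximity_offset_nm = gap,
                                 seed = config$seed))
}

# --- rasterization -----------------------------------------------------------

#' Rasterize an organelle scene into a label volume
#'
#' Point-in-mesh labelling on a regular grid (samples at index *
#' \code{voxelSize} after shifting the scene into the positive octant; the
#' shift is recorded in the metadata). Overlaps (nested organelles) are
#' resolved by priority: by default, smaller-bounding-box meshes are
#' rasterized first, so contained structures keep their own label.
#'
#' @param scene an [OrganelleScene-class].
#' @param voxelSize nm; must resolve the thinnest structure with >= 3 voxels.
#' @param priority optional character vector of mesh names, highest priority
#'   first.
#' @param includeCell also label the remaining cell interior (cytosol) using
#'   the cell boundary mesh, lowest priority.
#' @return a [LabelVolume-class] with labels 1..n in priority order.
#' @export
rasterizeScene <- function(scene, voxelSize, priority = NULL,
                           includeCell = FALSE) {
  stopifnot(is(scene, "OrganelleScene"), voxelSize > 0)
  meshes <- scene@meshes
  if (includeCell) {
    if (is.null(scene@cellBoundary)) stop("scene has no cell boundary")
    meshes$cell <- scene@cellBoundary
  }
  if (!length(meshes)) stop("scene has no meshes to rasterize")
  bboxes <- lapply(meshes, function(m) apply(m@vertices, 2L, range))
  for (nm in names(meshes)) {
    ext <- bboxes[[nm]][2, ] - bboxes[[nm]][1, ]
    if (min(ext) < 3 * voxelSize)
      stop("voxelSize too coarse: '", nm, "' spans fewer than 3 voxels (",
           sprintf("%.0f", min(ext)), " nm thinnest extent)")
  }
  if (is.null(priority)) {
    vol <- vapply(bboxes, function(b) prod(b[2, ] - b[1, ]), numeric(1))
    priority <- names(sort(vol))
  } else {
    if (!all(priority %in% names(meshes)))
      stop("priority names absent from scene")
    priority <- c(priority, setdiff(names(meshes), priority))
  }
  lo <- do.call(pmin, lapply(bboxes, function(b) b[1, ]))
  hi <- do.call(pmax, lapply(bboxes, function(b) b[2, ]))
  shift <- lo - 2 * voxelSize
  dims <- ceiling((hi - shift) / voxelSize) + 3L  # (x,y,z) sample counts
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  vox <- array(0L, dim = c(nz, ny, nx))
  labelMap <- stats::setNames(seq_along(priority), priority)
  for (nm in priority) {
    m <- meshes[[nm]]
    Vsh <- sweep(m@vertices, 2L, shift)
    inside <- cpp_voxelize(Vsh, m@faces, nz, ny, nx, voxelSize)
    put <- inside & (vox == 0L)
    vox[put] <- labelMap[[nm]]
  }
  out <- LabelVolume(vox, voxelSize, labelMap)
  attr(out, "shift") <- shift
  out
}
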