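# Synthetic undisturbed-soil CT phantoms with voxel-accurate ground truth.
# The generator emulates the obstacles that make field samples hard to
# segment: partial-volume mixed voxels at aggregate borders, organic
# debris with root-like gray values, unconnected root segments of multiple
# plants, inhomogeneous moisture, and an optional container wall.

#' Phantom specification
#'
#' Defaults describe a 25.6 mm cube of loamy field soil at 0.1 mm voxels:
#' three unconnected root segments (cut roots of multiple plants, as in a
#' field core), mineral aggregates filling half the volume, twenty organic
#' debris blobs below the component-size filter, and one-voxel
#' partial-volume blur.
#'
#' @param shape grid dimensions (slices, rows, columns), each >= 32.
#' @param voxelSize isotropic voxel edge length in mm.
#' @param nRoots number of roots.
#' @param rootRadiusRange root radius range in mm at the top of the root.
#' @param rootTaper fractional radius loss per mm of root length.
#' @param branchingProbability per-mm probability of spawning a lateral.
#' @param rootsConnected if TRUE all roots emerge from one crown point
#'   (single plant, connected system); if FALSE they are independent cut
#'   segments (multi-plant field core).
#' @param mineralFillFraction target volume fraction of mineral
#'   aggregates; must be <= 0.9.
#' @param rootClearanceVoxels pore clearance carved around roots when
#'   aggregates are rasterized, in voxels. Roots in structured field soil
#'   predominantly follow pores and biopores and carry a rhizosphere water
#'   film, so aggregates are rarely flush against the root surface;
#'   default 1.5 voxels. Set 0 for fully flush contact.
#' @param aggregateRadiusRange semi-axis range of aggregate ellipsoids, mm.
#' @param nDebris number of organic debris blobs (root-like gray).
#' @param debrisSizeRangeVoxels voxel-count range of debris blobs; the
#'   default stays below the 10000-voxel size filter so that the filter is
#'   the mechanism that discriminates debris from roots.
#' @param grayMeans named gray means (air, water, root, mineral, wall) on
#'   the 16-bit scale; must respect the ordering air < root < mineral.
#'   The default wall gray is mineral-like (PVC); use a lower value for
#'   PE-like pots.
#' @param graySds per-class gray standard deviations.
#' @param blurSigma Gaussian sigma in voxels applied to the rendered
#'   volume; the partial-volume scale creating mixed voxels.
#' @param moistureGradient linear pore gray drift in gray levels per mm of
#'   depth (wetter, brighter pores with depth); 0 disables.
#' @param containerWall \code{"none"}, \code{"pvc_like"} (mineral-like
#'   gray) or \code{"pe_like"} (low gray).
#' @param seed random seed; identical spec and seed give bit-identical
#'   output.
#' @return validated spec list.
#' @export
phantomSpec <- function(shape = c(256L, 256L, 256L),
                        voxelSize = 0.1,
                        nRoots = 3L,
                        rootRadiusRange = c(0.6, 1.2),
                        rootTaper = 0.01,
                        branchingProbability = 0,
                        rootsConnected = FALSE,
                        mineralFillFraction = 0.5,
                        rootClearanceVoxels = 1.5,
                        aggregateRadiusRange = c(0.3, 1.2),
                        nDebris = 20L,
                        debrisSizeRangeVoxels = c(100, 3000),
                        grayMeans = c(air = 5000, water = 12000,
                                      root = 18000, mineral = 45000,
                                      wall = 43000),
                        graySds = c(air = 800, water = 800, root = 900,
                                    mineral = 1500, wall = 1200),
                        blurSigma = 1.0,
                        moistureGradient = 0,
                        containerWall = c("none", "pvc_like", "pe_like"),
                        seed = 1L) {
  containerWall <- match.arg(containerWall)
  if (length(shape) != 3L || any(shape < 32L))
    stop("shape must be three dimensions, each >= 32")
  if (voxelSize <= 0) stop("voxelSize must be positive")
  if (mineralFillFraction > 0.9)
    stop("infeasible mineral fill fraction > 0.9")
  if (any(rootRadiusRange <= 0) || any(aggregateRadiusRange <= 0))
    stop("all radius ranges must be positive")
  need <- c("air", "water", "root", "mineral", "wall")
  if (!all(need %in% names(grayMeans)) || !all(need %in% names(graySds)))
    stop("grayMeans and graySds must name air, water, root, mineral, wall")
  if (!(grayMeans["air"] < grayMeans["root"] &&
        grayMeans["root"] < grayMeans["mineral"]))
    stop("gray means must be ordered air < root < mineral")
  list(shape = as.integer(shape), voxelSize = voxelSize,
       nRoots = as.integer(nRoots), rootRadiusRange = rootRadiusRange,
       rootTaper = rootTaper, branchingProbability = branchingProbability,
       rootsConnected = isTRUE(rootsConnected),
       mineralFillFraction = mineralFillFraction,
       rootClearanceVoxels = rootClearanceVoxels,
       aggregateRadiusRange = aggregateRadiusRange,
       nDebris = as.integer(nDebris),
       debrisSizeRangeVoxels = debrisSizeRangeVoxels,
       grayMeans = grayMeans, graySds = graySds, blurSigma = blurSigma,
       moistureGradient = moistureGradient, containerWall = containerWall,
       seed = as.integer(seed))
}

# one random-walk centerline with tapering radius; coordinates are 0-based
# continuous voxel positions, radii in voxels. Roots run roughly along +z.
.growCenterline <- function(start, dims, r0Vox, taperPerVox, wobble = 0.05,
                            maxLen = Inf) {
  pts <- list(start)
  dir <- c(1, rnorm(2, 0, 0.15))
  dir <- dir / sqrt(sum(dir^2))
  p <- start
  len <- 0
  rmin <- 0.5
  repeat {
    dir <- dir + c(0.08, 0, 0) + rnorm(3, 0, wobble) # pull downwards
    if (dir[1] < 0.2) dir[1] <- 0.2                  # never turn back up
    dir <- dir / sqrt(sum(dir^2))
    p <- p + dir
    len <- len + 1
    r <- max(rmin, r0Vox * (1 - taperPerVox * len))
    if (p[1] < 1 || p[1] > dims[1] - 2 || p[2] < 1 || p[2] > dims[2] - 2 ||
        p[3] < 1 || p[3] > dims[3] - 2 || len >= maxLen)
      break
    pts[[length(pts) + 1L]] <- p
  }
  cl <- do.call(rbind, pts)
  radii <- pmax(rmin, r0Vox * (1 - taperPerVox * (seq_len(nrow(cl)) - 1)))
  list(centerline = cl, radiiVox = radii)
}

# deterministic root geometries; each root is confined to its own lane of
# the cross-section so that unconnected roots stay unconnected
.makeRootGeometries <- function(spec, nRoots) {
  dims <- spec$shape
  vox <- spec$voxelSize
  roots <- list()
  ncell <- ceiling(sqrt(nRoots))
  cellY <- (dims[2] - 2) / ncell
  cellX <- (dims[3] - 2) / max(1, ceiling(nRoots / ncell))
  crown <- c(2, dims[2] / 2, dims[3] / 2) +
    c(0, rnorm(2, 0, dims[2] / 20))
  for (i in seq_len(nRoots)) {
    r0Mm <- runif(1, spec$rootRadiusRange[1], spec$rootRadiusRange[2])
    r0Vox <- r0Mm / vox
    if (r0Vox < 1) {
      warning("root radius below one voxel; clamped to one voxel")
      r0Vox <- 1
    }
    if (spec$rootsConnected) {
      start <- crown
    } else {
      iy <- (i - 1) %% ncell
      ix <- (i - 1) %/% ncell
      start <- c(runif(1, 2, max(3, dims[1] / 6)),
                 1 + cellY * (iy + runif(1, 0.35, 0.65)),
                 1 + cellX * (ix + runif(1, 0.35, 0.65)))
    }
    geom <- .growCenterline(start, dims, r0Vox, spec$rootTaper * vox)
    root <- list(centerline = geom$centerline, radiiVox = geom$radiiVox)
    roots[[length(roots) + 1L]] <- root
    # laterals: spawned along the parent with the per-mm branching rate
    if (spec$branchingProbability > 0) {
      nPts <- nrow(geom$centerline)
      pBranch <- spec$branchingProbability * vox
      at <- which(runif(nPts) < pBranch)
      for (j in at) {
        child <- .growCenterline(geom$centerline[j, ], dims,
                                 max(1, geom$radiiVox[j] * 0.6),
                                 spec$rootTaper * vox, wobble = 0.25,
                                 maxLen = nPts / 2)
        roots[[length(roots) + 1L]] <-
          list(centerline = child$centerline,
               radiiVox = child$radiiVox, parent = i)
      }
    }
  }
  roots
}

.segmentsOf <- function(root) {
  cl <- root$centerline
  r <- root$radiiVox
  cbind(cl[-nrow(cl), , drop = FALSE], cl[-1, , drop = FALSE],
        r[-length(r)], r[-1])
}

# analytic tube volume in mm^3 from centerline and radii (truncated cones)
.analyticRootVolume <- function(roots, vox) {
  tot <- 0
  for (root in roots) {
    cl <- root$centerline
    if (nrow(cl) < 2) next
    dl <- sqrt(rowSums((cl[-1, , drop = FALSE] -
                          cl[-nrow(cl), , drop = FALSE])^2)) * vox
    r <- root$radiiVox * vox
    r0 <- r[-length(r)]; r1 <- r[-1]
    tot <- tot + sum(pi / 3 * dl * (r0^2 + r0 * r1 + r1^2))
  }
  tot
}

# analytic surface-weighted diameter histogram (lateral cone areas)
.truthSurfaceHistogram <- function(roots, vox, binWidth) {
  dia <- numeric(0); area <- numeric(0)
  for (root in roots) {
    cl <- root$centerline
    if (nrow(cl) < 2) next
    dl <- sqrt(rowSums((cl[-1, , drop = FALSE] -
                          cl[-nrow(cl), , drop = FALSE])^2)) * vox
    r <- root$radiiVox * vox
    rbar <- (r[-length(r)] + r[-1]) / 2
    dia <- c(dia, 2 * rbar)
    area <- c(area, 2 * pi * rbar * dl)
  }
  if (!length(dia))
    return(data.frame(bin_low_mm = numeric(0), bin_high_mm = numeric(0),
                      surface_mm2 = numeric(0), frequency = numeric(0)))
  nb <- max(1L, ceiling(max(dia) / binWidth))
  idx <- pmin(pmax(ceiling(dia / binWidth), 1L), nb)
  s <- vapply(seq_len(nb), function(b) sum(area[idx == b]), numeric(1))
  data.frame(bin_low_mm = binWidth * (seq_len(nb) - 1),
             bin_high_mm = binWidth * seq_len(nb),
             surface_mm2 = s, frequency = s / sum(s))
}

#' Generate a synthetic soil phantom with ground truth
#'
#' Roots are rendered as smooth tapering tubes along random-walk
#' centerlines, rasterized by a 3x supersampled coverage test (a voxel is
#' truth-foreground when at least half its sub-samples fall inside the
#' tube); minerals as overlapping random ellipsoids up to the target fill
#' fraction; debris as small blobs with root-like gray. Class gray values
#' are drawn per voxel (mean + Gaussian sd), the whole volume is blurred
#' by \code{blurSigma} to create partial-volume mixed voxels, and the
#' optional wall and moisture drift are applied. Truth masks come from the
#' pre-noise rasterization and are pairwise disjoint (roots displace
#' minerals; debris occupies pore space).
#'
#' @param spec a \code{\link{phantomSpec}}.
#' @return list with elements \code{volume} (a \linkS4class{VoxelVolume}),
#'   \code{truth} (a \linkS4class{PhantomTruth}) and \code{perRootMasks}
#'   (one truth \linkS4class{ROIMask} per root, useful for per-root recall).
#' @export
generatePhantom <- function(spec) {
  .withSeed(spec$seed, .generatePhantomImpl(spec, NULL))
}

.generatePhantomImpl <- function(spec, rootsOverride) {
  dims <- spec$shape
  vox <- spec$voxelSize
  n <- prod(dims)

  roots <- if (is.null(rootsOverride)) .makeRootGeometries(spec, spec$nRoots)
           else rootsOverride

  # root rasterization (supersampled), per root so truth keeps identities;
  # a single-sample pass with enlarged radii marks the rhizosphere pore
  # clearance that aggregates must keep open
  rootMask <- logical(n)
  clearMask <- logical(n)
  perRoot <- vector("list", length(roots))
  half <- ceiling(27 / 2)
  for (i in seq_along(roots)) {
    segs <- .segmentsOf(roots[[i]])
    cnt <- .raster_tubes_cpp(dims, segs, 3L)
    m <- cnt >= half
    dim(m) <- dims
    perRoot[[i]] <- m
    rootMask <- rootMask | m
    if (spec$rootClearanceVoxels > 0) {
      segsClear <- segs
      segsClear[, 7:8] <- segsClear[, 7:8] + spec$rootClearanceVoxels
      clearMask <- clearMask | (.raster_tubes_cpp(dims, segsClear, 1L) >= 1L)
    }
  }
  dim(rootMask) <- dims
  clearMask <- clearMask | rootMask
  dim(clearMask) <- dims

  # container wall: cylindrical shell over the full height
  wall <- array(FALSE, dims)
  if (spec$containerWall != "none") {
    cy <- (dims[2] + 1) / 2; cx <- (dims[3] + 1) / 2
    rw <- min(dims[2], dims[3]) / 2 - 2
    tw <- max(2, round(0.1 * rw))
    rr <- sqrt(outer((seq_len(dims[2]) - cy)^2,
                     (seq_len(dims[3]) - cx)^2, "+"))
    shell <- rr <= rw & rr >= rw - tw
    wall <- aperm(array(shell, c(dims[2], dims[3], dims[1])), c(3, 1, 2))
    wall <- wall & !rootMask
  }

  # mineral aggregates: enough overlapping ellipsoids for the target fill
  # (Poisson coverage: fill = 1 - exp(-k * vol / grid))
  aggR <- spec$aggregateRadiusRange / vox
  meanVol <- 4 / 3 * pi * mean(aggR)^3
  nAgg <- ceiling(-log(1 - spec$mineralFillFraction) * n / meanVol)
  ell <- cbind(runif(nAgg, 0, dims[1] - 1),
               runif(nAgg, 0, dims[2] - 1),
               runif(nAgg, 0, dims[3] - 1),
               matrix(runif(3 * nAgg, aggR[1], aggR[2]), ncol = 3))
  mineral <- .raster_ellipsoids_cpp(dims, ell)
  dim(mineral) <- dims
  # roots displace aggregates; the rhizosphere pore clearance stays open
  mineral <- mineral & !clearMask & !wall

  # organic debris blobs in pore space; centers drawn by rejection
  # sampling over the grid (deterministic under the seed)
  debris <- array(FALSE, dims)
  if (spec$nDebris > 0) {
    centers <- matrix(0, spec$nDebris, 3)
    for (i in seq_len(spec$nDebris)) {
      repeat {
        p <- ceiling(runif(3) * (dims - 2)) + 1
        if (!mineral[p[1], p[2], p[3]] && !rootMask[p[1], p[2], p[3]] &&
            !wall[p[1], p[2], p[3]]) break
      }
      centers[i, ] <- p
    }
    sz <- runif(spec$nDebris, spec$debrisSizeRangeVoxels[1],
                spec$debrisSizeRangeVoxels[2])
    rEq <- (3 * sz / (4 * pi))^(1 / 3)
    stretch <- matrix(runif(3 * spec$nDebris, 0.6, 1.7), ncol = 3)
    stretch <- stretch / exp(rowMeans(log(stretch)))  # volume-preserving
    dEll <- cbind(centers - 1, rEq * stretch)
    debris <- .raster_ellipsoids_cpp(dims, dEll)
    dim(debris) <- dims
    debris <- debris & !mineral & !rootMask & !wall
  }

  # gray rendering: per-class mean + Gaussian noise, then moisture drift,
  # partial-volume blur, and quantization to the 16-bit scale
  gm <- spec$grayMeans; gs <- spec$graySds
  gray <- rnorm(n, gm["air"], gs["air"])
  dim(gray) <- dims
  gray[mineral] <- rnorm(sum(mineral), gm["mineral"], gs["mineral"])
  gray[debris] <- rnorm(sum(debris), gm["root"], gs["root"])
  gray[rootMask] <- rnorm(sum(rootMask), gm["root"], gs["root"])
  if (any(wall)) {
    wallMean <- if (spec$containerWall == "pvc_like") gm["wall"]
                else (gm["air"] + gm["root"]) / 2
    gray[wall] <- rnorm(sum(wall), wallMean, gs["wall"])
  }
  if (spec$moistureGradient != 0) {
    pore <- !mineral & !rootMask & !debris & !wall
    zmm <- (slice.index(pore, 1) - 1) * vox
    gray[pore] <- gray[pore] + spec$moistureGradient * zmm[pore]
  }
  if (spec$blurSigma > 0) {
    gray <- .gauss3d_cpp(gray, dims, spec$blurSigma)
    dim(gray) <- dims
  }
  gray <- round(pmin(pmax(gray, 0), 65535))

  truthRoots <- lapply(roots, function(r)
    list(centerline = r$centerline + 1, radiusMm = r$radiiVox * vox))
  truth <- new("PhantomTruth",
    rootMask = roiMask(rootMask, "root_truth", vox),
    mineralMask = roiMask(mineral, "mineral_truth", vox),
    debrisMask = roiMask(debris, "debris_truth", vox),
    rootVolume = sum(rootMask) * vox^3,
    roots = truthRoots,
    surfaceHistogram = .truthSurfaceHistogram(roots, vox, vox))
  list(volume = voxelVolume(gray, vox),
       truth = truth, perRootMasks = lapply(perRoot, function(m)
         roiMask(m, "root_truth", vox)))
}

#' Generate a series of phantoms with increasing root content
#'
#' Roots accumulate across the series: phantom i contains the roots of
#' phantom i-1 plus additional ones, so ground-truth root volumes are
#' strictly increasing by construction. Seeds for the per-volume mineral
#' and noise fields derive deterministically from the base seed.
#'
#' @param baseSpec a \code{\link{phantomSpec}}; its \code{nRoots} is the
#'   root count of the first phantom.
#' @param nVolumes number of phantoms, >= 3.
#' @param rootsPerStep roots added per phantom (default 1); ignored when
#'   \code{targetVolumes} is given.
#' @param targetVolumes optional increasing vector of target root volumes
#'   in mm^3; roots are added until the analytic tube volume reaches each
#'   target.
#' @param seed base seed.
#' @return list of \code{list(volume, truth)} entries.
#' @export
phantomSeries <- function(baseSpec, nVolumes, rootsPerStep = 1L,
                          targetVolumes = NULL, seed = baseSpec$seed) {
  if (nVolumes < 3) stop("nVolumes must be >= 3")
  if (!is.null(targetVolumes)) {
    if (length(targetVolumes) != nVolumes || is.unsorted(targetVolumes,
                                                         strictly = TRUE))
      stop("targetVolumes must be strictly increasing, one per volume")
  }
  maxRoots <- if (is.null(targetVolumes))
    baseSpec$nRoots + rootsPerStep * (nVolumes - 1) else 10000L
  pool <- list()
  counts <- integer(nVolumes)
  .withSeed(seed, {
    if (is.null(targetVolumes)) {
      pool <- .makeRootGeometries(baseSpec, maxRoots)
      counts <- baseSpec$nRoots + rootsPerStep * (seq_len(nVolumes) - 1)
      # laterals enlarge the pool; map requested root counts onto it
      counts <- pmin(counts, length(pool))
    } else {
      vol <- 0
      for (i in seq_len(nVolumes)) {
        while (vol < targetVolumes[i] ||
               (i > 1 && length(pool) == counts[i - 1])) {
          more <- .makeRootGeometries(baseSpec, 1L)
          pool <- c(pool, more)
          vol <- .analyticRootVolume(pool, baseSpec$voxelSize)
        }
        counts[i] <- length(pool)
      }
    }
  })
  out <- vector("list", nVolumes)
  for (i in seq_len(nVolumes)) {
    speci <- baseSpec
    speci$seed <- baseSpec$seed + i
    res <- .withSeed(speci$seed,
                     .generatePhantomImpl(speci, pool[seq_len(counts[i])]))
    out[[i]] <- list(volume = res$volume, truth = res$truth)
  }
  out
}
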