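# Example-area material definition and gradient-refined surface
# determination: the operation that turns a gray volume (restricted to a
# domain) into a material mask with the boundary relocated to the gray
# gradient maximum.

#' Surface-determination parameters
#'
#' @param searchDistance positive integer, half-width in voxels of the
#'   profile sampled along the local gradient when relocating a boundary.
#'   Default 3: biased initial thresholds within +/- 3 voxels of the true
#'   edge are corrected.
#' @param smoothingSigma non-negative Gaussian sigma (voxels) applied
#'   before gradient estimation. Default 1.0 suppresses voxel noise while
#'   keeping partial-volume edges localized.
#' @param subvoxel refine the gradient maximum by a three-point parabolic
#'   fit before rounding back to the voxel grid.
#' @return a named list of validated parameters.
#' @export
surfaceParams <- function(searchDistance = 3L, smoothingSigma = 1.0,
                          subvoxel = TRUE) {
  if (searchDistance < 1) stop("searchDistance must be >= 1")
  if (smoothingSigma < 0) stop("smoothingSigma must be >= 0")
  list(searchDistance = as.integer(searchDistance),
       smoothingSigma = as.numeric(smoothingSigma),
       subvoxel = isTRUE(subvoxel))
}

#' Derive an initial threshold from example areas
#'
#' Computes gray-value statistics of operator-supplied background (air)
#' and material example voxels and returns the ISO-50 midpoint of the two
#' class means as the initial global threshold, together with the
#' orientation (whether material is the brighter class).
#'
#' @param volume a \linkS4class{VoxelVolume}.
#' @param examples a \linkS4class{MaterialExample}.
#' @param domain optional \linkS4class{ROIMask}; all example coordinates
#'   must lie inside it.
#' @return list with \code{threshold}, \code{materialBrighter}, and the
#'   class statistics \code{backgroundMean}, \code{materialMean},
#'   \code{backgroundSd}, \code{materialSd}.
#' @export
defineMaterialByExample <- function(volume, examples, domain = NULL) {
  stopifnot(is(volume, "VoxelVolume"), is(examples, "MaterialExample"))
  dims <- dim(volume)
  bgIdx <- .coordsToIdx(examples@backgroundVoxels, dims)
  mtIdx <- .coordsToIdx(examples@materialVoxels, dims)
  if (!is.null(domain)) {
    .checkSameShape(volume@data, domain@data)
    if (!all(domain@data[bgIdx]) || !all(domain@data[mtIdx]))
      stop("example coordinates must lie inside the domain")
  }
  bg <- volume@data[bgIdx]
  mt <- volume@data[mtIdx]
  bgMean <- mean(bg); mtMean <- mean(mt)
  if (bgMean == mtMean)
    stop("background and material example means are equal; ",
         "choose more distinctive example areas")
  list(threshold = (bgMean + mtMean) / 2,
       materialBrighter = mtMean > bgMean,
       backgroundMean = bgMean, materialMean = mtMean,
       backgroundSd = if (length(bg) > 1) sd(bg) else 0,
       materialSd = if (length(mt) > 1) sd(mt) else 0)
}

#' Gradient-refined surface determination
#'
#' Converts a gray volume, restricted to a domain, into a material mask.
#' The volume is first thresholded on the domain; then, for every boundary
#' voxel of that initial mask, the Gaussian-smoothed gray profile is
#' sampled along the local gradient direction over +/-
#' \code{searchDistance} voxels and the boundary is relocated to the
#' position of maximum gradient magnitude (optionally refined to sub-voxel
#' precision by a parabolic fit, then rounded back to the voxel grid).
#' Voxels between the old and the new boundary are reclassified. The same
#' gray value is thereby reinterpreted according to the gray values of the
#' neighboring voxels: a biased global threshold still yields a surface at
#' the partial-volume inflection point.
#'
#' The refinement is conservative (the output differs from the initial
#' thresholded mask only within \code{searchDistance} voxels of the
#' initial boundary), and voxels outside the domain contribute neither to
#' gradients nor to profiles (profiles truncate at the domain edge). Where
#' the local gradient is numerically zero the initial classification is
#' kept.
#'
#' @param volume a \linkS4class{VoxelVolume}.
#' @param threshold initial gray threshold, e.g. from
#'   \code{\link{defineMaterialByExample}}; must lie within the gray range
#'   of the domain.
#' @param domain optional \linkS4class{ROIMask} restricting the operation;
#'   default whole volume. The output is empty outside the domain.
#' @param materialBrighter is material the brighter class? Default TRUE
#'   (minerals and roots are brighter than air).
#' @param params see \code{\link{surfaceParams}}.
#' @param label role tag of the output mask.
#' @param .smoothed optional pre-computed Gaussian-smoothed gray array
#'   (matching \code{params$smoothingSigma}); avoids re-smoothing when
#'   several surfaces are determined on the same volume.
#' @return an \linkS4class{ROIMask} of the material.
#' @export
advancedSurfaceDetermination <- function(volume, threshold, domain = NULL,
                                         materialBrighter = TRUE,
                                         params = surfaceParams(),
                                         label = "material",
                                         .smoothed = NULL) {
  stopifnot(is(volume, "VoxelVolume"))
  dims <- dim(volume)
  if (is.null(domain)) {
    domArr <- array(TRUE, dims)
  } else {
    stopifnot(is(domain, "ROIMask"))
    .checkSameShape(volume@data, domain@data)
    domArr <- domain@data
  }
  if (!any(domArr)) stop("domain is empty")
  if (threshold < 0 || threshold > 65535)
    stop(sprintf("threshold %.1f outside the 16-bit gray range", threshold))

  init <- if (materialBrighter) domArr & (volume@data >= threshold)
          else domArr & (volume@data <= threshold)
  storage.mode(init) <- "integer"
  domInt <- domArr
  storage.mode(domInt) <- "integer"

  smoothed <- if (!is.null(.smoothed)) .smoothed
              else .gauss3d_cpp(as.numeric(volume@data), dim(volume),
                                params$smoothingSigma)
  bnd <- .boundary_in_domain_cpp(init, domInt, dims, 26L)
  bcoord <- .idxToCoords(which(bnd), dims) - 1L  # 0-based for C++
  mode(bcoord) <- "integer"
  refined <- .refine_surface_cpp(smoothed, init, domInt, dims, bcoord,
                                 params$searchDistance,
                                 materialBrighter, params$subvoxel)
  roiMask(array(refined == 1L, dims), label = label,
          voxelSize = volume@voxelSize)
}

#' Boundary voxels of a mask
#'
#' The foreground voxels with at least one background neighbor under the
#' stated connectivity; voxels beyond the grid edge count as background.
#' These are the "surface elements" used for the surface diameter
#' histogram.
#'
#' @param mask an \linkS4class{ROIMask}.
#' @param connectivity 6, 18 or 26 (default).
#' @return n x 3 matrix of 1-based (slice, row, column) coordinates.
#' @export
maskBoundary <- function(mask, connectivity = 26L) {
  stopifnot(is(mask, "ROIMask"))
  if (!(connectivity %in% c(6L, 18L, 26L)))
    stop("connectivity must be 6, 18 or 26")
  b <- .boundary3d_cpp(.maskInt(mask), dim(mask), as.integer(connectivity))
  .idxToCoords(which(b), dim(mask))
}
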