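# The five-step segmentation protocol for (possibly unconnected,
# multi-plant) root systems in undisturbed soil volumes:
#   1. surface determination of the mineral phase on the whole volume
#   2. dilation of the mineral ROI to absorb partial-volume mixed voxels
#   3. subtraction from the whole-volume ROI -> roots-and-pores domain
#   4. surface determination of the roots within that domain
#   5. connected-component labeling and size-threshold noise elimination

#' Protocol parameters
#'
#' @param soilExamples \linkS4class{MaterialExample} with air background
#'   and mineral material voxels (step 1).
#' @param rootExamples \linkS4class{MaterialExample} with air background
#'   and root material voxels inside the roots-and-pores domain (step 4).
#' @param dilationRadius dilation of the mineral ROI in voxels (step 2);
#'   0.5--1 voxel absorbs the mixed-voxel shell at aggregate borders.
#'   Default 1.
#' @param minComponentVoxels step-5 noise threshold; connected structures
#'   smaller than this are deleted. Default 10000.
#' @param connectivity component connectivity, default 26.
#' @param surface \code{\link{surfaceParams}} used by both surface
#'   determinations.
#' @param excludeMask optional \linkS4class{ROIMask} removed from the
#'   roots-and-pores domain in addition to the dilated mineral ROI, e.g. an
#'   explicit cylindrical wall mask for containers whose gray values do not
#'   resemble the mineral phase (PVC-like walls need no special handling:
#'   they segment with the minerals in step 1).
#' @return validated parameter list.
#' @export
protocolParams <- function(soilExamples, rootExamples,
                           dilationRadius = 1.0,
                           minComponentVoxels = 10000L,
                           connectivity = 26L,
                           surface = surfaceParams(),
                           excludeMask = NULL) {
  stopifnot(is(soilExamples, "MaterialExample"),
            is(rootExamples, "MaterialExample"))
  if (dilationRadius < 0) stop("dilationRadius must be >= 0")
  if (minComponentVoxels < 1) stop("minComponentVoxels must be >= 1")
  if (!(connectivity %in% c(6L, 18L, 26L)))
    stop("connectivity must be 6, 18 or 26")
  list(soilExamples = soilExamples, rootExamples = rootExamples,
       dilationRadius = as.numeric(dilationRadius),
       minComponentVoxels = as.integer(minComponentVoxels),
       connectivity = as.integer(connectivity),
       surface = surface, excludeMask = excludeMask)
}

#' Run the five-step root segmentation protocol
#'
#' Executes, in order: (1) gradient-refined surface determination of the
#' mineral phase on the whole volume; (2) dilation of the mineral ROI by
#' \code{dilationRadius} voxels, absorbing the mixed voxels that
#' partial-volume averaging creates at the border of soil aggregates to
#' air-filled pores (their gray values mimic roots and would otherwise
#' contaminate step 4); (3) subtraction of the dilated ROI from the
#' whole-volume ROI, leaving only roots and pores filled with air and
#' water; (4) surface determination of the roots restricted to that
#' domain; (5) connected-component labeling and deletion of all structures
#' smaller than \code{minComponentVoxels} connected voxels.
#'
#' The whole-volume ROI of step 3 is the full grid minus a one-voxel
#' frame, since frame voxels lack the full neighborhood needed for
#' gradient refinement. The final mask is disjoint from the dilated
#' mineral ROI by construction (asserted). The pipeline is deterministic:
#' identical volume and parameters give a bit-identical root mask.
#'
#' @param volume a \linkS4class{VoxelVolume}.
#' @param params see \code{\link{protocolParams}}.
#' @return a \linkS4class{SegmentationResult}.
#' @export
runProtocol <- function(volume, params) {
  stopifnot(is(volume, "VoxelVolume"))
  dims <- dim(volume)
  log <- list()
  note <- function(step, what, fg, extra = "") {
    log[[length(log) + 1L]] <<- data.frame(
      step = step, operation = what, foreground_voxels = fg,
      parameters = extra, stringsAsFactors = FALSE)
  }

  # the same smoothed gray field serves both surface determinations
  smoothed <- .gauss3d_cpp(as.numeric(volume@data), dims,
                           params$surface$smoothingSigma)

  # step 1: mineral surface determination on the whole volume
  thr1 <- defineMaterialByExample(volume, params$soilExamples)
  mineral <- advancedSurfaceDetermination(
    volume, thr1$threshold, domain = NULL,
    materialBrighter = thr1$materialBrighter,
    params = params$surface, label = "mineral", .smoothed = smoothed)
  note(1L, "mineral_surface_determination", foregroundCount(mineral),
       sprintf("threshold=%.1f", thr1$threshold))

  # step 2: add the mixed-voxel shell
  dilated <- dilateROI(mineral, params$dilationRadius,
                       label = "mineral_dilated")
  note(2L, "roi_dilation", foregroundCount(dilated),
       sprintf("radius=%.2f", params$dilationRadius))

  # step 3: whole volume (minus 1-voxel frame) minus dilated mineral ROI
  whole <- array(FALSE, dims)
  whole[2:(dims[1] - 1), 2:(dims[2] - 1), 2:(dims[3] - 1)] <- TRUE
  wholeMask <- roiMask(whole, label = "whole_volume",
                       voxelSize = volume@voxelSize)
  domain <- subtractROI(wholeMask, dilated, label = "roots_and_pores_domain")
  if (!is.null(params$excludeMask))
    domain <- subtractROI(domain, params$excludeMask,
                          label = "roots_and_pores_domain")
  if (foregroundCount(domain) == 0L)
    stop("configuration error: roots-and-pores domain is empty after ",
         "subtracting the dilated mineral ROI")
  note(3L, "roi_subtraction", foregroundCount(domain), "")

  # step 4: root surface determination within the domain
  thr2 <- defineMaterialByExample(volume, params$rootExamples,
                                  domain = domain)
  rootsRaw <- advancedSurfaceDetermination(
    volume, thr2$threshold, domain = domain,
    materialBrighter = thr2$materialBrighter,
    params = params$surface, label = "roots_raw", .smoothed = smoothed)
  note(4L, "root_surface_determination", foregroundCount(rootsRaw),
       sprintf("threshold=%.1f", thr2$threshold))

  # step 5: size-threshold noise elimination
  labeling <- labelComponents(rootsRaw, params$connectivity)
  filt <- sizeFilter(labeling, params$minComponentVoxels,
                     label = "roots_filtered")
  note(5L, "size_filter", foregroundCount(filt$mask),
       sprintf("min_voxels=%d retained=%d deleted=%d",
               params$minComponentVoxels, filt$retainedCount,
               filt$deletedCount))

  stopifnot(!any(filt$mask@data & dilated@data)) # disjointness invariant
  new("SegmentationResult",
      rootMask = filt$mask,
      rootVolume = rootVolume(filt$mask),
      componentCount = as.integer(filt$retainedCount),
      stepLog = do.call(rbind, log))
}

#' Root volume of a mask
#'
#' @param mask an \linkS4class{ROIMask}.
#' @param voxelSize voxel edge length in mm; defaults to the mask's own.
#' @return volume in mm^3 (foreground voxel count x voxel size cubed).
#' @export
rootVolume <- function(mask, voxelSize = mask@voxelSize) {
  stopifnot(is(mask, "ROIMask"))
  sum(mask@data) * voxelSize^3
}

#' Regress root dry mass on CT root volume
#'
#' Ordinary least squares of dry mass (g) on CT-reconstructed root volume,
#' the standard validation of CT segmentation against washed-and-dried
#' reference roots. When the CT volume is interpreted as a fresh-weight
#' equivalent (1 cm^3 ~ 1 g fresh weight), the slope is the implied
#' average dry-matter content of the roots.
#'
#' @param ctVolume numeric vector of CT root volumes.
#' @param dryMass numeric vector of root dry masses in g.
#' @param volumeUnit \code{"cm3"} (default) or \code{"mm3"}; used only to
#'   express the implied dry-matter content as g dry / g fresh.
#' @return list with slope, intercept, rSquared, pValue (t test of the OLS
#'   slope), n, and impliedDryMatterContent.
#' @export
regressVolumeVsMass <- function(ctVolume, dryMass,
                                volumeUnit = c("cm3", "mm3")) {
  volumeUnit <- match.arg(volumeUnit)
  if (length(ctVolume) != length(dryMass))
    stop("ctVolume and dryMass must have equal length")
  n <- length(ctVolume)
  if (n < 3) stop("at least 3 pairs are required")
  if (var(ctVolume) == 0)
    stop("degenerate x-variance: all CT volumes identical")
  fit <- lm(dryMass ~ ctVolume)
  sm <- summary(fit)
  slope <- unname(coef(fit)[2])
  list(slope = slope,
       intercept = unname(coef(fit)[1]),
       rSquared = sm$r.squared,
       pValue = unname(sm$coefficients[2, 4]),
       n = n,
       impliedDryMatterContent =
         slope * if (volumeUnit == "mm3") 1000 else 1)
}
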