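# Root diameter via local thickness: the diameter of the largest inscribed
# sphere containing each voxel, and its distribution over the root surface.

#' Thickness-analysis parameters
#'
#' @param minThickness,maxThickness clamp range for reported diameters in
#'   mm; values outside are clamped, never dropped. Defaults: one voxel
#'   (nothing thinner is resolvable) and 100 voxels.
#' @param binWidth histogram bin width in mm; default one voxel, matching
#'   the resolution at which diameters are distinguishable.
#' @param voxelSize voxel edge length in mm used to build the defaults.
#' @return validated parameter list.
#' @export
thicknessParams <- function(voxelSize,
                            minThickness = voxelSize,
                            maxThickness = 100 * voxelSize,
                            binWidth = voxelSize) {
  if (minThickness <= 0 || maxThickness <= minThickness)
    stop("need 0 < minThickness < maxThickness")
  if (binWidth <= 0) stop("binWidth must be positive")
  list(minThickness = minThickness, maxThickness = maxThickness,
       binWidth = binWidth)
}

#' Local thickness (root diameter) of a mask
#'
#' For every foreground voxel, the diameter of the largest sphere fully
#' inscribed in the mask that contains the voxel, in mm. The inscribed
#' radius at a voxel is its Euclidean distance to the nearest background
#' voxel center minus half a voxel (the surface sits half a voxel beyond
#' foreground centers), so an isolated voxel has thickness one voxel.
#' Doubling the voxel size doubles all reported diameters exactly, and
#' growing the mask never decreases any voxel's thickness.
#'
#' @param mask a non-empty \linkS4class{ROIMask}.
#' @param params see \code{\link{thicknessParams}}; defaults derived from
#'   the mask's voxel size.
#' @param connectivity connectivity used to extract the surface voxels for
#'   the histogram (default 26).
#' @return a \linkS4class{ThicknessMap} whose surface histogram is
#'   computed over the mask's boundary voxels.
#' @export
localThickness <- function(mask, params = thicknessParams(mask@voxelSize),
                           connectivity = 26L) {
  stopifnot(is(mask, "ROIMask"))
  if (foregroundCount(mask) == 0L) stop("mask is empty")
  dims <- dim(mask)
  bg <- !mask@data
  storage.mode(bg) <- "integer"
  d <- .edt3d_cpp(bg, dims)            # distance to nearest background
  thVox <- .local_thickness_cpp(.maskInt(mask), dims, d)
  th <- thVox * mask@voxelSize
  th[th < params$minThickness & thVox > 0] <- params$minThickness
  th[th > params$maxThickness] <- params$maxThickness
  th[!mask@data] <- NA_real_
  values <- array(th, dims)

  hist <- .surfaceHistogram(values, mask, params, connectivity)
  new("ThicknessMap", values = values, surfaceHistogram = hist,
      clampRange = c(params$minThickness, params$maxThickness),
      voxelSize = mask@voxelSize)
}

.surfaceHistogram <- function(values, mask, params, connectivity) {
  bcoords <- maskBoundary(mask, connectivity)
  v <- values[.coordsToIdx(bcoords, dim(mask))]
  v <- v[!is.na(v)]
  if (!length(v)) stop("no surface elements: empty thickness map")
  nb <- max(1L, ceiling((max(v) - params$minThickness) / params$binWidth +
                          1e-9))
  breaks <- params$minThickness + params$binWidth * 0:nb
  # values exactly at minThickness fall in the first bin
  idx <- pmin(pmax(ceiling((v - params$minThickness) / params$binWidth -
                             1e-9), 1L), nb)
  counts <- tabulate(idx, nbins = nb)
  data.frame(bin_low_mm = breaks[-(nb + 1)],
             bin_high_mm = breaks[-1],
             count = counts,
             frequency = counts / sum(counts))
}

#' Surface diameter histogram of a thickness map
#'
#' Distribution of the local diameter over the surface elements (boundary
#' voxels) of the root mask: the frequency of root surface elements with a
#' specific root diameter. Counts are voxel counts of the boundary, not
#' mesh areas.
#'
#' @param map a \linkS4class{ThicknessMap}.
#' @param mask the \linkS4class{ROIMask} the map was computed on.
#' @param connectivity boundary connectivity (default 26).
#' @param binWidth bin width in mm; defaults to one voxel.
#' @return data.frame with bin_low_mm, bin_high_mm, count, frequency.
#' @export
surfaceDiameterHistogram <- function(map, mask, connectivity = 26L,
                                     binWidth = map@voxelSize) {
  stopifnot(is(map, "ThicknessMap"), is(mask, "ROIMask"))
  .checkSameShape(map@values, mask@data)
  params <- list(minThickness = map@clampRange[1],
                 maxThickness = map@clampRange[2], binWidth = binWidth)
  .surfaceHistogram(map@values, mask, params, connectivity)
}

#' Fraction of the root surface formed by fine roots
#'
#' Sums the relative frequencies of histogram bins strictly below the
#' diameter cutoff; a bin straddling the cutoff contributes the linear
#' fraction of its width that lies below. Fine roots (thinner than
#' 0.2--0.5 mm; 0.25 mm is the conventional cutoff used here) form the
#' major part of the root surface in fine-textured field root systems.
#'
#' @param histogram a surface diameter histogram
#'   (\code{\link{surfaceDiameterHistogram}}) or a
#'   \linkS4class{ThicknessMap} (its stored histogram is used).
#' @param cutoff diameter cutoff in mm, default 0.25.
#' @return fraction in [0, 1] of surface elements below the cutoff.
#' @export
fineRootFraction <- function(histogram, cutoff = 0.25) {
  if (is(histogram, "ThicknessMap")) histogram <- histogram@surfaceHistogram
  stopifnot(is.data.frame(histogram), nrow(histogram) > 0)
  lo <- histogram$bin_low_mm
  hi <- histogram$bin_high_mm
  if (cutoff < min(lo) || cutoff > max(hi))
    warning("cutoff ", cutoff, " mm lies outside the histogram range [",
            min(lo), ", ", max(hi), "] mm")
  below <- pmin(pmax((cutoff - lo) / (hi - lo), 0), 1)
  sum(histogram$frequency * below)
}

#' Write a thickness map as a 16-bit TIFF stack with a value-scale sidecar
#'
#' Diameters are scaled linearly onto the 16-bit range; the sidecar JSON
#' records the mm-per-gray-level scale so viewers can map colors back to
#' diameters.
#'
#' @param map a \linkS4class{ThicknessMap}.
#' @param path output TIFF path.
#' @return the path, invisibly.
#' @export
saveThicknessStack <- function(map, path) {
  mx <- max(map@values, na.rm = TRUE)
  scaled <- map@values / mx
  scaled[is.na(scaled)] <- 0
  vol <- voxelVolume(array(round(scaled * 65535), dim(map@values)),
                     voxelSize = map@voxelSize)
  saveStack(vol, path)
  jsonlite::write_json(
    list(content = "thickness_map", mm_per_level = mx / 65535,
         voxel_size_mm = map@voxelSize,
         clamp_range_mm = map@clampRange),
    paste0(path, ".scale.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
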