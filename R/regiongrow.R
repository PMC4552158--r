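# Adaptive region-growing baseline. Flood fill from seed voxels within a
# gray tolerance; the interactive workflow it models restricts the search
# area in 3D and accumulates newly grown structures onto the already
# segmented part of the root system.

#' Seed specification for region growing
#'
#' @param seeds n x 3 matrix of 1-based (slice, row, column) seed
#'   coordinates.
#' @param tolerance gray-value half-width; a voxel is accepted when its
#'   gray value lies within tolerance of the reference.
#' @param searchBox optional inclusive box \code{c(z0, z1, y0, y1, x0,
#'   x1)} (1-based) restricting growth in 3D.
#' @param adaptive if TRUE the reference is the running mean of all
#'   accepted voxels (updated incrementally, breadth-first order); if
#'   FALSE it is the fixed mean of the seed gray values.
#' @return validated list.
#' @export
seedSpec <- function(seeds, tolerance, searchBox = NULL, adaptive = FALSE) {
  seeds <- rbind(seeds)
  if (nrow(seeds) < 1) stop("seeds must be non-empty")
  if (tolerance < 0) stop("tolerance must be >= 0")
  if (!is.null(searchBox)) {
    if (length(searchBox) != 6)
      stop("searchBox must be c(z0, z1, y0, y1, x0, x1)")
    if (any(seeds[, 1] < searchBox[1] | seeds[, 1] > searchBox[2] |
            seeds[, 2] < searchBox[3] | seeds[, 2] > searchBox[4] |
            seeds[, 3] < searchBox[5] | seeds[, 3] > searchBox[6]))
      stop("all seeds must lie inside the search box")
  }
  list(seeds = seeds, tolerance = as.numeric(tolerance),
       searchBox = searchBox, adaptive = isTRUE(adaptive))
}

#' Grow a region from seed voxels within a gray tolerance
#'
#' 26-connected flood fill from the seeds over voxels whose gray value
#' lies within \code{tolerance} of the reference. Non-adaptive growth uses
#' the fixed mean of the seed gray values; adaptive growth updates the
#' reference as the running mean of accepted voxels, following local
#' gray-level drifts along a root. The result is unioned with
#' \code{accumulated} to model the stepwise interactive workflow in which
#' each newly segmented structure is added to the already segmented part
#' of the root system. Larger tolerance never yields a smaller mask in
#' non-adaptive mode, and growth can never cross a gap: voxels not
#' connected to the seeds are never reached.
#'
#' @param volume a \linkS4class{VoxelVolume}.
#' @param spec a \code{\link{seedSpec}}.
#' @param accumulated optional \linkS4class{ROIMask} from previous steps.
#' @param label role tag of the output mask.
#' @return an \linkS4class{ROIMask}.
#' @export
regionGrow <- function(volume, spec, accumulated = NULL,
                       label = "region_grown") {
  stopifnot(is(volume, "VoxelVolume"))
  dims <- dim(volume)
  .coordsToIdx(spec$seeds, dims)  # validates in-volume
  box <- if (is.null(spec$searchBox)) c(1, dims[1], 1, dims[2], 1, dims[3])
         else spec$searchBox
  seeds0 <- spec$seeds - 1L
  mode(seeds0) <- "integer"
  grown <- .region_grow_cpp(as.numeric(volume@data), dims, seeds0,
                            spec$tolerance,
                            as.integer(box - 1L), spec$adaptive)
  out <- array(grown, dims)
  if (!is.null(accumulated)) {
    .checkSameShape(out, accumulated@data)
    out <- out | accumulated@data
  }
  roiMask(out, label = label, voxelSize = volume@voxelSize)
}

#' Overlap report between two masks
#'
#' Dice coefficient 2|A n B| / (|A| + |B|), precision and recall of
#' \code{a} against \code{b}, and exclusive voxel counts. Two empty masks
#' compare as identical (Dice 1) with a warning.
#'
#' @param a,b \linkS4class{ROIMask}s of identical shape; \code{b} is the
#'   reference for precision/recall.
#' @return list with dice, precision, recall, aOnly, bOnly, intersection.
#' @export
compareMasks <- function(a, b) {
  stopifnot(is(a, "ROIMask"), is(b, "ROIMask"))
  .checkSameShape(a@data, b@data)
  na <- sum(a@data); nb <- sum(b@data)
  ni <- sum(a@data & b@data)
  if (na + nb == 0) {
    warning("both masks are empty; Dice defined as 1")
    return(list(dice = 1, precision = 1, recall = 1,
                aOnly = 0, bOnly = 0, intersection = 0))
  }
  list(dice = 2 * ni / (na + nb),
       precision = if (na > 0) ni / na else 0,
       recall = if (nb > 0) ni / nb else 0,
       aOnly = na - ni, bOnly = nb - ni, intersection = ni)
}
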