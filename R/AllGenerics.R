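#' Construct a VoxelVolume
#'
#' @param data 3D numeric array of gray values (slices, rows, columns) on
#'   the 16-bit unsigned scale.
#' @param voxelSize isotropic voxel edge length in mm.
#' @param sourceDtype original sample type tag.
#' @return a \linkS4class{VoxelVolume}.
#' @examples
#' v <- voxelVolume(array(0, c(4, 4, 4)), voxelSize = 0.1)
#' voxelSize(v)
#' @export
voxelVolume <- function(data, voxelSize, sourceDtype = "uint16") {
  new("VoxelVolume", data = data, voxelSize = as.numeric(voxelSize),
      sourceDtype = sourceDtype)
}

#' Construct an ROIMask
#'
#' @param data 3D logical array (or array coercible to logical).
#' @param label free-text role tag.
#' @param voxelSize voxel edge length in mm.
#' @return an \linkS4class{ROIMask}.
#' @export
roiMask <- function(data, label = "mask", voxelSize = 1) {
  storage.mode(data) <- "logical"
  new("ROIMask", data = data, label = label,
      voxelSize = as.numeric(voxelSize))
}

#' Construct a MaterialExample from coordinate sets
#'
#' @param backgroundVoxels n x 3 matrix of 1-based (slice, row, column)
#'   coordinates of background (air) example voxels.
#' @param materialVoxels m x 3 matrix of material example voxels.
#' @return a \linkS4class{MaterialExample}.
#' @export
materialExample <- function(backgroundVoxels, materialVoxels) {
  mode(backgroundVoxels) <- "integer"
  mode(materialVoxels) <- "integer"
  new("MaterialExample", backgroundVoxels = backgroundVoxels,
      materialVoxels = materialVoxels)
}

#' @rdname voxelVolume
#' @param x a VoxelVolume or ROIMask.
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' @rdname voxelVolume
#' @export
setMethod("voxelSize", "VoxelVolume", function(x) x@voxelSize)

#' @rdname voxelVolume
#' @export
setMethod("voxelSize", "ROIMask", function(x) x@voxelSize)

#' Voxel data accessors
#'
#' \code{voxelData} returns the gray-value array of a volume;
#' \code{maskData} the logical array of a mask; \code{maskLabel} its role
#' tag; \code{foregroundCount} the number of TRUE voxels.
#'
#' @param x a \linkS4class{VoxelVolume} or \linkS4class{ROIMask}.
#' @return array, character or numeric as described.
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))

#' @rdname voxelData
#' @export
setMethod("voxelData", "VoxelVolume", function(x) x@data)

#' @rdname voxelData
#' @export
setGeneric("maskData", function(x) standardGeneric("maskData"))

#' @rdname voxelData
#' @export
setMethod("maskData", "ROIMask", function(x) x@data)

#' @rdname voxelData
#' @export
setGeneric("maskLabel", function(x) standardGeneric("maskLabel"))

#' @rdname voxelData
#' @export
setMethod("maskLabel", "ROIMask", function(x) x@label)

#' @rdname voxelData
#' @export
setGeneric("foregroundCount", function(x) standardGeneric("foregroundCount"))

#' @rdname voxelData
#' @export
setMethod("foregroundCount", "ROIMask", function(x) sum(x@data))

#' @export
setMethod("dim", "VoxelVolume", function(x) dim(x@data))

#' @export
setMethod("dim", "ROIMask", function(x) dim(x@data))

setMethod("show", "VoxelVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf(
    "VoxelVolume: %d x %d x %d voxels (slice x row x col), %.4g mm/voxel\n",
    d[1], d[2], d[3], object@voxelSize))
  cat(sprintf("  gray range [%d, %d], source dtype %s\n",
              round(min(object@data)), round(max(object@data)),
              object@sourceDtype))
})

setMethod("show", "ROIMask", function(object) {
  d <- dim(object@data)
  cat(sprintf(
    "ROIMask '%s': %d x %d x %d voxels, %d foreground (%.2f%%)\n",
    object@label, d[1], d[2], d[3], sum(object@data),
    100 * mean(object@data)))
})

setMethod("show", "ComponentLabeling", function(object) {
  cat(sprintf(
    "ComponentLabeling: %d components (%d-connectivity), sizes %s\n",
    length(object@sizes), object@connectivity,
    if (length(object@sizes))
      paste(range(object@sizes), collapse = "..") else "-"))
})

setMethod("show", "SegmentationResult", function(object) {
  cat(sprintf(
    "SegmentationResult: %d component(s), root volume %.4g mm^3\n",
    object@componentCount, object@rootVolume))
  cat("Step log:\n")
  print(object@stepLog)
})

setMethod("show", "ThicknessMap", function(object) {
  v <- object@values[!is.na(object@values)]
  cat(sprintf(
    "ThicknessMap: %d voxels, diameters %.3f-%.3f mm (clamp [%.3f, %.3f])\n",
    length(v), if (length(v)) min(v) else NA, if (length(v)) max(v) else NA,
    object@clampRange[1], object@clampRange[2]))
})

setMethod("show", "PhantomTruth", function(object) {
  cat(sprintf(
    "PhantomTruth: %d root(s), root volume %.4g mm^3, mineral fill %.2f\n",
    length(object@roots), object@rootVolume,
    mean(object@mineralMask@data)))
})
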