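#' @useDynLib rootct, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom methods new validObject is slot
#' @importFrom stats rnorm runif quantile sd lm coef var
#' @importFrom utils write.csv packageVersion
NULL

#' VoxelVolume: a 3D gray-value CT volume with physical voxel size
#'
#' Container for a reconstructed CT volume. Voxel data are stored as a 3D
#' array indexed \code{[slice, row, column]} with gray values on the 16-bit
#' unsigned scale (0--65535) after ingest. The voxel edge length is
#' isotropic and given in mm.
#'
#' @slot data 3D numeric array of gray values, dim = (slices, rows, columns).
#' @slot voxelSize positive scalar, isotropic voxel edge length in mm.
#' @slot sourceDtype sample type of the source data: \code{"uint8"},
#'   \code{"uint16"} or \code{"float32"}.
#'
#' @export
setClass("VoxelVolume",
  representation(data = "array", voxelSize = "numeric",
                 sourceDtype = "character"),
  validity = function(object) {
    d <- dim(object@data)
    if (length(d) != 3L || any(d < 1L))
      return("data must be a 3D array with all dimensions >= 1")
    if (length(object@voxelSize) != 1L || !is.finite(object@voxelSize) ||
        object@voxelSize <= 0)
      return("voxelSize must be a positive scalar (mm)")
    rng <- range(object@data)
    if (rng[1] < 0 || rng[2] > 65535)
      return("gray values must lie in [0, 65535]")
    TRUE
  })

#' ROIMask: a binary region of interest aligned to a VoxelVolume
#'
#' Binary 3D mask carrying soil, root and intermediate regions through the
#' segmentation protocol. The label tags the mask's role (e.g.
#' \code{"mineral"}, \code{"mineral_dilated"}, \code{"roots_and_pores_domain"},
#' \code{"roots_raw"}, \code{"roots_filtered"}).
#'
#' @slot data 3D logical array, dim = (slices, rows, columns).
#' @slot label free-text role tag.
#' @slot voxelSize voxel edge length in mm, inherited from the parent volume.
#'
#' @export
setClass("ROIMask",
  representation(data = "array", label = "character", voxelSize = "numeric"),
  validity = function(object) {
    d <- dim(object@data)
    if (length(d) != 3L || any(d < 1L))
      return("data must be a 3D array with all dimensions >= 1")
    if (!is.logical(object@data))
      return("mask data must be strictly binary (logical)")
    if (anyNA(object@data))
      return("mask data must not contain NA")
    if (length(object@voxelSize) != 1L || object@voxelSize <= 0)
      return("voxelSize must be a positive scalar (mm)")
    TRUE
  })

#' ComponentLabeling: connected components of a binary mask
#'
#' @slot labels 3D integer array; 0 is background, components are numbered
#'   contiguously from 1 in raster-scan order of first contact.
#' @slot sizes integer vector; \code{sizes[i]} is the voxel count of
#'   component \code{i}.
#' @slot connectivity neighborhood used: 6, 18 or 26.
#' @slot voxelSize voxel edge length in mm, carried from the source mask.
#'
#' @export
setClass("ComponentLabeling",
  representation(labels = "array", sizes = "integer",
                 connectivity = "integer", voxelSize = "numeric"),
  validity = function(object) {
    if (!(object@connectivity %in% c(6L, 18L, 26L)))
      return("connectivity must be 6, 18 or 26")
    if (length(object@sizes) && any(object@sizes < 1L))
      return("every component must have size >= 1")
    if (sum(as.double(object@sizes)) != sum(object@labels > 0))
      return("component sizes must sum to the foreground voxel count")
    TRUE
  })

#' MaterialExample: operator-supplied example voxels for two materials
#'
#' Coordinates of example background (air) and material (mineral or root)
#' voxels, the 3D analogue of drawing example areas on slices. Coordinates
#' are 1-based (slice, row, column) rows of a matrix.
#'
#' @slot backgroundVoxels n x 3 integer matrix of (slice, row, column).
#' @slot materialVoxels m x 3 integer matrix of (slice, row, column).
#'
#' @export
setClass("MaterialExample",
  representation(backgroundVoxels = "matrix", materialVoxels = "matrix"),
  validity = function(object) {
    if (nrow(object@backgroundVoxels) < 1L || nrow(object@materialVoxels) < 1L)
      return("both example sets must be non-empty")
    if (ncol(object@backgroundVoxels) != 3L || ncol(object@materialVoxels) != 3L)
      return("example coordinates must be (slice, row, column) triples")
    key <- function(m) paste(m[, 1], m[, 2], m[, 3])
    if (length(intersect(key(object@backgroundVoxels),
                         key(object@materialVoxels))))
      return("background and material example sets must be disjoint")
    TRUE
  })

#' ThicknessMap: per-voxel local diameter of a root mask
#'
#' Diameters follow the inscribed-sphere (local thickness) definition: the
#' value at a voxel is the diameter in mm of the largest sphere fully
#' contained in the mask that covers that voxel. Values are clamped to the
#' configured [min, max] range and are NA outside the mask.
#'
#' @slot values 3D numeric array of diameters in mm (NA outside the mask).
#' @slot surfaceHistogram data.frame with columns bin_low_mm, bin_high_mm,
#'   count, frequency over boundary (surface) voxels.
#' @slot clampRange numeric(2), the (min, max) diameter clamp in mm.
#' @slot voxelSize voxel edge length in mm.
#'
#' @export
setClass("ThicknessMap",
  representation(values = "array", surfaceHistogram = "data.frame",
                 clampRange = "numeric", voxelSize = "numeric"),
  validity = function(object) {
    v <- object@values[!is.na(object@values)]
    if (length(v) &&
        (min(v) < object@clampRange[1] - 1e-9 ||
         max(v) > object@clampRange[2] + 1e-9))
      return("defined thickness values must lie within the clamp range")
    h <- object@surfaceHistogram
    if (nrow(h) && sum(h$count) > 0 && abs(sum(h$frequency) - 1) > 1e-6)
      return("relative frequencies must sum to 1")
    TRUE
  })

#' SegmentationResult: output of the five-step protocol
#'
#' @slot rootMask final filtered root \linkS4class{ROIMask}.
#' @slot rootVolume root volume in mm^3 (foreground voxels x voxel size^3).
#' @slot componentCount number of retained connected components.
#' @slot stepLog data.frame, one row per protocol step with its parameters
#'   and the foreground voxel count after the step.
#'
#' @export
setClass("SegmentationResult",
  representation(rootMask = "ROIMask", rootVolume = "numeric",
                 componentCount = "integer", stepLog = "data.frame"),
  validity = function(object) {
    expect <- sum(object@rootMask@data) * object@rootMask@voxelSize^3
    if (abs(object@rootVolume - expect) > 1e-6 * max(1, expect))
      return("rootVolume must equal foreground voxels x voxelSize^3")
    TRUE
  })

#' PhantomTruth: voxel-accurate ground truth of a synthetic phantom
#'
#' @slot rootMask true root voxels (pre-noise rasterization).
#' @slot mineralMask true mineral-aggregate voxels.
#' @slot debrisMask true organic-debris voxels.
#' @slot rootVolume ground-truth root volume in mm^3.
#' @slot roots list, one entry per root, with the centerline (n x 3 matrix
#'   of voxel coordinates) and the radius profile in mm.
#' @slot surfaceHistogram analytic surface-weighted diameter histogram
#'   (bin_low_mm, bin_high_mm, surface_mm2, frequency).
#'
#' @export
setClass("PhantomTruth",
  representation(rootMask = "ROIMask", mineralMask = "ROIMask",
                 debrisMask = "ROIMask", rootVolume = "numeric",
                 roots = "list", surfaceHistogram = "data.frame"),
  validity = function(object) {
    if (any(object@rootMask@data & object@mineralMask@data) ||
        any(object@rootMask@data & object@debrisMask@data) ||
        any(object@mineralMask@data & object@debrisMask@data))
      return("truth masks must be pairwise disjoint")
    expect <- sum(object@rootMask@data) * object@rootMask@voxelSize^3
    if (abs(object@rootVolume - expect) > 1e-6 * max(1, expect))
      return("rootVolume must be consistent with rootMask")
    TRUE
  })
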