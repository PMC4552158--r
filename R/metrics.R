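# Evaluation of a segmentation result against phantom ground truth.

#' Evaluate a segmentation against phantom ground truth
#'
#' Voxel-exact overlap metrics of the recovered root mask against the
#' truth root mask, plus component-count bookkeeping and the signed
#' volume error.
#'
#' @param result a \linkS4class{SegmentationResult} (or a plain
#'   \linkS4class{ROIMask}).
#' @param truth a \linkS4class{PhantomTruth}.
#' @param connectivity connectivity for counting truth components,
#'   default 26.
#' @return list with dice, precision, recall, volumeErrorFraction =
#'   (found - true) / true, componentCountTrue, componentCountFound, and
#'   the per-step voxel counts echoed from the result's step log (NULL
#'   for a plain mask).
#' @export
evaluateSegmentation <- function(result, truth, connectivity = 26L) {
  stopifnot(is(truth, "PhantomTruth"))
  if (is(result, "SegmentationResult")) {
    mask <- result@rootMask
    stepLog <- result@stepLog
    nFound <- result@componentCount
  } else if (is(result, "ROIMask")) {
    mask <- result
    stepLog <- NULL
    nFound <- length(labelComponents(mask, connectivity)@sizes)
  } else stop("result must be a SegmentationResult or ROIMask")
  .checkSameShape(mask@data, truth@rootMask@data)
  if (truth@rootVolume == 0)
    stop("zero-volume truth: nothing to evaluate against")

  ov <- compareMasks(mask, truth@rootMask)
  vFound <- rootVolume(mask)
  nTrue <- length(labelComponents(truth@rootMask, connectivity)@sizes)
  list(dice = ov$dice, precision = ov$precision, recall = ov$recall,
       volumeErrorFraction = (vFound - truth@rootVolume) / truth@rootVolume,
       componentCountTrue = nTrue,
       componentCountFound = as.integer(nFound),
       stepLog = stepLog)
}

#' Deterministic example areas from phantom ground truth
#'
#' Selects interior voxels of each truth class as example areas for the
#' two surface determinations, replacing the interactive per-sample
#' selection with a reproducible, configuration-driven one. Mineral and
#' root examples are taken well inside their masks (Euclidean distance to
#' the class boundary above a margin), air examples from pore space far
#' from any structure so that they survive the mineral dilation of the
#' protocol. Selection is deterministic: evenly spaced voxels in
#' raster-scan order, no randomness.
#'
#' @param truth a \linkS4class{PhantomTruth}.
#' @param nPerClass voxels per class (default 200).
#' @param margin interior margin in voxels (default 2 for material
#'   classes, 3.5 for air).
#' @return list with \code{soil} and \code{root}
#'   \linkS4class{MaterialExample}s; \code{root} is NULL when the truth
#'   contains no roots.
#' @export
phantomExamples <- function(truth, nPerClass = 200L, margin = 2) {
  dims <- dim(truth@rootMask)
  pick <- function(which, n) {
    if (!length(which)) stop("a truth class has no interior voxels")
    sel <- which[unique(round(seq(1, length(which), length.out = n)))]
    .idxToCoords(sel, dims)
  }
  distToBg <- function(maskArr) {
    bg <- !maskArr
    storage.mode(bg) <- "integer"
    .edt3d_cpp(bg, dims)
  }
  occupied <- truth@rootMask@data | truth@mineralMask@data |
    truth@debrisMask@data
  dAir <- distToBg(!occupied)   # distance of air voxels to any structure
  # all examples stay off the 1-voxel frame (it is outside the protocol's
  # whole-volume ROI)
  frame <- array(FALSE, dims)
  frame[3:(dims[1] - 2), 3:(dims[2] - 2), 3:(dims[3] - 2)] <- TRUE
  airIdx <- which(!occupied & frame & dAir >= margin + 1.5)

  # root examples additionally keep clear of minerals so they survive the
  # mineral dilation step and stay inside the roots-and-pores domain
  soilIdx <- which(truth@mineralMask@data & frame &
                     distToBg(truth@mineralMask@data) >= margin + 1)
  air <- pick(airIdx, nPerClass)
  soil <- pick(soilIdx, nPerClass)

  rootEx <- NULL
  if (any(truth@rootMask@data)) {
    dRoot <- distToBg(truth@rootMask@data)
    dMin <- distToBg(!truth@mineralMask@data)  # distance TO the minerals
    rootIdx <- integer(0)
    for (m in c(margin, margin / 2, 1)) {
      rootIdx <- which(truth@rootMask@data & frame & dRoot >= m &
                         dMin >= 3.5)
      if (length(rootIdx) >= nPerClass) break
    }
    rootEx <- materialExample(air, pick(rootIdx, nPerClass))
  }
  list(soil = materialExample(air, soil), root = rootEx)
}
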