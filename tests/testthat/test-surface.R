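test_that("example-area thresholding returns the ISO-50 midpoint with orientation", {
  arr <- array(1000, c(4, 4, 4))
  arr[1, 1, 1:2] <- 1000          # background examples
  arr[4, 4, 3:4] <- 30000         # material examples
  vol <- voxelVolume(arr, 0.1)
  ex <- materialExample(cbind(1, 1, 1:2), cbind(4, 4, 3:4))
  th <- defineMaterialByExample(vol, ex)
  expect_equal(th$threshold, 15500)
  expect_true(th$materialBrighter)

  # symmetric case: dark material
  arr2 <- array(30000, c(4, 4, 4))
  arr2[4, 4, 3:4] <- 1000
  th2 <- defineMaterialByExample(voxelVolume(arr2, 0.1), ex)
  expect_equal(th2$threshold, 15500)
  expect_false(th2$materialBrighter)

  # equal means are rejected
  expect_error(
    defineMaterialByExample(voxelVolume(array(5, c(4, 4, 4)), 0.1), ex),
    "equal")
  # disjointness enforced at construction
  expect_error(materialExample(cbind(1, 1, 1), cbind(1, 1, 1)), "disjoint")
})

test_that("midpoint threshold is near-optimal on a two-Gaussian phantom", {
  set.seed(301)
  n <- 40
  isMat <- array(runif(n^3) < 0.5, c(n, n, n))
  gray <- ifelse(isMat, rnorm(n^3, 40000, 1500), rnorm(n^3, 8000, 1500))
  gray <- pmin(pmax(round(gray), 0), 65535)
  vol <- voxelVolume(array(gray, c(n, n, n)), 0.1)
  bgi <- which(!isMat)[1:100]
  mti <- which(isMat)[1:100]
  dims <- c(n, n, n)
  toCoord <- function(i) {
    i0 <- i - 1
    cbind(i0 %% n + 1, (i0 %/% n) %% n + 1, i0 %/% (n * n) + 1)
  }
  th <- defineMaterialByExample(vol, materialExample(toCoord(bgi),
                                                     toCoord(mti)))
  # brute-force sweep for the best achievable global threshold
  cand <- seq(6000, 42000, by = 250)
  err <- vapply(cand, function(t) mean((gray >= t) != isMat), numeric(1))
  errAt <- mean((gray >= th$threshold) != isMat)
  expect_lte(errAt, min(err) + 0.01)
})

test_that("gradient refinement relocates a biased boundary to the blurred edge", {
  vol <- blurredStepVolume(edgeX = 20.5)
  # bias the threshold so the naive boundary sits at column 23
  thr <- 10000 + 30000 * pnorm(22.5, 20.5, 2)
  naiveCol <- min(which(apply(voxelData(vol) >= thr, 3, any)))
  expect_equal(naiveCol, 23)
  mask <- advancedSurfaceDetermination(vol, thr, materialBrighter = TRUE)
  refinedCol <- min(which(maskData(mask)[4, 4, ]))
  # true material side starts at column 21 (edge at 20.5)
  expect_lte(abs(refinedCol - 21), 1)

  # oracle: argmax of the finite-difference gradient along the row
  prof <- voxelData(vol)[4, 4, ]
  grad <- abs(diff(prof))
  expect_lte(abs(refinedCol - (which.max(grad) + 0.5)), 1.5)

  # bias in the other direction (threshold too low)
  thrLow <- 10000 + 30000 * pnorm(18.5, 20.5, 2)
  maskLow <- advancedSurfaceDetermination(vol, thrLow,
                                          materialBrighter = TRUE)
  expect_lte(abs(min(which(maskData(maskLow)[4, 4, ])) - 21), 1)
})

test_that("refined blurred ball recovers the analytic volume within 3%", {
  r <- 12
  vol <- blurredBallVolume(r)
  # threshold biased to inflate the naive mask by ~2 voxels
  thr <- 40000 - 30000 * pnorm(r + 2, r, 1.5)
  mask <- advancedSurfaceDetermination(vol, thr, materialBrighter = TRUE)
  vTrue <- 4 / 3 * pi * r^3
  expect_lt(abs(foregroundCount(mask) - vTrue) / vTrue, 0.03)
})

test_that("refinement is conservative and near-idempotent on smooth phantoms", {
  vol <- blurredBallVolume(10)
  thr <- 40000 - 30000 * pnorm(12, 10, 1.5)
  init <- voxelData(vol) >= thr
  p <- surfaceParams()
  m1 <- advancedSurfaceDetermination(vol, thr, params = p)
  # changes confined to within searchDistance of the initial boundary
  changed <- which(maskData(m1) != init, arr.ind = TRUE)
  bnd <- maskBoundary(roiMask(init, voxelSize = 0.1))
  for (i in seq_len(nrow(changed))) {
    d <- sqrt(min(colSums((t(bnd) - changed[i, ])^2)))
    expect_lte(d, p$searchDistance + 1)
  }
  # second refinement pass moves almost nothing
  thr2 <- 25000
  m2 <- advancedSurfaceDetermination(vol, thr2, params = p)
  m3 <- advancedSurfaceDetermination(vol, thr2, params = p)
  expect_lte(mean(maskData(m2) != maskData(m3)), 0.005)
})

test_that("degenerate inputs follow the documented contracts", {
  uni <- voxelVolume(array(100, c(6, 6, 6)), 0.1)
  m <- advancedSurfaceDetermination(uni, 5000, materialBrighter = TRUE)
  expect_equal(foregroundCount(m), 0)           # all below threshold
  expect_error(advancedSurfaceDetermination(uni, -5), "16-bit")
  dom <- roiMask(array(FALSE, c(6, 6, 6)), voxelSize = 0.1)
  expect_error(advancedSurfaceDetermination(uni, 50, domain = dom),
               "empty")
})

test_that("maskBoundary matches exhaustive neighbor enumeration", {
  cube <- array(FALSE, c(5, 5, 5))
  cube[2:4, 2:4, 2:4] <- TRUE
  b <- maskBoundary(roiMask(cube))
  expect_equal(nrow(b), 26)                     # all but the center voxel
  single <- array(FALSE, c(3, 3, 3))
  single[2, 2, 2] <- TRUE
  expect_equal(maskBoundary(roiMask(single)),
               cbind(2, 2, 2), ignore_attr = TRUE)

  set.seed(77)
  for (conn in c(6L, 18L, 26L)) {
    m <- randomMask(c(12, 12, 12), 0.4)
    got <- maskBoundary(roiMask(m), conn)
    want <- bfBoundary(m, conn)
    expect_equal(got[order(got[, 1], got[, 2], got[, 3]), , drop = FALSE],
                 want[order(want[, 1], want[, 2], want[, 3]), ,
                      drop = FALSE],
                 ignore_attr = TRUE)
  }
})
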