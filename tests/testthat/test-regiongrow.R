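test_that("flood fill recovers a uniform blob exactly", {
  arr <- array(1000, c(12, 12, 12))
  blob <- array(FALSE, c(12, 12, 12))
  blob[4:8, 4:8, 4:8] <- TRUE
  arr[blob] <- 20000
  vol <- voxelVolume(arr, 0.1)
  got <- regionGrow(vol, seedSpec(cbind(6, 6, 6), tolerance = 500))
  expect_identical(maskData(got), blob)

  # tolerance 0: only voxels equal to the seed value and connected to it
  arr2 <- arr
  arr2[5, 5, 5] <- 20001
  got2 <- regionGrow(voxelVolume(arr2, 0.1),
                     seedSpec(cbind(6, 6, 6), tolerance = 0))
  want <- blob
  want[5, 5, 5] <- FALSE
  expect_identical(maskData(got2), want)
})

test_that("growth respects the search box and accumulates across steps", {
  arr <- array(20000, c(10, 10, 10))
  vol <- voxelVolume(arr, 0.1)
  box <- c(1, 5, 1, 10, 1, 10)
  got <- regionGrow(vol, seedSpec(cbind(2, 5, 5), 100, searchBox = box))
  expect_equal(foregroundCount(got), 5 * 10 * 10)
  expect_error(seedSpec(cbind(8, 5, 5), 100, searchBox = box), "inside")

  prev <- roiMask(array(FALSE, c(10, 10, 10)), voxelSize = 0.1)
  prev@data[10, 10, 10] <- TRUE
  acc <- regionGrow(vol, seedSpec(cbind(2, 5, 5), 100, searchBox = box),
                    accumulated = prev)
  expect_equal(foregroundCount(acc), 5 * 100 + 1)
})

test_that("adaptive growth follows gray drift that defeats a fixed reference", {
  # a bar whose gray value drifts 30% along its length
  n <- 40
  arr <- array(1000, c(6, 6, n))
  drift <- round(seq(20000, 26000, length.out = n))
  for (x in 1:n) arr[3, 3, x] <- drift[x]
  vol <- voxelVolume(arr, 0.1)
  tol <- 3500
  fixed <- regionGrow(vol, seedSpec(cbind(3, 3, 1), tol, adaptive = FALSE))
  adap <- regionGrow(vol, seedSpec(cbind(3, 3, 1), tol, adaptive = TRUE))
  expect_true(all(maskData(fixed) <= maskData(adap)))   # strict subset
  expect_lt(foregroundCount(fixed), foregroundCount(adap))
  expect_equal(foregroundCount(adap), n)                # full bar reached

  # monotone in tolerance (non-adaptive)
  small <- regionGrow(vol, seedSpec(cbind(3, 3, 1), 1000))
  expect_true(all(maskData(small) <= maskData(fixed)))
})

test_that("region growing never crosses a pore gap between unconnected roots", {
  # low-aggregate soil: the partial-volume gray band around aggregate
  # surfaces stays disconnected, so any leakage would be a flood-fill bug
  # rather than a percolating mixed-voxel bridge
  spec <- phantomSpec(shape = c(96L, 96L, 96L), nRoots = 2L,
                      rootRadiusRange = c(0.7, 1.0),
                      mineralFillFraction = 0.2, nDebris = 0L,
                      seed = 61L)
  ph <- generatePhantom(spec)
  stopifnot(length(labelComponents(ph$truth@rootMask)@sizes) == 2)
  maskA <- ph$perRootMasks[[1]]
  maskB <- ph$perRootMasks[[2]]
  # the operator seeds at clear, bright root centres: interior voxels of
  # root A, farther than 2.5 voxels from the surface
  outside <- roiMask(!maskData(maskA), voxelSize = voxelSize(maskA))
  interior <- maskData(maskA) & !maskData(dilateROI(outside, 2))
  idx <- which(interior, arr.ind = TRUE)
  seed <- idx[round(seq(1, nrow(idx), length.out = 12)), , drop = FALSE]
  grown <- regionGrow(ph$volume, seedSpec(seed, tolerance = 3500))
  expect_gt(sum(maskData(grown) & maskData(maskA)) /
              foregroundCount(maskA), 0.5)
  expect_equal(sum(maskData(grown) & maskData(maskB)), 0)
  # output is a single 26-connected set
  expect_length(labelComponents(grown, 26L)@sizes, 1)
})

test_that("compareMasks agrees with brute-force set arithmetic", {
  set.seed(707)
  a <- randomMask(c(10, 10, 10), 0.3)
  b <- randomMask(c(10, 10, 10), 0.3)
  got <- compareMasks(roiMask(a), roiMask(b))
  expect_equal(got$dice, 2 * sum(a & b) / (sum(a) + sum(b)))
  expect_equal(got$precision, sum(a & b) / sum(a))
  expect_equal(got$recall, sum(a & b) / sum(b))
  expect_equal(got$aOnly, sum(a & !b))
  expect_equal(got$bOnly, sum(!a & b))

  same <- roiMask(a)
  expect_equal(compareMasks(same, same)$dice, 1)
  empty <- roiMask(array(FALSE, c(4, 4, 4)))
  expect_warning(res <- compareMasks(empty, empty), "empty")
  expect_equal(res$dice, 1)
  disA <- array(FALSE, c(4, 4, 4)); disA[1, 1, 1] <- TRUE
  disB <- array(FALSE, c(4, 4, 4)); disB[4, 4, 4] <- TRUE
  expect_equal(compareMasks(roiMask(disA), roiMask(disB))$dice, 0)
})
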