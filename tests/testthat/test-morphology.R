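test_that("fractional dilation has boundary-offset semantics", {
  m <- array(FALSE, c(5, 5, 5))
  m[3, 3, 3] <- TRUE
  mk <- roiMask(m, voxelSize = 0.1)
  expect_identical(maskData(dilateROI(mk, 0)), m)       # identity
  # face neighbors at distance 1 - 0.5 = 0.5
  expect_equal(foregroundCount(dilateROI(mk, 0.5)), 7)
  # + edge neighbors (sqrt(2) - 0.5 ~ 0.914); corners stay out
  expect_equal(foregroundCount(dilateROI(mk, 1.0)), 19)
  expect_error(dilateROI(mk, -1), "non-negative")

  # brute-force distance oracle on random masks and radii
  set.seed(101)
  for (rad in c(0.5, 1.0, 1.7)) {
    rm <- randomMask(c(9, 9, 9), 0.08)
    if (!any(rm)) next
    got <- maskData(dilateROI(roiMask(rm), rad))
    expect_identical(got, bfDilate(rm, rad))
  }
})

test_that("dilation is extensive and monotone; integer radii equal ball-SE dilation", {
  set.seed(202)
  for (i in 1:3) {
    m <- randomMask(c(14, 14, 14), 0.05)
    mk <- roiMask(m)
    d1 <- maskData(dilateROI(mk, 0.6))
    d2 <- maskData(dilateROI(mk, 1.4))
    expect_true(all(m <= d1))                  # extensive
    expect_true(all(d1 <= d2))                 # monotone in radius
    m2 <- m | randomMask(c(14, 14, 14), 0.03)
    expect_true(all(d1 <= maskData(dilateROI(roiMask(m2), 0.6))))
  }
  # classical Euclidean ball of radius r + 0.5 sampled at voxel centers
  set.seed(203)
  for (r in c(1, 2)) {
    m <- randomMask(c(12, 12, 12), 0.04)
    expect_identical(maskData(dilateROI(roiMask(m), r)),
                     bfBallDilate(m, r + 0.5))
  }
})

test_that("subtractROI is exact set difference", {
  set.seed(303)
  a <- roiMask(randomMask(c(10, 10, 10), 0.5))
  b <- roiMask(randomMask(c(10, 10, 10), 0.5))
  expect_equal(foregroundCount(subtractROI(a, a)), 0)
  expect_identical(maskData(subtractROI(a, roiMask(array(FALSE, dim(a))))),
                   maskData(a))
  got <- maskData(subtractROI(a, b))
  expect_identical(got, maskData(a) & !maskData(b))
  expect_false(any(got & maskData(b)))
  expect_error(subtractROI(a, roiMask(array(FALSE, c(9, 9, 9)))),
               "mismatch")
})

test_that("component labeling matches a flood-fill oracle across connectivities", {
  # two voxels sharing only a corner
  m <- array(FALSE, c(4, 4, 4))
  m[1, 1, 1] <- m[2, 2, 2] <- TRUE
  expect_length(labelComponents(roiMask(m), 26L)@sizes, 1)
  expect_length(labelComponents(roiMask(m), 18L)@sizes, 2)
  expect_length(labelComponents(roiMask(m), 6L)@sizes, 2)
  expect_length(labelComponents(roiMask(array(FALSE, c(4, 4, 4))))@sizes, 0)
  expect_error(labelComponents(roiMask(m), 7), "connectivity")

  set.seed(404)
  for (conn in c(6L, 26L)) {
    rm <- randomMask(c(14, 14, 14), 0.25)
    got <- labelComponents(roiMask(rm), conn)
    want <- bfComponents(rm, conn)
    # same partition: labels must be a bijection
    expect_equal(max(got@labels), max(want))
    expect_equal(length(unique(paste(got@labels[rm], want[rm]))),
                 max(want))
    expect_equal(sum(got@sizes), sum(rm))
    expect_true(all(got@sizes >= 1))
  }
})

test_that("size filter deletes strictly-smaller components and keeps equality", {
  # three bars of controlled sizes on one grid
  m <- array(FALSE, c(6, 6, 40))
  m[1, 1, 1:12] <- TRUE                        # size 12
  m[3, 3, 1:9] <- TRUE                         # size 9
  m[6, 6, 1:3] <- TRUE                         # size 3
  lab <- labelComponents(roiMask(m))
  f <- sizeFilter(lab, minVoxels = 10)
  expect_equal(f$retainedCount, 1)
  expect_equal(f$deletedCount, 2)
  expect_equal(foregroundCount(f$mask), 12)
  # boundary semantics: exactly min_voxels survives
  f2 <- sizeFilter(lab, minVoxels = 9)
  expect_equal(f2$retainedCount, 2)
  expect_equal(foregroundCount(f2$mask), 21)
  expect_error(sizeFilter(lab, 0), "positive")

  # oracle: count-and-compare on random masks; never splits or merges
  set.seed(505)
  for (i in 1:3) {
    rm <- randomMask(c(16, 16, 16), 0.2)
    lab <- labelComponents(roiMask(rm), 26L)
    f <- sizeFilter(lab, minVoxels = 5)
    want <- bfComponents(rm, 26L)
    sizes <- table(want[want > 0])
    keepLabels <- as.integer(names(sizes)[sizes >= 5])
    expect_identical(maskData(f$mask),
                     array(want %in% keepLabels & want > 0, dim(rm)))
    expect_equal(f$retainedCount, length(keepLabels))
  }
})

test_that("component tables report voxel counts and physical volumes", {
  m <- array(FALSE, c(4, 4, 4))
  m[1:2, 1, 1] <- TRUE
  m[4, 4, 4] <- TRUE
  tab <- componentTable(labelComponents(roiMask(m, voxelSize = 0.5)))
  expect_equal(tab$voxel_count, c(2L, 1L))
  expect_equal(tab$volume_mm3, c(0.25, 0.125))
})
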