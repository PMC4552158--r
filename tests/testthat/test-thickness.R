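test_that("inscribed-sphere thickness recovers ball and cylinder diameters", {
  # solid balls: modal thickness within one voxel of the diameter
  for (r in c(4, 8, 12)) {
    mk <- roiMask(digitalBall(r), voxelSize = 1)
    tm <- localThickness(mk, thicknessParams(1, maxThickness = 100))
    v <- tm@values[!is.na(tm@values)]
    mode <- as.numeric(names(which.max(table(v))))
    expect_lte(abs(mode - 2 * r), 1)
    expect_lte(abs(max(v) - 2 * r), 1)
  }
  # exhaustive inscribed-sphere oracle at r = 4
  mk4 <- roiMask(digitalBall(4), voxelSize = 1)
  tm4 <- localThickness(mk4, thicknessParams(1, maxThickness = 100))
  want <- bfLocalThickness(digitalBall(4))
  expect_lte(max(abs(tm4@values - want), na.rm = TRUE), 1)

  # cylinders at the fine CT resolution: histogram mode within one bin
  for (r in c(3, 5, 8)) {
    mk <- roiMask(digitalCylinder(r, len = 30), voxelSize = 0.044)
    tm <- localThickness(mk)
    h <- tm@surfaceHistogram
    modeBin <- h[which.max(h$count), ]
    expect_lte(abs((modeBin$bin_low_mm + modeBin$bin_high_mm) / 2 -
                     2 * r * 0.044), 0.044)
  }
})

test_that("an isolated voxel clamps to the minimum thickness", {
  m <- array(FALSE, c(5, 5, 5))
  m[3, 3, 3] <- TRUE
  tm <- localThickness(roiMask(m, voxelSize = 0.044))
  expect_equal(tm@values[3, 3, 3], 0.044)
  expect_error(localThickness(roiMask(array(FALSE, c(4, 4, 4)))), "empty")
})

test_that("thickness is monotone under dilation and covariant with voxel size", {
  set.seed(606)
  m <- digitalBall(3) | randomMask(dim(digitalBall(3)), 0.02)
  mk <- roiMask(m, voxelSize = 1)
  tp <- thicknessParams(1, maxThickness = 1000)
  t1 <- localThickness(mk, tp)
  t2 <- localThickness(dilateROI(mk, 1), tp)
  common <- !is.na(t1@values)
  expect_true(all(t2@values[common] >= t1@values[common] - 1e-9))

  mkBig <- roiMask(m, voxelSize = 2)
  tBig <- localThickness(mkBig, thicknessParams(2, maxThickness = 2000))
  expect_equal(tBig@values, 2 * t1@values)
})

test_that("surface histograms separate a two-cylinder mixture", {
  # uniform through-going cylinder (no end caps): a single bin holds
  # nearly all surface elements
  side <- 17
  sl <- outer((1:side - 9)^2, (1:side - 9)^2, "+") <= 25
  arr <- array(rep(sl, 40), c(side, side, 40))
  mk <- roiMask(arr, voxelSize = 0.044)
  h <- localThickness(mk)@surfaceHistogram
  expect_gte(max(h$frequency), 0.95)
  expect_equal(sum(h$frequency), 1)

  # two disjoint cylinders, radii 3 and 8: bimodal with correct modes
  c1 <- digitalCylinder(3, len = 40)
  c2 <- digitalCylinder(8, len = 40)
  side <- dim(c1)[1] + dim(c2)[1]
  arr <- array(FALSE, c(side, max(dim(c1)[2], dim(c2)[2]),
                        max(dim(c1)[3], dim(c2)[3])))
  arr[seq_len(dim(c1)[1]), seq_len(dim(c1)[2]), seq_len(dim(c1)[3])] <- c1
  arr[dim(c1)[1] + seq_len(dim(c2)[1]), seq_len(dim(c2)[2]),
      seq_len(dim(c2)[3])] <- c2
  tm <- localThickness(roiMask(arr, voxelSize = 1),
                       thicknessParams(1, maxThickness = 100, binWidth = 1))
  h2 <- tm@surfaceHistogram
  # local maxima of the bin counts
  peaks <- h2$count > c(-1, head(h2$count, -1)) &
    h2$count >= c(tail(h2$count, -1), -1) & h2$count > 0
  centers <- (h2$bin_low_mm[peaks] + h2$bin_high_mm[peaks]) / 2
  expect_true(any(abs(centers - 6) <= 1.5))
  expect_true(any(abs(centers - 16) <= 1.5))
})

test_that("fineRootFraction apportions straddling bins linearly", {
  h1 <- data.frame(bin_low_mm = c(0.1, 0.2), bin_high_mm = c(0.2, 0.3),
                   count = c(10, 0), frequency = c(1, 0))
  expect_equal(fineRootFraction(h1, 0.25), 1.0)
  # symmetric histogram around the cutoff
  h2 <- data.frame(bin_low_mm = c(0.15, 0.25), bin_high_mm = c(0.25, 0.35),
                   count = c(5, 5), frequency = c(0.5, 0.5))
  expect_equal(fineRootFraction(h2, 0.25), 0.5)
  # single straddling bin: linear share below the cutoff
  h3 <- data.frame(bin_low_mm = 0.2, bin_high_mm = 0.3, count = 10,
                   frequency = 1)
  expect_equal(fineRootFraction(h3, 0.25), 0.5)
  expect_warning(fineRootFraction(h3, 0.9), "outside")
})

test_that("thickness maps export as scaled 16-bit stacks with a scale sidecar", {
  dir <- withr::local_tempdir()
  mk <- roiMask(digitalBall(4), voxelSize = 0.1)
  tm <- localThickness(mk)
  p <- file.path(dir, "th.tif")
  saveThicknessStack(tm, p)
  scale <- jsonlite::read_json(paste0(p, ".scale.json"))
  back <- loadStack(p, voxelSize = 0.1)
  mx <- max(tm@values, na.rm = TRUE)
  expect_equal(scale$mm_per_level * 65535, mx)
  recon <- voxelData(back) * scale$mm_per_level
  expect_lt(max(abs(recon[!is.na(tm@values)] -
                      tm@values[!is.na(tm@values)])), 1e-3)
})
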