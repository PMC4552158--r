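test_that("identical spec and seed reproduce the phantom bit for bit", {
  spec <- smallPhantomSpec(seed = 71L)
  a <- generatePhantom(spec)
  b <- generatePhantom(spec)
  expect_identical(voxelData(a$volume), voxelData(b$volume))
  expect_identical(maskData(a$truth@rootMask), maskData(b$truth@rootMask))
  expect_identical(a$truth@surfaceHistogram, b$truth@surfaceHistogram)
  # and the generator does not disturb the caller's RNG stream
  set.seed(1); x1 <- runif(1)
  set.seed(1); invisible(generatePhantom(spec)); x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("truth masks are disjoint and consistent with the reported volume", {
  ph <- generatePhantom(smallPhantomSpec(seed = 72L))
  tr <- ph$truth
  expect_false(any(maskData(tr@rootMask) & maskData(tr@mineralMask)))
  expect_false(any(maskData(tr@rootMask) & maskData(tr@debrisMask)))
  expect_false(any(maskData(tr@mineralMask) & maskData(tr@debrisMask)))
  expect_equal(tr@rootVolume, rootVolume(tr@rootMask))
  expect_equal(foregroundCount(
    generatePhantom(smallPhantomSpec(nRoots = 0L, seed = 73L))$truth@rootMask),
    0)
})

test_that("a straight tube rasterizes to the analytic cylinder volume", {
  # radius 0.5 mm, length 20 mm at 0.05 mm voxels -> ~15.71 mm^3
  spec <- phantomSpec(shape = c(440L, 48L, 48L), voxelSize = 0.05,
                      nRoots = 1L, rootRadiusRange = c(0.5, 0.5),
                      rootTaper = 0, mineralFillFraction = 0,
                      nDebris = 0L, blurSigma = 0, seed = 74L)
  geom <- list(list(centerline = cbind(seq(10, 409.99, by = 1), 24, 24),
                    radiiVox = rep(10, 400)))
  res <- rootct:::.withSeed(74L, rootct:::.generatePhantomImpl(spec, geom))
  vTrue <- pi * 0.5^2 * 20
  expect_lt(abs(res$truth@rootVolume - vTrue) / vTrue, 0.05)
})

test_that("unblurred class gray values peak near the specified means", {
  spec <- smallPhantomSpec(seed = 75L, blurSigma = 0)
  ph <- generatePhantom(spec)
  g <- voxelData(ph$volume)
  gm <- spec$grayMeans
  gs <- spec$graySds
  expect_lte(abs(mean(g[maskData(ph$truth@rootMask)]) - gm["root"]),
             2 * gs["root"])
  expect_lte(abs(mean(g[maskData(ph$truth@mineralMask)]) - gm["mineral"]),
             2 * gs["mineral"])
  pore <- !maskData(ph$truth@rootMask) & !maskData(ph$truth@mineralMask) &
    !maskData(ph$truth@debrisMask)
  expect_lte(abs(mean(g[pore]) - gm["air"]), 2 * gs["air"])
})

test_that("partial-volume blur creates mixed voxels at mineral borders", {
  spec <- smallPhantomSpec(seed = 76L, blurSigma = 1.0, nRoots = 0L,
                           nDebris = 0L)
  ph <- generatePhantom(spec)
  g <- voxelData(ph$volume)
  minMask <- maskData(ph$truth@mineralMask)
  shell <- maskData(dilateROI(ph$truth@mineralMask, 1)) & !minMask
  gm <- spec$grayMeans
  mixed <- shell & g > (gm["air"] + gm["root"]) / 2 &
    g < (gm["root"] + gm["mineral"]) / 2
  expect_gt(sum(mixed), 0)
  # root-like gray values appear at the borders although no root exists
  expect_gt(sum(abs(g[shell] - gm["root"]) < 2000), 0)
})

test_that("phantom series accumulate roots with strictly increasing truth volumes", {
  base <- smallPhantomSpec(seed = 77L)
  s1 <- phantomSeries(base, nVolumes = 3)
  vols <- vapply(s1, function(e) e$truth@rootVolume, numeric(1))
  expect_true(all(diff(vols) > 0))
  s2 <- phantomSeries(base, nVolumes = 3)
  expect_identical(vapply(s2, function(e) e$truth@rootVolume, numeric(1)),
                   vols)
  expect_identical(voxelData(s1[[2]]$volume), voxelData(s2[[2]]$volume))

  # volume-targeted series approach their targets
  targets <- c(2, 4, 6)
  s3 <- phantomSeries(base, nVolumes = 3, targetVolumes = targets)
  v3 <- vapply(s3, function(e) e$truth@rootVolume, numeric(1))
  expect_true(all(diff(v3) > 0))
  expect_true(all(v3 >= targets * 0.9))
  expect_error(phantomSeries(base, nVolumes = 2), ">= 3")
  expect_error(phantomSeries(base, 3, targetVolumes = c(3, 2, 1)),
               "increasing")
})

test_that("spec validation rejects infeasible configurations", {
  expect_error(smallPhantomSpec(mineralFillFraction = 0.95), "infeasible")
  expect_error(phantomSpec(shape = c(16L, 64L, 64L)), "32")
  expect_error(smallPhantomSpec(
    grayMeans = c(air = 30000, water = 12000, root = 18000,
                  mineral = 45000, wall = 43000)), "ordered")
})
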