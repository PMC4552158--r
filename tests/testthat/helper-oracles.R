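# Shared fixture builders and independent brute-force oracles. All
# fixtures are generated in code; oracles are deliberately naive (full
# enumeration) and independent of the package's C++ implementations.

digitalBall <- function(r, pad = 3L) {
  n <- 2L * (r + pad) + 1L
  ctr <- r + pad + 1L
  g <- expand.grid(z = 1:n, y = 1:n, x = 1:n)
  array((g$z - ctr)^2 + (g$y - ctr)^2 + (g$x - ctr)^2 <= r^2, c(n, n, n))
}

# solid cylinder along the column (x) axis
digitalCylinder <- function(r, len, pad = 3L) {
  side <- 2L * (r + pad) + 1L
  ctr <- r + pad + 1L
  sl <- outer((1:side - ctr)^2, (1:side - ctr)^2, "+") <= r^2
  arr <- array(FALSE, c(side, side, len + 2L * pad))
  for (x in (pad + 1L):(pad + len)) arr[, , x] <- sl
  arr
}

randomMask <- function(dims, p = 0.3) {
  array(runif(prod(dims)) < p, dims)
}

neighborOffsets <- function(connectivity) {
  off <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  m <- rowSums(abs(off))
  keep <- switch(as.character(connectivity),
                 "6" = m == 1, "18" = m >= 1 & m <= 2, "26" = m >= 1)
  off[keep, , drop = FALSE]
}

# exhaustive boundary oracle: foreground voxel with >= 1 background
# neighbor (out-of-grid counts as background)
bfBoundary <- function(mask, connectivity = 26L) {
  dims <- dim(mask)
  off <- neighborOffsets(connectivity)
  idx <- which(mask, arr.ind = TRUE)
  isB <- logical(nrow(idx))
  for (i in seq_len(nrow(idx))) {
    for (k in seq_len(nrow(off))) {
      p <- idx[i, ] + off[k, ]
      if (any(p < 1) || any(p > dims) || !mask[p[1], p[2], p[3]]) {
        isB[i] <- TRUE
        break
      }
    }
  }
  idx[isB, , drop = FALSE]
}

# exhaustive flood-fill component oracle
bfComponents <- function(mask, connectivity = 26L) {
  dims <- dim(mask)
  off <- neighborOffsets(connectivity)
  lab <- array(0L, dims)
  nxt <- 0L
  for (start in which(mask)) {
    if (lab[start] > 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      cur <- queue[1]
      queue <- queue[-1]
      cz <- (cur - 1) %% dims[1] + 1
      cy <- ((cur - 1) %/% dims[1]) %% dims[2] + 1
      cx <- (cur - 1) %/% (dims[1] * dims[2]) + 1
      for (k in seq_len(nrow(off))) {
        p <- c(cz, cy, cx) + off[k, ]
        if (any(p < 1) || any(p > dims)) next
        j <- (p[1] - 1) + dims[1] * ((p[2] - 1) + dims[2] * (p[3] - 1)) + 1
        if (mask[j] && lab[j] == 0L) {
          lab[j] <- nxt
          queue <- c(queue, j)
        }
      }
    }
  }
  lab
}

# brute-force fractional-radius dilation: background voxel joins when
# (min distance to a foreground center) - 0.5 <= radius
bfDilate <- function(mask, radius) {
  dims <- dim(mask)
  fg <- which(mask, arr.ind = TRUE)
  out <- mask
  for (j in which(!mask)) {
    cz <- (j - 1) %% dims[1] + 1
    cy <- ((j - 1) %/% dims[1]) %% dims[2] + 1
    cx <- (j - 1) %/% (dims[1] * dims[2]) + 1
    d <- sqrt(min((fg[, 1] - cz)^2 + (fg[, 2] - cy)^2 + (fg[, 3] - cx)^2))
    if (d - 0.5 <= radius + 1e-9) out[j] <- TRUE
  }
  out
}

# classical dilation with a Euclidean ball structuring element sampled at
# voxel centers (independent formulation used for the integer-radius
# equivalence check)
bfBallDilate <- function(mask, ballRadius) {
  dims <- dim(mask)
  se <- as.matrix(expand.grid(dz = -ceiling(ballRadius):ceiling(ballRadius),
                              dy = -ceiling(ballRadius):ceiling(ballRadius),
                              dx = -ceiling(ballRadius):ceiling(ballRadius)))
  se <- se[rowSums(se^2) <= ballRadius^2 + 1e-9, , drop = FALSE]
  out <- array(FALSE, dims)
  fg <- which(mask, arr.ind = TRUE)
  for (i in seq_len(nrow(fg))) {
    p <- sweep(se, 2, fg[i, ], "+")
    ok <- p[, 1] >= 1 & p[, 1] <= dims[1] & p[, 2] >= 1 &
      p[, 2] <= dims[2] & p[, 3] >= 1 & p[, 3] <= dims[3]
    p <- p[ok, , drop = FALSE]
    out[p] <- TRUE
  }
  out
}

# exhaustive inscribed-sphere local thickness for tiny masks: the radius
# at a candidate center is (distance to nearest background center - 0.5),
# and a voxel's thickness is the largest sphere that covers it
bfLocalThickness <- function(mask) {
  dims <- dim(mask)
  fg <- which(mask, arr.ind = TRUE)
  bg <- which(!mask, arr.ind = TRUE)
  rad <- numeric(nrow(fg))
  for (i in seq_len(nrow(fg))) {
    d <- sqrt(min((bg[, 1] - fg[i, 1])^2 + (bg[, 2] - fg[i, 2])^2 +
                    (bg[, 3] - fg[i, 3])^2))
    rad[i] <- max(0.5, d - 0.5)
  }
  th <- array(NA_real_, dims)
  for (i in seq_len(nrow(fg))) {
    d2 <- (fg[, 1] - fg[i, 1])^2 + (fg[, 2] - fg[i, 2])^2 +
      (fg[, 3] - fg[i, 3])^2
    covers <- d2 <= (rad + 0.5)^2 + 1e-9   # sphere overlaps the voxel cube
    th[fg[i, 1], fg[i, 2], fg[i, 3]] <- 2 * max(rad[covers])
  }
  th
}

# blurred bright ball volume: gray profile is a smooth sigmoid of the
# radial distance, mimicking partial-volume blur
blurredBallVolume <- function(r, gridN = 2 * r + 16, sigma = 1.5,
                              lowGray = 10000, highGray = 40000,
                              voxelSize = 0.1) {
  ctr <- (gridN + 1) / 2
  g <- expand.grid(z = 1:gridN, y = 1:gridN, x = 1:gridN)
  rad <- sqrt((g$z - ctr)^2 + (g$y - ctr)^2 + (g$x - ctr)^2)
  gray <- highGray - (highGray - lowGray) * pnorm(rad, r, sigma)
  voxelVolume(array(round(gray), c(gridN, gridN, gridN)), voxelSize)
}

# blurred planar step edge: dark below, bright above edgeX (column axis)
blurredStepVolume <- function(edgeX, nCols = 40, side = 8, sigma = 2,
                              lowGray = 10000, highGray = 40000,
                              voxelSize = 0.1) {
  x <- array(rep(seq_len(nCols), each = side * side),
             c(side, side, nCols))
  gray <- lowGray + (highGray - lowGray) * pnorm(x, edgeX, sigma)
  voxelVolume(round(gray), voxelSize)
}

smallPhantomSpec <- function(...) {
  args <- list(shape = c(64L, 64L, 64L), nRoots = 1L,
               rootRadiusRange = c(0.5, 0.8), mineralFillFraction = 0.35,
               nDebris = 5L, debrisSizeRangeVoxels = c(30, 300))
  over <- list(...)
  args[names(over)] <- over
  do.call(phantomSpec, args)
}
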