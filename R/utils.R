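# internal helpers shared across modules

.maskInt <- function(mask) {
  d <- if (is(mask, "ROIMask")) mask@data else mask
  storage.mode(d) <- "integer"
  d
}

.checkSameShape <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("shape mismatch: ", paste(dim(a), collapse = "x"), " vs ",
         paste(dim(b), collapse = "x"))
  invisible(TRUE)
}

# 1-based (slice, row, column) coordinate matrix -> linear indices
.coordsToIdx <- function(coords, dims) {
  coords <- rbind(coords)
  if (any(coords < 1) || any(coords[, 1] > dims[1]) ||
      any(coords[, 2] > dims[2]) || any(coords[, 3] > dims[3]))
    stop("coordinates outside the volume")
  (coords[, 1] - 1) + dims[1] * ((coords[, 2] - 1) +
    dims[2] * (coords[, 3] - 1)) + 1
}

# linear indices -> 1-based (slice, row, column) matrix
.idxToCoords <- function(idx, dims) {
  i0 <- idx - 1
  z <- i0 %% dims[1]
  rest <- i0 %/% dims[1]
  y <- rest %% dims[2]
  x <- rest %/% dims[2]
  cbind(z + 1, y + 1, x + 1)
}

# run an expression with a locally seeded RNG, restoring global state
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
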