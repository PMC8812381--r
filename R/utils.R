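# internal helpers shared across modules

# Evaluate expr under a local RNG state. seed = NULL leaves the ambient
# stream untouched (caller manages reproducibility).
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) stats::runif(1)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(expr)
}

# Stable per-subject child seed from the root seed: adding subjects never
# perturbs existing ones. Kept strictly below 2^31.
subjectSeed <- function(rootSeed, subject) {
  as.integer((as.numeric(rootSeed) + 1000003 * as.numeric(subject)) %% 2147483647)
}

# Near-cubic integer factorisation of the voxel count into a 3-D grid
# (single slab, isotropic voxels). Falls back towards flatter grids when the
# count has no cubic-ish factorisation.
gridDims <- function(nVoxels) {
  n <- as.integer(nVoxels)
  stopifnot(n >= 1L)
  best <- c(n, 1L, 1L)
  bestScore <- Inf
  for (a in seq_len(floor(n^(1 / 3)) + 1L)) {
    if (n %% a != 0L) next
    m <- n %/% a
    for (b in seq_len(floor(sqrt(m)) + 1L)) {
      if (m %% b != 0L) next
      d <- sort(c(a, b, m %/% b), decreasing = TRUE)
      score <- d[1] / d[3]
      if (score < bestScore) {
        bestScore <- score
        best <- d
      }
    }
  }
  as.integer(best)
}

# Uniform draw from the closed interval [lo, hi] restricted to a fixed grid
# (grid step in the same units as the bounds). Values are rounded onto the
# grid so repeated serialisation is exact.
sampleOnGrid <- function(n, range, step = 0.1) {
  if (range[1] > range[2]) stop("invalid range: lower bound exceeds upper bound")
  k <- round((range[2] - range[1]) / step)
  vals <- range[1] + step * (0:k)
  vals[sample.int(length(vals), n, replace = TRUE)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
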