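# Internal helpers shared across modules.

# Evaluate expr under a fixed RNG state without disturbing the caller's
# stream; all package randomness flows through explicit seeds.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Voxel edge lengths in mm from a 4x4 affine (column norms of the 3x3 part).
voxelSizes <- function(affine) {
  sqrt(colSums(affine[1:3, 1:3]^2))
}

# Default scanner-style affine: scaled identity centred on the grid.
defaultAffine <- function(grid, voxel_size) {
  stopifnot(length(grid) == 3L)
  vs <- rep_len(voxel_size, 3L)
  aff <- diag(c(vs, 1))
  aff[1:3, 4] <- -vs * (grid - 1) / 2
  aff
}

# voxel (i,j,k) 1-based -> mm coordinates
voxelToMm <- function(affine, ijk) {
  ijk <- rbind(t(ijk) - 1, 1)
  t(affine %*% ijk)[, 1:3, drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
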