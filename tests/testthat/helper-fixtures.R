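# Shared fixtures: tiny scans, atlases and study configs built in code.

# scan whose in-mask voxels all carry the same series
constant_scan <- function(series, shape = c(4, 4, 2), tr = 1, mask = NULL) {
  nt <- length(series)
  data <- array(rep(series, each = prod(shape)), dim = c(shape, nt))
  bold_scan(data, tr_seconds = tr, mask = mask)
}

# scan from a voxel x time matrix over a given mask
matrix_scan <- function(Y, shape, tr = 1, mask = array(TRUE, shape), ...) {
  nt <- ncol(Y)
  flat <- matrix(0, prod(shape), nt)
  flat[as.vector(mask), ] <- Y
  bold_scan(array(flat, dim = c(shape, nt)), tr_seconds = tr, mask = mask, ...)
}

small_atlas <- function(R = 6, shape = c(14, 14, 8), seed = 42) {
  generate_atlas(R, shape, seed = seed)
}

# short-scan config for fast activation tests
quick_sim_config <- function(...) {
  phmri_sim_config(
    n_acquisitions = 120L, baseline_window = c(2L, 30L),
    response_window = c(90L, 119L), onset_acquisition = 35L,
    ramp_length = 30L, ...
  )
}

# smooth analytic "brain" intensity: evaluable at arbitrary continuous voxel
# coordinates (rows of `pts`, 1-based), so misregistered images can be
# sampled exactly rather than by double interpolation
brain_field <- function(pts, shape = c(24, 24, 16)) {
  ctr <- (shape + 1) / 2
  ax <- 0.42 * shape
  d2 <- ((pts[, 1] - ctr[1]) / ax[1])^2 + ((pts[, 2] - ctr[2]) / ax[2])^2 +
    ((pts[, 3] - ctr[3]) / ax[3])^2
  grad <- pts[, 1] / shape[1] + 0.5 * pts[, 2] / shape[2] +
    0.25 * pts[, 3] / shape[3]
  blob <- function(c1, c2, c3, w) {
    exp(-((pts[, 1] - c1 * shape[1])^2 + (pts[, 2] - c2 * shape[2])^2 +
      (pts[, 3] - c3 * shape[3])^2) / (2 * w^2))
  }
  tex <- 1 + 0.5 * grad + 0.8 * blob(0.35, 0.6, 0.45, 2.5) +
    0.6 * blob(0.62, 0.38, 0.55, 2)
  pmax(1 - d2, 0) * tex
}

grid_points <- function(shape) {
  as.matrix(expand.grid(
    x = seq_len(shape[1]), y = seq_len(shape[2]), z = seq_len(shape[3])
  ))
}

smooth_brain <- function(shape = c(24, 24, 16)) {
  array(brain_field(grid_points(shape), shape), dim = shape)
}

# image of the brain under `tf` (subject world -> reference world, unit
# voxels): subject voxel y carries the reference intensity at tf(y)
misregistered_brain <- function(tf, shape = c(24, 24, 16)) {
  pts <- grid_points(shape)
  world <- pts - 1
  mapped <- world %*% t(tf$matrix[1:3, 1:3]) +
    matrix(tf$matrix[1:3, 4], nrow(world), 3, byrow = TRUE)
  array(brain_field(mapped + 1, shape), dim = shape)
}

# adjusted Rand index between two labelings (independent of any package path)
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  (sum_ij - expected) / (maxi - expected)
}
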