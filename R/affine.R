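# Affine transforms (translation, rotation, scale — no shear), trilinear
# resampling into a target grid, and intensity-based affine registration.
#
# Conventions: voxel indices are 1-based in R; world coordinates are mm from
# the volume corner, world = (index - 1) * voxel_size. Transforms act on
# world coordinates and map SOURCE world -> TARGET world.

#' Build an affine transform
#'
#' Composes `translation . rotation . scale` about a given centre (the
#' centre is folded into the translation part of the 4x4 matrix, so the
#' transform still decomposes as translation-rotation-scale).
#'
#' @param translation mm, length 3.
#' @param rotation Euler angles (rad) about x, y, z, applied z–y–x.
#' @param scale Per-axis scale factors, length 3.
#' @param center Rotation/scaling centre in world mm.
#' @return Object of class `affine_transform` wrapping the 4x4 matrix.
#' @export
affine_transform <- function(translation = c(0, 0, 0), rotation = c(0, 0, 0),
                             scale = c(1, 1, 1), center = c(0, 0, 0)) {
  if (any(scale == 0)) abort("scale factors must be nonzero.")
  cx <- cos(rotation[1]); sx <- sin(rotation[1])
  cy <- cos(rotation[2]); sy <- sin(rotation[2])
  cz <- cos(rotation[3]); sz <- sin(rotation[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  RS <- Rx %*% Ry %*% Rz %*% diag(scale, 3)
  m <- diag(4)
  m[1:3, 1:3] <- RS
  m[1:3, 4] <- translation + center - RS %*% center
  new_affine(m, params = list(
    translation = translation, rotation = rotation,
    scale = scale, center = center
  ))
}

new_affine <- function(matrix, params = NULL) {
  if (abs(det(matrix[1:3, 1:3])) < 1e-12) abort("transform is singular.")
  structure(list(matrix = matrix, params = params), class = "affine_transform")
}

#' @export
print.affine_transform <- function(x, ...) {
  cat("<affine_transform>\n")
  print(round(x$matrix, 5))
  invisible(x)
}

#' Invert an affine transform
#' @param transform An `affine_transform`.
#' @return The inverse `affine_transform`.
#' @export
affine_invert <- function(transform) new_affine(solve(transform$matrix))

#' Compose affine transforms
#' @param a,b `affine_transform`s; the result applies `b` then `a`.
#' @return An `affine_transform`.
#' @export
affine_compose <- function(a, b) new_affine(a$matrix %*% b$matrix)

#' Resample a volume into a target grid by trilinear interpolation
#'
#' Each target voxel is inverse-mapped through `transform` (which maps source
#' world coordinates to target world coordinates) to a continuous source
#' location, and takes the trilinear interpolation of the eight surrounding
#' source voxels. Locations falling outside the source field of view are
#' returned as `NA` (missing, not zero), so downstream averages can exclude
#' them.
#'
#' @param volume 3D numeric array (source).
#' @param transform `affine_transform`, source world -> target world.
#' @param target_dim Target grid dimensions (length 3); defaults to the
#'   source dimensions.
#' @param source_voxel_size,target_voxel_size mm per axis.
#' @return 3D array of `target_dim` with `NA` outside the mapped field.
#' @export
resample_trilinear <- function(volume, transform, target_dim = dim(volume),
                               source_voxel_size = c(1, 1, 1),
                               target_voxel_size = source_voxel_size) {
  inv <- solve(transform$matrix)
  idx <- as.matrix(expand.grid(
    x = seq_len(target_dim[1]), y = seq_len(target_dim[2]),
    z = seq_len(target_dim[3])
  ))
  world <- sweep(idx - 1, 2, target_voxel_size, `*`)
  src_world <- world %*% t(inv[1:3, 1:3]) +
    matrix(inv[1:3, 4], nrow(world), 3, byrow = TRUE)
  src <- sweep(src_world, 2, source_voxel_size, `/`) + 1 # continuous voxel coord
  d <- dim(volume)
  i0 <- floor(src)
  f <- src - i0
  ok <- i0[, 1] >= 1 & i0[, 2] >= 1 & i0[, 3] >= 1 &
    i0[, 1] + 1 <= d[1] & i0[, 2] + 1 <= d[2] & i0[, 3] + 1 <= d[3]
  # allow exact hits on the far faces
  on_face <- function(a) {
    hit <- abs(src[, a] - d[a]) < 1e-9
    i0[hit, a] <<- d[a] - 1
    f[hit, a] <<- 1
    hit
  }
  face_ok <- on_face(1) | on_face(2) | on_face(3)
  ok <- ok | (face_ok &
    src[, 1] >= 1 - 1e-9 & src[, 1] <= d[1] + 1e-9 &
    src[, 2] >= 1 - 1e-9 & src[, 2] <= d[2] + 1e-9 &
    src[, 3] >= 1 - 1e-9 & src[, 3] <= d[3] + 1e-9 &
    i0[, 1] >= 1 & i0[, 2] >= 1 & i0[, 3] >= 1)
  out <- rep(NA_real_, nrow(idx))
  if (any(ok)) {
    i0k <- i0[ok, , drop = FALSE]
    fk <- f[ok, , drop = FALSE]
    lin <- function(dx, dy, dz) {
      volume[cbind(i0k[, 1] + dx, i0k[, 2] + dy, i0k[, 3] + dz)]
    }
    wx0 <- 1 - fk[, 1]; wy0 <- 1 - fk[, 2]; wz0 <- 1 - fk[, 3]
    out[ok] <-
      lin(0, 0, 0) * wx0 * wy0 * wz0 + lin(1, 0, 0) * fk[, 1] * wy0 * wz0 +
      lin(0, 1, 0) * wx0 * fk[, 2] * wz0 + lin(0, 0, 1) * wx0 * wy0 * fk[, 3] +
      lin(1, 1, 0) * fk[, 1] * fk[, 2] * wz0 +
      lin(1, 0, 1) * fk[, 1] * wy0 * fk[, 3] +
      lin(0, 1, 1) * wx0 * fk[, 2] * fk[, 3] +
      lin(1, 1, 1) * fk[, 1] * fk[, 2] * fk[, 3]
  }
  array(out, dim = target_dim)
}

# normalized correlation over jointly valid voxels
.ncc <- function(a, b) {
  ok <- is.finite(a) & is.finite(b)
  if (sum(ok) < 10) return(-1)
  a <- a[ok]; b <- b[ok]
  if (sd(a) == 0 || sd(b) == 0) return(-1)
  cor(a, b)
}

#' Intensity-based affine registration
#'
#' Estimates the 9-parameter transform (translation, rotation, per-axis
#' scale; no shear) mapping a subject volume into the reference frame, by
#' maximising the normalized correlation between the reference and the
#' resampled subject over a coarse-to-fine schedule: both images are
#' Gaussian-smoothed at decreasing widths and a Nelder-Mead direct search
#' refines the parameters at each level.
#'
#' @param subject_volume 3D numeric array to register.
#' @param reference 3D numeric array, or an [atlas_volume()] (its in-brain
#'   mask is used as the template image).
#' @param init `affine_transform` initial guess (default identity).
#' @param voxel_size mm per axis, shared by both grids.
#' @param levels Smoothing FWHMs (mm) for the coarse-to-fine schedule; the
#'   final 0 level refines on the unsmoothed images (smoothing does not
#'   commute with scaling, so a smoothed-only schedule leaves a small scale
#'   bias).
#' @param maxit Nelder-Mead iterations per level.
#' @return The fitted `affine_transform` (subject world -> reference world),
#'   with the final normalized correlation in `$metric`.
#' @export
register_affine <- function(subject_volume, reference,
                            init = affine_transform(),
                            voxel_size = c(1, 1, 1),
                            levels = c(4, 1, 0) * mean(voxel_size),
                            maxit = 400) {
  if (inherits(reference, "atlas_volume")) {
    voxel_size <- reference$voxel_size
    reference <- (reference$labels > 0) * 1
  }
  ctr <- (dim(reference) - 1) / 2 * voxel_size
  p0 <- c(
    init$params$translation %||% init$matrix[1:3, 4],
    init$params$rotation %||% c(0, 0, 0),
    log(init$params$scale %||% c(1, 1, 1))
  )
  make_tf <- function(p) {
    affine_transform(
      translation = p[1:3], rotation = p[4:6], scale = exp(p[7:9]),
      center = ctr
    )
  }
  # staged parameter blocks avoid translation/rotation trade-offs on
  # weakly textured images: translation first, then + scale, then all 9
  stages <- list(1:3, c(1:3, 7:9), 1:9)
  fit <- NULL
  for (fwhm in levels) {
    ref_s <- gaussian_smooth(reference, fwhm, voxel_size)
    sub_s <- gaussian_smooth(subject_volume, fwhm, voxel_size)
    for (idx in stages) {
      obj <- function(q) {
        p <- p0
        p[idx] <- q
        res <- resample_trilinear(sub_s, make_tf(p),
          target_dim = dim(ref_s),
          source_voxel_size = voxel_size
        )
        -.ncc(res, ref_s)
      }
      fit <- optim(p0[idx], obj,
        method = "Nelder-Mead",
        control = list(maxit = maxit, reltol = 1e-9)
      )
      p0[idx] <- fit$par
    }
  }
  metric <- -fit$value
  if (!is.finite(metric) || metric < 0.2) {
    abort(sprintf(
      "affine registration failed to converge (normalized correlation %.3f, convergence code %d)",
      metric, fit$convergence
    ))
  }
  out <- make_tf(p0)
  out$metric <- metric
  out
}

#' Write / read a transform as a plain-text 4x4 matrix
#' @param transform An `affine_transform`.
#' @param path File path.
#' @return `write_affine` returns the path invisibly; `read_affine` the
#'   transform.
#' @export
write_affine <- function(transform, path) {
  utils::write.table(transform$matrix, path,
    row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' @rdname write_affine
#' @export
read_affine <- function(path) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  dimnames(m) <- NULL
  new_affine(m)
}
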