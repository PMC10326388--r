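# Atlas container and the synthetic parcellation generator.

#' Atlas volume
#'
#' A 3D integer label image partitioning an ellipsoidal "brain" into named
#' regions. Label 0 is background; labels `1..R` are regions. This is the
#' coordinate frame all group-level results live in.
#'
#' @param labels 3D integer array, 0 = background.
#' @param voxel_size Numeric length-3, mm per axis; strictly positive.
#' @param region_names Data frame with columns `region_id`, `region_name`;
#'   defaults to `"region_<id>"` for every label present.
#'
#' @return An object of class `atlas_volume`: a list with elements `labels`,
#'   `voxel_size` and `region_names` (a tibble).
#' @export
atlas_volume <- function(labels, voxel_size = c(1, 1, 1), region_names = NULL) {
  labels <- as.array(labels)
  if (length(dim(labels)) != 3L) abort("`labels` must be a 3D array.")
  if (any(labels < 0) || any(labels != round(labels))) {
    abort("`labels` must contain non-negative integers.")
  }
  if (length(voxel_size) != 3L || any(voxel_size <= 0)) {
    abort("`voxel_size` must be 3 strictly positive values (mm).")
  }
  ids <- sort(unique(as.integer(labels[labels > 0])))
  if (length(ids) && !identical(ids, seq_len(max(ids)))) {
    # allow gaps but record them: regions absent from the image are "empty"
    ids <- seq_len(max(ids))
  }
  if (is.null(region_names)) {
    region_names <- tibble(
      region_id = ids,
      region_name = paste0("region_", ids)
    )
  } else {
    region_names <- as_tibble(region_names)
    stopifnot(all(c("region_id", "region_name") %in% names(region_names)))
  }
  present <- tabulate(as.integer(labels[labels > 0]), nbins = max(c(ids, 0L)))
  region_names$n_voxels <- present[region_names$region_id]
  region_names$empty <- region_names$n_voxels == 0L
  structure(
    list(
      labels = labels,
      voxel_size = as.numeric(voxel_size),
      region_names = region_names
    ),
    class = "atlas_volume"
  )
}

#' @export
print.atlas_volume <- function(x, ...) {
  cat(
    "<atlas_volume> ", paste(dim(x$labels), collapse = " x "),
    " voxels, ", nrow(x$region_names), " regions (",
    sum(!x$region_names$empty), " non-empty), voxel size ",
    paste(signif(x$voxel_size, 3), collapse = " x "), " mm\n",
    sep = ""
  )
  invisible(x)
}

#' Number of regions declared in an atlas
#' @param atlas An `atlas_volume`.
#' @return Integer count of declared regions.
#' @export
n_regions <- function(atlas) nrow(atlas$region_names)

# boolean in-brain mask: ellipsoid centred in the volume with semi-axes at
# 45% of each dimension
ellipsoid_mask <- function(shape) {
  ctr <- (shape + 1) / 2
  ax <- 0.45 * shape
  gx <- ((seq_len(shape[1]) - ctr[1]) / ax[1])^2
  gy <- ((seq_len(shape[2]) - ctr[2]) / ax[2])^2
  gz <- ((seq_len(shape[3]) - ctr[3]) / ax[3])^2
  d2 <- outer(outer(gx, gy, `+`), gz, `+`)
  d2 <= 1
}

#' Generate a synthetic parcellated atlas
#'
#' Partitions an ellipsoidal brain mask into `R` regions by nearest-seed
#' (Voronoi) assignment: `R` seed voxels are drawn uniformly from the in-brain
#' voxels and every in-brain voxel takes the label of its nearest seed
#' (Euclidean distance in voxel units, ties broken by the lower region id).
#' Region geometry is deliberately blocky rather than anatomical; the
#' statistics downstream only need a labelled partition with known membership.
#'
#' @param R Number of regions (>= 1). A rat-brain-style parcellation uses 173.
#' @param shape 3D voxel dimensions, each >= 4.
#' @param seed Integer seed; the partition is deterministic given it.
#' @param voxel_size mm per axis.
#'
#' @return An [atlas_volume()].
#' @examples
#' atl <- generate_atlas(R = 12, shape = c(16, 16, 8), seed = 1)
#' table(atl$labels[atl$labels > 0])
#' @export
generate_atlas <- function(R, shape, seed = 1L, voxel_size = c(1, 1, 1)) {
  if (R < 1) abort("`R` must be >= 1.")
  if (length(shape) != 3L || any(shape < 4)) abort("each `shape` dim must be >= 4.")
  mask <- ellipsoid_mask(shape)
  n_in <- sum(mask)
  if (R > n_in) abort("`R` exceeds the in-brain voxel count.")
  idx <- which(mask, arr.ind = TRUE)
  seeds <- with_preserved_seed(seed, idx[sample.int(n_in, R), , drop = FALSE])
  # nearest-seed assignment; loop over seeds keeps memory at O(n_in)
  best_d2 <- rep(Inf, n_in)
  lab <- integer(n_in)
  for (r in seq_len(R)) {
    d2 <- (idx[, 1] - seeds[r, 1])^2 +
      (idx[, 2] - seeds[r, 2])^2 +
      (idx[, 3] - seeds[r, 3])^2
    upd <- d2 < best_d2 # strict: ties keep the earlier (lower) id
    best_d2[upd] <- d2[upd]
    lab[upd] <- r
  }
  labels <- array(0L, dim = shape)
  labels[mask] <- lab
  atlas_volume(labels, voxel_size = voxel_size)
}

#' Per-region voxel counts
#' @param atlas An `atlas_volume`.
#' @return Tibble with `region_id`, `region_name`, `n_voxels`.
#' @export
region_sizes <- function(atlas) {
  atlas$region_names[, c("region_id", "region_name", "n_voxels")]
}
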