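# Resting-state generator: region (node) time courses drawn from a known
# covariance network, mapped onto atlas voxels with observation noise.

#' Configuration for the resting-state simulator
#'
#' @param n_timepoints Scan length in acquisitions (15-minute resting scans
#'   at TR 1 s give 150).
#' @param tr_seconds Repetition time (s).
#' @param node_covariance R x R symmetric positive-semidefinite matrix with
#'   unit diagonal: the generating covariance of the region time courses.
#' @param observation_noise_sd Standard deviation of independent voxel-level
#'   noise added on top of each region's course.
#'
#' @return A list of class `resting_sim_config`.
#' @export
resting_sim_config <- function(n_timepoints = 150L, tr_seconds = 1,
                               node_covariance, observation_noise_sd = 0.3) {
  node_covariance <- as.matrix(node_covariance)
  if (!isSymmetric(node_covariance, tol = 1e-8)) {
    abort("`node_covariance` must be symmetric.")
  }
  ev <- eigen(node_covariance, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev))) {
    abort("`node_covariance` must be positive semidefinite.")
  }
  if (max(abs(diag(node_covariance) - 1)) > 1e-8) {
    abort("`node_covariance` must have unit diagonal.")
  }
  structure(
    list(
      n_timepoints = as.integer(n_timepoints), tr_seconds = tr_seconds,
      node_covariance = node_covariance,
      observation_noise_sd = observation_noise_sd
    ),
    class = "resting_sim_config"
  )
}

#' Block covariance for a modular network
#'
#' Builds an R x R unit-diagonal covariance where nodes inside the same
#' module correlate at `within_r` and nodes in different modules at
#' `between_r`. Useful for planting resting-state networks with known
#' structure.
#'
#' @param R Number of nodes.
#' @param modules List of integer vectors of node ids (non-overlapping);
#'   nodes not listed form singletons.
#' @param within_r,between_r Correlations inside / across modules.
#' @return R x R covariance matrix.
#' @export
block_covariance <- function(R, modules, within_r = 0.2, between_r = 0) {
  sig <- matrix(between_r, R, R)
  for (m in modules) sig[m, m] <- within_r
  diag(sig) <- 1
  sig
}

# node courses: t x R matrix with the requested covariance (PSD-safe via
# eigen square root)
draw_node_series <- function(cfg) {
  sig <- cfg$node_covariance
  R <- ncol(sig)
  ed <- eigen(sig, symmetric = TRUE)
  L <- ed$vectors %*% diag(sqrt(pmax(ed$values, 0)), R)
  z <- matrix(rnorm(cfg$n_timepoints * R), ncol = R)
  z %*% t(L)
}

#' Simulate one resting-state subject
#'
#' Region time courses are drawn from `cfg$node_covariance`; every voxel of a
#' region carries its region's course plus independent Gaussian observation
#' noise. Nuisance series (motion parameters, tissue means) are attached so
#' the full preprocessing chain can run on the simulated scan.
#'
#' @param atlas An [atlas_volume()] with at least as many regions as the
#'   covariance has rows.
#' @param cfg A [resting_sim_config()]; `node_covariance` dimension must
#'   equal the number of atlas regions.
#' @param seed Integer seed.
#' @param subject_id Identifier stored on the scan.
#'
#' @return A list with `scan` (a [bold_scan()]) and `node_series`
#'   (t x R matrix of the generating courses, the ground truth).
#' @export
simulate_resting_subject <- function(atlas, cfg, seed,
                                     subject_id = paste0("rs_s", seed)) {
  R <- ncol(cfg$node_covariance)
  if (R != n_regions(atlas)) {
    abort("`node_covariance` dimension must equal the atlas region count.")
  }
  mask <- atlas$labels > 0
  lab_in <- as.integer(atlas$labels[mask])
  nt <- cfg$n_timepoints
  with_preserved_seed(seed, {
    courses <- draw_node_series(cfg) # t x R
    vox <- t(courses[, lab_in, drop = FALSE]) # voxel x t
    vox <- vox + matrix(rnorm(length(vox), sd = cfg$observation_noise_sd),
      nrow = nrow(vox)
    )
    flat <- matrix(0, nrow = prod(dim(mask)), ncol = nt)
    flat[as.vector(mask), ] <- vox
    data <- array(flat, dim = c(dim(mask), nt))
    motion <- matrix(cumsum(rnorm(nt * 6, sd = 0.002)), nrow = nt)
    tissue <- list(
      white_matter = rnorm(nt, sd = cfg$observation_noise_sd),
      csf = rnorm(nt, sd = cfg$observation_noise_sd)
    )
    scan <- bold_scan(
      data, tr_seconds = cfg$tr_seconds, mask = mask,
      motion_params = motion, tissue_means = tissue, subject_id = subject_id
    )
    list(scan = scan, node_series = courses)
  })
}
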