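# Synthetic phMRI generator: drug-challenge scans with known ground truth.
#
# Signal model per voxel v and acquisition t (percent units inside the
# parenthesis, multiplicative around a constant baseline level):
#   y[v, t] = level * (1 + (drift[t] + amp[v] * ramp[t] + noise[v, t]
#                           + spike[t]) / 100)
# ramp[] rises linearly from the injection acquisition to a plateau, so the
# response has reached its full amplitude long before the late response
# window used by the activation analysis. noise is stationary AR(1) with the
# requested marginal standard deviation. Motion spikes are global intensity
# deviations at flagged acquisitions; the pipeline scrubs by flag.

#' Configuration for the phMRI simulator
#'
#' Defaults mirror a 35-minute awake-rodent drug-challenge session: 350
#' acquisitions at TR 6 s, a 50-acquisition pre-injection baseline, analysis
#' windows at acquisitions 5--45 (baseline) and 300--345 (response), and a
#' drug response of a few percent in selected regions.
#'
#' @param n_acquisitions Scan length in acquisitions.
#' @param tr_seconds Repetition time (s).
#' @param baseline_window,response_window Inclusive acquisition index ranges
#'   (1-based) used downstream; kept in the config so the generator and the
#'   analysis agree on the design.
#' @param active_regions Integer region ids carrying the drug response.
#' @param amplitude_by_dose Named numeric: peak percent BOLD change per dose
#'   label. The default four-arm design (vehicle plus three doses with the
#'   middle dose strongest) gives the inverted-U dose-response shape.
#' @param onset_acquisition Injection acquisition: response is 0 before it.
#' @param ramp_length Acquisitions over which the response ramps linearly to
#'   its plateau.
#' @param noise_sd Marginal standard deviation of the AR(1) noise (percent).
#' @param ar1_coefficient Lag-1 autocorrelation of the noise, in `[0, 1)`.
#' @param drift_slope Linear drift (percent per acquisition).
#' @param motion_spike_prob Per-acquisition probability of a global motion
#'   spike (flagged outlier).
#' @param n_per_group Named integer: subjects per dose label.
#' @param baseline_level Baseline signal level (arbitrary units).
#'
#' @return A list of class `phmri_sim_config`.
#' @export
phmri_sim_config <- function(n_acquisitions = 350L,
                             tr_seconds = 6,
                             baseline_window = c(5L, 45L),
                             response_window = c(300L, 345L),
                             active_regions = integer(0),
                             amplitude_by_dose = c(
                               vehicle = 0, `1mg` = 0.5, `3mg` = 2, `10mg` = 0.5
                             ),
                             onset_acquisition = 50L,
                             ramp_length = 100L,
                             noise_sd = 1,
                             ar1_coefficient = 0.3,
                             drift_slope = 0,
                             motion_spike_prob = 0.02,
                             n_per_group = c(
                               vehicle = 6L, `1mg` = 7L, `3mg` = 7L, `10mg` = 7L
                             ),
                             baseline_level = 1000) {
  cfg <- list(
    n_acquisitions = as.integer(n_acquisitions), tr_seconds = tr_seconds,
    baseline_window = as.integer(baseline_window),
    response_window = as.integer(response_window),
    active_regions = as.integer(active_regions),
    amplitude_by_dose = amplitude_by_dose,
    onset_acquisition = as.integer(onset_acquisition),
    ramp_length = as.integer(ramp_length),
    noise_sd = noise_sd, ar1_coefficient = ar1_coefficient,
    drift_slope = drift_slope, motion_spike_prob = motion_spike_prob,
    n_per_group = n_per_group, baseline_level = baseline_level
  )
  windows_ok <- function(w) {
    length(w) == 2L && w[1] >= 1L && w[2] <= cfg$n_acquisitions && w[1] <= w[2]
  }
  if (!windows_ok(cfg$baseline_window) || !windows_ok(cfg$response_window)) {
    abort("analysis windows must lie within [1, n_acquisitions].")
  }
  if (cfg$noise_sd < 0) abort("`noise_sd` must be >= 0 (0 = noise-free).")
  if (cfg$ar1_coefficient < 0 || cfg$ar1_coefficient >= 1) {
    abort("`ar1_coefficient` must be in [0, 1).")
  }
  if (is.null(names(cfg$amplitude_by_dose))) {
    abort("`amplitude_by_dose` must be a named vector.")
  }
  if (!all(names(cfg$n_per_group) %in% names(cfg$amplitude_by_dose))) {
    abort("`amplitude_by_dose` must cover every dose label in `n_per_group`.")
  }
  structure(cfg, class = "phmri_sim_config")
}

# stationary AR(1) noise, one column per voxel; marginal sd = sd
ar1_noise <- function(nt, nvox, phi, sd, burn = 50L) {
  innov_sd <- sd * sqrt(1 - phi^2)
  e <- matrix(rnorm((nt + burn) * nvox, sd = innov_sd), nrow = nt + burn)
  if (phi > 0) {
    x <- stats::filter(e, phi, method = "recursive")
    x <- matrix(as.numeric(x), nrow = nt + burn)
  } else {
    x <- e
  }
  x[burn + seq_len(nt), , drop = FALSE]
}

#' Simulate one phMRI subject with ground truth
#'
#' @param atlas An [atlas_volume()]; the in-brain mask and region membership
#'   come from its labels.
#' @param cfg A [phmri_sim_config()].
#' @param dose Dose label; must appear in `cfg$amplitude_by_dose`.
#' @param seed Integer seed; output is deterministic given it.
#' @param subject_id Identifier stored on the scan.
#'
#' @return A list with elements `scan` (a [bold_scan()]; motion spikes are
#'   already flagged in `outlier_flags`) and `truth` (class `phmri_truth`:
#'   `active_voxel_mask`, `amplitude_map` in percent, `dose_label`,
#'   `spike_flags`).
#' @examples
#' atl <- generate_atlas(6, c(12, 12, 8), seed = 1)
#' cfg <- phmri_sim_config(active_regions = 2, n_acquisitions = 60,
#'                         baseline_window = c(2, 20),
#'                         response_window = c(40, 59))
#' sim <- simulate_phmri_subject(atl, cfg, dose = "3mg", seed = 7)
#' sim$scan
#' @export
simulate_phmri_subject <- function(atlas, cfg, dose, seed,
                                   subject_id = paste0(dose, "_s", seed)) {
  if (!dose %in% names(cfg$amplitude_by_dose)) {
    abort(paste0("dose label '", dose, "' absent from `amplitude_by_dose`."))
  }
  extra <- setdiff(cfg$active_regions, atlas$region_names$region_id)
  if (length(extra)) {
    abort(paste0("active regions not in atlas: ", paste(extra, collapse = ", ")))
  }
  nt <- cfg$n_acquisitions
  mask <- atlas$labels > 0
  lab_in <- as.integer(atlas$labels[mask])
  nvox <- length(lab_in)
  amp <- cfg$amplitude_by_dose[[dose]]
  amp_vox <- ifelse(lab_in %in% cfg$active_regions, amp, 0)

  tt <- seq_len(nt)
  ramp <- pmin(pmax((tt - cfg$onset_acquisition) / max(cfg$ramp_length, 1L), 0), 1)
  drift <- cfg$drift_slope * (tt - 1)

  with_preserved_seed(seed, {
    noise <- ar1_noise(nt, nvox, cfg$ar1_coefficient, cfg$noise_sd)
    spikes <- runif(nt) < cfg$motion_spike_prob
    spike_pct <- numeric(nt)
    spike_pct[spikes] <- sample(c(-1, 1), sum(spikes), replace = TRUE) *
      runif(sum(spikes), 4, 8)

    # percent deviation, acquisitions x voxels
    pct <- noise + outer(ramp, amp_vox) + drift + spike_pct
    series <- cfg$baseline_level * (1 + pct / 100)

    motion <- matrix(cumsum(rnorm(nt * 6, sd = 0.002)), nrow = nt)
    motion[spikes, ] <- motion[spikes, ] +
      matrix(rnorm(sum(spikes) * 6, sd = 0.3), ncol = 6)
    tissue <- list(
      white_matter = cfg$baseline_level *
        (1 + ar1_noise(nt, 1L, cfg$ar1_coefficient, cfg$noise_sd)[, 1] / 100),
      csf = cfg$baseline_level *
        (1 + ar1_noise(nt, 1L, cfg$ar1_coefficient, cfg$noise_sd)[, 1] / 100)
    )

    data <- array(0, dim = c(dim(mask), nt))
    flat <- matrix(0, nrow = prod(dim(mask)), ncol = nt)
    flat[as.vector(mask), ] <- t(series)
    data <- array(flat, dim = c(dim(mask), nt))

    scan <- bold_scan(
      data, tr_seconds = cfg$tr_seconds, mask = mask,
      motion_params = motion, outlier_flags = spikes,
      tissue_means = tissue, subject_id = subject_id
    )
    amp_map <- array(0, dim = dim(mask))
    amp_map[mask] <- amp_vox
    truth <- structure(
      list(
        active_voxel_mask = amp_map != 0,
        amplitude_map = amp_map,
        dose_label = dose,
        spike_flags = spikes
      ),
      class = "phmri_truth"
    )
    list(scan = scan, truth = truth)
  })
}

#' Simulate a complete multi-dose phMRI study
#'
#' Draws one subject per row of the group design in `cfg$n_per_group`, each
#' with its own seed derived from `seed`.
#'
#' @inheritParams simulate_phmri_subject
#' @param seed Master seed; per-subject seeds are drawn from it.
#' @return A list with `subjects` (named list of `simulate_phmri_subject()`
#'   results) and `manifest`, a tibble with `subject_id`, `dose`, `seed`.
#' @export
simulate_phmri_study <- function(atlas, cfg, seed = 1L) {
  design <- rep(names(cfg$n_per_group), times = cfg$n_per_group)
  n <- length(design)
  sub_seeds <- with_preserved_seed(seed, sample.int(2^31 - 2, n))
  ids <- paste0("sub", formatC(seq_len(n), width = 2, flag = "0"))
  subjects <- purrr::pmap(
    list(design, sub_seeds, ids),
    function(dose, s, id) simulate_phmri_subject(atlas, cfg, dose, s, id)
  )
  names(subjects) <- ids
  list(
    subjects = subjects,
    manifest = tibble(subject_id = ids, dose = design, seed = sub_seeds)
  )
}
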